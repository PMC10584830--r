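test_that("reverse_complement is the antiparallel Watson-Crick involution", {
  expect_equal(reverse_complement("AACG"), "CGTT")
  expect_equal(reverse_complement("aacg"), "CGTT")
  expect_equal(reverse_complement(c("A", "GATTACA")), c("T", "TGTAATC"))
  expect_error(reverse_complement("AXCG"), "outside")
  expect_error(reverse_complement(""), "non-empty")
  set.seed(11)
  for (r in 1:20) {
    s <- random_seq(sample(1:40, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("compile_network concatenates tokens and complements correctly", {
  d <- oligo_design(variable = c(a = "AACG"),
                    oligomers = list(X = "a", Y = "a*"))
  net <- compile_network(d)
  expect_equal(unname(net$oligomers), c("AACG", "CGTT"))
  # provenance covers every base exactly once and round-trips to the token
  pt <- provenance_table(net)
  expect_equal(nrow(pt), 8L)
  expect_true(all(table(pt$oligomer) == 4L))
  a_seq <- chars("AACG")
  for (r in seq_len(nrow(pt))) {
    base_in_domain <- a_seq[pt$domain_pos[r]]
    expect_equal(pt$base[r],
                 if (pt$complement[r]) COMP[[base_in_domain]] else
                   base_in_domain)
  }
})

test_that("the three-strand model system compiles to 49/49/41-mers", {
  net <- compile_network(model_system_design(seed = 1))
  expect_equal(unname(nchar(net$oligomers[c("S1", "S2", "S3")])),
               c(49L, 49L, 41L))
  # alpha composition is fixed: 10 C, 10 G, 10 A, 11 T
  alpha <- net$design$variable[["a"]]
  expect_equal(unname(table(chars(alpha))[c("A", "C", "G", "T")]),
               c(10L, 10L, 10L, 11L), ignore_attr = TRUE)
  expect_equal(net$design$fixed[["b"]], "TCTCCATG")
  # S2 is the reverse complement of S1, so the intended duplex is full length
  expect_equal(net$oligomers[["S2"]],
               reverse_complement(net$oligomers[["S1"]]))
})

test_that("design constructor validates names, tokens, and alphabets", {
  expect_error(oligo_design(variable = c(a = "ACGU"),
                            oligomers = list(X = "a")), "outside")
  expect_error(oligo_design(fixed = c(a = "AC"), variable = c(a = "GT"),
                            oligomers = list(X = "a")), "duplicate domain")
  expect_error(oligo_design(variable = c(a = "AC"),
                            oligomers = list(X = "b")), "undeclared")
  expect_error(oligo_design(variable = c(a = "AC"),
                            oligomers = list(X = "a", X = "a")),
               "duplicate oligomer")
})

test_that("random networks are uniform, reproducible, and design-free", {
  n1 <- random_network(1, 8, seed = 3)
  expect_equal(length(n1$oligomers), 1L)
  expect_equal(nchar(n1$oligomers[[1]]), 8L)
  expect_identical(random_network(3, 10, seed = 42)$oligomers,
                   random_network(3, 10, seed = 42)$oligomers)
  # base frequencies ~ 1/4 within 3 binomial sigmas over 1e5 draws
  big <- random_network(10, 10000, seed = 7)
  counts <- table(chars(paste(big$oligomers, collapse = "")))
  p <- counts / 1e5
  expect_true(all(abs(p - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
  # no intentional duplexes: every run is unnecessary
  pr <- duplex_profile(random_network(2, 12, seed = 5))
  expect_true(all(!pr$run_hist$necessary))
})

test_that("design files round-trip byte-stably and report parse errors", {
  dir <- withr::local_tempdir()
  d <- model_system_design(seed = 2)
  pars <- list(CPL = 100000, GPC = 1, NDPM = 1, NL = 8, NMPC = 1)
  paths <- write_design(d, dir, pars)
  parsed <- parse_design(paths[1], paths[2], paths[3], paths[4])
  expect_equal(parsed$design$fixed, d$fixed)
  expect_equal(parsed$design$variable, d$variable)
  expect_equal(parsed$design$oligomers, d$oligomers)
  expect_equal(parsed$parameters$CPL, 100000)
  # canonical rewrite is byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- write_design(parsed$design, dir2, pars)
  for (f in 2:4) {
    expect_identical(readLines(paths2[f]), readLines(paths[f]))
  }
  # defaults fill in for an empty parameters file
  writeLines("# nothing", paths[1])
  expect_equal(parse_design(paths[1], paths[2], paths[3],
                            paths[4])$parameters$CPL, 100000L)
  # unknown keys warn, bad syntax errors with the line number
  writeLines("FOO=1", paths[1])
  expect_warning(parse_design(paths[1], paths[2], paths[3], paths[4]),
                 "unknown parameter")
  writeLines("not a key value", paths[1])
  expect_error(parse_design(paths[1], paths[2], paths[3], paths[4]),
               "line 1")
  expect_error(parse_design(paths[1], paths[2], file.path(dir, "nope.txt"),
                            paths[4]), "variable")
})

test_that("FASTA export has one named record per oligomer", {
  net <- compile_network(oligo_design(variable = c(a = "AACG"),
                                      oligomers = list(X = "a", Y = "a*")))
  expect_equal(write_fasta(net), ">X\nAACG\n>Y\nCGTT\n")
  long <- compile_network(oligo_design(
    variable = c(v = paste(rep("ACGT", 30), collapse = "")),
    oligomers = list(Z = "v")))
  txt <- write_fasta(long, width = 80)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], ">Z")
  expect_true(all(nchar(lines[-1]) <= 80))
  expect_equal(paste(lines[-1], collapse = ""), long$oligomers[["Z"]])
})
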
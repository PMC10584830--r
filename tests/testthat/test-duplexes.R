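single_net <- function(s) {
  compile_network(oligo_design(variable = c(v = s), oligomers = list(S = "v")))
}

pair_net <- function(a, b) {
  compile_network(oligo_design(variable = c(va = a, vb = b),
                               oligomers = list(A = "va", B = "vb")))
}

test_that("intra enumeration matches hand-derived examples", {
  expect_equal(nrow(enumerate_intra(single_net("AAAA"), "S")), 0L)
  at <- enumerate_intra(single_net("AT"), "S")
  expect_equal(at$length, 1L)
  expect_equal(at$start_a, 1L)
  expect_equal(at$start_b, 2L)
  g <- enumerate_intra(single_net("GGGAAACCC"), "S")
  expect_equal(sort(g$length, decreasing = TRUE), c(3L, 2L, 2L, 1L, 1L))
  top <- g[g$length == 3L, ]
  expect_equal(top$start_a, 1L) # G1..G3 against C7..C9
  expect_equal(top$start_b, 7L)
})

test_that("inter enumeration matches hand-derived examples", {
  net <- pair_net("AT", "AT")
  self <- enumerate_inter(net, "A", "A")
  expect_equal(self$length, 2L) # the self-complementary register, once
  xy <- enumerate_inter(pair_net("AACG", "CGTT"), "A", "B")
  expect_equal(sort(xy$length, decreasing = TRUE), c(4L, 1L, 1L))
  expect_equal(nrow(enumerate_inter(pair_net("AAAA", "CCCC"), "A", "B")), 0L)
})

test_that("enumeration equals the brute-force oracle on random networks", {
  set.seed(301)
  for (rep in 1:40) {
    i <- sample(1:4, 1)
    j <- sample(2:12, 1)
    net <- random_network(i, j)
    nms <- names(net$oligomers)
    for (o in nms) {
      got <- enumerate_intra(net, o)
      expect_equal(sorted_runs(got), oracle_intra(net$oligomers[[o]]),
                   ignore_attr = TRUE)
    }
    a <- sample(nms, 1); b <- sample(nms, 1)
    got <- enumerate_inter(net, a, b)
    expect_equal(sorted_runs(got),
                 oracle_inter(net$oligomers[[a]], net$oligomers[[b]]),
                 ignore_attr = TRUE)
  }
})

test_that("inter enumeration is symmetric in its arguments", {
  set.seed(302)
  for (rep in 1:10) {
    net <- random_network(2, 9)
    ab <- enumerate_inter(net, "X1", "X2")
    ba <- enumerate_inter(net, "X2", "X1")
    expect_equal(nrow(ab), nrow(ba))
    if (nrow(ab)) {
      # role swap: a run pairing a[p..] with b[q-L+1..q] appears in the
      # swapped call with the roles of the two segments exchanged
      swapped <- data.frame(start_a = ba$start_b, start_b = ba$start_a,
                            length = ba$length)
      expect_equal(sorted_runs(ab),
                   swapped[order(swapped$start_a, swapped$start_b,
                                 swapped$length), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("a strand's self-alignment embeds each intra run twice", {
  set.seed(303)
  for (rep in 1:20) {
    s <- random_seq(sample(4:14, 1))
    net <- single_net(s)
    intra_score <- oracle_score(enumerate_intra(net, "S")$length)
    self_score <- oracle_score(enumerate_inter(net, "S", "S")$length)
    expect_gte(self_score, 2 * intra_score)
  }
})

test_that("necessary classification follows domain provenance", {
  net <- compile_network(oligo_design(variable = c(a = "AACG"),
                                      oligomers = list(X = "a", Y = "a*")))
  xy <- enumerate_inter(net, "X", "Y")
  expect_equal(xy$necessary, xy$length == 4L) # intended run only
  expect_true(all(!enumerate_inter(net, "X", "X")$necessary))
  expect_true(all(!enumerate_intra(net, "X")$necessary))
  # a domain shared across oligomers: both intended pairings are necessary
  ms <- compile_network(model_system_design(seed = 4))
  s1s2 <- enumerate_inter(ms, "S1", "S2")
  expect_true(any(s1s2$necessary & s1s2$length == 49L))
  s3s2 <- enumerate_inter(ms, "S3", "S2")
  expect_true(any(s3s2$necessary & s3s2$length == 41L))
})

test_that("profiles aggregate runs and windows consistently", {
  net <- compile_network(oligo_design(variable = c(a = "AACG"),
                                      oligomers = list(X = "a", Y = "a*")))
  prof <- duplex_profile(net)
  expect_equal(prof$largest_unnecessary_intra, 1L)
  expect_equal(prof$largest_unnecessary_inter, 2L)
  # window counts: a maximal run of length M yields M-L+1 windows of length L
  wh <- prof$window_hist
  inter_all <- tapply(wh$count[wh$kind == "inter"], wh$L[wh$kind == "inter"],
                      sum)
  expect_equal(as.numeric(inter_all[c("1", "2", "3", "4")]), c(10, 5, 2, 1))
  # internal consistency: profile window score equals the fitness N and O
  fr <- fitness(net, x = 1)
  expect_equal(score_windows(wh[wh$kind == "inter", ]), fr$N)
  expect_equal(score_windows(wh[wh$kind == "intra", ]), fr$O)
  expect_equal(score_windows(wh[wh$kind == "inter" & !wh$necessary, ]),
               fr$delta_N)
  expect_equal(score_windows(wh[wh$kind == "intra" & !wh$necessary, ]),
               fr$delta_O)
})

test_that("a poly-A network yields an all-zero profile", {
  prof <- duplex_profile(single_net("AAAAAAAA"))
  expect_equal(nrow(prof$run_hist), 0L)
  expect_equal(prof$largest_unnecessary_intra, 0L)
  expect_equal(prof$largest_unnecessary_inter, 0L)
})

test_that("random 16-mers mostly carry a 3-bp intra run", {
  set.seed(304)
  largest <- replicate(300, {
    runs <- enumerate_intra(single_net(random_seq(16)), "S")
    if (nrow(runs)) max(runs$length) else 0L
  })
  expect_gte(median(largest), 3)
})

test_that("profile reports serialize with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  net <- compile_network(model_system_design(seed = 3))
  write_profile_report(duplex_profile(net), path)
  txt <- readLines(path)
  expect_true(any(grepl("^kind\tnecessary\tL\trun_count\twindow_count",
                        txt)))
  expect_true(any(grepl("largest_unnecessary_intra", txt)))
})
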
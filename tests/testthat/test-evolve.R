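test_that("mutations conserve domain length and base composition", {
  set.seed(501)
  net <- compile_network(model_system_design())
  comp0 <- lapply(net$design$variable, function(s) sort(chars(s)))
  for (rep in 1:200) {
    net <- mutate_network(net)
    comp <- lapply(net$design$variable, function(s) sort(chars(s)))
    expect_identical(comp, comp0)
  }
  # fixed domains never change
  expect_equal(net$design$fixed[["b"]], "TCTCCATG")
})

test_that("length-1 domains make mutation the identity", {
  net <- compile_network(oligo_design(variable = c(v = "A"),
                                      oligomers = list(S = "v")))
  set.seed(502)
  expect_identical(mutate_network(net)$oligomers, net$oligomers)
})

test_that("mutating a design with no variable domains is an error", {
  net <- compile_network(oligo_design(fixed = c(f = "ACGT"),
                                      oligomers = list(S = "f")))
  expect_error(mutate_network(net), "variable")
})

test_that("optimization is deterministic, monotone, and composition-safe", {
  d <- independent_duplex_design(2, seed = 31)
  cfg <- evolver_config(CPL = 120, NL = 4, seed = 99)
  r1 <- optimize_network(d, cfg)
  r2 <- optimize_network(d, cfg)
  expect_identical(r1$best_network$oligomers, r2$best_network$oligomers)
  expect_identical(r1$trajectory, r2$trajectory)
  # trajectory of best-so-far scores never increases
  expect_true(all(diff(r1$trajectory) <= 0))
  expect_equal(r1$best_score, min(r1$trajectory))
  expect_lte(r1$best_score, r1$initial_score)
  # per-domain composition preserved end to end
  expect_identical(lapply(r1$best_network$design$variable,
                          function(s) sort(chars(s))),
                   lapply(d$variable, function(s) sort(chars(s))))
})

test_that("accepted networks always satisfy the homopolymer limits", {
  d <- single_duplex_design(20, seed = 7)
  res <- optimize_network(d, evolver_config(CPL = 200, NL = 4, seed = 12))
  expect_true(validity_check(res$best_network)$pass)
})

test_that("incremental rescoring is exact (matches a full recomputation)", {
  set.seed(503)
  for (s in 1:3) {
    d <- model_system_design(seed = s)
    res <- optimize_network(d, evolver_config(CPL = 60, NL = 2, seed = s,
                                              scoringWeightX = 1))
    fr <- fitness(res$best_network, x = 1)
    expect_equal(res$best_score, fr$delta_W)
  }
})

test_that("the optimizer reaches the brute-force optimum on a tiny domain", {
  # one 6-mer duplex: exhaustive search over all distinct permutations of
  # the domain gives the true minimum of dW_1
  base <- "ACGTCA"
  perm_all <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perm_all(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    }
    out
  }
  seqs <- unique(vapply(perm_all(chars(base)), paste, character(1),
                        collapse = ""))
  best_true <- min(vapply(seqs, function(s) {
    net <- compile_network(oligo_design(variable = c(a = s),
                                        oligomers = list(X = "a", Y = "a*")))
    fitness(net, x = 1)$delta_W
  }, numeric(1)))
  d <- oligo_design(variable = c(a = base),
                    oligomers = list(X = "a", Y = "a*"))
  res <- optimize_network(d, evolver_config(CPL = 400, NL = 4,
                                            scoringWeightX = 1, seed = 21))
  expect_equal(res$best_score, best_true)
})

test_that("rule satisfaction is reachable for small independent duplexes", {
  res <- optimize_network(independent_duplex_design(2, seed = 3),
                          evolver_config(CPL = 500, NL = 8, seed = 11))
  expect_true(rule_check(res$best_network)$pass)
})

test_that("scoring-length tuning drives the model system to the rule", {
  # raising the scoring length criteria (intra 3, inter 5) makes every
  # rule-violating duplex the only scored structure; the optimizer then
  # reaches objective zero, i.e. a rule-satisfying network
  res <- optimize_network(model_system_design(seed = 1),
                          evolver_config(CPL = 2500, NL = 8,
                                         intraSLC = 3, interSLC = 5,
                                         scoringWeightX = 1e6, seed = 51))
  expect_equal(res$best_score, 0)
  rc <- rule_check(res$best_network)
  expect_true(rc$pass)
  expect_lte(rc$largest_unnecessary_inter, 4L)
})

test_that("infeasible homopolymer limits fail with a clear error", {
  d <- oligo_design(variable = c(a = "CCCCCC"),
                    oligomers = list(X = "a", Y = "a*"))
  expect_error(optimize_network(d, evolver_config(CPL = 10, NL = 2,
                                                  seed = 1)),
               "homopolymer")
})

test_that("the size-search protocol follows double-then-increment growth", {
  # deterministic stand-in generators exercise the protocol arithmetic via
  # the exported search with the random generator on trivially passing and
  # failing systems
  set.seed(504)
  # a single 8-bp duplex virtually always passes; search must return >= 8
  r <- largest_satisfiable_search("single-duplex", "random")
  expect_gte(r$size, 8L)
  expect_true(all(diff(r$history$size) > 0 | !r$history$pass[-nrow(r$history)]))
  # sizes double while passing
  passes <- r$history[r$history$pass, "size"]
  if (length(passes) >= 2) {
    doubling <- passes[passes %in% (8L * 2L^(0:10))]
    expect_true(all(diff(doubling) == doubling[-length(doubling)]))
  }
})

test_that("the optimizer generator outgrows random assignment", {
  set.seed(505)
  rnd <- largest_satisfiable_search("single-duplex", "random")$size
  set.seed(505)
  opt <- largest_satisfiable_search(
    "single-duplex", "optimizer",
    config = evolver_config(CPL = 150, NL = 4, intraSLC = 3, interSLC = 5,
                            scoringWeightX = 1e6))$size
  expect_gt(opt, rnd)
})
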
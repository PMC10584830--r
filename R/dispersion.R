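# Kinetic-dispersion statistics.  Dispersion of a set of rate constants is
# quantified as the interquartile range of their natural logarithms (IQRNL):
# robust to outliers, scale-invariant, and insensitive to the outer 50% of
# the data, but negatively biased at small sample sizes, so estimates are
# only compared between equal-sized sub-populations.

#' Interquartile range of log rate constants (IQRNL)
#'
#' `Q75 - Q25` of `ln(k)` using linearly interpolated (type 7) quantiles.
#' Scale-invariant: multiplying all rate constants by a common factor leaves
#' the value unchanged.
#'
#' @param ks Numeric vector of rate constants (all > 0, length >= 2).
#' @return The IQRNL (natural-log units).
#' @examples
#' iqrnl(exp(0:3)) # 1.5
#' @export
iqrnl <- function(ks) {
  if (length(ks) < 2L) stop("need at least 2 rate constants", call. = FALSE)
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("rate constants must be positive and finite", call. = FALSE)
  }
  q <- quantile(log(ks), c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

# score one record's oligomer set: each oligomer its own variable domain, no
# intended duplexes
score_record_sequences <- function(seqs, x = 10000) {
  seqs <- strsplit(seqs, ",", fixed = TRUE)[[1]]
  seqs <- trimws(seqs[nzchar(trimws(seqs))])
  vars <- stats::setNames(seqs, paste0("v", seq_along(seqs)))
  oligs <- stats::setNames(as.list(names(vars)), paste0("S", seq_along(seqs)))
  fitness(compile_network(oligo_design(variable = vars, oligomers = oligs)),
          x = x)
}

record_scores <- function(records, score, x) {
  col <- switch(score, dO = "dO", dN = "dN", dW = "dW")
  if (col %in% names(records)) return(records[[col]])
  if (!"sequences" %in% names(records)) {
    stop("records have neither a precomputed ", col,
         " column nor a sequences column", call. = FALSE)
  }
  vapply(records$sequences, function(s) {
    fr <- score_record_sequences(s, x)
    switch(score, dO = fr$delta_O, dN = fr$delta_N, dW = fr$delta_W)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Select the most-fit sub-population of rate-constant records
#'
#' Ranks records by an above-baseline fitness score (smaller = fewer
#' unnecessary duplexes) and returns the `n` best. Scores are taken from a
#' precomputed column (`dO`, `dN`, `dW`) when present, otherwise computed
#' from the `sequences` column. Ties are broken by ascending `sample_id` for
#' determinism.
#'
#' @param records Data.frame of rate-constant records (see
#'   [read_rate_table()]).
#' @param score `"dO"`, `"dN"`, or `"dW"`.
#' @param n Sub-population size.
#' @param x Weight used when `score = "dW"`.
#' @return The selected rows, with a `fitness_score` column appended.
#' @export
select_fit_subpop <- function(records, score = c("dO", "dN", "dW"), n,
                              x = 10000) {
  score <- match.arg(score)
  if (n > nrow(records)) {
    stop("n exceeds the number of records", call. = FALSE)
  }
  sc <- record_scores(records, score, x)
  ord <- order(sc, records$sample_id)
  out <- records[ord[seq_len(n)], , drop = FALSE]
  out$fitness_score <- sc[ord[seq_len(n)]]
  out
}

new_dispersion_estimate <- function(p, n, normalized = NULL) {
  structure(list(p25 = p[[1]], p50 = p[[2]], p75 = p[[3]], n = n,
                 normalized = normalized),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Dispersion estimate (n = %d): IQRNL %.4g [%.4g, %.4g]\n",
              x$n, x$p50, x$p25, x$p75))
  if (!is.null(x$normalized)) {
    cat(sprintf("  normalized to random-selection median: %.3g\n",
                x$normalized))
  }
  invisible(x)
}

#' Bootstrap dispersion of the most-fit sub-population
#'
#' Selects the `n` most-fit records, resamples their rate constants with
#' replacement `B` times, computes the IQRNL of each resample, and reports
#' the 25th/50th/75th percentiles of those bootstrap values.
#'
#' @inheritParams select_fit_subpop
#' @param B Bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @return A `dispersion_estimate` (percentiles `p25 <= p50 <= p75`).
#' @export
bootstrap_dispersion_fit <- function(records, score = c("dO", "dN", "dW"),
                                     n, B = 1000L, x = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- select_fit_subpop(records, score, n, x)
  boots <- cpp_iqrnl_boot(log(sub$k), as.integer(n), as.integer(B))
  new_dispersion_estimate(quantile(boots, c(0.25, 0.5, 0.75), names = FALSE),
                          n)
}

#' Bootstrap dispersion of random sub-populations
#'
#' Draws `R` random sub-populations of size `n` (without replacement); for
#' each, computes `B` bootstrap IQRNL values and their 25th/50th/75th
#' percentiles; reports the median of each percentile across the `R` draws.
#'
#' @inheritParams bootstrap_dispersion_fit
#' @param R Outer random draws (default 1000).
#' @return A `dispersion_estimate`.
#' @export
bootstrap_dispersion_random <- function(records, n, B = 1000L, R = 1000L,
                                        seed = NULL) {
  if (n > nrow(records)) stop("n exceeds the number of records",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lnk <- log(records$k)
  pcts <- matrix(0, R, 3)
  for (r in seq_len(R)) {
    draw <- lnk[sample.int(length(lnk), n)]
    boots <- cpp_iqrnl_boot(draw, as.integer(n), as.integer(B))
    pcts[r, ] <- quantile(boots, c(0.25, 0.5, 0.75), names = FALSE)
  }
  new_dispersion_estimate(apply(pcts, 2, median), n)
}

#' Relative dispersion reduction
#'
#' Percentage reduction of the fit sub-population's median bootstrap IQRNL
#' relative to the random-selection median: `100 * (1 - fit$p50/random$p50)`.
#' Bounds come from the fit estimate's 25th/75th percentiles normalized by
#' the same random median. Negative values mean the fit sub-population is
#' more dispersed than random.
#'
#' @param fit,random `dispersion_estimate` objects.
#' @return List: `reduction` (percent), `lower`, `upper` (percent bounds),
#'   `normalized` (fit p50 / random p50).
#' @export
relative_dispersion <- function(fit, random) {
  stopifnot(inherits(fit, "dispersion_estimate"),
            inherits(random, "dispersion_estimate"))
  if (!is.finite(random$p50) || random$p50 <= 0) {
    stop("random-selection median dispersion is zero; reduction undefined",
         call. = FALSE)
  }
  list(reduction = 100 * (1 - fit$p50 / random$p50),
       lower = 100 * (1 - fit$p75 / random$p50),
       upper = 100 * (1 - fit$p25 / random$p50),
       normalized = fit$p50 / random$p50)
}

# two-sample Anderson-Darling (Scholz-Stephens A2akN for k = 2) with a
# Monte-Carlo permutation p-value; no installed package provides this test
ad2_stat <- function(x, y) {
  z <- sort(c(x, y))
  n <- length(x); m <- length(y); N <- n + m
  a2 <- 0
  for (s in list(x, y)) {
    ni <- length(s)
    Mij <- vapply(z[-N], function(t) sum(s <= t), numeric(1))
    jj <- seq_len(N - 1)
    a2 <- a2 + (1 / ni) * sum((N * Mij - ni * jj)^2 / (jj * (N - jj)))
  }
  a2 / N
}

#' Two-sample distribution test on log rate constants
#'
#' Tests whether two groups of rate constants share an underlying
#' distribution, on the `ln(k)` scale. `"KS"` is the two-sample
#' Kolmogorov-Smirnov test, `"Wilcoxon"` the rank-sum test, `"AD"` the
#' two-sample Anderson-Darling statistic with a permutation p-value.
#' P-values are reported raw (no multiplicity correction).
#'
#' @param sub,rest Numeric vectors of rate constants (> 0).
#' @param method `"KS"`, `"Wilcoxon"`, or `"AD"`.
#' @param n_perm Permutations for the AD p-value (default 999).
#' @param seed Optional seed for the permutation test.
#' @return The p-value.
#' @export
distribution_test <- function(sub, rest, method = c("KS", "Wilcoxon", "AD"),
                              n_perm = 999L, seed = NULL) {
  method <- match.arg(method)
  if (length(sub) == 0L || length(rest) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  x <- log(sub); y <- log(rest)
  if (method == "KS") {
    return(suppressWarnings(ks.test(x, y))$p.value)
  }
  if (method == "Wilcoxon") {
    return(suppressWarnings(wilcox.test(x, y))$p.value)
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- ad2_stat(x, y)
  pool <- c(x, y)
  n <- length(x)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n)
    if (ad2_stat(pool[idx], pool[-idx]) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
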
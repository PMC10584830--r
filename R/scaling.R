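# Scaling of unnecessary duplexes with network size.  Networks of i random
# oligomers of j bases have no intentional duplexes, so dN = N and dO = O;
# quartiles of their scores over many random draws characterize the typical
# unnecessary duplex load, and medians over an (i, j) grid are fitted with
# the power law  score = a * i^b * j^c  on the log scale.

#' Score quartiles of random networks
#'
#' Generates `n` networks of `i` random oligomers with `j` bases each and
#' returns 25th/50th/75th percentiles of the above-baseline scores dN and dO
#' (equal to N and O here), plus the distribution of the largest intra- and
#' inter-oligomer run lengths.
#'
#' @param i Oligomers per network.
#' @param j Bases per oligomer.
#' @param n Networks sampled.
#' @param seed Optional integer seed.
#' @param intraSLC,interSLC Scoring length criteria.
#' @param min_loop Minimum intra-run loop length.
#' @return List: `dN`, `dO` (each p25/p50/p75), `max_intra`, `max_inter`
#'   (numeric vectors of per-network largest run lengths).
#' @export
sample_quartiles <- function(i, j, n, seed = NULL, intraSLC = 1L,
                             interSLC = 1L, min_loop = 0L) {
  stopifnot(i >= 1, j >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_random_scores(as.integer(i), as.integer(j), as.integer(n),
                         score_table(j, interSLC), score_table(j, intraSLC),
                         as.integer(min_loop))
  q <- function(v) stats::setNames(quantile(v, c(.25, .5, .75),
                                            names = FALSE),
                                   c("p25", "p50", "p75"))
  list(dN = q(m[, "N"]), dO = q(m[, "O"]),
       max_intra = m[, "max_intra"], max_inter = m[, "max_inter"])
}

#' Random-sampling scaling study over an (i, j) grid
#'
#' @param i_grid,j_grid Grid of oligomer counts and lengths.
#' @param n Networks per grid point.
#' @param seed Optional integer seed (each grid point gets a derived
#'   sub-seed so points are independently reproducible).
#' @return Data.frame: i, j, and quartiles of dN and dO.
#' @export
scaling_study <- function(i_grid = c(1L, 2L, 4L, 8L),
                          j_grid = c(8L, 16L, 32L, 64L, 128L, 256L),
                          n = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(i = i_grid, j = j_grid)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sq <- sample_quartiles(grid$i[g], grid$j[g], n)
    data.frame(i = grid$i[g], j = grid$j[g],
               dN_p25 = sq$dN[["p25"]], dN_p50 = sq$dN[["p50"]],
               dN_p75 = sq$dN[["p75"]],
               dO_p25 = sq$dO[["p25"]], dO_p50 = sq$dO[["p50"]],
               dO_p75 = sq$dO[["p75"]])
  })
  do.call(rbind, rows)
}

#' Fit the power-law model a * i^b * j^c to score medians
#'
#' Ordinary least squares on `ln(median) = ln(a) + b ln(i) + c ln(j)`.
#' Grid points with zero median are excluded (their logs are undefined; the
#' model is known to overshoot at small j anyway).
#'
#' @param medians Data.frame with columns `i`, `j`, and a median column.
#' @param target Which median column to fit: `"dN"` (uses `dN_p50` or
#'   `median`) or `"dO"`.
#' @return Object of class `power_law_fit` with coefficients `a`, `b`, `c`.
#' @export
fit_power_law <- function(medians, target = c("dN", "dO")) {
  target <- match.arg(target)
  col <- if ("median" %in% names(medians)) "median" else
    paste0(target, "_p50")
  if (!col %in% names(medians)) {
    stop("medians needs a '", col, "' or 'median' column", call. = FALSE)
  }
  df <- medians[medians[[col]] > 0, , drop = FALSE]
  if (nrow(df) < 3L) {
    stop("need at least 3 grid points with positive medians", call. = FALSE)
  }
  fit <- lm(log(df[[col]]) ~ log(df$i) + log(df$j))
  cf <- coef(fit)
  if (anyNA(cf)) stop("rank-deficient grid: vary both i and j", call. = FALSE)
  structure(list(a = exp(cf[[1]]), b = cf[[2]], c = cf[[3]],
                 target = target, n_points = nrow(df), lm = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit (%s): %.4g * i^%.3f * j^%.3f  (%d grid points)\n",
              x$target, x$a, x$b, x$c, x$n_points))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' Evaluate a power-law model
#'
#' @param fit A [fit_power_law()] result, or a numeric vector `c(a, b, c)`.
#' @param i,j Network dimensions.
#' @return Model fitness points `a * i^b * j^c`.
#' @export
model_eval <- function(fit, i, j) {
  cf <- if (inherits(fit, "power_law_fit")) coef(fit) else fit
  unname(cf[1] * i^cf[2] * j^cf[3])
}

#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  model_eval(object, newdata$i, newdata$j)
}

#' Smallest oligomer length reaching a score threshold
#'
#' The smallest integer `j` with `a * i^b * j^c >= target`. Non-increasing
#' in `i` since the model is monotone in both arguments.
#'
#' @inheritParams model_eval
#' @param target Threshold in fitness points (> 0).
#' @param j_max Search cap.
#' @return The minimal integer `j` (or `NA` if not reached by `j_max`).
#' @examples
#' threshold_min_j(c(0.0526, 1.56, 3.63), 1e3, i = 1) # 16
#' @export
threshold_min_j <- function(fit, target, i = 1, j_max = 100000L) {
  stopifnot(target > 0)
  for (j in seq_len(j_max)) {
    if (model_eval(fit, i, j) >= target) return(j)
  }
  NA_integer_
}

#' Fraction of single oligomers with a large intra-oligomer duplex
#'
#' Monte-Carlo fraction of random `j`-base oligomers whose largest
#' intra-oligomer run is at least `min_len` base pairs (default 3, the
#' intra condition of the "no 3's and no 8's" rule).
#'
#' @param j Oligomer length.
#' @param n Oligomers sampled.
#' @param seed Optional integer seed.
#' @param min_len Run-length threshold (default 3).
#' @param min_loop Minimum intra-run loop length.
#' @return The fraction in `[0, 1]`.
#' @export
largest_intra_fraction <- function(j, n, seed = NULL, min_len = 3L,
                                   min_loop = 0L) {
  stopifnot(j >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_random_scores(1L, as.integer(j), as.integer(n),
                         score_table(j, 1L), score_table(j, 1L),
                         as.integer(min_loop))
  mean(m[, "max_intra"] >= min_len)
}
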
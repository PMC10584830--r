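# Fitness scores: a duplex window of length L is worth 10^L fitness points.
# N sums windows over all inter-oligomer alignments (every unordered species
# pair, including each species against an identical copy of itself); O sums
# windows over intra-oligomer pairings; W_x = N + x*O.  Delta variants
# subtract the baseline contributed by necessary (design-implied) windows.
# Scores are IEEE doubles: exact integers up to 2^53 and overflowing to Inf
# only beyond window length 307.

# stab[M] = total window score of one maximal run of length M under the given
# scoring length criterion (windows shorter than slc score nothing)
score_table <- function(max_len, slc = 1L) {
  max_len <- max(1L, as.integer(max_len))
  slc <- as.integer(slc)
  pow <- 10^seq_len(max_len)
  if (slc > max_len) return(numeric(max_len))
  csum <- cumsum(pow)
  stab <- numeric(max_len)
  low <- if (slc > 1L) csum[slc - 1L] else 0
  for (M in seq(slc, max_len)) {
    stab[M] <- (if (M > slc) stab[M - 1L] else 0) + csum[M] - low
  }
  stab
}

#' Window counts of a maximal duplex run
#'
#' A maximal run of `M` contiguous base pairs contains `M - L + 1` windows of
#' each length `L` between the scoring length criterion and `M`.
#'
#' @param M Maximal run length (>= 1).
#' @param slc Scoring length criterion: windows shorter than `slc` are not
#'   counted.
#' @return Named numeric vector mapping window length to count (empty when
#'   `M < slc`).
#' @examples
#' run_windows(4) # 4 singles, 3 doubles, 2 triples, 1 quadruple
#' @export
run_windows <- function(M, slc = 1L) {
  stopifnot(M >= 1)
  if (M < slc) return(stats::setNames(numeric(0), character(0)))
  L <- seq(slc, M)
  stats::setNames(M - L + 1, L)
}

#' Score a window histogram
#'
#' Accumulates `10^L` fitness points per window of length `L`, ignoring
#' windows shorter than the scoring length criterion.
#'
#' @param hist Either a named numeric vector (names are window lengths) or a
#'   data.frame with columns `L` and `count`.
#' @param slc Scoring length criterion.
#' @return Total fitness points.
#' @examples
#' score_windows(c(`1` = 790, `2` = 105)) # 18400
#' @export
score_windows <- function(hist, slc = 1L) {
  if (is.data.frame(hist)) {
    L <- hist$L
    count <- hist$count
  } else {
    L <- as.numeric(names(hist))
    count <- as.numeric(hist)
  }
  if (length(L) == 0L) return(0)
  stopifnot(all(count >= 0))
  keep <- L >= slc
  sum(count[keep] * 10^L[keep])
}

#' Homopolymer validity limits
#'
#' Maximum acceptable runs of consecutive identical bases. The defaults
#' (6 A's, 3 C's, 3 G's, 6 T's) restrict the G/C homopolymers most tightly.
#'
#' @param maxAA,maxCC,maxGG,maxTT Per-base limits (all >= 1).
#' @return An object of class `validity_limits`.
#' @export
validity_limits <- function(maxAA = 6L, maxCC = 3L, maxGG = 3L, maxTT = 6L) {
  lim <- c(A = maxAA, C = maxCC, G = maxGG, T = maxTT)
  stopifnot(all(lim >= 1))
  structure(as.integer(lim), names = names(lim), class = "validity_limits")
}

#' Check homopolymer validity of a network
#'
#' @param network An `oligo_network`.
#' @param limits A [validity_limits()].
#' @return List with `pass` and a data.frame of `violations` (oligomer, base,
#'   run length, limit).
#' @export
validity_check <- function(network, limits = validity_limits()) {
  stopifnot(inherits(network, "oligo_network"))
  viol <- list()
  for (o in names(network$oligomers)) {
    r <- rle(strsplit(network$oligomers[[o]], "")[[1]])
    bad <- which(r$lengths > limits[r$values])
    for (idx in bad) {
      viol[[length(viol) + 1L]] <- data.frame(
        oligomer = o, base = r$values[idx], run = r$lengths[idx],
        limit = unname(limits[r$values[idx]]), stringsAsFactors = FALSE)
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(oligomer = character(), base = character(), run = integer(),
               limit = integer(), stringsAsFactors = FALSE)
  list(pass = nrow(viol) == 0L, violations = viol)
}

#' The "no 3's and no 8's" design rule
#'
#' A network passes when it contains no unnecessary intra-oligomer duplex of
#' 3 or more contiguous base pairs and no unnecessary inter-oligomer duplex
#' of 8 or more base pairs.
#'
#' @param x A [duplex_profile()] or an `oligo_network` (profiled on the fly).
#' @param max_intra,max_inter Largest acceptable unnecessary run lengths
#'   (defaults 2 and 7).
#' @return List with `pass` (logical) and `violations` (data.frame of
#'   offending runs, when available).
#' @export
rule_check <- function(x, max_intra = 2L, max_inter = 7L) {
  if (inherits(x, "oligo_network")) x <- duplex_profile(x)
  stopifnot(inherits(x, "duplex_profile"))
  intra_bad <- x$largest_unnecessary_intra > max_intra
  inter_bad <- x$largest_unnecessary_inter > max_inter
  viol <- x$largest_runs
  if (!is.null(viol)) {
    viol <- viol[(viol$kind == "intra" & viol$length > max_intra) |
                   (viol$kind == "inter" & viol$length > max_inter), ,
                 drop = FALSE]
  }
  list(pass = !(intra_bad || inter_bad), violations = viol,
       largest_unnecessary_intra = x$largest_unnecessary_intra,
       largest_unnecessary_inter = x$largest_unnecessary_inter)
}

# fast score of one network: per-pair inter scores (upper triangle incl. self
# pairs) and per-oligomer intra scores, via the compiled scanner
network_scores <- function(network, intraSLC = 1L, interSLC = 1L,
                           min_loop = 0L) {
  nms <- names(network$codes)
  jmax <- max(vapply(network$codes, length, integer(1)))
  stabN <- score_table(jmax, interSLC)
  stabO <- score_table(jmax, intraSLC)
  k <- length(nms)
  pairN <- matrix(0, k, k, dimnames = list(nms, nms))
  pairN_nec <- matrix(0, k, k, dimnames = list(nms, nms))
  pairN_un <- matrix(0, k, k, dimnames = list(nms, nms))
  oligO <- stats::setNames(numeric(k), nms)
  oligO_nec <- stats::setNames(numeric(k), nms)
  oligO_un <- stats::setNames(numeric(k), nms)
  max_un_intra <- 0L
  max_un_inter <- 0L
  for (ia in seq_len(k)) {
    a <- nms[ia]
    pa <- network$provenance[[a]]
    sc <- cpp_intra_score(network$codes[[a]], as.integer(min_loop), stabO,
                          pa$dom, pa$pos, pa$cmp)
    oligO[ia] <- sc[["total"]]
    oligO_nec[ia] <- sc[["necessary"]]
    oligO_un[ia] <- sc[["unnecessary"]]
    max_un_intra <- max(max_un_intra, sc[["max_unnecessary"]])
    for (ib in ia:k) {
      b <- nms[ib]
      pb <- network$provenance[[b]]
      sc <- cpp_pair_score(network$codes[[a]], network$codes[[b]], stabN,
                           pa$dom, pa$pos, pa$cmp, pb$dom, pb$pos, pb$cmp)
      pairN[ia, ib] <- sc[["total"]]
      pairN_nec[ia, ib] <- sc[["necessary"]]
      pairN_un[ia, ib] <- sc[["unnecessary"]]
      max_un_inter <- max(max_un_inter, sc[["max_unnecessary"]])
    }
  }
  list(pairN = pairN, pairN_nec = pairN_nec, pairN_un = pairN_un,
       oligO = oligO, oligO_nec = oligO_nec, oligO_un = oligO_un,
       max_unnecessary_intra = as.integer(max_un_intra),
       max_unnecessary_inter = as.integer(max_un_inter))
}

#' Fitness report of a network
#'
#' Computes the inter-oligomer score N, the intra-oligomer score O, the
#' weighted score `W_x = N + x*O`, the necessary-window baselines, and the
#' above-baseline values `dN = N - baseline_N`, `dO = O - baseline_O`,
#' `dW_x = dN + x*dO`. The scoring length criteria truncate both the totals
#' and the baselines.
#'
#' @param network An `oligo_network`.
#' @param x Weight on O in `W_x` (default 10000).
#' @param intraSLC,interSLC Scoring length criteria (default 1).
#' @param min_loop Minimum intra-run loop length (default 0).
#' @return Object of class `fitness_report` with fields `N`, `O`, `W`,
#'   `baseline_N`, `baseline_O`, `delta_N`, `delta_O`, `delta_W`, `x`,
#'   `intraSLC`, `interSLC`, and the largest unnecessary run lengths.
#' @examples
#' net <- compile_network(oligo_design(variable = c(a = "AACG"),
#'                                     oligomers = list(X = "a", Y = "a*")))
#' fitness(net, x = 1)
#' @export
fitness <- function(network, x = 10000, intraSLC = 1L, interSLC = 1L,
                    min_loop = 0L) {
  stopifnot(inherits(network, "oligo_network"), x > 0)
  sc <- network_scores(network, intraSLC, interSLC, min_loop)
  N <- sum(sc$pairN)
  O <- sum(sc$oligO)
  bN <- sum(sc$pairN_nec)
  bO <- sum(sc$oligO_nec)
  # deltas are summed per run so small unnecessary duplexes are never
  # absorbed by the floating-point epsilon of a large necessary baseline
  dN <- sum(sc$pairN_un)
  dO <- sum(sc$oligO_un)
  structure(list(N = N, O = O, W = N + x * O,
                 baseline_N = bN, baseline_O = bO,
                 delta_N = dN, delta_O = dO,
                 delta_W = dN + x * dO,
                 x = x, intraSLC = as.integer(intraSLC),
                 interSLC = as.integer(interSLC),
                 largest_unnecessary_intra = sc$max_unnecessary_intra,
                 largest_unnecessary_inter = sc$max_unnecessary_inter),
            class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = v >= 1e15)
  cat("Fitness report (x = ", format(x$x), ", intraSLC = ", x$intraSLC,
      ", interSLC = ", x$interSLC, ")\n", sep = "")
  cat("  N  = ", fmt(x$N), "   dN  = ", fmt(x$delta_N), "\n", sep = "")
  cat("  O  = ", fmt(x$O), "   dO  = ", fmt(x$delta_O), "\n", sep = "")
  cat("  Wx = ", fmt(x$W), "   dWx = ", fmt(x$delta_W), "\n", sep = "")
  cat("  largest unnecessary intra/inter: ",
      x$largest_unnecessary_intra, " / ", x$largest_unnecessary_inter,
      " bp\n", sep = "")
  invisible(x)
}

#' Write a fitness report as a key=value block
#'
#' @param report A [fitness()] result.
#' @param path Output file.
#' @export
write_fitness_report <- function(report, path) {
  stopifnot(inherits(report, "fitness_report"))
  keys <- c("N", "O", "W", "baseline_N", "baseline_O", "delta_N", "delta_O",
            "delta_W", "x", "intraSLC", "interSLC",
            "largest_unnecessary_intra", "largest_unnecessary_inter")
  writeLines(sprintf("%s=%s", keys,
                     vapply(report[keys], format, character(1),
                            scientific = FALSE)), path)
  invisible(path)
}
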
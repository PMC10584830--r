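# Exhaustive duplex enumeration: every maximal run of contiguous antiparallel
# Watson-Crick base pairs, within one oligomer (intra) or between two oligomer
# species (inter, including a species paired with an identical copy of
# itself).  Coordinates are 1-based positions of the 5'-most paired base of
# each segment.

empty_prov <- function(n) list(dom = integer(n), pos = integer(n),
                               cmp = integer(n))

runs_df <- function(mat, kind, a, b) {
  rownames(mat) <- NULL
  data.frame(kind = rep(kind, nrow(mat)),
             oligomer_a = rep(a, nrow(mat)),
             oligomer_b = rep(b, nrow(mat)),
             start_a = mat[, "start_a"], start_b = mat[, "start_b"],
             length = mat[, "length"],
             necessary = if ("necessary" %in% colnames(mat)) {
               mat[, "necessary"] == 1L
             } else rep(FALSE, nrow(mat)),
             stringsAsFactors = FALSE)
}

#' Enumerate intra-oligomer duplex runs
#'
#' All maximal runs of base pairs `(p, q)` with `p < q` on a single strand,
#' where consecutive pairs advance `(p+1, q-1)` and the two paired segments
#' are disjoint. Each unordered pairing is reported once. A run is flagged
#' `necessary` when every base pair is implied by the design (a domain paired
#' against a complemented instance of itself in designed registration).
#'
#' @param network An `oligo_network`.
#' @param oligomer Oligomer name.
#' @param min_loop Minimum number of unpaired bases between the two segments
#'   of an intra run (default 0: adjacent segments may pair).
#' @return Data.frame of runs: kind, oligomer names, `start_a`, `start_b`
#'   (5'-most paired base of each segment), `length`, `necessary`.
#' @export
enumerate_intra <- function(network, oligomer, min_loop = 0L) {
  stopifnot(inherits(network, "oligo_network"))
  if (!oligomer %in% names(network$codes)) {
    stop("no such oligomer: ", oligomer, call. = FALSE)
  }
  pr <- network$provenance[[oligomer]]
  res <- cpp_intra_runs_nec(network$codes[[oligomer]], as.integer(min_loop),
                            pr$dom, pr$pos, pr$cmp)
  runs_df(res$runs, "intra", oligomer, NA_character_)
}

#' Enumerate inter-oligomer duplex runs
#'
#' All maximal antiparallel complementary runs between two oligomer species,
#' over every alignment register (diagonal). `a == b` is allowed and treats
#' the species as two identical copies; each register is enumerated once.
#'
#' @param network An `oligo_network`.
#' @param a,b Oligomer names (may be equal).
#' @return Data.frame of runs as in [enumerate_intra()].
#' @export
enumerate_inter <- function(network, a, b) {
  stopifnot(inherits(network, "oligo_network"))
  for (nm in c(a, b)) {
    if (!nm %in% names(network$codes)) {
      stop("no such oligomer: ", nm, call. = FALSE)
    }
  }
  pa <- network$provenance[[a]]
  pb <- network$provenance[[b]]
  res <- cpp_inter_runs_nec(network$codes[[a]], network$codes[[b]],
                            pa$dom, pa$pos, pa$cmp, pb$dom, pb$pos, pb$cmp)
  runs_df(res$runs, "inter", a, b)
}

# iterate all unordered species pairs (incl. self) and intra scans, calling
# fun(kind, a, b, runs_matrix, nec_stretches)
walk_network_runs <- function(network, min_loop, fun) {
  nms <- names(network$codes)
  for (ia in seq_along(nms)) {
    a <- nms[ia]
    pa <- network$provenance[[a]]
    res <- cpp_intra_runs_nec(network$codes[[a]], as.integer(min_loop),
                              pa$dom, pa$pos, pa$cmp)
    fun("intra", a, a, res$runs, res$nec_stretches)
    for (ib in ia:length(nms)) {
      b <- nms[ib]
      pb <- network$provenance[[b]]
      res <- cpp_inter_runs_nec(network$codes[[a]], network$codes[[b]],
                                pa$dom, pa$pos, pa$cmp,
                                pb$dom, pb$pos, pb$cmp)
      fun("inter", a, b, res$runs, res$nec_stretches)
    }
  }
  invisible(NULL)
}

#' Duplex profile of a network
#'
#' Aggregates every maximal duplex run of the network into histograms, both
#' of maximal-run lengths and of all contiguous sub-duplex windows (a maximal
#' run of length M contributes M-L+1 windows of length L). Runs and windows
#' are split into necessary (entirely design-implied base pairs) and
#' unnecessary. The largest unnecessary intra- and inter-oligomer run lengths
#' drive the "no 3's and no 8's" design rule.
#'
#' @param network An `oligo_network`.
#' @param min_loop Minimum intra-run loop length (default 0).
#' @return An object of class `duplex_profile`: `run_hist` and `window_hist`
#'   data.frames (kind, necessary, L, count), `largest_unnecessary_intra`,
#'   `largest_unnecessary_inter`, and `largest_runs` (the maximal unnecessary
#'   runs with coordinates).
#' @export
duplex_profile <- function(network, min_loop = 0L) {
  stopifnot(inherits(network, "oligo_network"))
  jmax <- max(c(1L, vapply(network$codes, length, integer(1))))
  # window counts indexed [kind x necessary x L]
  wins <- list(intra = list(nec = numeric(jmax), unnec = numeric(jmax)),
               inter = list(nec = numeric(jmax), unnec = numeric(jmax)))
  runs <- list(intra = list(nec = numeric(jmax), unnec = numeric(jmax)),
               inter = list(nec = numeric(jmax), unnec = numeric(jmax)))
  largest <- c(intra = 0L, inter = 0L)
  largest_runs <- list()
  add_windows <- function(vec, lens) {
    for (M in lens) vec[seq_len(M)] <- vec[seq_len(M)] + (M - seq_len(M) + 1L)
    vec
  }
  walk_network_runs(network, min_loop, function(kind, a, b, rmat, necs) {
    if (nrow(rmat) == 0L && length(necs) == 0L) return(invisible(NULL))
    lens <- rmat[, "length"]
    nec <- rmat[, "necessary"] == 1L
    # run histogram: a run is necessary iff all its pairs are
    for (r in seq_len(nrow(rmat))) {
      slot <- if (nec[r]) "nec" else "unnec"
      runs[[kind]][[slot]][lens[r]] <<- runs[[kind]][[slot]][lens[r]] + 1
    }
    # window histogram: necessary windows are the windows of the maximal
    # all-necessary stretches; everything else is unnecessary
    wins[[kind]]$nec <<- add_windows(wins[[kind]]$nec, necs)
    all_w <- add_windows(numeric(length(wins[[kind]]$unnec)), lens)
    wins[[kind]]$unnec <<- wins[[kind]]$unnec + all_w -
      add_windows(numeric(length(wins[[kind]]$unnec)), necs)
    un <- lens[!nec]
    if (length(un) && max(un) > largest[[kind]]) {
      largest[[kind]] <<- max(un)
    }
    if (any(!nec)) {
      keep <- which(!nec & lens == max(un))
      largest_runs[[length(largest_runs) + 1L]] <<-
        runs_df(rmat[keep, , drop = FALSE], kind, a,
                if (kind == "intra") NA_character_ else b)
    }
  })
  hist_df <- function(lst) {
    out <- do.call(rbind, lapply(c("intra", "inter"), function(kind) {
      do.call(rbind, lapply(c(TRUE, FALSE), function(nec) {
        v <- lst[[kind]][[if (nec) "nec" else "unnec"]]
        L <- which(v > 0)
        if (!length(L)) return(NULL)
        data.frame(kind = kind, necessary = nec, L = L, count = v[L],
                   stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(out)) {
      out <- data.frame(kind = character(), necessary = logical(),
                        L = integer(), count = numeric(),
                        stringsAsFactors = FALSE)
    }
    out
  }
  lr <- if (length(largest_runs)) do.call(rbind, largest_runs) else NULL
  structure(list(run_hist = hist_df(runs), window_hist = hist_df(wins),
                 largest_unnecessary_intra = largest[["intra"]],
                 largest_unnecessary_inter = largest[["inter"]],
                 largest_runs = lr),
            class = "duplex_profile")
}

#' @export
print.duplex_profile <- function(x, ...) {
  cat("Duplex profile\n")
  cat("  largest unnecessary intra-oligomer run:",
      x$largest_unnecessary_intra, "bp\n")
  cat("  largest unnecessary inter-oligomer run:",
      x$largest_unnecessary_inter, "bp\n")
  if (nrow(x$window_hist)) {
    un <- x$window_hist[!x$window_hist$necessary, , drop = FALSE]
    if (nrow(un)) {
      cat("  unnecessary windows by length:\n")
      for (kind in unique(un$kind)) {
        sub <- un[un$kind == kind, ]
        cat("   ", kind, ":",
            paste(sprintf("%dbp x %g", sub$L, sub$count), collapse = ", "),
            "\n")
      }
    } else cat("  no unnecessary windows\n")
  } else {
    cat("  no duplexes\n")
  }
  invisible(x)
}

#' Write a duplex profile report
#'
#' Emits a machine-readable delimited table (kind, necessary, L, run_count,
#' window_count) followed by a listing of the largest unnecessary runs with
#' 1-based coordinates.
#'
#' @param profile A [duplex_profile()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_profile_report <- function(profile, path) {
  stopifnot(inherits(profile, "duplex_profile"))
  key <- function(df) paste(df$kind, df$necessary, df$L)
  all_keys <- unique(c(key(profile$run_hist), key(profile$window_hist)))
  rh <- profile$run_hist
  wh <- profile$window_hist
  tab <- do.call(rbind, lapply(all_keys, function(k) {
    parts <- strsplit(k, " ")[[1]]
    data.frame(kind = parts[1], necessary = as.logical(parts[2]),
               L = as.integer(parts[3]),
               run_count = sum(rh$count[key(rh) == k]),
               window_count = sum(wh$count[key(wh) == k]),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(tab)) {
    tab <- tab[order(tab$kind, !tab$necessary, tab$L), ]
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines("kind\tnecessary\tL\trun_count\twindow_count", con)
  }
  writeLines(c("", sprintf("largest_unnecessary_intra\t%d",
                           profile$largest_unnecessary_intra),
               sprintf("largest_unnecessary_inter\t%d",
                       profile$largest_unnecessary_inter)), con)
  if (!is.null(profile$largest_runs)) {
    writeLines("", con)
    write.table(profile$largest_runs, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
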
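# Evolution-inspired optimizer: lineage-based stochastic hill climbing that
# permutes bases within variable domains to minimize an above-baseline
# fitness score.  Mutations conserve the length and base composition of every
# domain, so the search space is the set of per-domain permutations of the
# initial sequences.

#' Optimizer configuration
#'
#' @param CPL Cycles per lineage (default 100000).
#' @param GPC Generations (mutation proposals) per cycle per lineage
#'   (default 1).
#' @param NDPM Number of variable domains mutated per mutation (default 1).
#' @param NL Number of lineages (default 8).
#' @param NMPC New mothers per cycle: each cycle the NMPC worst lineages are
#'   reseeded from the best network encountered so far (default 1).
#' @param intraSLC,interSLC Scoring length criteria (default 1).
#' @param scoringWeightX Weight x of the W_x objective (default 10000).
#' @param limits Homopolymer [validity_limits()].
#' @param objective Which above-baseline score to minimize: `"N"`, `"O"`, or
#'   `"W"`.
#' @param min_loop Minimum intra-run loop length.
#' @param seed Optional integer seed.
#' @return List of class `evolver_config`.
#' @export
evolver_config <- function(CPL = 100000L, GPC = 1L, NDPM = 1L, NL = 8L,
                           NMPC = 1L, intraSLC = 1L, interSLC = 1L,
                           scoringWeightX = 10000, limits = validity_limits(),
                           objective = c("W", "N", "O"), min_loop = 0L,
                           seed = NULL) {
  objective <- match.arg(objective)
  cfg <- list(CPL = as.integer(CPL), GPC = as.integer(GPC),
              NDPM = as.integer(NDPM), NL = as.integer(NL),
              NMPC = as.integer(NMPC), intraSLC = as.integer(intraSLC),
              interSLC = as.integer(interSLC),
              scoringWeightX = scoringWeightX, limits = limits,
              objective = objective, min_loop = as.integer(min_loop),
              seed = seed)
  stopifnot(cfg$CPL >= 1, cfg$GPC >= 1, cfg$NDPM >= 1, cfg$NL >= 1,
            cfg$NMPC >= 1, cfg$scoringWeightX > 0)
  class(cfg) <- "evolver_config"
  cfg
}

#' Mutate a network by shuffling bases within variable domains
#'
#' Chooses `ndpm` variable domains uniformly at random and applies one random
#' transposition (swap of two positions) within each; all oligomer instances
#' of a mutated domain are updated consistently. Fixed domains never change;
#' domain length and base composition are always conserved. A length-1
#' domain yields the identity mutation.
#'
#' @param network An `oligo_network`.
#' @param ndpm Number of domains to mutate.
#' @return A recompiled `oligo_network`.
#' @export
mutate_network <- function(network, ndpm = 1L) {
  stopifnot(inherits(network, "oligo_network"))
  design <- network$design
  vn <- names(design$variable)
  if (length(vn) == 0L) stop("design has no variable domains", call. = FALSE)
  pick <- vn[sample.int(length(vn), ndpm, replace = TRUE)]
  for (dn in pick) {
    s <- strsplit(design$variable[[dn]], "")[[1]]
    if (length(s) >= 2L) {
      ij <- sample.int(length(s), 2L)
      s[ij] <- s[rev(ij)]
      design$variable[[dn]] <- paste(s, collapse = "")
    }
  }
  compile_network(design)
}

# --- internal incremental-rescoring engine ---------------------------------

# static context shared by all lineages: token plans, provenance, tables
evo_context <- function(design, config) {
  net <- compile_network(design)
  nms <- names(net$codes)
  jmax <- max(vapply(net$codes, length, integer(1)))
  plans <- lapply(design$oligomers, function(toks) {
    list(dom = sub("\\*$", "", toks), comp = grepl("\\*$", toks))
  })
  # which oligomers contain each variable domain
  vn <- names(design$variable)
  touches <- lapply(vn, function(dn) {
    which(vapply(plans, function(p) dn %in% p$dom, logical(1)))
  })
  names(touches) <- vn
  list(nms = nms, k = length(nms), plans = plans, prov = net$provenance,
       touches = touches, vn = vn,
       stabN = score_table(jmax, config$interSLC),
       stabO = score_table(jmax, config$intraSLC),
       limits = config$limits, min_loop = config$min_loop)
}

evo_assemble <- function(ctx, doms, o) {
  p <- ctx$plans[[o]]
  parts <- vector("list", length(p$dom))
  for (t in seq_along(p$dom)) {
    dc <- doms[[p$dom[t]]]
    parts[[t]] <- if (p$comp[t]) rev(3L - dc) else dc
  }
  unlist(parts, use.names = FALSE)
}

evo_valid_olig <- function(ctx, codes_o) {
  r <- rle(codes_o)
  all(r$lengths <= ctx$limits[r$values + 1L])
}

# full scoring of a state: per-pair and per-oligomer above-baseline
# (unnecessary-window) scores; element [3] of the compiled scorers' output
evo_score_state <- function(ctx, codes) {
  k <- ctx$k
  pair_dN <- matrix(0, k, k)
  olig_dO <- numeric(k)
  for (ia in seq_len(k)) {
    pa <- ctx$prov[[ia]]
    sc <- cpp_intra_score(codes[[ia]], ctx$min_loop, ctx$stabO,
                          pa$dom, pa$pos, pa$cmp)
    olig_dO[ia] <- sc[[3L]]
    for (ib in ia:k) {
      pb <- ctx$prov[[ib]]
      sc <- cpp_pair_score(codes[[ia]], codes[[ib]], ctx$stabN,
                           pa$dom, pa$pos, pa$cmp, pb$dom, pb$pos, pb$cmp)
      pair_dN[ia, ib] <- sc[[3L]]
    }
  }
  list(pair_dN = pair_dN, olig_dO = olig_dO)
}

evo_objective <- function(config, dN, dO) {
  switch(config$objective,
         N = dN,
         O = dO,
         W = dN + config$scoringWeightX * dO)
}

#' Optimize a design's variable domains
#'
#' Maintains `NL` lineages seeded from the initial network. Each cycle every
#' lineage proposes `GPC` single-transposition mutations; a proposal is
#' accepted when it passes the homopolymer validity limits and its
#' above-baseline objective does not exceed the parent's (ties accepted).
#' After each cycle the `NMPC` worst lineages are reseeded from the best
#' network encountered so far. The initial network must pass the validity
#' limits; otherwise its variable domains are re-randomized (composition
#' preserved) a bounded number of times before giving up.
#'
#' @param design An [oligo_design()] with at least one variable domain.
#' @param config An [evolver_config()].
#' @return Object of class `evo_result`: `best_network`, `best_score`,
#'   `trajectory` (best-so-far objective per cycle, non-increasing),
#'   `evaluations`, `initial_score`, and `config`.
#' @export
optimize_network <- function(design, config = evolver_config()) {
  stopifnot(inherits(design, "oligo_design"))
  if (length(design$variable) == 0L) {
    stop("design has no variable domains", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  ctx <- evo_context(design, config)
  doms0 <- lapply(c(design$fixed, design$variable), encode_seq)
  codes0 <- lapply(ctx$nms, function(o) evo_assemble(ctx, doms0, o))

  attempts <- 0L
  while (!all(vapply(codes0, evo_valid_olig, logical(1), ctx = ctx))) {
    attempts <- attempts + 1L
    if (attempts > 100L) {
      stop("could not find a valid initial network within 100 ",
           "re-randomizations; homopolymer limits appear infeasible",
           call. = FALSE)
    }
    for (dn in ctx$vn) doms0[[dn]] <- sample(doms0[[dn]])
    codes0 <- lapply(ctx$nms, function(o) evo_assemble(ctx, doms0, o))
  }

  st0 <- evo_score_state(ctx, codes0)
  obj0 <- evo_objective(config, sum(st0$pair_dN), sum(st0$olig_dO))

  lineage <- list(doms = doms0, codes = codes0, pair_dN = st0$pair_dN,
                  olig_dO = st0$olig_dO, obj = obj0)
  lineages <- rep(list(lineage), config$NL)
  best <- lineage
  evaluations <- config$NL # initial scorings
  trajectory <- numeric(config$CPL)

  for (cyc in seq_len(config$CPL)) {
    for (l in seq_len(config$NL)) {
      lin <- lineages[[l]]
      for (g in seq_len(config$GPC)) {
        pick <- ctx$vn[sample.int(length(ctx$vn), config$NDPM,
                                  replace = TRUE)]
        nd <- lin$doms
        for (dn in pick) {
          v <- nd[[dn]]
          if (length(v) >= 2L) {
            ij <- sample.int(length(v), 2L)
            v[ij] <- v[rev(ij)]
            nd[[dn]] <- v
          }
        }
        aff <- sort(unique(unlist(ctx$touches[pick], use.names = FALSE)))
        ncodes <- lin$codes
        ok <- TRUE
        for (o in aff) {
          ncodes[[o]] <- evo_assemble(ctx, nd, o)
          if (!evo_valid_olig(ctx, ncodes[[o]])) { ok <- FALSE; break }
        }
        if (!ok) next
        # incremental rescoring: only pairs touching an affected oligomer
        pair_dN <- lin$pair_dN
        olig_dO <- lin$olig_dO
        for (o in aff) {
          po <- ctx$prov[[o]]
          sc <- cpp_intra_score(ncodes[[o]], ctx$min_loop, ctx$stabO,
                                po$dom, po$pos, po$cmp)
          olig_dO[o] <- sc[[3L]]
          for (other in seq_len(ctx$k)) {
            if (other %in% aff && other < o) next # already rescored
            ia <- min(o, other); ib <- max(o, other)
            pa <- ctx$prov[[ia]]
            pb <- ctx$prov[[ib]]
            sc <- cpp_pair_score(ncodes[[ia]], ncodes[[ib]], ctx$stabN,
                                 pa$dom, pa$pos, pa$cmp,
                                 pb$dom, pb$pos, pb$cmp)
            pair_dN[ia, ib] <- sc[[3L]]
          }
        }
        evaluations <- evaluations + 1L
        nobj <- evo_objective(config, sum(pair_dN), sum(olig_dO))
        if (nobj <= lin$obj) {
          lin <- list(doms = nd, codes = ncodes, pair_dN = pair_dN,
                      olig_dO = olig_dO, obj = nobj)
        }
      }
      lineages[[l]] <- lin
      if (lin$obj < best$obj) best <- lin
    }
    # reseed the worst lineages from the global best ("new mothers")
    ord <- order(vapply(lineages, `[[`, numeric(1), "obj"),
                 decreasing = TRUE)
    for (m in seq_len(min(config$NMPC, config$NL))) {
      lineages[[ord[m]]] <- best
    }
    trajectory[cyc] <- best$obj
  }

  out_design <- design
  for (dn in ctx$vn) out_design$variable[[dn]] <- decode_seq(best$doms[[dn]])
  structure(list(best_network = compile_network(out_design),
                 best_score = best$obj, trajectory = trajectory,
                 evaluations = evaluations, initial_score = obj0,
                 config = config),
            class = "evo_result")
}

#' @export
print.evo_result <- function(x, ...) {
  cat("Sequence evolution result\n")
  cat("  objective d", x$config$objective,
      if (x$config$objective == "W") paste0(" (x = ",
                                            format(x$config$scoringWeightX),
                                            ")"),
      ": ", format(x$initial_score), " -> ", format(x$best_score), "\n",
      sep = "")
  cat("  cycles:", x$config$CPL, " lineages:", x$config$NL,
      " evaluations:", x$evaluations, "\n")
  invisible(x)
}

#' Write an optimization report
#'
#' Records the resolved runtime parameters, the score trajectory endpoints,
#' and the most-fit network (domains and oligomers).
#'
#' @param result A [optimize_network()] result.
#' @param path Output file.
#' @export
write_evolve_report <- function(result, path) {
  stopifnot(inherits(result, "evo_result"))
  cfg <- result$config
  net <- result$best_network
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# runtime parameters", con)
  for (key in c("CPL", "GPC", "NDPM", "NL", "NMPC", "intraSLC", "interSLC",
                "scoringWeightX", "objective")) {
    writeLines(sprintf("%s=%s", key, format(cfg[[key]], scientific = FALSE)),
               con)
  }
  writeLines(c("", "# scores",
               sprintf("initial_score=%s",
                       format(result$initial_score, scientific = FALSE)),
               sprintf("best_score=%s",
                       format(result$best_score, scientific = FALSE)),
               sprintf("evaluations=%d", result$evaluations), "",
               "# most-fit network"), con)
  for (dn in names(net$design$fixed)) {
    writeLines(sprintf("fixed\t%s\t%s", dn, net$design$fixed[[dn]]), con)
  }
  for (dn in names(net$design$variable)) {
    writeLines(sprintf("variable\t%s\t%s", dn, net$design$variable[[dn]]),
               con)
  }
  for (o in names(net$oligomers)) {
    writeLines(sprintf("oligomer\t%s\t%s", o, net$oligomers[[o]]), con)
  }
  invisible(path)
}

# --- largest-satisfiable-network search ------------------------------------

make_single_duplex_design <- function(j) {
  oligo_design(variable = c(a = paste(sample(BASES, j, TRUE), collapse = "")),
               oligomers = list(X = "a", Y = "a*"))
}

make_independent_duplex_design <- function(n_duplex, bp = 8L) {
  vars <- vapply(seq_len(n_duplex), function(m) {
    paste(sample(BASES, bp, TRUE), collapse = "")
  }, character(1))
  names(vars) <- paste0("d", seq_len(n_duplex))
  oligs <- list()
  for (m in seq_len(n_duplex)) {
    oligs[[paste0("X", m)]] <- paste0("d", m)
    oligs[[paste0("Y", m)]] <- paste0("d", m, "*")
  }
  oligo_design(variable = vars, oligomers = oligs)
}

#' Largest network satisfying the "no 3's and no 8's" rule
#'
#' Size-search protocol: starting from a single 8-base-pair duplex (or one
#' duplex for the independent-duplexes system), the size is doubled while any
#' of `attempts_per_size` generation attempts passes [rule_check()]; on the
#' first all-fail size the search backtracks to the last passing size and
#' grows in 10% increments (rounded up) until all attempts fail again. The
#' largest passing size is returned (0 when even the starting size fails).
#'
#' @param kind `"single-duplex"` (size = base pairs in the one intended
#'   duplex) or `"independent-8bp-duplexes"` (size = number of independent
#'   8-bp duplexes).
#' @param generator `"random"` draws domain bases uniformly at random;
#'   `"optimizer"` additionally runs [optimize_network()] on each attempt.
#' @param attempts_per_size Generation attempts per size (default 3).
#' @param config [evolver_config()] used by the optimizer generator.
#' @param seed Optional integer seed.
#' @return List: `size` (largest passing), `history` (data.frame of size,
#'   attempt outcomes).
#' @export
largest_satisfiable_search <- function(kind = c("single-duplex",
                                                "independent-8bp-duplexes"),
                                       generator = c("random", "optimizer"),
                                       attempts_per_size = 3L,
                                       config = evolver_config(),
                                       seed = NULL) {
  kind <- match.arg(kind)
  generator <- match.arg(generator)
  if (!is.null(seed)) set.seed(seed)
  make_design <- switch(kind,
    "single-duplex" = make_single_duplex_design,
    "independent-8bp-duplexes" = make_independent_duplex_design)
  attempt <- function(size) {
    design <- make_design(size)
    net <- if (generator == "optimizer") {
      cfg <- config
      cfg$seed <- NULL # RNG stream already seeded for the whole protocol
      optimize_network(design, cfg)$best_network
    } else {
      compile_network(design)
    }
    rule_check(net)$pass
  }
  any_pass <- function(size) {
    for (t in seq_len(attempts_per_size)) if (attempt(size)) return(TRUE)
    FALSE
  }
  history <- list()
  note <- function(size, pass) {
    history[[length(history) + 1L]] <<- data.frame(size = size, pass = pass)
  }
  size <- if (kind == "single-duplex") 8L else 1L
  last_pass <- 0L
  repeat {
    ok <- any_pass(size)
    note(size, ok)
    if (!ok) break
    last_pass <- size
    size <- size * 2L
  }
  if (last_pass > 0L) {
    size <- last_pass
    repeat {
      nxt <- as.integer(ceiling(size * 1.1))
      if (nxt == size) nxt <- size + 1L
      ok <- any_pass(nxt)
      note(nxt, ok)
      if (!ok) break
      size <- nxt
    }
    last_pass <- size
  }
  list(size = last_pass, history = do.call(rbind, history))
}
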
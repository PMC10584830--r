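#' Reverse complement of a DNA sequence
#'
#' Antiparallel Watson-Crick complement, read 5'->3'. Only the four standard
#' bases are accepted; the function is an involution.
#'
#' @param seq Character vector of base strings over `{A,C,G,T}` (case
#'   insensitive; returned uppercase).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AACG") # "CGTT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) < 1L) {
    stop("seq must be a character vector of base strings", call. = FALSE)
  }
  vapply(seq, function(s) {
    check_base_string(s, "seq")
    decode_seq(rev(3L - encode_seq(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Domain-based network design
#'
#' A design declares named binding domains (fixed domains keep their base
#' sequence during optimization; variable domains may be permuted) and a set
#' of oligomers, each a 5'->3' list of domain tokens. A trailing `"*"` on a
#' token denotes the reverse complement of the domain, so an oligomer
#' `c("a", "b*")` is the sequence of domain `a` followed by the reverse
#' complement of domain `b`. The intended ("necessary") duplexes of the
#' network are exactly the pairings between a domain instance and a
#' complemented instance of the same domain.
#'
#' @param fixed Named character vector of fixed-domain sequences (may be
#'   empty).
#' @param variable Named character vector of variable-domain sequences.
#' @param oligomers Named list; each element a character vector of domain
#'   tokens.
#' @return An object of class `oligo_design`.
#' @examples
#' d <- oligo_design(variable = c(a = "AACG"),
#'                   oligomers = list(X = "a", Y = "a*"))
#' compile_network(d)
#' @export
oligo_design <- function(fixed = character(), variable = character(),
                         oligomers = list()) {
  fixed <- vapply(fixed, check_base_string, character(1), what = "fixed domain")
  variable <- vapply(variable, check_base_string, character(1),
                     what = "variable domain")
  if (length(fixed) + length(variable) == 0L) {
    stop("design declares no domains", call. = FALSE)
  }
  nm <- c(names(fixed), names(variable))
  if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm)) {
    stop("all domains must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate domain name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  if (length(oligomers) == 0L) stop("design declares no oligomers", call. = FALSE)
  onm <- names(oligomers)
  if (is.null(onm) || any(!nzchar(onm))) {
    stop("all oligomers must be named", call. = FALSE)
  }
  if (anyDuplicated(onm)) {
    stop("duplicate oligomer name: ", onm[duplicated(onm)][1], call. = FALSE)
  }
  for (o in onm) {
    toks <- oligomers[[o]]
    if (!is.character(toks) || length(toks) == 0L) {
      stop("oligomer ", o, " has no domain tokens", call. = FALSE)
    }
    base <- sub("\\*$", "", toks)
    bad <- setdiff(base, nm)
    if (length(bad)) {
      stop("oligomer ", o, " references undeclared domain: ", bad[1],
           call. = FALSE)
    }
  }
  structure(list(fixed = fixed, variable = variable, oligomers = oligomers),
            class = "oligo_design")
}

#' @export
print.oligo_design <- function(x, ...) {
  cat("Domain-based design:", length(x$fixed), "fixed +", length(x$variable),
      "variable domains,", length(x$oligomers), "oligomers\n")
  for (o in names(x$oligomers)) {
    cat("  ", o, ": ", paste(x$oligomers[[o]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

domain_sequences <- function(design) c(design$fixed, design$variable)

#' Compile a design into a concrete network
#'
#' Concatenates each oligomer's domain tokens into a base sequence (complement
#' tokens contribute the reverse complement of the domain) and records, for
#' every base, its provenance: which domain it came from, its 1-based position
#' within that domain's own 5'->3' coordinates, and whether the token was
#' complemented. Provenance is what later distinguishes necessary base pairs
#' (same domain, same domain position, opposite complement flags) from
#' unnecessary ones.
#'
#' @param design An [oligo_design()].
#' @return An object of class `oligo_network` with elements `oligomers`
#'   (named character vector of sequences), `codes`, `provenance`, and the
#'   originating `design`.
#' @export
compile_network <- function(design) {
  if (!inherits(design, "oligo_design")) {
    stop("design must be an oligo_design", call. = FALSE)
  }
  doms <- domain_sequences(design)
  dom_ids <- seq_along(doms)
  names(dom_ids) <- names(doms)
  codes <- list()
  prov <- list()
  seqs <- character(0)
  for (o in names(design$oligomers)) {
    toks <- design$oligomers[[o]]
    parts <- vector("list", length(toks))
    pr_dom <- pr_pos <- pr_cmp <- vector("list", length(toks))
    for (t in seq_along(toks)) {
      comp <- grepl("\\*$", toks[t])
      dn <- sub("\\*$", "", toks[t])
      dc <- encode_seq(doms[[dn]])
      len <- length(dc)
      if (comp) {
        parts[[t]] <- rev(3L - dc)
        pr_pos[[t]] <- rev(seq_len(len))
      } else {
        parts[[t]] <- dc
        pr_pos[[t]] <- seq_len(len)
      }
      pr_dom[[t]] <- rep.int(dom_ids[[dn]], len)
      pr_cmp[[t]] <- rep.int(as.integer(comp), len)
    }
    codes[[o]] <- unlist(parts, use.names = FALSE)
    prov[[o]] <- list(dom = unlist(pr_dom, use.names = FALSE),
                      pos = unlist(pr_pos, use.names = FALSE),
                      cmp = unlist(pr_cmp, use.names = FALSE))
    seqs[[o]] <- decode_seq(codes[[o]])
  }
  structure(list(oligomers = seqs, codes = codes, provenance = prov,
                 design = design, domain_names = names(doms)),
            class = "oligo_network")
}

#' @export
print.oligo_network <- function(x, ...) {
  cat("Oligomer network:", length(x$oligomers), "oligomers,",
      sum(nchar(x$oligomers)), "bases\n")
  for (o in names(x$oligomers)) {
    cat("  ", o, " (", nchar(x$oligomers[[o]]), " nt): ", x$oligomers[[o]],
        "\n", sep = "")
  }
  invisible(x)
}

#' Per-base provenance of a compiled network
#'
#' @param network An [compile_network()] result.
#' @return A data.frame with one row per base: oligomer, position, base,
#'   domain, domain_pos, complement.
#' @export
provenance_table <- function(network) {
  stopifnot(inherits(network, "oligo_network"))
  do.call(rbind, lapply(names(network$oligomers), function(o) {
    pr <- network$provenance[[o]]
    data.frame(oligomer = o, position = seq_along(pr$dom),
               base = strsplit(network$oligomers[[o]], "")[[1]],
               domain = network$domain_names[pr$dom],
               domain_pos = pr$pos, complement = pr$cmp == 1L,
               stringsAsFactors = FALSE)
  }))
}

#' Random network with no intentional duplexes
#'
#' Generates `i` oligomers of `j` bases each, with bases drawn i.i.d.
#' uniformly from `{A,C,G,T}`. Each oligomer is its own variable singleton
#' domain, so the design declares no intended duplexes and every duplex the
#' network can form is unnecessary.
#'
#' @param i Number of oligomers (>= 1).
#' @param j Bases per oligomer (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return An `oligo_network`.
#' @export
random_network <- function(i, j, seed = NULL) {
  stopifnot(i >= 1, j >= 1)
  if (!is.null(seed)) set.seed(seed)
  vars <- vapply(seq_len(i), function(k) {
    paste(sample(BASES, j, replace = TRUE), collapse = "")
  }, character(1))
  names(vars) <- paste0("v", seq_len(i))
  oligs <- as.list(names(vars))
  names(oligs) <- paste0("X", seq_len(i))
  compile_network(oligo_design(variable = vars, oligomers = oligs))
}
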
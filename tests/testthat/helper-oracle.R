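# Independent brute-force oracles used to cross-check the compiled duplex
# scanner.  These deliberately share no code with the package internals: they
# test every candidate base pair directly and assemble maximal runs by
# explicit extension.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

pair_ok <- function(x, y) COMP[[x]] == y

# all maximal antiparallel inter runs between strings a and b
oracle_inter <- function(a, b) {
  av <- chars(a); bv <- chars(b)
  n <- length(av); m <- length(bv)
  match_pq <- function(p, q) {
    p >= 1 && p <= n && q >= 1 && q <= m && pair_ok(av[p], bv[q])
  }
  runs <- list()
  for (p in seq_len(n)) for (q in seq_len(m)) {
    if (!match_pq(p, q)) next
    if (match_pq(p - 1, q + 1)) next # not the 5'-most pair of the run
    L <- 1
    while (match_pq(p + L, q - L)) L <- L + 1
    runs[[length(runs) + 1L]] <- c(start_a = p, start_b = q - L + 1,
                                   length = L)
  }
  if (!length(runs)) {
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer()))
  }
  out <- as.data.frame(do.call(rbind, runs))
  out[order(out$start_a, out$start_b, out$length), ]
}

# all maximal intra runs (pairs p < q, disjoint segments) of one strand
oracle_intra <- function(s, min_loop = 0L) {
  sv <- chars(s)
  n <- length(sv)
  match_pq <- function(p, q) {
    p >= 1 && q <= n && q - p > min_loop && pair_ok(sv[p], sv[q])
  }
  runs <- list()
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (q <= p || !match_pq(p, q)) next
    if (match_pq(p - 1, q + 1)) next
    L <- 1
    while (match_pq(p + L, q - L)) L <- L + 1
    runs[[length(runs) + 1L]] <- c(start_a = p, start_b = q - L + 1,
                                   length = L)
  }
  if (!length(runs)) {
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer()))
  }
  out <- as.data.frame(do.call(rbind, runs))
  out[order(out$start_a, out$start_b, out$length), ]
}

# window score of a set of maximal run lengths, computed the slow way
oracle_score <- function(lens, slc = 1L) {
  total <- 0
  for (M in lens) {
    for (L in seq_len(M)) {
      if (L >= slc) total <- total + (M - L + 1) * 10^L
    }
  }
  total
}

random_seq <- function(j) paste(sample(c("A", "C", "G", "T"), j, TRUE),
                                collapse = "")

sorted_runs <- function(df) {
  df <- df[, c("start_a", "start_b", "length")]
  rownames(df) <- NULL
  df[order(df$start_a, df$start_b, df$length), ]
}
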
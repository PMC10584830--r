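# Ready-made designs and synthetic datasets.  These generators define the
# study conditions used throughout the tests and the acceptance analyses.

#' Three-strand formation/displacement model system
#'
#' Two binding domains: a variable 41-mer alpha whose base composition is
#' fixed at 10 C, 10 G, 10 A and 11 T (a random permutation thereof), and
#' the fixed 8-mer toehold beta = TCTCCATG. Three oligomers: S1 = alpha,
#' beta; S2 = beta*, alpha*; S3 = alpha. S1+S2 form the full 49-bp duplex
#' (formation reaction) and S1 displaces S3 from the S3:S2 duplex via the
#' beta toehold (displacement reaction).
#'
#' @param seed Optional integer seed for the alpha permutation.
#' @return An [oligo_design()].
#' @export
model_system_design <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- c(rep("C", 10), rep("G", 10), rep("A", 10), rep("T", 11))
  alpha <- paste(sample(comp), collapse = "")
  oligo_design(fixed = c(b = "TCTCCATG"),
               variable = c(a = alpha),
               oligomers = list(S1 = c("a", "b"),
                                S2 = c("b*", "a*"),
                                S3 = "a"))
}

#' Single-duplex and independent-duplexes designs
#'
#' `single_duplex_design(j)`: one variable `j`-mer domain and two oligomers
#' forming one intended `j`-bp duplex. `independent_duplex_design(i)`: `i`
#' independent intended duplexes of `bp` base pairs each (2*i oligomers).
#' Domain sequences are drawn uniformly at random.
#'
#' @param j Duplex length in base pairs.
#' @param i Number of duplexes.
#' @param bp Base pairs per duplex (default 8).
#' @param seed Optional integer seed.
#' @return An [oligo_design()].
#' @export
single_duplex_design <- function(j, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_single_duplex_design(j)
}

#' @rdname single_duplex_design
#' @export
independent_duplex_design <- function(i, bp = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_independent_duplex_design(i, bp)
}

#' Synthetic rate-constant table with a planted fit sub-population
#'
#' Emulates the shape of the published rate-constant collections: five
#' datasets (formation reactions at 37, 55 and 22 degrees C and a catalytic
#' and a leak reaction at 25 degrees C), each holding dozens of samples with
#' one random oligomer sequence per sample. Within each dataset the
#' `n_fit` samples with the lowest intra-oligomer score above baseline (dO)
#' are "clean": their log rate constants sit tightly (s.d. `sd_fit`) at the
#' dataset's rate ceiling. Every other sample falls below the ceiling by a
#' half-normal amount of scale `sd_unfit` in `ln(k)` — unintended duplexes
#' can only slow these reactions down, which reproduces the left-skewed,
#' orders-of-magnitude-wide histograms of the real collections. The planted
#' contrast is what the dispersion pipeline should recover.
#'
#' @param n_fit Planted clean samples per dataset (default 3).
#' @param sd_fit Normal s.d. of clean samples' `ln(k)` (default 0.1).
#' @param sd_unfit Half-normal scale of the dispersed samples' `ln(k)`
#'   shortfall below the ceiling (default 1.5).
#' @param olig_len Oligomer length per sample (default 30).
#' @param seed Optional integer seed.
#' @return Data.frame of rate-constant records (columns dataset, sample_id,
#'   k, temperature, reaction, sequences, dO, clean).
#' @export
synthetic_rate_table <- function(n_fit = 3L, sd_fit = 0.1, sd_unfit = 1.5,
                                 olig_len = 30L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  specs <- data.frame(
    dataset = c("Z37F", "Z55F", "H22F", "O25C", "O25L"),
    n = c(98L, 95L, 47L, 51L, 51L),
    temperature = c(37, 55, 22, 25, 25),
    reaction = c("formation", "formation", "formation", "catalytic", "leak"),
    meanlog_k = log(c(3e6, 5e6, 1e6, 5e3, 1e1)),
    stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(specs)), function(s) {
    n <- specs$n[s]
    seqs <- vapply(seq_len(n), function(t) {
      paste(sample(BASES, olig_len, TRUE), collapse = "")
    }, character(1))
    dO <- vapply(seqs, function(sq) {
      score_record_sequences(sq)$delta_O
    }, numeric(1), USE.NAMES = FALSE)
    clean <- rank(dO, ties.method = "first") <= n_fit
    ceiling_lnk <- specs$meanlog_k[s]
    lnk <- ifelse(clean,
                  rnorm(n, ceiling_lnk, sd_fit),
                  ceiling_lnk - abs(rnorm(n, 0, sd_unfit)))
    data.frame(dataset = specs$dataset[s],
               sample_id = sprintf("%s-%03d", specs$dataset[s], seq_len(n)),
               k = exp(lnk), temperature = specs$temperature[s],
               reaction = specs$reaction[s], sequences = seqs, dO = dO,
               clean = clean, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Synthetic fluorescence traces on a compensation line
#'
#' Generates one second-order trace per (activation energy, temperature)
#' combination, with rate constants given by the compensation model
#' `k = C3 exp((Ea/kB)(1/Tc - 1/T))` and signals from
#' [simulate_second_order()].
#'
#' @param Eas Activation energies (J) of the simulated networks.
#' @param temps_c Temperatures (degrees C).
#' @param C3,Tc Compensation constants (defaults 1.97e8 M^-1 s^-1, 352 K).
#' @param times Sampling times (s).
#' @param C0 Initial concentration (M).
#' @param noise_sd Gaussian signal noise.
#' @param seed Optional integer seed.
#' @return Data.frame: network, Ea, temperature, k_true, and a list-column
#'   `trace` of `fluorescence_trace` objects.
#' @export
synthetic_traces <- function(Eas = seq(1.2e-19, 2.0e-19, length.out = 5),
                             temps_c = c(10, 20, 30, 40, 50, 60),
                             C3 = 1.97e8, Tc = 352,
                             times = seq(0, 500, by = 1), C0 = 1e-8,
                             noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(net = seq_along(Eas), temp = temps_c)
  traces <- vector("list", nrow(grid))
  ks <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    Ea <- Eas[grid$net[g]]
    ks[g] <- rate_from_compensation(Ea, grid$temp[g] + 273.15, C3, Tc)
    traces[[g]] <- simulate_second_order(ks[g], times, C0 = C0,
                                         noise_sd = noise_sd,
                                         temperature = grid$temp[g])
  }
  out <- data.frame(network = grid$net, Ea = Eas[grid$net],
                    temperature = grid$temp, k_true = ks)
  out$trace <- traces
  out
}
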
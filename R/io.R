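#' Default runtime parameters
#'
#' Optimizer and scoring defaults: CPL (cycles per lineage) 100000, GPC
#' (generations per cycle) 1, NDPM (domains mutated per mutation) 1, NL
#' (lineages) 8, NMPC (new mothers per cycle) 1; scoring length criteria
#' intraSLC = interSLC = 1; scoringWeightX = 10000; homopolymer limits
#' maxAA = 6, maxCC = 3, maxGG = 3, maxTT = 6.
#'
#' @return Named list of default parameter values.
#' @export
default_parameters <- function() {
  list(CPL = 100000L, GPC = 1L, NDPM = 1L, NL = 8L, NMPC = 1L,
       intraSLC = 1L, interSLC = 1L, scoringWeightX = 10000,
       maxAA = 6L, maxCC = 3L, maxGG = 3L, maxTT = 6L,
       objective = "W")
}

read_kv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  list(lines = lines[keep], numbers = keep)
}

#' Read a domain-based design from its four text files
#'
#' The on-disk dialect: the parameters file holds `key=value` lines; the
#' fixed-domains and variable-domains files hold one `name<TAB>sequence` per
#' line; the oligomers file holds `name<TAB>token token ...` where a token is
#' a domain name, optionally suffixed `*` for its reverse complement. `#`
#' comments and blank lines are ignored in all four files. Unknown parameter
#' keys produce a warning and are kept verbatim.
#'
#' @param parameters,fixed,variable,oligomers Paths to the four files.
#' @return A list with elements `design` ([oligo_design()]) and `parameters`
#'   (defaults overridden by the file).
#' @export
parse_design <- function(parameters, fixed, variable, oligomers) {
  paths <- c(parameters = parameters, fixed = fixed, variable = variable,
             oligomers = oligomers)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      stop("missing ", nm, " file: ", paths[[nm]], call. = FALSE)
    }
  }
  pars <- default_parameters()
  kv <- read_kv_lines(parameters)
  for (idx in seq_along(kv$lines)) {
    ln <- kv$lines[idx]
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(parameters, " line ", kv$numbers[idx], ": expected key=value",
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (key %in% names(pars)) {
      pars[[key]] <- if (key == "objective") val else as.numeric(val)
    } else {
      warning("unknown parameter key ignored: ", key, call. = FALSE)
      pars[[key]] <- val
    }
  }
  read_domfile <- function(path) {
    kv <- read_kv_lines(path)
    out <- character(0)
    for (idx in seq_along(kv$lines)) {
      fields <- strsplit(kv$lines[idx], "\t", fixed = TRUE)[[1]]
      fields <- fields[nzchar(trimws(fields))]
      if (length(fields) != 2L) {
        stop(path, " line ", kv$numbers[idx],
             ": expected name<TAB>sequence", call. = FALSE)
      }
      nm <- trimws(fields[1])
      if (nm %in% names(out)) {
        stop(path, " line ", kv$numbers[idx], ": duplicate domain name ", nm,
             call. = FALSE)
      }
      out[[nm]] <- trimws(fields[2])
    }
    out
  }
  fixed_dom <- read_domfile(fixed)
  variable_dom <- read_domfile(variable)
  kv <- read_kv_lines(oligomers)
  oligs <- list()
  for (idx in seq_along(kv$lines)) {
    fields <- strsplit(kv$lines[idx], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop(oligomers, " line ", kv$numbers[idx],
           ": expected name<TAB>token token ...", call. = FALSE)
    }
    nm <- trimws(fields[1])
    if (nm %in% names(oligs)) {
      stop(oligomers, " line ", kv$numbers[idx],
           ": duplicate oligomer name ", nm, call. = FALSE)
    }
    toks <- strsplit(trimws(paste(fields[-1], collapse = " ")), "\\s+")[[1]]
    oligs[[nm]] <- toks
  }
  list(design = oligo_design(fixed = fixed_dom, variable = variable_dom,
                             oligomers = oligs),
       parameters = pars)
}

#' Write a design (and optional parameters) as the four-file dialect
#'
#' Inverse of [parse_design()]; the canonical output round-trips byte-stably.
#'
#' @param design An [oligo_design()].
#' @param dir Output directory (created if needed).
#' @param parameters Optional named list written to the parameters file.
#' @return Invisibly, the four file paths.
#' @export
write_design <- function(design, dir, parameters = NULL) {
  stopifnot(inherits(design, "oligo_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("parameters.txt", "fixed-domains.txt",
                            "variable-domains.txt", "oligomers.txt"))
  names(paths) <- c("parameters", "fixed", "variable", "oligomers")
  if (is.null(parameters)) parameters <- list()
  writeLines(sprintf("%s=%s", names(parameters),
                     vapply(parameters, format, character(1))),
             paths[["parameters"]])
  writeLines(sprintf("%s\t%s", names(design$fixed), design$fixed),
             paths[["fixed"]])
  writeLines(sprintf("%s\t%s", names(design$variable), design$variable),
             paths[["variable"]])
  writeLines(sprintf("%s\t%s", names(design$oligomers),
                     vapply(design$oligomers, paste, character(1),
                            collapse = " ")),
             paths[["oligomers"]])
  invisible(paths)
}

#' Export a network's oligomers as FASTA
#'
#' One record per oligomer; headers are oligomer names.
#'
#' @param network An `oligo_network`.
#' @param path Optional file path; when `NULL` the FASTA text is returned.
#' @param width Optional line-wrap width (e.g. 80); default no wrapping.
#' @return The FASTA text, invisibly when written to a file.
#' @export
write_fasta <- function(network, path = NULL, width = NULL) {
  stopifnot(inherits(network, "oligo_network"))
  recs <- vapply(names(network$oligomers), function(o) {
    s <- network$oligomers[[o]]
    if (!is.null(width)) {
      s <- paste(substring(s, seq(1, nchar(s), width),
                           pmin(nchar(s), seq(width, nchar(s) + width - 1,
                                              width))),
                 collapse = "\n")
    }
    paste0(">", o, "\n", s, "\n")
  }, character(1))
  txt <- paste(recs, collapse = "")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Read / write rate-constant tables
#'
#' Tab-delimited text with header columns `dataset`, `sample_id`, `k`
#' (M^-1 s^-1, positive), and optionally `temperature` (degrees C),
#' `reaction`, and `sequences` (comma-separated oligomer base strings used
#' for fitness scoring).
#'
#' @param path File path.
#' @return A data.frame of rate-constant records.
#' @export
read_rate_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("dataset", "sample_id", "k")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("rate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$k)) || any(df$k <= 0)) {
    stop("rate constants must be positive and finite", call. = FALSE)
  }
  df
}

#' @rdname read_rate_table
#' @param records Data.frame of rate-constant records.
#' @export
write_rate_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
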
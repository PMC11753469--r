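#' Read a fluctuation colony-count table
#'
#' Expected CSV schema (one row per culture): `environment`, `count`, `Nt`,
#' `epsilon`. The `count` column holds a non-negative integer or one of the
#' flags `burst` (uncountable plate, kept as a censored culture) or `invalid`
#' (discarded plate, excluded entirely). Malformed rows raise an error that
#' lists the offending line numbers.
#'
#' @param path CSV file path.
#' @return data.frame with columns `environment`, `count` (integer, `NA` for
#'   burst plates), `censored` (logical), `Nt`, `epsilon`; `invalid` rows are
#'   dropped.
#' @export
read_counts_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .require_columns(raw, c("environment", "count", "Nt", "epsilon"), path)
  cnt <- trimws(raw$count)
  flag_burst <- tolower(cnt) == "burst"
  flag_invalid <- tolower(cnt) == "invalid"
  num <- suppressWarnings(as.numeric(cnt))
  bad <- !flag_burst & !flag_invalid &
    (is.na(num) | num < 0 | num != floor(num))
  nt <- suppressWarnings(as.numeric(raw$Nt))
  eps <- suppressWarnings(as.numeric(raw$epsilon))
  bad <- bad | is.na(nt) | nt <= 0 | is.na(eps) | eps <= 0 | eps > 1
  if (any(bad)) {
    stop(sprintf("malformed rows in %s (data lines %s)", path,
                 paste(which(bad) + 1L, collapse = ", ")))
  }
  out <- data.frame(
    environment = raw$environment,
    count = ifelse(flag_burst, NA_integer_, as.integer(num)),
    censored = flag_burst,
    Nt = nt,
    epsilon = eps,
    stringsAsFactors = FALSE
  )
  out[!flag_invalid, , drop = FALSE]
}

#' Write a fluctuation colony-count table
#' @param counts data.frame in the layout returned by [read_counts_table()].
#' @param path output CSV path.
#' @export
write_counts_table <- function(counts, path) {
  out <- data.frame(
    environment = counts$environment,
    count = ifelse(counts$censored, "burst", as.character(counts$count)),
    Nt = counts$Nt,
    epsilon = counts$epsilon,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble fluctuation experiments from a counts table
#' @param counts data.frame from [read_counts_table()].
#' @param censor_mode,ceiling see [fluctuation_experiment()].
#' @return Named list of [fluctuation_experiment()]s, one per environment.
#' @export
experiments_from_counts <- function(counts, censor_mode = "exclude",
                                    ceiling = NULL) {
  envs <- unique(counts$environment)
  out <- lapply(envs, function(env) {
    sub <- counts[counts$environment == env, , drop = FALSE]
    if (length(unique(sub$Nt)) > 1 || length(unique(sub$epsilon)) > 1) {
      stop(sprintf("environment '%s' mixes Nt or epsilon values", env))
    }
    fluctuation_experiment(sub$count, n_total_cells = sub$Nt[1],
                           plating_fraction = sub$epsilon[1],
                           environment_label = env,
                           censored_high = sub$censored,
                           censor_mode = censor_mode, ceiling = ceiling)
  })
  names(out) <- envs
  out
}

#' Read a gene catalogue CSV (`gene`, `length_bp`, `lps_class`)
#' @param path CSV file path.
#' @return Validated catalogue data.frame.
#' @export
read_gene_catalogue <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(g, c("gene", "length_bp", "lps_class"), path)
  .check_gene_catalogue(g)
  g
}

#' Read a long-format survival matrix CSV (`gene`, `environment`, `x`, `n`)
#' @param path CSV file path.
#' @return Validated survival data.frame.
#' @export
read_survival_matrix <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(s, c("gene", "environment", "x", "n"), path)
  .check_survival(s)
  s
}

#' Write a survival matrix CSV
#' @param survival long-format survival data.frame.
#' @param path output CSV path.
#' @export
write_survival_matrix <- function(survival, path) {
  .check_survival(survival)
  write.csv(survival, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mutant genotype table CSV
#'
#' Schema: `isolate_id`, `environment`, `mutated_genes`
#' (semicolon-separated), optional precomputed `causal_gene`.
#'
#' @param path CSV file path.
#' @return data.frame suitable for [mutant_spectrum()].
#' @export
read_mutant_table <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(m, c("isolate_id", "environment"), path)
  if (!("mutated_genes" %in% names(m)) && !("causal_gene" %in% names(m))) {
    stop(sprintf("%s needs a mutated_genes or causal_gene column", path))
  }
  if ("mutated_genes" %in% names(m)) {
    empty <- !nzchar(trimws(m$mutated_genes))
    if (any(empty)) {
      stop(sprintf("empty mutated_genes in %s (data lines %s)", path,
                   paste(which(empty) + 1L, collapse = ", ")))
    }
  }
  m
}

#' Read a greyscale plate table CSV
#'
#' Schema: `strain`, `antibiotic`, `concentration`, `replicate`,
#' `mean_greyscale`, `blank_greyscale`. Antibiotic names are restricted to
#' `none`, `chloramphenicol`, `gentamicin`.
#'
#' @param path CSV file path.
#' @return Validated plate-record data.frame.
#' @export
read_plate_table <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(p, c("strain", "antibiotic", "concentration", "replicate",
                        "mean_greyscale", "blank_greyscale"), path)
  ok <- c("none", "chloramphenicol", "gentamicin")
  bad <- !(p$antibiotic %in% ok)
  if (any(bad)) {
    stop(sprintf("unknown antibiotic in %s (data lines %s): %s", path,
                 paste(which(bad) + 1L, collapse = ", "),
                 paste(unique(p$antibiotic[bad]), collapse = ", ")))
  }
  rng <- p$mean_greyscale < 0 | p$mean_greyscale > 255 |
    p$blank_greyscale < 0 | p$blank_greyscale > 255
  if (any(rng)) {
    stop(sprintf("greyscale values outside [0, 255] in %s (data lines %s)",
                 path, paste(which(rng) + 1L, collapse = ", ")))
  }
  p
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing columns: %s", path,
                 paste(miss, collapse = ", ")))
  }
  invisible(df)
}
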
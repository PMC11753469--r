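#' Median blank-subtracted growth values per strain and concentration
#'
#' Growth on an agar lawn is quantified as the mean 8-bit greyscale value of a
#' fixed plate region minus the mean greyscale of a blank plate; replicates
#' (1-5 per strain x concentration) are summarised by their median.
#'
#' @param records data.frame of plate measurements with columns `strain`,
#'   `antibiotic`, `concentration`, `replicate`, `mean_greyscale`,
#'   `blank_greyscale`.
#' @return data.frame with one row per strain x antibiotic x concentration:
#'   `median_growth_value` (may be negative; clamped only when calling
#'   growth) and `n_replicates`.
#' @export
growth_values <- function(records) {
  need <- c("strain", "antibiotic", "concentration",
            "mean_greyscale", "blank_greyscale")
  if (!all(need %in% names(records))) {
    stop("plate records need columns ", paste(need, collapse = ", "))
  }
  if (nrow(records) == 0) stop("no plate measurements supplied")
  gv <- records$mean_greyscale - records$blank_greyscale
  key <- interaction(records$strain, records$antibiotic,
                     records$concentration, drop = TRUE)
  med <- tapply(gv, key, median)
  n <- tapply(gv, key, length)
  first <- !duplicated(key)
  out <- data.frame(
    strain = records$strain[first],
    antibiotic = records$antibiotic[first],
    concentration = records$concentration[first],
    median_growth_value = as.numeric(med[as.character(key[first])]),
    n_replicates = as.integer(n[as.character(key[first])]),
    stringsAsFactors = FALSE
  )
  out[order(out$strain, out$antibiotic, out$concentration), , drop = FALSE]
}

#' Call growth from a median greyscale value
#'
#' A lawn is called "growth" when its median blank-subtracted greyscale value
#' strictly exceeds the threshold tau (8 under the strict convention, 12
#' under the lenient one used by model 3); equality counts as no growth, so
#' the growth/no-growth pair is complementary with the MIC rule.
#'
#' @param median_value numeric vector of median growth values.
#' @param threshold growth threshold tau (default 8).
#' @return Logical vector: `TRUE` where the strain grows.
#' @export
call_growth <- function(median_value, threshold = 8) {
  if (threshold <= 0) stop("threshold must be positive")
  pmax(median_value, 0) > threshold
}

#' Minimum inhibitory concentration from a growth series
#'
#' Scans a strain's median growth values over ascending antibiotic
#' concentrations and returns the lowest concentration whose median falls
#' below the growth threshold (first crossing; non-monotone profiles are
#' resolved by the same rule). If the strain grows at every tested
#' concentration the MIC is above the tested range and `Inf` is returned.
#'
#' @param concentrations strictly ascending numeric vector.
#' @param median_values median growth value at each concentration.
#' @param threshold growth threshold tau (8 or 12).
#' @return A list with `mic` (numeric, `Inf` meaning above range) and
#'   `above_range` (logical).
#' @export
mic <- function(concentrations, median_values, threshold = 8) {
  if (length(concentrations) == 0) stop("empty concentration series")
  if (length(concentrations) != length(median_values)) {
    stop("concentrations and median values differ in length")
  }
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly ascending")
  }
  no_growth <- !call_growth(median_values, threshold)
  i <- which(no_growth)
  if (length(i) == 0) {
    list(mic = Inf, above_range = TRUE)
  } else {
    list(mic = concentrations[min(i)], above_range = FALSE)
  }
}

#' Build the per-gene survival matrix from growth calls
#'
#' Aggregates strain-level growth calls into the gene-level survival entries
#' consumed by the target-size models: for each gene and environment, `x` is
#' the number of strains carrying a mutation in that gene that grow, and `n`
#' the total number of strains carrying a mutation in that gene.
#'
#' @param calls data.frame with columns `strain`, `environment`, `grows`
#'   (logical).
#' @param strain_to_gene named character vector mapping each strain to its
#'   causal gene.
#' @return Long-format data.frame `gene`, `environment`, `x`, `n`.
#' @export
survival_matrix <- function(calls, strain_to_gene) {
  need <- c("strain", "environment", "grows")
  if (!all(need %in% names(calls))) {
    stop("growth calls need columns ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(unique(calls$strain), names(strain_to_gene))
  if (length(unknown) > 0) {
    stop("strains without gene assignment: ", paste(unknown, collapse = ", "))
  }
  gene <- strain_to_gene[calls$strain]
  key <- interaction(gene, calls$environment, drop = TRUE)
  x <- tapply(calls$grows, key, sum)
  n <- tapply(calls$grows, key, length)
  first <- !duplicated(key)
  out <- data.frame(
    gene = unname(gene[first]),
    environment = calls$environment[first],
    x = as.integer(x[as.character(key[first])]),
    n = as.integer(n[as.character(key[first])]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$environment, out$gene), , drop = FALSE]
}

#' MIC table for a set of strains
#'
#' Applies [growth_values()] and [mic()] across strains and antibiotics.
#'
#' @inheritParams growth_values
#' @param threshold growth threshold tau.
#' @return data.frame `strain`, `antibiotic`, `mic` (`Inf` = above tested
#'   range).
#' @export
mic_table <- function(records, threshold = 8) {
  med <- growth_values(records)
  combos <- unique(med[, c("strain", "antibiotic")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- med[med$strain == combos$strain[i] &
                 med$antibiotic == combos$antibiotic[i], , drop = FALSE]
    sub <- sub[order(sub$concentration), , drop = FALSE]
    m <- mic(sub$concentration, sub$median_growth_value, threshold)
    data.frame(strain = combos$strain[i], antibiotic = combos$antibiotic[i],
               mic = m$mic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
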
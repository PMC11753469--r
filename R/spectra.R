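#' Assign the causal gene of a multi-mutation isolate
#'
#' When a phage-resistant isolate carries mutations in several genes, the
#' causal gene is taken to be the one predicted to cause the most dramatic
#' LPS change: severity precedence `deep_rough > regulatory > rough >
#' non_lps`. Ties within a class are broken deterministically by the earlier
#' position in the biosynthetic-pathway order of the catalogue. Genes absent
#' from the catalogue rank as `non_lps`; if no mutated gene is catalogued the
#' first listed gene is returned (and classifies as `non_lps`).
#'
#' @param mutated_genes non-empty character vector of mutated gene names.
#' @param catalogue gene catalogue (see [lps_gene_catalogue()]).
#' @return The causal gene name (length-1 character).
#' @export
assign_causal_gene <- function(mutated_genes, catalogue = lps_gene_catalogue()) {
  if (length(mutated_genes) == 0) stop("mutated gene list must be non-empty")
  severity <- c(deep_rough = 1, regulatory = 2, rough = 3, non_lps = 4)
  pos <- match(mutated_genes, catalogue$gene)
  cls <- ifelse(is.na(pos), "non_lps", catalogue$lps_class[pos])
  rank_class <- severity[cls]
  # tie-break: catalogue row order; uncatalogued genes keep input order last
  rank_pos <- ifelse(is.na(pos), nrow(catalogue) + seq_along(mutated_genes), pos)
  mutated_genes[order(rank_class, rank_pos)][1]
}

#' LPS class of a gene
#' @param gene character vector of gene names.
#' @param catalogue gene catalogue.
#' @return Character vector of classes; uncatalogued genes are `non_lps`.
#' @export
gene_class <- function(gene, catalogue = lps_gene_catalogue()) {
  pos <- match(gene, catalogue$gene)
  ifelse(is.na(pos), "non_lps", catalogue$lps_class[pos])
}

#' Observed mutant spectrum of an environment
#'
#' Counts causal genes among the resistant isolates of one plating
#' environment, zero-filled over the gene catalogue, with gene-wise and
#' LPS-class proportions.
#'
#' @param mutants data.frame with columns `isolate_id`, `environment` and
#'   either `causal_gene` or `mutated_genes` (semicolon-separated string or
#'   list-column); causal genes are derived with [assign_causal_gene()] when
#'   absent.
#' @param environment environment label to tabulate.
#' @param catalogue gene catalogue.
#' @return An object of class `mutant_spectrum`: list with `counts`
#'   (named integer vector over the catalogue plus any extra observed genes),
#'   `proportions`, `class_proportions`, `n_isolates`, `environment`.
#' @export
mutant_spectrum <- function(mutants, environment,
                            catalogue = lps_gene_catalogue()) {
  if (!all(c("isolate_id", "environment") %in% names(mutants))) {
    stop("mutant table needs columns isolate_id, environment")
  }
  sub <- mutants[mutants$environment == environment, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("no isolates for environment '%s'", environment))
  }
  causal <- if ("causal_gene" %in% names(sub) && !anyNA(sub$causal_gene)) {
    as.character(sub$causal_gene)
  } else {
    if (!("mutated_genes" %in% names(sub))) {
      stop("mutant table needs causal_gene or mutated_genes")
    }
    vapply(sub$mutated_genes, function(g) {
      if (!is.character(g) || length(g) == 1L) {
        g <- strsplit(as.character(g), ";", fixed = TRUE)[[1]]
      }
      assign_causal_gene(trimws(g), catalogue)
    }, character(1), USE.NAMES = FALSE)
  }
  genes <- union(catalogue$gene, unique(causal))
  counts <- vapply(genes, function(g) sum(causal == g), integer(1))
  n <- sum(counts)
  prop <- counts / n
  cls <- gene_class(genes, catalogue)
  classes <- c("rough", "deep_rough", "regulatory", "non_lps")
  class_prop <- vapply(classes, function(cl) sum(prop[cls == cl]), numeric(1))
  structure(
    list(counts = counts, proportions = prop,
         class_proportions = class_prop,
         n_isolates = n, environment = environment),
    class = "mutant_spectrum"
  )
}

#' @export
print.mutant_spectrum <- function(x, ...) {
  cat(sprintf("Mutant spectrum [%s], %d isolates\n", x$environment,
              x$n_isolates))
  nz <- x$counts[x$counts > 0]
  cat("  ", paste(sprintf("%s: %d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap standard deviations of a mutant spectrum
#'
#' Quantifies sampling error of the observed gene and LPS-class proportions
#' by resampling with replacement. Before sampling, a pseudo-count of
#' `pseudo_count` pseudo-isolates is added for every candidate gene that
#' could confer phage resistance in the environment, so that unobserved but
#' accessible genes can be resampled; each replicate draws the full augmented
#' pool size with replacement, and the standard deviation of the per-gene
#' (and per-class) proportions across replicates is reported.
#'
#' @param spectrum a [mutant_spectrum()].
#' @param candidate_genes character vector of genes able to confer resistance
#'   in this environment (receive the pseudo-count).
#' @param n_boot number of bootstrap replicates (default 100).
#' @param pseudo_count pseudo-isolates per candidate gene (default 1).
#' @param seed integer seed; resampling is reproducible given the seed.
#' @param catalogue gene catalogue used for class aggregation.
#' @return List with `sd_gene` (named numeric), `sd_class`,
#'   `pool_proportions` (proportions in the augmented pool), `pool_size`,
#'   `n_boot`.
#' @export
bootstrap_spectrum <- function(spectrum, candidate_genes, n_boot = 100,
                               pseudo_count = 1, seed,
                               catalogue = lps_gene_catalogue()) {
  stopifnot(inherits(spectrum, "mutant_spectrum"))
  if (n_boot < 1) stop("n_boot must be positive")
  if (pseudo_count < 0) stop("pseudo_count must be non-negative")
  if (missing(seed)) stop("a seed is required for reproducibility")
  genes <- union(names(spectrum$counts), candidate_genes)
  counts <- spectrum$counts[genes]
  counts[is.na(counts)] <- 0L
  names(counts) <- genes
  counts[candidate_genes] <- counts[candidate_genes] + pseudo_count
  pool_size <- sum(counts)
  if (pool_size == 0) stop("augmented resampling pool is empty")
  probs <- counts / pool_size
  cls <- gene_class(genes, catalogue)
  classes <- c("rough", "deep_rough", "regulatory", "non_lps")
  class_mat <- outer(classes, cls, "==") * 1

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- rmultinom(n_boot, size = pool_size, prob = probs) / pool_size
  sd_gene <- apply(draws, 1, sd)
  names(sd_gene) <- genes
  class_draws <- class_mat %*% draws
  sd_class <- apply(class_draws, 1, sd)
  names(sd_class) <- classes
  list(sd_gene = sd_gene, sd_class = sd_class,
       pool_proportions = probs, pool_size = pool_size, n_boot = n_boot)
}

#' Chi-square goodness of fit of an observed spectrum to a model prediction
#'
#' Pearson chi-square test of observed causal-gene counts (or LPS-class
#' counts) against the proportions predicted by a target-size model, with
#' asymptotic p-values and no continuity correction. Categories with zero
#' expected proportion are disallowed: extend the model-1 catalogue with the
#' added genes (`lps_gene_catalogue(added_genes = TRUE)`) so that every
#' observed category has positive expectation.
#'
#' @param observed a [mutant_spectrum()].
#' @param predicted a [predicted_distributions()] result.
#' @param mode `"gene_wise"` compares per-gene counts, `"lps_type"` compares
#'   rough / deep-rough / regulatory (and non-LPS if observed) classes.
#' @param catalogue gene catalogue for class aggregation.
#' @return List with `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
gof_chisq <- function(observed, predicted,
                      mode = c("gene_wise", "lps_type"),
                      catalogue = lps_gene_catalogue()) {
  mode <- match.arg(mode)
  stopifnot(inherits(observed, "mutant_spectrum"),
            inherits(predicted, "model_prediction"))
  if (mode == "gene_wise") {
    genes <- names(predicted$gene_proportions)
    obs <- observed$counts[genes]
    obs[is.na(obs)] <- 0L
    names(obs) <- genes
    extra <- setdiff(names(observed$counts)[observed$counts > 0], genes)
    if (length(extra) > 0) {
      stop("observed categories with zero expectation: ",
           paste(extra, collapse = ", "),
           "; use the added-genes catalogue variant")
    }
    expp <- predicted$gene_proportions
  } else {
    obs_all <- observed$class_proportions * observed$n_isolates
    expp_all <- predicted$lps_type_proportions
    keep <- obs_all > 0 | expp_all > 0
    obs <- obs_all[keep]
    expp <- expp_all[keep]
  }
  if (any(expp == 0 & obs > 0)) {
    stop("observed categories with zero expectation; ",
         "use the added-genes catalogue variant")
  }
  keep <- expp > 0
  obs <- obs[keep]
  expp <- expp[keep] / sum(expp[keep])
  n <- sum(obs)
  expected <- n * expp
  statistic <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  list(statistic = statistic, df = df,
       p_value = pchisq(statistic, df, lower.tail = FALSE),
       observed = obs, expected = expected)
}
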
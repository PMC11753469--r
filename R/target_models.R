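#' Mutational target-size weights, model 1 (gene-length model)
#'
#' Model 1 assumes that phage-resistance mutations occur with probability
#' proportional to the coding length of the target gene, and that a mutation
#' in gene g establishes a colony in a phage+antibiotic environment with the
#' empirically measured survival fraction x/n of mutants in that gene. The
#' per-gene weight is therefore `(x_g / n_g) * length_g` and the total weight
#' is the environment's permissible mutational target size (in bp
#' equivalents). For example, with 1 of 5 galU mutants growing at 2 ug/ml
#' chloramphenicol, galU (909 bp) scores `(1/5) * 909 = 181.8`, displayed as
#' 182 under round-half-up.
#'
#' @param genes gene catalogue, as from [lps_gene_catalogue()]: columns
#'   `gene`, `length_bp`, `lps_class`.
#' @param survival long-format survival matrix (columns `gene`,
#'   `environment`, `x`, `n`), as from [table1_survival()] or
#'   [survival_matrix()].
#' @param environment environment label to build weights for.
#' @param survival_proxy named character vector mapping genes without a
#'   survival entry to the gene whose profile they borrow (defaults to the
#'   stated proxies `hldD -> hldE`, `gmhA -> gmhB`).
#' @return A `gene_weight_table`: data.frame with columns `gene`, `weight`
#'   and attributes `model_id`, `environment`, `total_weight`, plus the
#'   catalogue's `lps_class`.
#' @export
model1_weights <- function(genes, survival, environment,
                           survival_proxy = c(hldD = "hldE", gmhA = "gmhB")) {
  frac <- .survival_fractions(genes, survival, environment, survival_proxy)
  .weight_table(genes, frac * genes$length_bp, "model1", environment)
}

#' Mutational target-size weights, model 2 (observed-spectrum model)
#'
#' Model 2 replaces gene length with the number of mutations actually
#' observed per gene in the reference (phage-only) environment, augmented by
#' a pseudo-count so that genes with zero observed mutations retain a nonzero
#' weight: `weight_g = (x_g / n_g) * (count_g + pseudo_count)`.
#'
#' @inheritParams model1_weights
#' @param observed_counts_reference named integer vector (or data.frame with
#'   columns `gene`, `count`) of observed causal-mutation counts per gene in
#'   the phage-only environment. Genes of the catalogue absent from the
#'   vector count as zero.
#' @param pseudo_count added to every catalogued gene's count (default 1).
#' @return A `gene_weight_table` (see [model1_weights()]).
#' @export
model2_weights <- function(genes, observed_counts_reference, survival,
                           environment, pseudo_count = 1,
                           survival_proxy = c(hldD = "hldE", gmhA = "gmhB")) {
  counts <- .as_named_counts(observed_counts_reference)
  if (any(counts < 0)) stop("observed counts must be non-negative")
  if (pseudo_count < 0) stop("pseudo_count must be non-negative")
  base <- counts[genes$gene]
  base[is.na(base)] <- 0
  base <- base + pseudo_count
  frac <- .survival_fractions(genes, survival, environment, survival_proxy)
  .weight_table(genes, frac * base, "model2", environment)
}

#' Mutational target-size weights, model 3 (lenient growth threshold)
#'
#' Model 3 is model 2 evaluated against a survival matrix rebuilt with the
#' lenient greyscale growth threshold of 12 instead of the strict 8 (see
#' [call_growth()] and [survival_matrix()]): candidate genes and baseline
#' weights are unchanged, but genes whose mutants no longer clear the higher
#' threshold drop out of the permissible target.
#'
#' @inheritParams model2_weights
#' @param survival_t12 survival matrix recomputed at growth threshold 12.
#' @return A `gene_weight_table` (see [model1_weights()]).
#' @export
model3_weights <- function(genes, observed_counts_reference, survival_t12,
                           environment, pseudo_count = 1,
                           survival_proxy = c(hldD = "hldE", gmhA = "gmhB")) {
  w <- model2_weights(genes, observed_counts_reference, survival_t12,
                      environment, pseudo_count, survival_proxy)
  attr(w, "model_id") <- "model3"
  w
}

#' Predicted relative phage-resistance rate
#'
#' The predicted resistance rate of an environment relative to a reference is
#' the ratio of their total weighted mutational target sizes,
#' `rho = total_env / total_ref`. With the built-in gene table this gives,
#' e.g., 5458.8 / 11736 = 0.465 (printed 0.47) for phage + 2 ug/ml
#' chloramphenicol versus phage alone.
#'
#' @param weights_env,weights_ref `gene_weight_table`s from the same model
#'   and gene catalogue.
#' @return The relative rate, a non-negative number.
#' @export
predicted_relative_rate <- function(weights_env, weights_ref) {
  .check_weight_table(weights_env)
  .check_weight_table(weights_ref)
  if (attr(weights_env, "model_id") != attr(weights_ref, "model_id")) {
    stop("weight tables come from different models")
  }
  if (!identical(weights_env$gene, weights_ref$gene)) {
    stop("weight tables use different gene catalogues")
  }
  total_ref <- attr(weights_ref, "total_weight")
  if (total_ref <= 0) stop("reference environment has zero total weight")
  attr(weights_env, "total_weight") / total_ref
}

#' Predicted mutant-spectrum distribution under a target-size model
#'
#' Normalizes a gene-weight table into predicted per-gene mutation
#' proportions and aggregates them by LPS phenotype class. `rfaH` is reported
#' as its own `regulatory` category and never folded into rough or
#' deep-rough.
#'
#' @param weights a `gene_weight_table`.
#' @param genes the gene catalogue the weights were built from.
#' @return An object of class `model_prediction`: list with
#'   `gene_proportions` (named, sums to 1), `lps_type_proportions` (named over
#'   `rough`, `deep_rough`, `regulatory`, `non_lps`), `model_id`,
#'   `environment`, `total_weight`.
#' @export
predicted_distributions <- function(weights, genes) {
  .check_weight_table(weights)
  total <- attr(weights, "total_weight")
  if (total <= 0) stop("total weight is zero; no distribution is defined")
  prop <- weights$weight / total
  names(prop) <- weights$gene
  cls <- genes$lps_class[match(weights$gene, genes$gene)]
  cls[is.na(cls)] <- "non_lps"
  classes <- c("rough", "deep_rough", "regulatory", "non_lps")
  by_class <- vapply(classes, function(cl) sum(prop[cls == cl]), numeric(1))
  structure(
    list(
      gene_proportions = prop,
      lps_type_proportions = by_class,
      model_id = attr(weights, "model_id"),
      environment = attr(weights, "environment"),
      total_weight = total
    ),
    class = "model_prediction"
  )
}

#' @export
print.model_prediction <- function(x, ...) {
  cat(sprintf("Predicted mutant spectrum (%s, %s; total weight %.1f)\n",
              x$model_id, x$environment, x$total_weight))
  cat("  LPS classes:",
      paste(sprintf("%s %.1f%%", names(x$lps_type_proportions),
                    100 * x$lps_type_proportions), collapse = ", "), "\n")
  invisible(x)
}

#' Summarise model-1 predictions across environments in the printed layout
#'
#' Convenience wrapper reproducing the layout of the a-priori prediction
#' table: per-gene integer weights (round-half-up) per environment, totals,
#' and relative rates versus the reference environment.
#'
#' @param genes gene catalogue.
#' @param survival long-format survival matrix.
#' @param environments environments to tabulate.
#' @param reference reference environment for relative rates.
#' @return A list with `weights` (gene x environment data.frame of displayed
#'   integer weights), `totals`, and `relative_rates` (2-decimal).
#' @export
model1_prediction_table <- function(genes,
                                    survival = table1_survival(),
                                    environments = phage_environments(),
                                    reference = "phage") {
  tabs <- lapply(environments, function(env)
    model1_weights(genes, survival, env))
  names(tabs) <- environments
  ref <- tabs[[reference]]
  w <- data.frame(gene = genes$gene, length_bp = genes$length_bp)
  for (env in environments) {
    w[[env]] <- round_half_up(tabs[[env]]$weight)
  }
  totals <- vapply(tabs, function(t) attr(t, "total_weight"), numeric(1))
  rel <- round(totals / attr(ref, "total_weight"), 2)
  list(weights = w, totals = totals, relative_rates = rel)
}

# ---- internal helpers -------------------------------------------------------

.survival_fractions <- function(genes, survival, environment, survival_proxy) {
  .check_gene_catalogue(genes)
  .check_survival(survival)
  sub <- survival[survival$environment == environment, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("unknown environment '%s' in survival matrix", environment))
  }
  frac <- vapply(genes$gene, function(g) {
    src <- g
    if (!(src %in% sub$gene) && g %in% names(survival_proxy)) {
      src <- survival_proxy[[g]]
    }
    i <- match(src, sub$gene)
    if (is.na(i)) {
      stop(sprintf(
        "gene '%s' has no survival entry for environment '%s' (and no proxy)",
        g, environment))
    }
    sub$x[i] / sub$n[i]
  }, numeric(1))
  unname(frac)
}

.weight_table <- function(genes, weight, model_id, environment) {
  out <- data.frame(gene = genes$gene, lps_class = genes$lps_class,
                    weight = as.numeric(weight), stringsAsFactors = FALSE)
  structure(out,
            model_id = model_id,
            environment = environment,
            total_weight = sum(out$weight),
            class = c("gene_weight_table", "data.frame"))
}

.check_weight_table <- function(w) {
  if (!inherits(w, "gene_weight_table")) stop("expected a gene_weight_table")
  if (any(w$weight < 0)) stop("weights must be non-negative")
  stopifnot(abs(attr(w, "total_weight") - sum(w$weight)) < 1e-9)
  invisible(w)
}

.check_gene_catalogue <- function(genes) {
  need <- c("gene", "length_bp", "lps_class")
  if (!all(need %in% names(genes))) {
    stop("gene catalogue needs columns gene, length_bp, lps_class")
  }
  if (anyDuplicated(genes$gene)) stop("gene names must be unique")
  if (any(genes$length_bp <= 0)) stop("gene lengths must be positive")
  ok <- c("rough", "deep_rough", "regulatory", "non_lps")
  if (!all(genes$lps_class %in% ok)) {
    stop("lps_class must be one of ", paste(ok, collapse = ", "))
  }
  invisible(genes)
}

.check_survival <- function(survival) {
  need <- c("gene", "environment", "x", "n")
  if (!all(need %in% names(survival))) {
    stop("survival matrix needs columns gene, environment, x, n")
  }
  if (any(survival$n <= 0)) stop("survival denominators must be positive")
  if (any(survival$x < 0 | survival$x > survival$n)) {
    stop("survival numerators must satisfy 0 <= x <= n")
  }
  invisible(survival)
}

.as_named_counts <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("gene", "count") %in% names(x))) {
      stop("observed counts data.frame needs columns gene, count")
    }
    out <- x$count
    names(out) <- x$gene
    return(out)
  }
  if (is.null(names(x))) stop("observed counts must be named by gene")
  x
}
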
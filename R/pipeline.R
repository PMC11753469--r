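#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end from a single configuration: mutation
#' rate estimation per plating environment with likelihood-ratio comparisons
#' against a reference environment, target-size predictions for models 1-3,
#' and observed mutant spectra with bootstrap standard deviations and
#' chi-square goodness-of-fit tables. Stages whose inputs are absent from
#' the configuration are skipped with a logged notice; any stage failure
#' aborts with a stage-tagged error. Given a fixed seed the written report is
#' byte-identical across runs.
#'
#' @param config named list, or path to a YAML file with the same fields:
#'   \describe{
#'     \item{genes}{path to a gene-catalogue CSV (default: built-in
#'       catalogue).}
#'     \item{survival}{path to a survival-matrix CSV (default: built-in
#'       table); `survival_t12` optionally supplies the lenient-threshold
#'       rebuild for model 3.}
#'     \item{counts}{path to a fluctuation counts CSV (optional).}
#'     \item{mutants}{path to a mutant genotype CSV (optional).}
#'     \item{observed_counts}{path to a per-gene observed-count CSV
#'       (`gene`, `count`) for models 2/3 (optional).}
#'     \item{reference_env}{reference plating environment (default
#'       `"phage"`).}
#'     \item{models}{subset of `c("model1", "model2", "model3")`.}
#'     \item{pseudo_count}{pseudo-count for models 2/3 and bootstrap
#'       (default 1).}
#'     \item{n_boot}{bootstrap replicates (default 100).}
#'     \item{seed}{integer seed (required when spectra are computed).}
#'     \item{out_dir}{output directory for the report bundle (optional;
#'       without it results are only returned).}
#'   }
#' @param quiet suppress stage log messages.
#' @return Invisibly, a list with elements `estimates`, `comparisons`,
#'   `predictions`, `spectra`, `gof`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  say <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  fail <- function(stage, e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  ref_env <- if (is.null(config$reference_env)) "phage" else
    config$reference_env
  models <- if (is.null(config$models)) "model1" else config$models
  pseudo <- if (is.null(config$pseudo_count)) 1 else config$pseudo_count
  n_boot <- if (is.null(config$n_boot)) 100 else config$n_boot

  # ---- inputs ---------------------------------------------------------------
  inputs <- tryCatch({
    for (f in c("genes", "survival", "survival_t12", "counts", "mutants",
                "observed_counts")) {
      if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
        stop(sprintf("file for '%s' does not exist: %s", f, config[[f]]))
      }
    }
    genes <- if (is.null(config$genes)) lps_gene_catalogue() else
      read_gene_catalogue(config$genes)
    survival <- if (is.null(config$survival)) table1_survival() else
      read_survival_matrix(config$survival)
    survival_t12 <- if (is.null(config$survival_t12)) NULL else
      read_survival_matrix(config$survival_t12)
    counts <- if (is.null(config$counts)) NULL else
      read_counts_table(config$counts)
    mutants <- if (is.null(config$mutants)) NULL else
      read_mutant_table(config$mutants)
    obs_counts <- if (is.null(config$observed_counts)) NULL else
      read.csv(config$observed_counts, stringsAsFactors = FALSE)
    list(genes = genes, survival = survival, survival_t12 = survival_t12,
         counts = counts, mutants = mutants, obs_counts = obs_counts)
  }, error = function(e) fail("inputs", e))
  say("inputs", "configuration validated")

  # ---- rate estimation ------------------------------------------------------
  estimates <- NULL
  comparisons <- NULL
  if (!is.null(inputs$counts)) {
    tryCatch({
      exps <- experiments_from_counts(inputs$counts)
      estimates <- lapply(exps, estimate_rate)
      if (ref_env %in% names(exps)) {
        others <- setdiff(names(exps), ref_env)
        comparisons <- lapply(exps[others], compare_rates,
                              experiment_ref = exps[[ref_env]])
      } else {
        say("estimate", sprintf(
          "reference environment '%s' absent; comparisons skipped", ref_env))
      }
      say("estimate", sprintf("estimated %d environments",
                              length(estimates)))
    }, error = function(e) fail("estimate", e))
  } else {
    say("estimate", "no counts table supplied; estimation skipped")
  }

  # ---- model predictions ----------------------------------------------------
  predictions <- tryCatch({
    envs <- intersect(unique(inputs$survival$environment),
                      union(ref_env, unique(inputs$survival$environment)))
    out <- list()
    for (model in models) {
      wts <- lapply(envs, function(env) {
        switch(model,
          model1 = model1_weights(inputs$genes, inputs$survival, env),
          model2 = {
            if (is.null(inputs$obs_counts)) return(NULL)
            model2_weights(inputs$genes, inputs$obs_counts, inputs$survival,
                           env, pseudo)
          },
          model3 = {
            if (is.null(inputs$obs_counts) || is.null(inputs$survival_t12)) {
              return(NULL)
            }
            model3_weights(inputs$genes, inputs$obs_counts,
                           inputs$survival_t12, env, pseudo)
          },
          stop(sprintf("unknown model '%s'", model)))
      })
      names(wts) <- envs
      wts <- Filter(Negate(is.null), wts)
      if (length(wts) == 0 || !(ref_env %in% names(wts))) next
      ref_w <- wts[[ref_env]]
      out[[model]] <- lapply(wts, function(w) {
        pred <- predicted_distributions(w, inputs$genes)
        pred$relative_rate <- predicted_relative_rate(w, ref_w)
        pred$weights <- w
        pred
      })
    }
    if (length(out) > 0) {
      say("predict", sprintf("predictions for %s",
                             paste(names(out), collapse = ", ")))
    } else {
      say("predict", "no model had sufficient inputs; prediction skipped")
    }
    out
  }, error = function(e) fail("predict", e))

  # ---- observed spectra -----------------------------------------------------
  spectra <- NULL
  gof <- NULL
  if (!is.null(inputs$mutants)) {
    tryCatch({
      if (is.null(config$seed)) stop("a seed is required for the bootstrap")
      envs <- unique(inputs$mutants$environment)
      spectra <- lapply(envs, function(env) {
        sp <- mutant_spectrum(inputs$mutants, env, inputs$genes)
        cand <- inputs$genes$gene[
          .survival_fractions(inputs$genes, inputs$survival, env,
                              c(hldD = "hldE", gmhA = "gmhB")) > 0]
        boot <- bootstrap_spectrum(sp, cand, n_boot = n_boot,
                                   pseudo_count = pseudo,
                                   seed = config$seed,
                                   catalogue = inputs$genes)
        list(spectrum = sp, bootstrap = boot)
      })
      names(spectra) <- envs
      gof <- list()
      for (model in names(predictions)) {
        gof[[model]] <- lapply(envs, function(env) {
          if (!(env %in% names(predictions[[model]]))) return(NULL)
          pred <- predictions[[model]][[env]]
          list(
            gene_wise = tryCatch(
              gof_chisq(spectra[[env]]$spectrum, pred, "gene_wise",
                        inputs$genes),
              error = function(e) conditionMessage(e)),
            lps_type = tryCatch(
              gof_chisq(spectra[[env]]$spectrum, pred, "lps_type",
                        inputs$genes),
              error = function(e) conditionMessage(e))
          )
        })
        names(gof[[model]]) <- envs
      }
      say("spectra", sprintf("spectra for %d environments", length(spectra)))
    }, error = function(e) fail("spectra", e))
  } else {
    say("spectra", "no mutant table supplied; spectra skipped")
  }

  manifest <- list(
    package = "fluctarget",
    version = as.character(utils::packageVersion("fluctarget")),
    seed = config$seed,
    reference_env = ref_env,
    models = models,
    pseudo_count = pseudo,
    n_boot = n_boot,
    inputs = config[intersect(names(config),
                              c("genes", "survival", "survival_t12", "counts",
                                "mutants", "observed_counts"))]
  )
  result <- list(estimates = estimates, comparisons = comparisons,
                 predictions = predictions, spectra = spectra, gof = gof,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    tryCatch(.write_report(result, config$out_dir),
             error = function(e) fail("report", e))
    say("report", sprintf("report written to %s", config$out_dir))
  }
  invisible(result)
}

# Serialize the report bundle as JSON + CSVs (deterministic: no timestamps).
.write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jw <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  if (!is.null(result$estimates)) {
    est <- lapply(result$estimates, function(e)
      list(environment = e$environment_label, m_hat = e$m_hat,
           mu_hat = e$mu_hat, ci95_m = e$ci95_m, ci95_mu = e$ci95_mu,
           loglik = e$loglik_at_mle, n_cultures = e$n_cultures,
           n_censored = e$n_censored))
    jw(est, "rate_estimates.json")
  }
  if (!is.null(result$comparisons)) {
    cmp <- lapply(result$comparisons, function(x)
      list(ratio = x$ratio, ci95_ratio = x$ci95_ratio,
           lrt_statistic = x$lrt_statistic, p_value = x$p_value))
    jw(cmp, "rate_comparisons.json")
  }
  if (length(result$predictions) > 0) {
    pred <- lapply(result$predictions, function(pm)
      lapply(pm, function(p)
        list(relative_rate = p$relative_rate,
             gene_proportions = as.list(p$gene_proportions),
             lps_type_proportions = as.list(p$lps_type_proportions),
             total_weight = p$total_weight)))
    jw(pred, "model_predictions.json")
    # Table-1-shaped CSV for model 1
    if ("model1" %in% names(result$predictions)) {
      pm <- result$predictions$model1
      wide <- NULL
      for (env in names(pm)) {
        w <- pm[[env]]$weights
        col <- data.frame(gene = w$gene, weight = round_half_up(w$weight))
        names(col)[2] <- env
        wide <- if (is.null(wide)) col else merge(wide, col, by = "gene",
                                                  sort = FALSE)
      }
      write.csv(wide, file.path(out_dir, "model1_weights.csv"),
                row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(result$spectra)) {
    sp <- lapply(result$spectra, function(s)
      list(n_isolates = s$spectrum$n_isolates,
           counts = as.list(s$spectrum$counts),
           proportions = as.list(s$spectrum$proportions),
           class_proportions = as.list(s$spectrum$class_proportions),
           bootstrap_sd_gene = as.list(s$bootstrap$sd_gene),
           bootstrap_sd_class = as.list(s$bootstrap$sd_class)))
    jw(sp, "mutant_spectra.json")
  }
  if (!is.null(result$gof)) {
    gof <- lapply(result$gof, function(gm)
      lapply(gm, function(ge) {
        if (is.null(ge)) return(NULL)
        lapply(ge, function(g) {
          if (is.character(g)) return(list(error = g))
          list(statistic = g$statistic, df = g$df, p_value = g$p_value)
        })
      }))
    jw(gof, "gof_tests.json")
  }
  jw(result$manifest, "manifest.json")
  invisible(out_dir)
}
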
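#' Simulate the mutant clones of a single fluctuation culture
#'
#' Simulates a culture founded by a single wild-type cell growing
#' exponentially to `n_final` cells, with resistance mutations arising as a
#' Poisson process of per-division rate `mu` (expected mutations
#' `m = mu * (n_final - 1)`, the number of divisions). Mutant clones grow at
#' the wild-type rate (no differential fitness): each clone is a Yule pure
#' birth process started at the mutation's founding time, so a mutation
#' arising when the population holds `N_f` cells leaves a geometrically
#' distributed number of final descendants with success probability
#' `N_f / n_final`. Mixing over founding times yields the Lea-Coulson
#' clone-size law `P(j) = 1/(j (j+1))`, hence culture mutant counts follow
#' the Lea-Coulson distribution exactly.
#'
#' @param mu mutation rate per cell division (non-negative).
#' @param n_final final cells per culture (Nt).
#' @param seed optional integer seed for this call.
#' @return Integer vector of mutant clone sizes (possibly empty).
#' @export
simulate_culture <- function(mu, n_final, seed = NULL) {
  if (mu < 0) stop("mu must be non-negative")
  if (n_final <= 1) stop("n_final must exceed 1")
  if (!is.null(seed)) set.seed(seed)
  m <- mu * (n_final - 1)
  k <- rpois(1, m)
  if (k == 0) return(integer(0))
  founding <- 1 + runif(k) * (n_final - 1)   # population size at mutation
  sizes <- 1L + rgeom(k, pmin(founding / n_final, 1))
  as.integer(sizes)
}

# Vectorized version: clone sizes for n_cultures cultures at once.
# Returns list(culture = integer index, size = clone size).
.simulate_clones <- function(m, n_final, n_cultures) {
  k <- rpois(n_cultures, m)
  total <- sum(k)
  if (total == 0) {
    return(list(culture = integer(0), size = integer(0)))
  }
  founding <- 1 + runif(total) * (n_final - 1)
  sizes <- 1L + rgeom(total, pmin(founding / n_final, 1))
  list(culture = rep.int(seq_len(n_cultures), k), size = as.integer(sizes))
}

#' Plate a culture's mutant clones under partial plating and gene survival
#'
#' Implements the plating step generatively: every mutant clone is assigned a
#' causal gene categorically with probability proportional to the gene
#' weights; every mutant cell is plated independently with probability
#' `epsilon`; and every plated cell forms a colony with its gene's
#' environment-specific survival fraction as Bernoulli probability.
#'
#' @param clone_sizes integer vector of mutant clone sizes.
#' @param epsilon plating fraction in (0, 1].
#' @param gene_weights named non-negative numeric vector (or a
#'   `gene_weight_table`) of gene assignment weights.
#' @param survival named numeric vector of per-gene survival probabilities in
#'   \[0, 1\] (genes missing from the vector survive with probability 1), or a
#'   long-format survival data.frame restricted to one environment.
#' @param seed optional integer seed.
#' @return List with `count` (total colonies) and `colonies` (data.frame
#'   `gene`, `colonies` per clone with at least one colony).
#' @export
plate_culture <- function(clone_sizes, epsilon, gene_weights,
                          survival = NULL, seed = NULL) {
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  w <- .as_weight_vector(gene_weights)
  if (sum(w) <= 0) stop("gene weights must have positive total")
  s <- .as_survival_vector(survival, names(w))
  n <- length(clone_sizes)
  if (n == 0) {
    return(list(count = 0L,
                colonies = data.frame(gene = character(0),
                                      colonies = integer(0))))
  }
  gene <- sample(names(w), n, replace = TRUE, prob = w)
  plated <- rbinom(n, clone_sizes, epsilon)
  retained <- rbinom(n, plated, s[gene])
  keep <- retained > 0
  list(count = as.integer(sum(retained)),
       colonies = data.frame(gene = gene[keep],
                             colonies = as.integer(retained[keep]),
                             stringsAsFactors = FALSE))
}

#' Simulate a full fluctuation experiment under a known truth
#'
#' Generates `n_cultures` independent single-cell-founded cultures
#' ([simulate_culture()]), plates each under partial plating and per-gene
#' survival ([plate_culture()]), and packages the resulting colony counts as
#' a [fluctuation_experiment()] together with gene-resolved mutant records
#' (one randomly sampled colony per culture with colonies, mirroring the
#' study design of picking one colony per replicate plate).
#'
#' @param config list with elements `mu` (per-division mutation rate), `Nt`
#'   (final cells per culture), `epsilon` (plating fraction), `n_cultures`,
#'   `gene_weights` (named vector or `gene_weight_table`), `survival`
#'   (named per-gene survival probabilities; default all 1),
#'   `environment_label`, `seed` (required), and optionally
#'   `establishment_prob` (global per-colony establishment probability,
#'   default 1) and `count_ceiling` (counts at or above it are recorded as
#'   censored "burst" plates).
#' @return List of class `simulated_experiment` with elements `experiment`
#'   (a [fluctuation_experiment()]), `mutants` (data.frame `isolate_id`,
#'   `environment`, `causal_gene`), `colony_gene_counts` (named total
#'   colonies per gene across all plates), and `truth` (the config).
#' @export
simulate_fluctuation_experiment <- function(config) {
  need <- c("mu", "Nt", "epsilon", "n_cultures", "gene_weights", "seed")
  missing_f <- setdiff(need, names(config))
  if (length(missing_f) > 0) {
    stop("config is missing fields: ", paste(missing_f, collapse = ", "))
  }
  if (config$mu < 0) stop("mu must be non-negative")
  if (config$Nt <= 1) stop("Nt must exceed 1")
  if (config$epsilon <= 0 || config$epsilon > 1) {
    stop("epsilon must lie in (0, 1]")
  }
  n_cult <- as.integer(config$n_cultures)
  if (n_cult < 1) stop("n_cultures must be positive")
  est <- if (is.null(config$establishment_prob)) 1 else config$establishment_prob
  if (est < 0 || est > 1) stop("establishment_prob must lie in [0, 1]")
  env <- if (is.null(config$environment_label)) "" else config$environment_label

  w <- .as_weight_vector(config$gene_weights)
  if (sum(w) <= 0) stop("gene weights must have positive total")
  s <- .as_survival_vector(config$survival, names(w))
  set.seed(config$seed)

  m <- config$mu * (config$Nt - 1)
  clones <- .simulate_clones(m, config$Nt, n_cult)
  counts <- integer(n_cult)
  gene_tot <- stats::setNames(numeric(length(w)), names(w))
  mutants <- NULL
  if (length(clones$size) > 0) {
    gene <- sample(names(w), length(clones$size), replace = TRUE, prob = w)
    plated <- rbinom(length(clones$size), clones$size, config$epsilon)
    retained <- rbinom(length(clones$size), plated, s[gene] * est)
    cc <- rowsum(retained, clones$culture)
    counts[as.integer(rownames(cc))] <- as.integer(cc)
    keep <- retained > 0
    if (any(keep)) {
      tot <- rowsum(retained[keep], gene[keep])
      gene_tot[rownames(tot)] <- tot[, 1]
      # sample one colony per positive culture, weighted by clone colonies
      pos <- which(counts > 0)
      cult_k <- clones$culture[keep]
      gene_k <- gene[keep]
      ret_k <- retained[keep]
      picked <- vapply(pos, function(ci) {
        i <- which(cult_k == ci)
        if (length(i) == 1L) gene_k[i]
        else sample(gene_k[i], 1, prob = ret_k[i])
      }, character(1))
      mutants <- data.frame(
        isolate_id = sprintf("%s_c%03d", if (nzchar(env)) env else "sim", pos),
        environment = env,
        causal_gene = picked,
        stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(mutants)) {
    mutants <- data.frame(isolate_id = character(0), environment = character(0),
                          causal_gene = character(0), stringsAsFactors = FALSE)
  }

  ceiling_k <- config$count_ceiling
  if (!is.null(ceiling_k)) {
    cens <- counts >= ceiling_k
    exp_counts <- ifelse(cens, NA_integer_, counts)
    experiment <- fluctuation_experiment(
      exp_counts, n_total_cells = config$Nt,
      plating_fraction = config$epsilon, environment_label = env,
      censored_high = cens, censor_mode = "ceiling", ceiling = ceiling_k)
  } else {
    experiment <- fluctuation_experiment(
      counts, n_total_cells = config$Nt,
      plating_fraction = config$epsilon, environment_label = env)
  }
  structure(
    list(experiment = experiment, mutants = mutants,
         colony_gene_counts = gene_tot, raw_counts = counts, truth = config),
    class = "simulated_experiment"
  )
}

#' Simulate a greyscale plate-growth table
#'
#' Emulates the numeric plate tables produced by lawn photography: for each
#' strain and concentration, replicate mean-greyscale values are drawn from a
#' normal distribution around a high "lawn" level below the strain's true
#' MIC and a low "no lawn" level at or above it, clipped to the 8-bit range
#' \[0, 255\], with the blank-plate background defaulting to its typical mode
#' of 37.
#'
#' @param strain_mics named numeric vector of true MICs per strain.
#' @param concentrations ascending vector of tested concentrations.
#' @param antibiotic antibiotic label for the records.
#' @param n_replicates replicates per strain x concentration.
#' @param noise_sd greyscale noise standard deviation.
#' @param blank blank-plate mean greyscale.
#' @param lawn_level mean greyscale of a full lawn.
#' @param no_growth_level mean greyscale without a lawn.
#' @param seed integer seed (required).
#' @return data.frame of plate records in the format of [growth_values()].
#' @export
simulate_plate_growth_table <- function(strain_mics, concentrations,
                                        antibiotic = "chloramphenicol",
                                        n_replicates = 3, noise_sd = 3,
                                        blank = 37, lawn_level = 70,
                                        no_growth_level = 39, seed) {
  if (is.unsorted(concentrations)) stop("concentrations must be ascending")
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(seed)
  grid <- expand.grid(strain = names(strain_mics),
                      concentration = concentrations,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  below <- grid$concentration < strain_mics[grid$strain]
  level <- ifelse(below, lawn_level, no_growth_level)
  grey <- pmin(pmax(rnorm(nrow(grid), level, noise_sd), 0), 255)
  data.frame(
    strain = grid$strain,
    antibiotic = antibiotic,
    concentration = grid$concentration,
    replicate = grid$replicate,
    mean_greyscale = grey,
    blank_greyscale = blank,
    stringsAsFactors = FALSE
  )
}

# ---- helpers ----------------------------------------------------------------

.as_weight_vector <- function(gene_weights) {
  if (inherits(gene_weights, "gene_weight_table")) {
    w <- gene_weights$weight
    names(w) <- gene_weights$gene
  } else {
    w <- gene_weights
    if (is.null(names(w))) stop("gene weights must be named")
  }
  if (any(w < 0)) stop("gene weights must be non-negative")
  w
}

.as_survival_vector <- function(survival, genes) {
  s <- stats::setNames(rep(1, length(genes)), genes)
  if (is.null(survival)) return(s)
  if (is.data.frame(survival)) {
    v <- survival$x / survival$n
    names(v) <- survival$gene
    survival <- v
  }
  if (is.null(names(survival))) stop("survival probabilities must be named")
  if (any(survival < 0 | survival > 1)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  hit <- intersect(genes, names(survival))
  s[hit] <- survival[hit]
  s
}
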
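---
title: "Methods: fluctuation assays and mutational target-size models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluctuation assays and mutational target-size models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctarget)
```

# The scientific problem

Bacteriophage PhiX174 infects *Escherichia coli* C through its
lipopolysaccharide (LPS), and resistance arises by loss-of-function mutations
in LPS-pathway genes. Mutations that truncate the LPS more severely
("deep-rough" phenotypes) also make the cell more susceptible to some
antibiotics, so a phage + antibiotic combination removes part of the
mutational routes to phage resistance. `fluctarget` implements the
quantitative side of that argument:

1. **Target-size models** predict how much an antibiotic environment shrinks
   the mutational target for phage resistance, from gene lengths and simple
   plate-survival assays.
2. **Fluctuation-assay inference** measures realized resistance rates from
   Luria-Delbrück colony-count experiments, under the Lea-Coulson model with
   partial plating, and compares environments by likelihood-ratio tests.
3. **Mutant-spectrum statistics** (bootstrap errors and Pearson chi-square
   goodness of fit) compare observed distributions of causal genes with the
   models.
4. A **synthetic-data generator** produces all inputs under a known truth, so
   every stage is testable without the original laboratory data.

# The Lea-Coulson model with partial plating

A culture founded by a single sensitive cell grows to $N_t$ cells. Mutations
to resistance occur during growth at rate $\mu$ per cell division, so the
expected number of mutation events per culture is $m = \mu (N_t - 1)$
($N_t - 1$ divisions). Mutant clones grow at the wild-type rate. Under these
classical assumptions the number of mutant cells in the culture follows the
Lea-Coulson distribution, with probability generating function

$$G(z) = \exp\!\left( m\, \frac{(1-z)\ln(1-z)}{z} \right),$$

equivalently a compound-Poisson law: $\mathrm{Poisson}(m)$ mutation events,
each founding a clone whose final size $J$ has $P(J = j) = 1/(j(j+1))$.

Only a fraction $\varepsilon \in (0, 1]$ of the culture is plated. Each
mutant cell is plated independently, so observed colony counts are binomial
thinnings of the culture's mutant count and the observed pgf is
$H(z) = G(1 - \varepsilon + \varepsilon z)$. Two consequences used as exact
anchors throughout the test suite:

* $P(0) = \exp(m \varepsilon \ln\varepsilon / (1-\varepsilon))$ for
  $\varepsilon < 1$, and $e^{-m}$ at $\varepsilon = 1$;
* at $\varepsilon = 1$ the pmf obeys the classical recursion
  $p_k = (m/k) \sum_{i<k} p_i / (k-i+1)$.

## How the pmf is computed

Thinning a compound-Poisson law thins its clone-size distribution, so
$H(z) = \exp(\sum_k g_k z^k)$ with cumulant coefficients

$$g_k = m\,\varepsilon^k \sum_{j \ge k} \binom{j}{k}
        (1-\varepsilon)^{j-k} \frac{1}{j(j+1)}, \qquad k \ge 1,$$

and $g_0 = m \varepsilon \ln \varepsilon/(1-\varepsilon)$. Every term is
positive, so this representation is numerically stable for all
$\varepsilon$ — unlike a partial-fraction expansion of the composed pgf,
whose spurious pole at $z = -(1-\varepsilon)/\varepsilon$ enters the unit
disk for $\varepsilon > 1/2$ and causes catastrophic cancellation. Using
$1/(j+1) = \int_0^1 t^j \, dt$ the inner sum reduces to
$g_k/m = 1/k - M_k/\varepsilon$ with
$M_k = \int_0^1 v^k/(1 + c v)\, dv$, $c = (1-\varepsilon)/\varepsilon$.
$M_k$ satisfies $M_k = (1/k - M_{k-1})/c$; the forward recursion damps
rounding errors when $c > 1$ ($\varepsilon < 1/2$) and amplifies them
otherwise, so for $\varepsilon \ge 1/2$ the package instead sums the
equivalent beta-function series in $r = c/(1+c) \le 1/2$, which converges
geometrically. The pmf then follows from the standard exponential-series
recursion $p_0 = e^{g_0}$, $p_k = (1/k)\sum_{j=1}^k j\, g_j\, p_{k-j}$
(all-positive terms; implemented in C++ because it is the $O(k_{\max}^2)$
inner loop of every likelihood evaluation).

The implementation is cross-checked in the tests against an independent
oracle that extracts the same coefficients by numerical Cauchy integration
of $H(z)$ on a circle (FFT), against the closed forms above to $10^{-9}$,
and against Monte-Carlo culture simulation by chi-square goodness of fit.

## Estimation, intervals, and comparisons

`estimate_rate()` maximizes the log-likelihood in $m$ by a log-spaced scan
followed by Brent search on $\log m$ (relative tolerance $10^{-10}$, so rates
of order $10^{-8}$ converge as well as rates of order 1), with the boundary
case "all counts zero" handled exactly ($\hat m = 0$, lower limit 0, upper
limit from the closed-form deviance). Confidence intervals are profile
likelihood at the $\chi^2_1$ cutoff ($2\Delta\ln L = 3.84$ for 95%). The
per-division rate follows Foster's convention $\hat\mu = \hat m / N_t$.

`compare_rates()` tests equality of per-division rates between two plating
environments: the null model shares one $\mu$ with environment-specific
$m = \mu N_t$ and $\varepsilon$; the alternative fits each environment
separately; $2(\ln L_a + \ln L_{ref} - \ln L_{null})$ is referred to
$\chi^2_1$. The rate ratio $\hat\mu_a/\hat\mu_{ref}$ carries a
profile-likelihood interval obtained by profiling the ratio parameter with
the reference rate as nuisance.

**Uncountable plates.** Plates overgrown with colonies ("burst") carry no
count. The default follows the convention of computing rates without such
plates (`censor_mode = "exclude"`); alternatively they can enter the
likelihood as right-censored observations contributing
$P(X \ge \mathrm{ceiling})$. The second mode is also what makes large
simulation studies tractable: treating counts at or above a ceiling of 1,000
as uncountable mirrors real plate counting and caps the series length
without biasing the MLE (the censored likelihood is the exact likelihood of
the censored observation scheme).

# Mutational target-size models

The catalogue (`lps_gene_catalogue()`) holds the 13 LPS-pathway genes in
which resistance mutations were originally observed — total coding length
11,736 bp — with their phenotype class (`rough`, `deep_rough`, and `rfaH` as
its own `regulatory` class, since it controls the whole *waa* operon). Two
later-discovered target genes, `hldD` (933 bp) and `gmhA` (579 bp), can be
appended (`added_genes = TRUE`); their coding lengths come from the
reference *E. coli* genome annotation, and their antibiotic-survival
profiles — never measured directly — default to the stated proxies (`hldD`
behaves like `hldE`, `gmhA` like `gmhB`), both overridable.

* **Model 1** (a priori): mutation probability proportional to coding
  length; in an antibiotic environment each gene's weight is
  $(x_g/n_g) \times \mathrm{length}_g$, where $x_g$ of $n_g$ mutants of that
  gene grew on the antibiotic plate. Example: 1 of 5 galU mutants grows at
  2 µg/ml chloramphenicol, so galU scores $909/5 = 181.8$ (displayed 182).
* **Model 2**: gene length is replaced by the number of mutations actually
  observed in the phage-only environment, plus a pseudo-count of 1 for every
  catalogued candidate gene so that unobserved genes keep nonzero weight.
  The pseudo-count applies to the configured candidate catalogue only;
  uncatalogued (`non_lps`) isolates are tracked as a catch-all class but are
  not candidates by default.
* **Model 3**: model 2 with the survival matrix rebuilt at the lenient
  greyscale growth threshold 12 instead of the strict 8.

The predicted relative resistance rate of an environment is the ratio of its
total weight to the phage-only total; predicted spectra are the normalized
weights, aggregated to LPS classes with `rfaH` kept separate.

```{r table1}
tab <- model1_prediction_table(lps_gene_catalogue())
tab$relative_rates
```

Weights are kept in full precision; integer display uses round-half-up and
relative rates are reported at two decimals, the conventions of the printed
table. One printed cell (hldE at phage + 2 µg/ml gentamicin, 244) disagrees
with its own arithmetic ($1434/6 = 239$); the package computes 239 and does
not force the printed value — the relative rate is 0.80 either way.

# Susceptibility scoring

Growth on an agar lawn is measured as the mean 8-bit greyscale of a fixed
plate region minus the blank-plate mean (background mode typically 37);
replicates (1-5) are summarized by their median. A strain *grows* when the
median strictly exceeds the threshold $\tau$ ($\tau = 8$ strict, $\tau = 12$
lenient); equality counts as no growth, which makes the growth call and the
MIC rule ("lowest concentration whose median falls below threshold")
complementary. MIC scanning uses the first crossing in ascending
concentration, which also resolves non-monotone profiles; profiles that
never fall below threshold return an above-range sentinel. Negative
blank-subtracted values are clamped to zero for calls but preserved in
exports. `survival_matrix()` aggregates strain-level calls into the
per-gene $(x, n)$ entries the models consume; raising $\tau$ can only
shrink survival fractions (tested as a monotonicity property).

# Mutant spectra

Isolates with several mutated genes are assigned the causal gene predicted
to cause the most dramatic LPS change: severity order
`deep_rough > regulatory > rough > non_lps`, ties broken by the
catalogue's pathway order (deterministic and independent of input order).
Spectra are zero-filled over the catalogue. Isolates with no identified
mutation are excluded from denominators.

Bootstrap errors follow the published procedure: a pseudo-count of one
pseudo-isolate per candidate gene is added *before* sampling (so the
pseudo-isolates are part of the resampling pool, not only of the
denominator — the reading consistent with adding them "before sampling");
each of the 100 replicates (default) redraws the full augmented pool size
with replacement; the SD across replicates is reported per gene and per LPS
class. Goodness of fit uses the Pearson chi-square with asymptotic p-values
and no continuity correction; categories with zero expected proportion are
rejected with a pointer to the added-genes catalogue variant, which exists
precisely to avoid zero expectations.

# The synthetic-data generator

`simulate_fluctuation_experiment()` generates every input the pipeline
consumes under a known truth: single-cell-founded cultures grown to $N_t$,
mutation influx $\mu$ per division, gene assignment of each clone
proportional to a weight table, per-cell binomial plating at $\varepsilon$,
and per-colony Bernoulli survival with the gene's environment-specific
survival fraction. One colony per positive plate is sampled into the mutant
table, mirroring the study design of picking one colony per replicate.

**Growth model.** Cultures are simulated in the continuous-time
formulation: deterministic exponential wild-type growth, mutation events as
a Poisson process with intensity proportional to population size (hence
$m = \mu (N_t - 1)$ in total), and each mutant clone a Yule pure-birth
process from its founding time. A clone founded when the population holds
$N_f$ cells (with $N_f$ uniform on $(1, N_t)$ for a uniformly random event)
leaves a geometric number of descendants with success probability
$N_f/N_t$; mixing over founding times yields exactly the Lea-Coulson
clone-size law $1/(j(j+1))$. A synchronous doubling model was considered
and rejected: its clone sizes are concentrated on powers of two (e.g.
$P(J=2) = 1/4$ instead of $1/6$), which is distinguishable from the
Lea-Coulson law at a few thousand cultures — the continuous-time model is
the one whose output the inference machinery is actually a likelihood for,
which is what makes the generator usable as a distributional oracle.

**What the generator does and does not emulate.** It reproduces the
fluctuation-design assumptions exactly (equal mutant growth, no death, no
post-plating interactions) plus the survival semantics of the target-size
models. It deliberately does *not* model phage-antibiotic physiological
interactions: the observed rate at 1 µg/ml chloramphenicol (~15% of the
phage-only rate, far below every model's prediction) is attributed to such
interactions, and the generator only exposes a neutral per-environment
`establishment_prob` knob (default 1) rather than attempting to reproduce
that number. Passing tests therefore demonstrate correctness of the
inference and prediction machinery under the stated model, not that the
model captures every force acting on real plates.

**Fractional survival and estimator bias.** When some genes survive with
fractional probability (e.g. galU at 1/5), the observed counts are a
mixture of gene-specific thinned Lea-Coulson laws, which is not exactly a
Lea-Coulson law with a smaller $m$. The single-rate MLE applied to such
data recovers a rate slightly above the weight-renormalized target (the
end-to-end synergy test recovers ~0.48 against the predicted 0.465 for the
2 µg/ml chloramphenicol environment); the same approximation is implicit in
analysing the laboratory experiment with a single-rate model.

# Numerical choices and problem sizes

* Series truncation: likelihoods evaluate the pmf up to the largest
  observed count (plus the ceiling for censored plates); the user-facing
  `lc_pmf()` takes `k_max` explicitly.
* Optimization tolerances: $10^{-10}$ on $\log m$; profile roots to
  $10^{-10}$; LRT statistics below $10^{-8}$ are reported as exactly zero
  (an experiment compared with itself returns ratio 1, LRT 0, p 1).
* All randomness flows from a single seed per simulation or bootstrap call;
  seeded calls restore the caller's RNG state where they can.
* Test problem sizes were chosen to make Monte-Carlo error small relative
  to the tested tolerances: $10^5$ cultures for distributional GOF, 500
  experiments of 50 cultures for interval coverage (expected coverage
  0.95, binomial SE ~1%), $10^4$ cultures for bias (<5%) and for the
  end-to-end synergy recovery (±0.05 band), 1,000 paired simulations for
  the LRT type-I rate ([0.03, 0.07] band at nominal 0.05).

# Known limitations

* Model-2/3 predictions and the published observed rates depend on the
  original supplementary tables (observed mutation counts, raw colony
  counts), which are not redistributable with the package; the machinery is
  exercised on synthetic tables of the same shape, and printed values can
  be validated by pointing `options(fluctarget.supplementary_dir = ...)` at
  a local copy.
* Alternative fluctuation estimators (P0, median-based, variants with
  differential mutant fitness) and multi-dilution plating are out of scope;
  the likelihood assumes equal mutant and wild-type growth.
* The chi-square tests are asymptotic; with 40-50 isolates per environment
  and many categories, small expected counts make gene-wise p-values
  approximate (as in the source analyses).
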
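#' Screening thresholds for the onco-miRNA cascade
#'
#' Container for every cut-off used along the selection cascade.  Defaults
#' are the standard values of this screen design: a mature miRNA is called
#' CNV-correlated when Pearson r > 0.2 with p < 0.05; differentially
#' expressed in Sq when log2 fold change > 0 with BH-adjusted q < 1e-10 in
#' both the Sq-vs-Ad and Sq-vs-Normal comparisons; and prognostic when the
#' median-split log-rank p < 0.05 (corresponding BH q < 0.2) with worse
#' survival in the high-expression group.  Bootstrap stability uses
#' B = 10000 replicates at alpha = 0.05.
#'
#' @slot r_min minimum Pearson correlation (strict inequality).
#' @slot p_max maximum correlation p-value (strict).
#' @slot q_max maximum BH-adjusted q for differential expression (strict).
#' @slot logrank_p_max maximum log-rank p for prognosis (strict).
#' @slot logrank_q_max maximum BH-adjusted log-rank q (strict).
#' @slot bootstrap_B number of bootstrap replicates.
#' @slot bootstrap_alpha significance level counted within replicates.
#' @export
setClass("ScreenThresholds",
  representation(
    r_min = "numeric", p_max = "numeric", q_max = "numeric",
    logrank_p_max = "numeric", logrank_q_max = "numeric",
    bootstrap_B = "integer", bootstrap_alpha = "numeric"
  )
)

setValidity("ScreenThresholds", function(object) {
  msg <- character()
  if (!(object@r_min >= -1 && object@r_min <= 1)) msg <- c(msg, "r_min must lie in [-1, 1]")
  for (s in c("p_max", "q_max", "logrank_p_max", "logrank_q_max", "bootstrap_alpha")) {
    v <- slot(object, s)
    if (!(length(v) == 1L && is.finite(v) && v > 0 && v <= 1))
      msg <- c(msg, paste0(s, " must lie in (0, 1]"))
  }
  if (object@bootstrap_B < 1L) msg <- c(msg, "bootstrap_B must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param r_min,p_max,q_max,logrank_p_max,logrank_q_max,bootstrap_B,bootstrap_alpha
#'   see the corresponding slots.
#' @return `screenThresholds()` returns a validated `ScreenThresholds` object.
#' @examples
#' thr <- screenThresholds()
#' thr
#' @rdname ScreenThresholds-class
#' @export
screenThresholds <- function(r_min = 0.2, p_max = 0.05, q_max = 1e-10,
                             logrank_p_max = 0.05, logrank_q_max = 0.2,
                             bootstrap_B = 10000L, bootstrap_alpha = 0.05) {
  new("ScreenThresholds",
    r_min = r_min, p_max = p_max, q_max = q_max,
    logrank_p_max = logrank_p_max, logrank_q_max = logrank_q_max,
    bootstrap_B = as.integer(bootstrap_B), bootstrap_alpha = bootstrap_alpha
  )
}

#' @param x a `ScreenThresholds` object.
#' @param ... unused.
#' @rdname ScreenThresholds-class
#' @export
setMethod("as.list", "ScreenThresholds", function(x, ...) {
  nm <- slotNames(x)
  setNames(lapply(nm, function(s) slot(x, s)), nm)
})

setMethod("show", "ScreenThresholds", function(object) {
  cat("ScreenThresholds\n")
  cat(sprintf("  CNV correlation : r > %g, p < %g\n", object@r_min, object@p_max))
  cat(sprintf("  DEMI filter     : log2FC > 0, q < %g (both comparisons)\n", object@q_max))
  cat(sprintf("  survival screen : log-rank p < %g, q < %g, high = worse\n",
              object@logrank_p_max, object@logrank_q_max))
  cat(sprintf("  bootstrap       : B = %d, alpha = %g\n",
              object@bootstrap_B, object@bootstrap_alpha))
})

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions emulated by [generateCohort()]: cohort sizes
#' matching a TCGA-scale lung cohort (240 Sq / 239 Ad / 91 Normal), planted
#' miRNA effect classes, the distribution of focal low-level copy-number
#' gains, expression effect sizes, negative-binomial count noise, survival
#' hazards, and Table 1-like clinical covariate frequencies.
#'
#' Effect classes: `onco` miRNAs carry all three planted effects (CNV slope,
#' Sq offset, hazard contribution), `cnv_only` carries only the CNV slope,
#' `sq_up_only` only the Sq offset, and `null` none.
#'
#' @slot n_sq,n_ad,n_normal sample counts per histology.
#' @slot n_onco,n_cnv_only,n_sq_up_only,n_null miRNA counts per effect class.
#' @slot gain_fraction fraction of Sq samples with a gain at each planted locus.
#' @slot gain_mean,gain_sd segment-mean (log2 copy ratio) distribution of gains.
#' @slot cnv_slope log2-CPM change per copy-ratio unit for CNV-driven miRNAs.
#' @slot sq_log2fc Sq-specific log2 expression offset for up-regulated miRNAs.
#' @slot log_hr per-unit-z log hazard contribution of each prognostic miRNA.
#' @slot baseline_log2cpm_mean,baseline_log2cpm_sd baseline expression distribution.
#' @slot noise_sd residual log2 expression noise.
#' @slot dispersion negative-binomial dispersion of counts.
#' @slot library_meanlog,library_sdlog log-normal library-size distribution.
#' @slot baseline_hazard baseline death hazard per day.
#' @slot censoring_rate fraction of survival times administratively censored.
#' @slot male_freq_sq,smoker_freq_sq,nonsmoker_freq_sq,stage_freq_sq Sq covariate frequencies.
#' @slot male_freq_ad,smoker_freq_ad,nonsmoker_freq_ad,stage_freq_ad Ad covariate frequencies.
#' @slot age_mean_sq,age_sd_sq,age_mean_ad,age_sd_ad age distributions.
#' @slot n_missing_survival number of Sq samples stripped of survival data.
#' @slot seed mandatory RNG seed.
#' @export
setClass("GeneratorConfig",
  representation(
    n_sq = "integer", n_ad = "integer", n_normal = "integer",
    n_onco = "integer", n_cnv_only = "integer", n_sq_up_only = "integer",
    n_null = "integer",
    gain_fraction = "numeric", gain_mean = "numeric", gain_sd = "numeric",
    cnv_slope = "numeric", sq_log2fc = "numeric", log_hr = "numeric",
    baseline_log2cpm_mean = "numeric", baseline_log2cpm_sd = "numeric",
    noise_sd = "numeric", dispersion = "numeric",
    library_meanlog = "numeric", library_sdlog = "numeric",
    baseline_hazard = "numeric", censoring_rate = "numeric",
    male_freq_sq = "numeric", smoker_freq_sq = "numeric",
    nonsmoker_freq_sq = "numeric", stage_freq_sq = "numeric",
    male_freq_ad = "numeric", smoker_freq_ad = "numeric",
    nonsmoker_freq_ad = "numeric", stage_freq_ad = "numeric",
    age_mean_sq = "numeric", age_sd_sq = "numeric",
    age_mean_ad = "numeric", age_sd_ad = "numeric",
    n_missing_survival = "integer", seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  for (s in c("n_sq", "n_ad", "n_normal"))
    if (slot(object, s) < 1L) msg <- c(msg, paste0(s, " must be positive"))
  for (s in c("n_onco", "n_cnv_only", "n_sq_up_only", "n_null"))
    if (slot(object, s) < 0L) msg <- c(msg, paste0(s, " must be nonnegative"))
  if (object@n_onco + object@n_cnv_only + object@n_sq_up_only + object@n_null < 1L)
    msg <- c(msg, "at least one miRNA required")
  for (s in c("gain_fraction", "censoring_rate")) {
    v <- slot(object, s)
    if (!(v >= 0 && v <= 1)) msg <- c(msg, paste0(s, " must lie in [0, 1]"))
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  st <- object@stage_freq_sq
  if (length(st) != 5L || abs(sum(st) - 1) > 1e-8)
    msg <- c(msg, "stage_freq_sq must be 5 probabilities summing to 1")
  st <- object@stage_freq_ad
  if (length(st) != 5L || abs(sum(st) - 1) > 1e-8)
    msg <- c(msg, "stage_freq_ad must be 5 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

#' @param seed mandatory integer seed.
#' @param n_sq,n_ad,n_normal,n_onco,n_cnv_only,n_sq_up_only,n_null,gain_fraction,gain_mean,gain_sd,cnv_slope,sq_log2fc,log_hr,baseline_log2cpm_mean,baseline_log2cpm_sd,noise_sd,dispersion,library_meanlog,library_sdlog,baseline_hazard,censoring_rate,male_freq_sq,smoker_freq_sq,nonsmoker_freq_sq,stage_freq_sq,male_freq_ad,smoker_freq_ad,nonsmoker_freq_ad,stage_freq_ad,age_mean_sq,age_sd_sq,age_mean_ad,age_sd_ad,n_missing_survival
#'   see the corresponding slots.
#' @return `generatorConfig()` returns a validated `GeneratorConfig`.
#' @examples
#' cfg <- generatorConfig(seed = 1, n_sq = 10, n_ad = 10, n_normal = 5,
#'                        n_onco = 1, n_cnv_only = 2, n_sq_up_only = 2, n_null = 5)
#' cfg
#' @rdname GeneratorConfig-class
#' @export
generatorConfig <- function(seed,
                            n_sq = 240L, n_ad = 239L, n_normal = 91L,
                            n_onco = 3L, n_cnv_only = 20L,
                            n_sq_up_only = 20L, n_null = 257L,
                            gain_fraction = 0.5, gain_mean = 0.32, gain_sd = 0.1,
                            cnv_slope = 1.0, sq_log2fc = 1.5, log_hr = log(2.6),
                            baseline_log2cpm_mean = 5, baseline_log2cpm_sd = 2,
                            noise_sd = 0.4, dispersion = 0.05,
                            library_meanlog = log(5e6), library_sdlog = 0.3,
                            baseline_hazard = 4e-4, censoring_rate = 0.5,
                            male_freq_sq = 0.76, smoker_freq_sq = 0.93,
                            nonsmoker_freq_sq = 0.04,
                            stage_freq_sq = c(I = 0.48, II = 0.35, III = 0.15,
                                              IV = 0.01, Unknown = 0.01),
                            male_freq_ad = 0.45, smoker_freq_ad = 0.83,
                            nonsmoker_freq_ad = 0.14,
                            stage_freq_ad = c(I = 0.56, II = 0.24, III = 0.16,
                                              IV = 0.04, Unknown = 0.00),
                            age_mean_sq = 68, age_sd_sq = 9,
                            age_mean_ad = 65, age_sd_ad = 10,
                            n_missing_survival = 0L) {
  if (missing(seed)) stopf("generatorConfig(): seed is mandatory")
  new("GeneratorConfig",
    n_sq = as.integer(n_sq), n_ad = as.integer(n_ad),
    n_normal = as.integer(n_normal),
    n_onco = as.integer(n_onco), n_cnv_only = as.integer(n_cnv_only),
    n_sq_up_only = as.integer(n_sq_up_only), n_null = as.integer(n_null),
    gain_fraction = gain_fraction, gain_mean = gain_mean, gain_sd = gain_sd,
    cnv_slope = cnv_slope, sq_log2fc = sq_log2fc, log_hr = log_hr,
    baseline_log2cpm_mean = baseline_log2cpm_mean,
    baseline_log2cpm_sd = baseline_log2cpm_sd,
    noise_sd = noise_sd, dispersion = dispersion,
    library_meanlog = library_meanlog, library_sdlog = library_sdlog,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    male_freq_sq = male_freq_sq, smoker_freq_sq = smoker_freq_sq,
    nonsmoker_freq_sq = nonsmoker_freq_sq, stage_freq_sq = stage_freq_sq,
    male_freq_ad = male_freq_ad, smoker_freq_ad = smoker_freq_ad,
    nonsmoker_freq_ad = nonsmoker_freq_ad, stage_freq_ad = stage_freq_ad,
    age_mean_sq = age_mean_sq, age_sd_sq = age_sd_sq,
    age_mean_ad = age_mean_ad, age_sd_ad = age_sd_ad,
    n_missing_survival = as.integer(n_missing_survival),
    seed = as.integer(seed)
  )
}

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat(sprintf("  samples : %d Sq / %d Ad / %d Normal\n",
              object@n_sq, object@n_ad, object@n_normal))
  cat(sprintf("  miRNAs  : %d onco, %d cnv_only, %d sq_up_only, %d null\n",
              object@n_onco, object@n_cnv_only, object@n_sq_up_only,
              object@n_null))
  cat(sprintf("  effects : cnv_slope %g, sq_log2FC %g, HR %.3g\n",
              object@cnv_slope, object@sq_log2fc, exp(object@log_hr)))
  cat(sprintf("  seed    : %d\n", object@seed))
})

#' @rdname GeneratorConfig-class
#' @param x a `GeneratorConfig`.
#' @param ... unused.
#' @export
setMethod("as.list", "GeneratorConfig", function(x, ...) {
  nm <- slotNames(x)
  setNames(lapply(nm, function(s) slot(x, s)), nm)
})

#' Synthetic cohort container
#'
#' The coupled outputs of [generateCohort()]: copy-number segments, isoform
#' read counts, the miRNA annotation, clinical records, and the planted-truth
#' table, together with the generating configuration.  Every component is in
#' the exact dialect the corresponding reader of this package parses, so a
#' cohort can be written with [writeCohort()] and re-read losslessly.
#'
#' @slot segments `GRanges` of per-sample copy-number segments.
#' @slot isoforms `data.frame` of isoform-level read counts.
#' @slot annotation `GRanges` of (precursor, mature) miRNA records.
#' @slot clinical `data.frame` of clinical records.
#' @slot truth `data.frame` with one row per miRNA: class and planted effects.
#' @slot config the `GeneratorConfig` that produced the cohort.
#' @export
setClass("SyntheticCohort",
  representation(
    segments = "GRanges", isoforms = "data.frame",
    annotation = "GRanges", clinical = "data.frame",
    truth = "data.frame", config = "GeneratorConfig"
  )
)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort\n")
  cat(sprintf("  %d clinical samples, %d miRNAs, %d segments, %d isoform rows\n",
              nrow(object@clinical), nrow(object@truth),
              length(object@segments), nrow(object@isoforms)))
  print(table(object@truth$class))
})

#' Accessor: planted truth table of a synthetic cohort
#' @param x a `SyntheticCohort`.
#' @return `data.frame` with columns `mature_accession`, `mature_name`,
#'   `class`, `cnv_slope`, `sq_log2fc`, `log_hr`, `baseline_log2cpm`.
#' @export
cohortTruth <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@truth
}

#' Accessor: clinical table of a synthetic cohort
#' @param x a `SyntheticCohort`.
#' @return `data.frame` of clinical records.
#' @export
cohortClinical <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@clinical
}

#' Result of a full screening run
#'
#' Returned by [runScreen()].  Holds the per-stage result tables, the
#' cascade attrition counts, the thresholds in force, and (optionally)
#' Cox model reports, bootstrap stability and AUC diagnostics.
#'
#' @slot counts named integer vector of per-stage candidate counts
#'   (expressed, cnv_correlated, sq_upregulated, prognostic, final_combination).
#' @slot thresholds the `ScreenThresholds` used.
#' @slot correlation per-(mature, locus) correlation table.
#' @slot demi differential-expression table.
#' @slot survival per-miRNA log-rank table.
#' @slot combos subset-combination log-rank table.
#' @slot selected character vector of finally selected mature accessions.
#' @slot cox list of Cox model report tables (univariate, multivariate).
#' @slot bootstrap list of bootstrap stability results (possibly empty).
#' @slot auc per-miRNA AUC table (possibly empty).
#' @slot warnings character vector of warnings accumulated during the run.
#' @slot seed integer master seed of the run.
#' @export
setClass("ScreenRun",
  representation(
    counts = "integer", thresholds = "ScreenThresholds",
    correlation = "data.frame", demi = "data.frame",
    survival = "data.frame", combos = "data.frame",
    selected = "character", cox = "list", bootstrap = "list",
    auc = "data.frame", warnings = "character", seed = "integer"
  )
)

setMethod("show", "ScreenRun", function(object) {
  cat("ScreenRun: onco-miRNA selection cascade\n")
  nm <- names(object@counts)
  for (i in seq_along(object@counts))
    cat(sprintf("  %-18s %d\n", nm[i], object@counts[i]))
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

#' Accessors for `ScreenRun` components
#'
#' @param x a [ScreenRun-class] object.
#' @return `stageCounts()` the named attrition counts; `selectedMirnas()` the
#'   final accession set; the remaining accessors the corresponding result
#'   tables.
#' @name ScreenRun-accessors
NULL

#' @rdname ScreenRun-accessors
#' @export
stageCounts <- function(x) { stopifnot(is(x, "ScreenRun")); x@counts }

#' @rdname ScreenRun-accessors
#' @export
selectedMirnas <- function(x) { stopifnot(is(x, "ScreenRun")); x@selected }

#' @rdname ScreenRun-accessors
#' @export
correlationResults <- function(x) { stopifnot(is(x, "ScreenRun")); x@correlation }

#' @rdname ScreenRun-accessors
#' @export
demiResults <- function(x) { stopifnot(is(x, "ScreenRun")); x@demi }

#' @rdname ScreenRun-accessors
#' @export
survivalResults <- function(x) { stopifnot(is(x, "ScreenRun")); x@survival }

#' @rdname ScreenRun-accessors
#' @export
comboResults <- function(x) { stopifnot(is(x, "ScreenRun")); x@combos }

#' @rdname ScreenRun-accessors
#' @export
coxReports <- function(x) { stopifnot(is(x, "ScreenRun")); x@cox }
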
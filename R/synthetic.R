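#' Generate a coupled synthetic lung-cancer cohort
#'
#' Draws copy-number segments, miRNA isoform read counts, a miRBase-style
#' annotation, clinical records and overall survival for a three-histology
#' cohort (Sq / Ad / Normal), with planted miRNA effect classes recorded in
#' a truth table.  The generative model follows the statistical structure
#' the screening cascade assumes:
#'
#' * per Sq sample and planted locus, the copy ratio (segment mean,
#'   log2(CN/2)) is drawn N(gain_mean, gain_sd) with probability
#'   `gain_fraction` (a focal low-level gain) and N(0, 0.05) otherwise;
#'   loci without a planted CNV effect always draw N(0, 0.05);
#' * latent log2 CPM = baseline + cnv_slope * copy_ratio +
#'   sq_log2fc * \[Sq\] + Gaussian noise, with the slope / offset applied
#'   only to the classes that carry them;
#' * read counts are negative-binomial around CPM * library_size / 1e6,
#'   emitted as two mature isoform records per (miRNA, sample) at distinct
#'   loci plus a stemloop record (exercising the aggregation rules);
#' * overall survival is exponential with hazard
#'   `baseline_hazard * exp(sum(log_hr * z))` over the z-scored latent
#'   expression of the prognostic (onco) miRNAs, administratively censored
#'   at the empirical (1 - censoring_rate) quantile of the drawn times;
#' * clinical covariates follow the configured Table-1-like frequencies.
#'
#' The same seed yields a bitwise-identical cohort, and [writeCohort()]
#' writes every component in the exact dialect the package's readers parse.
#'
#' @param config a [GeneratorConfig-class] (the seed is mandatory).
#' @return a [SyntheticCohort-class] object.
#' @examples
#' coh <- generateCohort(generatorConfig(seed = 7, n_sq = 12, n_ad = 10,
#'   n_normal = 6, n_onco = 1, n_cnv_only = 2, n_sq_up_only = 2, n_null = 5))
#' coh
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  set.seed(config@seed)
  cfg <- config

  n_mir <- cfg@n_onco + cfg@n_cnv_only + cfg@n_sq_up_only + cfg@n_null
  cls <- rep(c("onco", "cnv_only", "sq_up_only", "null"),
             c(cfg@n_onco, cfg@n_cnv_only, cfg@n_sq_up_only, cfg@n_null))
  mi <- sprintf("MI%07d", seq_len(n_mir))
  mimat <- sprintf("MIMAT%07d", seq_len(n_mir))
  mir_name <- sprintf("syn-mir-%d", seq_len(n_mir))
  mat_name <- sprintf("syn-miR-%d-5p", seq_len(n_mir))
  chrom <- as.character(((seq_len(n_mir) - 1L) %% 22L) + 1L)
  prec_start <- 1000000L + ((seq_len(n_mir) - 1L) %/% 22L) * 1000000L
  prec_end <- prec_start + 83L
  mat_start <- prec_start + 30L
  mat_end <- mat_start + 21L
  annotation <- GRanges(
    seqnames = chrom, ranges = IRanges(mat_start, mat_end), strand = "+",
    mature_accession = mimat, mature_name = mat_name,
    precursor_accession = mi, precursor_name = mir_name,
    precursor_start = prec_start, precursor_end = prec_end,
    status = "alive"
  )

  sq_ids <- sprintf("SQ-%04d", seq_len(cfg@n_sq))
  ad_ids <- sprintf("AD-%04d", seq_len(cfg@n_ad))
  nm_ids <- sprintf("NM-%04d", seq_len(cfg@n_normal))
  all_ids <- c(sq_ids, ad_ids, nm_ids)
  histology <- rep(c("Sq", "Ad", "Normal"),
                   c(cfg@n_sq, cfg@n_ad, cfg@n_normal))
  n_all <- length(all_ids)

  # per-miRNA planted effects
  slope <- ifelse(cls %in% c("onco", "cnv_only"), cfg@cnv_slope, 0)
  sqfc <- ifelse(cls %in% c("onco", "sq_up_only"), cfg@sq_log2fc, 0)
  loghr <- ifelse(cls == "onco", cfg@log_hr, 0)
  baseline <- rnorm(n_mir, cfg@baseline_log2cpm_mean, cfg@baseline_log2cpm_sd)

  # copy ratios at each locus for Sq samples (miRNAs x Sq samples)
  has_cnv <- cls %in% c("onco", "cnv_only")
  gained <- matrix(rbinom(n_mir * cfg@n_sq, 1L, cfg@gain_fraction),
                   n_mir, cfg@n_sq) * has_cnv
  ratio <- matrix(rnorm(n_mir * cfg@n_sq, 0, 0.05), n_mir, cfg@n_sq)
  ngain <- sum(gained == 1L)
  ratio[gained == 1L] <- rnorm(ngain, cfg@gain_mean, cfg@gain_sd)
  dimnames(ratio) <- list(mi, sq_ids)

  segments <- GRanges(
    seqnames = rep(chrom, cfg@n_sq),
    ranges = IRanges(rep(pmax(prec_start - 50000L, 1L), cfg@n_sq),
                     rep(prec_end + 50000L, cfg@n_sq)),
    sample_id = rep(sq_ids, each = n_mir),
    num_probes = 50L,
    segment_mean = as.vector(ratio)
  )

  # latent expression (miRNAs x all samples)
  is_sq <- histology == "Sq"
  log2cpm <- matrix(baseline, n_mir, n_all) +
    matrix(rnorm(n_mir * n_all, 0, cfg@noise_sd), n_mir, n_all)
  log2cpm[, is_sq] <- log2cpm[, is_sq] + slope * ratio + sqfc
  dimnames(log2cpm) <- list(mimat, all_ids)

  lib <- rlnorm(n_all, cfg@library_meanlog, cfg@library_sdlog)
  redraw <- which(!(lib > 0))
  while (length(redraw)) {  # defensive; log-normal draws are positive
    lib[redraw] <- rlnorm(length(redraw), cfg@library_meanlog,
                          cfg@library_sdlog)
    redraw <- which(!(lib > 0))
  }
  mu <- 2^log2cpm * rep(lib, each = n_mir) / 1e6
  counts <- matrix(rnbinom(n_mir * n_all, mu = mu, size = 1 / cfg@dispersion),
                   n_mir, n_all, dimnames = list(mimat, all_ids))

  # isoform records: two mature isoforms at distinct loci + one stemloop
  c1 <- matrix(rbinom(n_mir * n_all, counts, 0.6), n_mir, n_all)
  c2 <- counts - c1
  stem <- matrix(rpois(n_mir * n_all, 5), n_mir, n_all)
  sample_rep <- rep(all_ids, each = n_mir)
  iso <- function(cnt, s_off, e_off, type, acc) data.frame(
    sample_id = sample_rep,
    precursor_name = rep(mir_name, n_all),
    chromosome = rep(chrom, n_all),
    start = rep(mat_start, n_all) + s_off,
    end = rep(mat_end, n_all) + e_off,
    strand = "+",
    read_count = as.integer(cnt),
    region_type = type,
    mature_accession = acc,
    stringsAsFactors = FALSE
  )
  isoforms <- rbind(
    iso(as.vector(c1), 0L, 0L, "mature", rep(mimat, n_all)),
    iso(as.vector(c2), 1L, 1L, "mature", rep(mimat, n_all)),
    data.frame(sample_id = sample_rep, precursor_name = rep(mir_name, n_all),
               chromosome = rep(chrom, n_all),
               start = rep(prec_start, n_all), end = rep(prec_end, n_all),
               strand = "+", read_count = as.integer(as.vector(stem)),
               region_type = "stemloop", mature_accession = NA_character_,
               stringsAsFactors = FALSE)
  )
  isoforms <- isoforms[isoforms$read_count > 0, , drop = FALSE]
  isoforms <- isoforms[order(isoforms$sample_id, isoforms$precursor_name,
                             isoforms$start, isoforms$region_type), ,
                       drop = FALSE]
  rownames(isoforms) <- NULL

  # clinical covariates
  draw_clin <- function(ids, male_p, smoke_p, nonsmoke_p, stage_p,
                        age_mean, age_sd) {
    n <- length(ids)
    sex <- ifelse(runif(n) < male_p, "male", "female")
    u <- runif(n)
    smoking <- ifelse(u < smoke_p, "current smoker",
                      ifelse(u < smoke_p + nonsmoke_p, "non-smoker",
                             NA_character_))
    stg <- sample(names(stage_p), n, replace = TRUE, prob = stage_p)
    sub <- sample(c("", "A", "B"), n, replace = TRUE)
    stage <- ifelse(stg == "Unknown", NA_character_,
                    paste0("Stage ", stg, sub))
    age <- round(rnorm(n, age_mean, age_sd))
    age <- pmin(pmax(age, age_mean - 3 * age_sd), age_mean + 3 * age_sd)
    data.frame(sample_id = ids, sex = sex, smoking_status = smoking,
               stage = stage, age = age, stringsAsFactors = FALSE)
  }
  sq_clin <- draw_clin(sq_ids, cfg@male_freq_sq, cfg@smoker_freq_sq,
                       cfg@nonsmoker_freq_sq, cfg@stage_freq_sq,
                       cfg@age_mean_sq, cfg@age_sd_sq)
  ad_clin <- draw_clin(ad_ids, cfg@male_freq_ad, cfg@smoker_freq_ad,
                       cfg@nonsmoker_freq_ad, cfg@stage_freq_ad,
                       cfg@age_mean_ad, cfg@age_sd_ad)
  nm_clin <- data.frame(sample_id = nm_ids, sex = NA_character_,
                        smoking_status = NA_character_,
                        stage = NA_character_, age = NA_real_,
                        stringsAsFactors = FALSE)

  # survival for Sq: hazard couples to the continuous z-scored latent
  # expression of the prognostic miRNAs (dichotomization stays an honest
  # downstream inference step)
  onco_idx <- which(cls == "onco")
  lp <- rep(0, cfg@n_sq)
  for (m in onco_idx) {
    z <- as.vector(scale(log2cpm[m, sq_ids]))
    lp <- lp + loghr[m] * z
  }
  hz <- cfg@baseline_hazard * exp(lp)
  tt <- rexp(cfg@n_sq, rate = hz)
  cens <- if (cfg@censoring_rate > 0) {
    unname(quantile(tt, 1 - cfg@censoring_rate, type = 7))
  } else max(tt) + 1
  os_time <- ceiling(pmin(tt, cens))
  os_event <- as.integer(tt <= cens)
  if (cfg@n_missing_survival > 0L) {
    miss <- sample.int(cfg@n_sq, cfg@n_missing_survival)
    os_time[miss] <- NA_real_; os_event[miss] <- NA_integer_
  }

  clinical <- rbind(
    data.frame(sq_clin[, "sample_id", drop = FALSE], histology = "Sq",
               os_time = os_time, os_event = os_event,
               sq_clin[, c("age", "sex", "smoking_status", "stage")],
               stringsAsFactors = FALSE),
    data.frame(ad_clin[, "sample_id", drop = FALSE], histology = "Ad",
               os_time = NA_real_, os_event = NA_integer_,
               ad_clin[, c("age", "sex", "smoking_status", "stage")],
               stringsAsFactors = FALSE),
    data.frame(nm_clin[, "sample_id", drop = FALSE], histology = "Normal",
               os_time = NA_real_, os_event = NA_integer_,
               nm_clin[, c("age", "sex", "smoking_status", "stage")],
               stringsAsFactors = FALSE)
  )
  clinical$survival_eligible <- !is.na(clinical$os_time) &
    !is.na(clinical$os_event)
  rownames(clinical) <- NULL

  truth <- data.frame(
    mature_accession = mimat, mature_name = mat_name,
    precursor_accession = mi, class = cls,
    cnv_slope = slope, sq_log2fc = sqfc, log_hr = loghr,
    baseline_log2cpm = baseline, stringsAsFactors = FALSE
  )
  new("SyntheticCohort", segments = segments, isoforms = isoforms,
      annotation = annotation, clinical = clinical, truth = truth,
      config = cfg)
}

#' Write / read a synthetic cohort in the standard file dialects
#'
#' `writeCohort()` writes `segments.seg.txt`, `isoform_quantification.txt`,
#' `annotation.gff3`, `clinical.tsv`, `truth.tsv` and `config.json` into
#' `dir`; the first four files are in the exact dialects parsed by
#' [readSegments()], [readIsoformCounts()], [readMirnaAnnotation()] and
#' [readClinical()].  `readCohortFiles()` reads them back.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return `writeCohort()` invisibly returns the named vector of paths;
#'   `readCohortFiles()` a list with `segments`, `isoforms`, `annotation`,
#'   `clinical` (and `truth` if present).
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    segments = file.path(dir, "segments.seg.txt"),
    isoforms = file.path(dir, "isoform_quantification.txt"),
    annotation = file.path(dir, "annotation.gff3"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  writeSegments(cohort@segments, paths["segments"])
  writeIsoformCounts(cohort@isoforms, paths["isoforms"])
  writeMirnaAnnotation(cohort@annotation, paths["annotation"])
  writeClinical(cohort@clinical, paths["clinical"])
  fwrite(as.data.table(cohort@truth), paths["truth"], sep = "\t",
         quote = FALSE)
  write_json(as.list(cohort@config), paths["config"], auto_unbox = TRUE,
             digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname writeCohort
#' @export
readCohortFiles <- function(dir) {
  out <- list(
    segments = readSegments(file.path(dir, "segments.seg.txt")),
    isoforms = readIsoformCounts(file.path(dir, "isoform_quantification.txt")),
    annotation = readMirnaAnnotation(file.path(dir, "annotation.gff3")),
    clinical = readClinical(file.path(dir, "clinical.tsv"))
  )
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp))
    out$truth <- fread(tp, sep = "\t", data.table = FALSE,
                       showProgress = FALSE)
  out
}

#' Select null-model miRNAs from the truth table
#'
#' Picks `k` null-class miRNAs to serve as comparators for bootstrap
#' stability, either uniformly at random or matched on baseline expression
#' (the `k` nulls whose baseline log2 CPM is closest to the mean baseline
#' of the onco set).  Deterministic given the seed.
#'
#' @param truth truth table from [cohortTruth()].
#' @param k number of null miRNAs to select.
#' @param matching `"none"` or `"expression-matched"`.
#' @param seed integer RNG seed.
#' @return character vector of `k` mature accessions.
#' @export
plantNullMirnas <- function(truth, k, matching = c("none", "expression-matched"),
                            seed = 1L) {
  matching <- match.arg(matching)
  nulls <- truth[truth$class == "null", , drop = FALSE]
  if (k > nrow(nulls))
    stopf("requested %d null miRNAs but only %d available", k, nrow(nulls))
  set.seed(as.integer(seed))
  if (matching == "none") {
    sample(nulls$mature_accession, k)
  } else {
    target <- mean(truth$baseline_log2cpm[truth$class == "onco"])
    ord <- order(abs(nulls$baseline_log2cpm - target))
    nulls$mature_accession[ord[seq_len(k)]]
  }
}

#' Confusion summary of a screen against the planted truth
#'
#' Compares the finally selected miRNA set against the planted onco class:
#' sensitivity = selected onco / all onco, specificity = unselected
#' non-onco / all non-onco.  Optionally attaches the per-stage attrition
#' counts of the run.
#'
#' @param truth truth table from [cohortTruth()].
#' @param selected character vector of selected mature accessions.
#' @param stage_counts optional named counts from [stageCounts()].
#' @return list with `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   and `stage_counts`.
#' @export
truthReport <- function(truth, selected, stage_counts = NULL) {
  unknown <- setdiff(selected, truth$mature_accession)
  if (length(unknown))
    stopf("selected id '%s' absent from the truth table", unknown[1])
  onco <- truth$mature_accession[truth$class == "onco"]
  other <- setdiff(truth$mature_accession, onco)
  tp <- length(intersect(selected, onco))
  fp <- length(intersect(selected, other))
  fn <- length(onco) - tp
  tn <- length(other) - fp
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (length(onco)) tp / length(onco) else NA_real_,
       specificity = if (length(other)) tn / length(other) else NA_real_,
       stage_counts = stage_counts)
}

#' Simulate a two-group exponential survival cohort
#'
#' Minimal survival simulator used for calibration and parameter-recovery
#' studies: a balanced binary group, exponential event times with hazard
#' `baseline_hazard * hazard_ratio^group`, administrative censoring at the
#' empirical (1 - censoring_rate) quantile.  Uses the caller's RNG state
#' (seed outside).
#'
#' @param n total sample size (split as evenly as possible).
#' @param hazard_ratio true hazard ratio of group 1 vs group 0.
#' @param baseline_hazard baseline hazard per day.
#' @param censoring_rate fraction of observations censored.
#' @return `data.frame` with `time`, `event`, `group`.
#' @export
simulateTwoGroupSurvival <- function(n, hazard_ratio,
                                     baseline_hazard = 4e-4,
                                     censoring_rate = 0.5) {
  group <- rep(c(0L, 1L), length.out = n)
  tt <- rexp(n, rate = baseline_hazard * hazard_ratio^group)
  cens <- if (censoring_rate > 0) {
    unname(quantile(tt, 1 - censoring_rate, type = 7))
  } else max(tt) + 1
  data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens),
             group = group)
}
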
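#' Run the full onco-miRNA selection cascade
#'
#' Orchestrates the screen end-to-end: isoform aggregation to mature
#' counts, CPM normalization, segment-mean assignment to precursor loci,
#' the CNV-expression correlation screen, the Sq-specific differential
#' filter, the median-split prognostic screen with subset combinations,
#' and (optionally) Cox models with categorized clinical covariates,
#' proportional-hazards checks, bootstrap stability, and per-miRNA AUC
#' diagnostics.  The run is deterministic given the inputs and the seed;
#' the master seed fans out to per-stage child seeds so stages are
#' individually reproducible.
#'
#' @param inputs a [SyntheticCohort-class], a directory written by
#'   [writeCohort()], or a named list with elements `segments` (GRanges),
#'   `isoforms`, `annotation` (GRanges), `clinical` (data.frames).
#' @param thresholds a [ScreenThresholds-class].
#' @param seed master seed for the stochastic stages (bootstrap).
#' @param run_cox fit Cox models for the selected miRNAs and combination.
#' @param run_bootstrap run bootstrap stability for the selected miRNAs and
#'   combination (uses `thresholds@bootstrap_B` replicates).
#' @param pseudocount CPM pseudocount for the differential fold changes.
#' @param cutoff_rule dichotomization rule, `"median"` or `"mean"`.
#' @return a [ScreenRun-class] object.
#' @examples
#' coh <- generateCohort(generatorConfig(seed = 11, n_sq = 40, n_ad = 30,
#'   n_normal = 15, n_onco = 1, n_cnv_only = 3, n_sq_up_only = 3,
#'   n_null = 13))
#' run <- runScreen(coh, run_cox = FALSE)
#' stageCounts(run)
#' @export
runScreen <- function(inputs, thresholds = screenThresholds(), seed = 1L,
                      run_cox = TRUE, run_bootstrap = FALSE,
                      pseudocount = 1, cutoff_rule = "median") {
  if (is(inputs, "SyntheticCohort")) {
    dat <- list(segments = inputs@segments, isoforms = inputs@isoforms,
                annotation = inputs@annotation, clinical = inputs@clinical)
  } else if (is.character(inputs) && length(inputs) == 1L) {
    dat <- readCohortFiles(inputs)
  } else if (is.list(inputs)) {
    dat <- inputs
  } else {
    stopf("runScreen: unsupported inputs")
  }
  for (nm in c("segments", "isoforms", "annotation", "clinical"))
    if (is.null(dat[[nm]])) stopf("runScreen: missing input '%s'", nm)

  warns <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  se <- collect(aggregateMatureCounts(dat$isoforms, dat$annotation,
                                      sample_manifest = dat$clinical$sample_id))
  expressed <- rowSums(assay(se, "counts")) > 0
  se <- se[expressed, ]
  se <- cpmNormalize(se)
  cpm <- assay(se, "cpm")

  cnv <- assignSegmentMeans(dat$segments, dat$annotation)
  corr <- correlationScreen(cpm, cnv, dat$annotation, thresholds)
  cand_cnv <- cnvCorrelatedMirnas(corr)

  groups <- setNames(dat$clinical$histology, dat$clinical$sample_id)
  demi <- if (length(cand_cnv)) {
    collect(demiFilter(cpm, groups, cand_cnv, thresholds,
                       pseudocount = pseudocount))
  } else {
    data.frame()
  }
  cand_demi <- if (nrow(demi)) demi$mature_accession[demi$passes] else
    character()

  surv <- if (length(cand_demi)) {
    collect(survivalScreen(cpm, dat$clinical, cand_demi, thresholds,
                           cutoff_rule = cutoff_rule))
  } else {
    list(per_mirna = data.frame(), combos = data.frame(),
         selected = character(), labels = NULL, cohort = NULL)
  }
  selected <- surv$selected

  counts <- c(
    expressed = sum(expressed),
    cnv_correlated = length(cand_cnv),
    sq_upregulated = length(cand_demi),
    prognostic = length(selected),
    final_combination = as.integer(length(selected) > 0L)
  )

  cox <- list(); boot <- list(); auc <- data.frame()
  if (length(selected)) {
    time <- surv$cohort$time; event <- surv$cohort$event
    high01 <- (surv$labels == "high") + 0L
    combo <- comboGroup(surv$labels)

    if (run_cox) {
      clin_coh <- dat$clinical[match(surv$cohort$sample_id,
                                     dat$clinical$sample_id), , drop = FALSE]
      cov <- encodeCovariates(clin_coh)
      covX <- as.matrix(cov[, c("stage_high", "smoker", "age_high",
                                "sex_male")])
      designs <- c(
        setNames(lapply(selected, function(a)
          cbind(mirna_high = high01[, a])), selected),
        list(combo_high = cbind(combo_high = (combo == "high") + 0L))
      )
      fit_one <- function(X) {
        tryCatch({
          f <- coxFit(X, time, event)
          ph <- if (f$converged) phTest(f) else NULL
          list(fit = f, ph = ph)
        }, error = function(e) list(fit = NULL, ph = NULL,
                                    error = conditionMessage(e)))
      }
      report <- function(model, res) {
        f <- res$fit
        if (is.null(f) || !f$converged) {
          return(data.frame(model = model, variable = NA_character_,
                            hazard_ratio = NA_real_, ci_lower = NA_real_,
                            ci_upper = NA_real_, p = NA_real_,
                            ph_p = NA_real_, converged = FALSE,
                            stringsAsFactors = FALSE))
        }
        data.frame(model = model, variable = names(f$coefficients),
                   hazard_ratio = unname(f$hazard_ratio),
                   ci_lower = unname(f$ci_lower),
                   ci_upper = unname(f$ci_upper),
                   p = unname(f$wald_p),
                   ph_p = if (!is.null(res$ph)) res$ph$p else NA_real_,
                   converged = TRUE, stringsAsFactors = FALSE)
      }
      uni <- do.call(rbind, lapply(names(designs), function(nm)
        report(nm, fit_one(designs[[nm]]))))
      multi <- do.call(rbind, lapply(names(designs), function(nm)
        report(paste0(nm, " + clinical covariates"),
               fit_one(cbind(designs[[nm]], covX)))))
      cox <- list(univariate = uni, multivariate = multi)
    }

    if (run_bootstrap) {
      units <- c(setNames(lapply(selected, function(a) surv$labels[, a]),
                          selected),
                 list(combo = combo))
      boot <- lapply(seq_along(units), function(i) {
        bootstrapStability(time, event, units[[i]],
                           B = thresholds@bootstrap_B,
                           alpha = thresholds@bootstrap_alpha,
                           seed = childSeed(seed, i))
      })
      names(boot) <- names(units)
    }

    auc <- aucTable(cpm, groups, selected)
  }

  new("ScreenRun",
      counts = counts, thresholds = thresholds,
      correlation = corr,
      demi = if (nrow(demi)) demi else data.frame(),
      survival = surv$per_mirna, combos = surv$combos,
      selected = selected, cox = cox, bootstrap = boot, auc = auc,
      warnings = warns, seed = as.integer(seed))
}

#' Write the result files of a screening run
#'
#' Writes the per-stage result tables as TSV with stable column order, the
#' bootstrap results as JSON, and a machine-readable run report
#' (`report.json`: stage counts, thresholds, seed, warnings, and the
#' output-file inventory) plus a short human-readable `report.txt`.
#'
#' @param run a [ScreenRun-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
writeScreenRun <- function(run, dir) {
  stopifnot(is(run, "ScreenRun"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wtab <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    p <- file.path(dir, name)
    fwrite(as.data.table(df), p, sep = "\t", quote = FALSE, na = "NA")
    paths[[name]] <<- p
  }
  wtab(run@correlation, "correlation.tsv")
  wtab(run@demi, "demi.tsv")
  wtab(run@survival, "survival.tsv")
  wtab(run@combos, "combinations.tsv")
  wtab(run@auc, "auc.tsv")
  if (length(run@cox)) {
    wtab(run@cox$univariate, "cox_univariate.tsv")
    wtab(run@cox$multivariate, "cox_multivariate.tsv")
  }
  if (length(run@bootstrap)) {
    p <- file.path(dir, "bootstrap.json")
    write_json(run@bootstrap, p, auto_unbox = TRUE, digits = NA)
    paths[["bootstrap.json"]] <- p
  }
  rep_path <- file.path(dir, "report.json")
  write_json(list(
    stage_counts = as.list(run@counts),
    selected = run@selected,
    thresholds = as.list(run@thresholds),
    seed = run@seed,
    warnings = run@warnings,
    files = as.list(paths)
  ), rep_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["report.json"]] <- rep_path

  txt <- c("onco-miRNA screen run report", "",
           sprintf("  %-18s %d", names(run@counts), run@counts), "",
           if (length(run@selected))
             paste("selected:", paste(run@selected, collapse = ", "))
           else "selected: (none)")
  writeLines(txt, file.path(dir, "report.txt"))
  paths[["report.txt"]] <- file.path(dir, "report.txt")
  invisible(paths)
}
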
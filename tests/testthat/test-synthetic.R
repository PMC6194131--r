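test_that("generated cohorts honour the dimension contract", {
  coh <- generateCohort(generatorConfig(seed = 5, n_sq = 10, n_ad = 10,
    n_normal = 5, n_onco = 2, n_cnv_only = 3, n_sq_up_only = 3, n_null = 12))
  expect_equal(nrow(cohortClinical(coh)), 25L)
  expect_equal(nrow(cohortTruth(coh)), 20L)
  se <- aggregateMatureCounts(coh@isoforms, coh@annotation)
  expect_equal(dim(SummarizedExperiment::assay(se, "counts")), c(20L, 25L))
  expect_equal(table(cohortTruth(coh)$class)[["onco"]], 2L)
  # CNV segments exist only for the Sq samples
  expect_setequal(unique(S4Vectors::mcols(coh@segments)$sample_id),
                  cohortClinical(coh)$sample_id[cohortClinical(coh)$histology == "Sq"])
})

test_that("the same seed yields byte-identical cohort files", {
  cfg <- generatorConfig(seed = 6, n_sq = 15, n_ad = 10, n_normal = 5,
                         n_onco = 1, n_cnv_only = 2, n_sq_up_only = 2,
                         n_null = 5)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  p1 <- writeCohort(generateCohort(cfg), d1)
  p2 <- writeCohort(generateCohort(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = paste("file:", nm))
  }
  # and a different seed does not
  p3 <- writeCohort(generateCohort(generatorConfig(seed = 7, n_sq = 15,
    n_ad = 10, n_normal = 5, n_onco = 1, n_cnv_only = 2, n_sq_up_only = 2,
    n_null = 5)), file.path(tempdir(), "coh_c"))
  expect_false(identical(readLines(p1[["isoforms"]]),
                         readLines(p3[["isoforms"]])))
})

test_that("written cohorts parse back through the standard readers", {
  coh <- generateCohort(small_config(8))
  dir <- file.path(tempdir(), "coh_rt")
  writeCohort(coh, dir)
  back <- readCohortFiles(dir)
  expect_equal(length(back$segments), length(coh@segments))
  expect_equal(S4Vectors::mcols(back$segments)$segment_mean,
               S4Vectors::mcols(coh@segments)$segment_mean)
  expect_equal(nrow(back$isoforms), nrow(coh@isoforms))
  expect_equal(sort(back$clinical$sample_id),
               sort(coh@clinical$sample_id))
  expect_equal(length(back$annotation), length(coh@annotation))
})

test_that("covariate frequencies converge to the configured values", {
  coh <- generateCohort(generatorConfig(seed = 9, n_sq = 10000, n_ad = 10,
    n_normal = 5, n_onco = 0, n_cnv_only = 0, n_sq_up_only = 0, n_null = 2))
  cl <- cohortClinical(coh)
  sq <- cl[cl$histology == "Sq", ]
  n <- nrow(sq)
  tol <- 4 * sqrt(0.25 / n)  # 4 binomial standard errors
  expect_lt(abs(mean(sq$sex == "male") - 0.76), tol)
  smoker <- !is.na(sq$smoking_status) & sq$smoking_status == "current smoker"
  expect_lt(abs(mean(smoker) - 0.93), tol)
  stage1 <- grepl("^Stage I($|[AB])", sq$stage)
  expect_lt(abs(mean(stage1, na.rm = TRUE) - 0.48 / 0.99), tol + 0.01)
})

test_that("null-stratum survival follows the exponential baseline", {
  cfg <- generatorConfig(seed = 10, n_sq = 400, n_ad = 10, n_normal = 5,
                         n_onco = 0, n_cnv_only = 0, n_sq_up_only = 0,
                         n_null = 2, censoring_rate = 0.3)
  coh <- generateCohort(cfg)
  cl <- cohortClinical(coh)
  sq <- cl[cl$histology == "Sq", ]
  km <- kmEstimate(sq$os_time, sq$os_event)
  h <- cfg@baseline_hazard
  # compare at interior event times (wide tolerance: one cohort draw)
  mid <- km$survival[km$survival > 0.35 & km$survival < 0.95]
  ref <- exp(-h * km$time[km$survival > 0.35 & km$survival < 0.95])
  expect_lt(max(abs(mid - ref)), 0.08)
})

test_that("planted CNV effects are recoverable; nulls stay uncorrelated", {
  cfg <- generatorConfig(seed = 11, n_sq = 500, n_ad = 10, n_normal = 5,
                         n_onco = 0, n_cnv_only = 5, n_sq_up_only = 0,
                         n_null = 100)
  coh <- generateCohort(cfg)
  se <- cpmNormalize(aggregateMatureCounts(coh@isoforms, coh@annotation))
  cpm <- SummarizedExperiment::assay(se, "cpm")
  cnv <- assignSegmentMeans(coh@segments, coh@annotation)
  res <- correlationScreen(cpm, cnv, coh@annotation)
  truth <- cohortTruth(coh)
  res$class <- truth$class[match(res$mature_accession,
                                 truth$mature_accession)]
  # nulls: |r| below the screen threshold nearly always
  nulls <- res[res$class == "null", ]
  expect_gte(mean(abs(nulls$r) < 0.2), 0.95)
  # planted slopes: all pass at n = 500
  expect_true(all(res$passes[res$class == "cnv_only"]))
})

test_that("null miRNA selection is deterministic and matchable", {
  coh <- generateCohort(small_config(12))
  truth <- cohortTruth(coh)
  a <- plantNullMirnas(truth, 3, seed = 4)
  b <- plantNullMirnas(truth, 3, seed = 4)
  expect_identical(a, b)
  expect_true(all(truth$class[match(a, truth$mature_accession)] == "null"))
  target <- mean(truth$baseline_log2cpm[truth$class == "onco"])
  dist_of <- function(ids) {
    abs(mean(truth$baseline_log2cpm[match(ids, truth$mature_accession)]) -
        target)
  }
  for (s in 1:5) {
    m <- plantNullMirnas(truth, 3, matching = "expression-matched", seed = s)
    u <- plantNullMirnas(truth, 3, matching = "none", seed = s)
    expect_lte(dist_of(m), dist_of(u))
  }
  expect_error(plantNullMirnas(truth, 10000), "available")
})

test_that("truth report scores selections against the planted classes", {
  coh <- generateCohort(small_config(13))
  truth <- cohortTruth(coh)
  onco <- truth$mature_accession[truth$class == "onco"]
  perfect <- truthReport(truth, onco)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  empty <- truthReport(truth, character())
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$fp, 0L)
  expect_error(truthReport(truth, "MIMAT9999999"), "absent")
})
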
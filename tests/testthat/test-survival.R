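test_that("dichotomization uses the strict-greater tie rule", {
  expect_equal(dichotomize(c(1, 2, 3, 4)),
               c("low", "low", "high", "high"), ignore_attr = TRUE)
  # ties at the cut-off fall in the low group
  expect_equal(dichotomize(c(1, 2, 2, 3)),
               c("low", "low", "low", "high"), ignore_attr = TRUE)
  expect_equal(attr(dichotomize(c(1, 2, 3, 4)), "cutoff"), 2.5)
  expect_equal(dichotomize(c(1, 2, 3, 4), "mean"),
               c("low", "low", "high", "high"), ignore_attr = TRUE)
  expect_error(dichotomize(rep(3, 5)), "degenerate")
})

test_that("Kaplan-Meier estimate equals hand-computed product limits", {
  # no censoring: empirical survivor function
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  # censoring at 2 shrinks the risk set at t = 3 to one
  km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$survival, c(2/3, 0))
  expect_equal(km2$n_risk, c(3L, 1L))
  # one early event among n: single drop by (n-1)/n
  km3 <- kmEstimate(c(1, 5, 6, 7), c(1, 0, 0, 0))
  expect_equal(km3$survival, 3/4)
  expect_error(kmEstimate(c(1, 2), c(0, 0)), "no events")
})

test_that("KM without censoring equals the empirical survivor function", {
  set.seed(31)
  for (rep in 1:10) {
    t <- sample(1:50, 30, replace = TRUE)
    km <- kmEstimate(t, rep(1, 30))
    emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
    expect_equal(km$survival, emp, tolerance = 1e-12)
  }
})

test_that("log-rank test reproduces the hand-computed hypergeometric sums", {
  res <- logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(res$chisq, 2.882353, tolerance = 1e-6)
  expect_equal(res$p, 0.0895551, tolerance = 1e-6)
  expect_equal(unname(res$observed["A"] - res$expected["A"]), 1.16667,
               tolerance = 1e-5)
  # identical event-time multisets in both groups: no signal
  res2 <- logrankTest(c(1, 1, 2, 2), c(1, 1, 1, 1), c("A", "B", "A", "B"))
  expect_equal(res2$chisq, 0)
  expect_equal(res2$p, 1)
  expect_error(logrankTest(1:3, c(1, 1, 1), c("A", "A", "A")), "2 non-empty")
})

test_that("log-rank is invariant to group relabelling", {
  set.seed(32)
  for (rep in 1:10) {
    n <- 60
    t <- rexp(n, 0.01); e <- rbinom(n, 1, 0.7); g <- rbinom(n, 1, 0.5)
    if (sum(e) == 0 || length(unique(g)) < 2) next
    a <- logrankTest(t, e, ifelse(g == 1, "X", "Y"))
    b <- logrankTest(t, e, ifelse(g == 1, "Y", "X"))
    expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
  }
})

test_that("combination grouping requires all members high", {
  m <- rbind(S1 = c("high", "high", "high"),
             S2 = c("high", "high", "low"),
             S3 = c("low", "low", "low"))
  expect_equal(comboGroup(m),
               c(S1 = "high", S2 = "low", S3 = "low"))
  # a single-member set is the identity
  expect_equal(unname(comboGroup(cbind(c("high", "low")))), c("high", "low"))
  m[2, 3] <- NA
  expect_error(comboGroup(m), "missing label")
})

test_that("covariate encoding follows the categorization rules", {
  cl <- data.frame(
    sample_id = c("P1", "P2", "P3", "P4"),
    histology = "Sq",
    os_time = c(100, 200, 300, 400), os_event = c(1L, 0L, 1L, 0L),
    age = c(60, 70, 65, 65),   # median 65
    sex = c("male", "female", "male", "female"),
    smoking_status = c("current smoker", "reformed smoker", NA, "non-smoker"),
    stage = c("Stage IIIA", "Stage I", "Stage IV", NA),
    survival_eligible = TRUE, stringsAsFactors = FALSE
  )
  enc <- encodeCovariates(cl)
  expect_equal(enc$smoker, c(1L, 0L, 0L, 0L))  # only "current smoker"
  expect_equal(enc$stage_high, c(1L, 0L, 1L, NA_integer_))
  expect_equal(enc$sex_male, c(1L, 0L, 1L, 0L))
  # age exactly at the median is low under the strict-greater rule
  expect_equal(enc$age_high, c(0L, 1L, 0L, 0L))
  cl$stage[2] <- "Stage Q"
  expect_error(encodeCovariates(cl), "Stage Q")
})

test_that("Cox fit matches the independent partial-likelihood oracle", {
  library(survival)
  set.seed(33)
  for (rep in 1:10) {
    n <- 120
    X <- cbind(a = rbinom(n, 1, 0.5), b = rnorm(n))
    tt <- rexp(n, 1e-3 * exp(0.6 * X[, 1] - 0.4 * X[, 2]))
    cens <- unname(quantile(tt, 0.6))
    time <- pmin(tt, cens) + runif(n) * 1e-8  # break ties
    ev <- as.integer(tt <= cens)
    mine <- coxFit(X, time, ev)
    ref <- coxph(Surv(time, ev) ~ X, ties = "efron")
    expect_true(mine$converged)
    expect_equal(unname(mine$coefficients), unname(coef(ref)),
                 tolerance = 1e-7)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
    expect_equal(mine$score_chisq, ref$score, tolerance = 1e-7)
  }
})

test_that("Cox handles ties with the Efron correction", {
  library(survival)
  set.seed(34)
  n <- 100
  x <- rbinom(n, 1, 0.5)
  time <- sample(1:20, n, replace = TRUE)  # heavy ties
  ev <- rbinom(n, 1, 0.7)
  mine <- coxFit(cbind(x = x), time, ev)
  ref <- coxph(Surv(time, ev) ~ x, ties = "efron")
  expect_equal(unname(mine$coefficients), unname(coef(ref)),
               tolerance = 1e-7)
  expect_equal(unname(mine$wald_p),
               unname(summary(ref)$coefficients[, "Pr(>|z|)"]),
               tolerance = 1e-6)
})

test_that("Cox flags monotone likelihoods instead of reporting estimates", {
  # perfect separation: all events in one group before any in the other
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- c(1, 1, 1, 1, 1, 1, 1, 1)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- coxFit(cbind(x = x), time, ev)
  expect_false(fit$converged)
  expect_true(all(is.na(fit$hazard_ratio)))
  expect_error(coxFit(cbind(x = rep(1, 8)), time, ev), "constant")
})

test_that("Cox score test with one binary covariate equals the log-rank", {
  # hand-computed 4-sample example
  fit <- coxFit(cbind(g = c(1, 1, 0, 0)), c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(fit$score_chisq, 2.882353, tolerance = 1e-6)
  set.seed(35)
  for (rep in 1:10) {
    n <- 50
    g <- rbinom(n, 1, 0.5)
    time <- rexp(n, 0.02 * exp(0.5 * g)) + runif(n) * 1e-9
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2 || length(unique(g)) < 2) next
    fit <- coxFit(cbind(g = g), time, ev)
    lr <- logrankTest(time, ev, g)
    expect_equal(fit$score_chisq, lr$chisq, tolerance = 1e-8)
  }
})

test_that("proportional-hazards slope test is calibrated and has power", {
  set.seed(36)
  rej <- 0L; R <- 200L
  for (i in seq_len(R)) {
    d <- simulateTwoGroupSurvival(150, 2.0)
    d$time <- d$time + runif(150) * 1e-8
    f <- coxFit(cbind(g = d$group), d$time, d$event)
    if (f$converged && phTest(f)$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / R, 0.02)
  expect_lte(rej / R, 0.09)

  # hazard ratio crossing 1 mid-study must be detected
  set.seed(37)
  rej <- 0L; R <- 60L
  base <- 1e-3; t0 <- log(2) / base
  for (i in seq_len(R)) {
    n <- 300; g <- rep(0:1, length.out = n)
    t1 <- rexp(n, base * ifelse(g == 1, 3, 1))
    tt <- ifelse(t1 <= t0, t1, t0 + rexp(n, base * ifelse(g == 1, 1/3, 1)))
    cens <- unname(quantile(tt, 0.9))
    time <- pmin(tt, cens) + runif(n) * 1e-8
    ev <- as.integer(tt <= cens)
    f <- coxFit(cbind(g = g), time, ev)
    if (f$converged && phTest(f)$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / R, 0.5)
  # a single-event dataset cannot support the slope test
  f <- coxFit(cbind(g = c(1, 0, 1, 0)), c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_error(phTest(f))
})

test_that("bootstrap stability is deterministic and saturates", {
  # wildly separated groups: every resample is significant
  time <- c(1:50, 101:150)
  ev <- rep(1, 100)
  g <- rep(c("A", "B"), each = 50)
  bs <- bootstrapStability(time, ev, g, B = 200, seed = 99)
  expect_equal(bs$fraction, 1.0)
  bs2 <- bootstrapStability(time, ev, g, B = 200, seed = 99)
  expect_identical(bs$n_significant, bs2$n_significant)  # bitwise reproducible
  expect_error(bootstrapStability(time, ev, g, B = 0), "B must be")
})

test_that("survival screen selects prognostic miRNAs with the worse-high direction", {
  set.seed(38)
  n <- 120
  ids <- sprintf("SQ-%03d", 1:n)
  expr_bad <- rnorm(n)    # high expression -> shorter survival
  expr_good <- rnorm(n)   # high expression -> longer survival (protective)
  expr_null <- rnorm(n)
  tt <- rexp(n, 4e-4 * exp(0.9 * expr_bad - 0.9 * expr_good))
  cens <- unname(quantile(tt, 0.5))
  clinical <- data.frame(
    sample_id = ids, histology = "Sq",
    os_time = ceiling(pmin(tt, cens)), os_event = as.integer(tt <= cens),
    age = 65, sex = "male", smoking_status = NA_character_,
    stage = "Stage I", survival_eligible = TRUE, stringsAsFactors = FALSE
  )
  cpm <- rbind(bad = expr_bad, good = expr_good, null = expr_null)
  colnames(cpm) <- ids
  res <- survivalScreen(cpm, clinical, c("bad", "good", "null"))
  expect_true("bad" %in% res$selected)
  expect_false("good" %in% res$selected)  # protective direction rejected
  tab <- res$per_mirna
  expect_false(tab$worse_high[tab$mature_accession == "good"])
})

test_that("subset combinations enumerate every non-empty subset", {
  set.seed(39)
  n <- 150
  ids <- sprintf("SQ-%03d", 1:n)
  e1 <- rnorm(n); e2 <- 0.8 * e1 + rnorm(n, 0, 0.6)
  e3 <- 0.8 * e1 + rnorm(n, 0, 0.6)
  tt <- rexp(n, 4e-4 * exp(0.8 * (e1 + e2 + e3)))
  cens <- unname(quantile(tt, 0.5))
  clinical <- data.frame(
    sample_id = ids, histology = "Sq",
    os_time = ceiling(pmin(tt, cens)), os_event = as.integer(tt <= cens),
    age = 65, sex = "male", smoking_status = NA_character_,
    stage = "Stage I", survival_eligible = TRUE, stringsAsFactors = FALSE
  )
  cpm <- rbind(m1 = e1, m2 = e2, m3 = e3)
  colnames(cpm) <- ids
  res <- survivalScreen(cpm, clinical, c("m1", "m2", "m3"))
  if (length(res$selected) == 3L) {
    expect_equal(nrow(res$combos), 7L)  # 2^3 - 1 non-empty subsets
    expect_equal(sort(unique(res$combos$size)), 1:3)
  } else {
    succeed("fewer than 3 selected under this draw; enumeration not exercised")
  }
})

test_that("cohort summary rounds percentages half away from zero", {
  cl <- rbind(
    make_clinical(185, "Sq", sex = "male"),
    make_clinical(60, "Sq", sex = "female")
  )
  cs <- cohortSummary(cl)
  sexrow <- cs$sex[cs$sex$histology == "Sq" & cs$sex$level == "male", ]
  expect_equal(sexrow$count, 185L)
  expect_equal(sexrow$percent, 76)  # 75.51 rounds up
  # empty histology: zero rows, no division error
  expect_equal(unname(cs$n["Ad"]), 0L)
  expect_equal(cs$sex$percent[cs$sex$histology == "Ad"], c(0, 0))
})
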
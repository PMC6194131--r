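#' Dichotomize expression values into high/low groups
#'
#' Splits samples at the cohort median (default) or mean of the values.
#' A sample is labelled `high` when its value is strictly greater than the
#' cut-off, so values tied with the cut-off fall in the `low` group.
#'
#' @param values numeric vector (finite), named by sample if available.
#' @param cutoff_rule `"median"` or `"mean"`.
#' @return character vector of `"low"`/`"high"` labels with the cut-off in
#'   `attr(, "cutoff")`.
#' @examples
#' dichotomize(c(1, 2, 2, 3))
#' @export
dichotomize <- function(values, cutoff_rule = c("median", "mean")) {
  cutoff_rule <- match.arg(cutoff_rule)
  if (length(values) < 2L) stopf("need at least 2 samples")
  if (any(!is.finite(values))) stopf("values must be finite")
  if (max(values) == min(values))
    stopf("degenerate split: all values identical")
  cutoff <- if (cutoff_rule == "median") median(values) else mean(values)
  labels <- ifelse(values > cutoff, "high", "low")
  if (length(unique(labels)) < 2L)
    stopf("degenerate split: all samples on one side of the cut-off")
  attr(labels, "cutoff") <- cutoff
  labels
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survivor function S(t) over the distinct event times:
#' at each event time the estimate is multiplied by (1 - d/n) where d is
#' the number of deaths and n the number at risk.  Censored observations
#' leave the risk set after their censoring time.
#'
#' @param time survival times in days (> 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @return `data.frame` with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival`.  S(0) = 1 implicitly.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 0, 1))
#' @export
kmEstimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time) | time <= 0)) stopf("times must be positive")
  event <- as.integer(event)
  if (!any(event == 1L)) stopf("no events: survivor curve undefined")
  et <- sort(unique(time[event == 1L]))
  n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = et, n_risk = n_risk, n_event = n_event, survival = surv)
}

# fast log-rank core: g1 logical membership of group 1
.logrankCore <- function(time, event, g1) {
  agg <- rowsum(cbind(event, event & g1, 1, g1), time)  # sorted by time
  d <- agg[, 1]; d1 <- agg[, 2]; m <- agg[, 3]; m1 <- agg[, 4]
  n_at <- rev(cumsum(rev(m))); n1_at <- rev(cumsum(rev(m1)))
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]; n <- n_at[keep]; n1 <- n1_at[keep]
  E1 <- d * n1 / n
  Vt <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  O1 <- sum(d1); E <- sum(E1); V <- sum(Vt)
  chisq <- if (V > 0) (O1 - E)^2 / V else 0
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       obs1 = O1, exp1 = E, var = V)
}

#' Two-group log-rank test
#'
#' Compares survival between two groups via the hypergeometric
#' observed-minus-expected event sums over the distinct event times (ties
#' pooled): chi-square = (sum(O - E))^2 / sum(V) on 1 degree of freedom.
#'
#' @param time survival times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group two-level group label per sample.
#' @return list with `chisq`, `p`, and per-group observed/expected event
#'   counts (`observed`, `expected`, named by group level).
#' @examples
#' logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L)
    stopf("log-rank test requires exactly 2 non-empty groups (got %d)",
          length(lev))
  event <- as.integer(event)
  if (!any(event == 1L)) stopf("no events")
  res <- .logrankCore(time, event, as.character(group) == lev[1])
  O <- sum(event)
  list(chisq = res$chisq, p = res$p,
       observed = setNames(c(res$obs1, O - res$obs1), lev),
       expected = setNames(c(res$exp1, O - res$exp1), lev))
}

#' Combination grouping of per-miRNA high/low labels
#'
#' The combination group for a miRNA set is `high` for a sample iff *all*
#' member miRNAs are labelled high in that sample; every other sample forms
#' the comparator group.
#'
#' @param labels matrix or data.frame of `"high"`/`"low"` labels (samples in
#'   rows, member miRNAs in columns), or a single label vector.
#' @return character vector of `"high"`/`"low"` combination labels.
#' @export
comboGroup <- function(labels) {
  m <- as.matrix(labels)
  if (any(is.na(m))) stopf("missing label for a member miRNA")
  if (!all(m %in% c("high", "low")))
    stopf("labels must be 'high' or 'low'")
  out <- ifelse(rowSums(m == "high") == ncol(m), "high", "low")
  names(out) <- rownames(m)
  out
}

#' Bootstrap stability of log-rank significance
#'
#' Resamples patients with replacement `B` times (group labels travel with
#' the patients), recomputes the log-rank p-value for each replicate, and
#' counts replicates significant at `alpha`.  Replicates in which the
#' resample contains a single group or no events are redrawn (the redraw
#' count is reported).
#'
#' @param time,event,group the survival data and two-level group labels.
#' @param B number of bootstrap replicates.
#' @param alpha significance level counted within replicates.
#' @param seed integer RNG seed (bitwise-reproducible given the same input).
#' @return list with `B`, `n_significant`, `fraction`, `alpha`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrapStability <- function(time, event, group, B = 10000L, alpha = 0.05,
                               seed = 1L) {
  if (B < 1L) stopf("B must be >= 1")
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L) stopf("need exactly 2 groups")
  g1 <- as.character(group) == lev[1]
  event <- as.integer(event)
  n <- length(time)
  set.seed(as.integer(seed))
  n_sig <- 0L; n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      gb <- g1[idx]; eb <- event[idx]
      if (any(gb) && !all(gb) && any(eb == 1L)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * B)
        stopf("bootstrap: too many degenerate resamples")
    }
    if (.logrankCore(time[idx], eb, gb)$p < alpha) n_sig <- n_sig + 1L
  }
  list(B = as.integer(B), n_significant = n_sig, fraction = n_sig / B,
       alpha = alpha, seed = as.integer(seed), n_redrawn = n_redrawn)
}

#' Categorize clinical covariates for Cox modelling
#'
#' Encodes the raw clinical covariates with the conventional rules of this
#' screen: age is `high` when strictly greater than the cohort median;
#' sex is coded male = 1, female = 0 (female is the reference); a patient
#' is a smoker iff the smoking status is `current smoker` (any other or
#' unknown status counts as non-smoker); stage is `high` for stage III or
#' IV by Roman-numeral prefix (so `"Stage IIIA"` is high), low for I/II,
#' and `NA` when missing or recorded as unknown.
#'
#' @param clinical `data.frame` as from [readClinical()] (the cohort over
#'   which the age median is computed — normally the survival-eligible Sq
#'   records).
#' @return `data.frame` with `sample_id` and 0/1 columns `age_high`,
#'   `sex_male`, `smoker`, `stage_high` (`NA` where the raw value is
#'   missing), plus the age cut-off as an attribute.
#' @export
encodeCovariates <- function(clinical) {
  age_cut <- median(clinical$age, na.rm = TRUE)
  age_high <- ifelse(is.na(clinical$age), NA_integer_,
                     as.integer(clinical$age > age_cut))
  sex_male <- ifelse(is.na(clinical$sex), NA_integer_,
                     as.integer(clinical$sex == "male"))
  smoker <- as.integer(!is.na(clinical$smoking_status) &
                       tolower(clinical$smoking_status) == "current smoker")
  stage_high <- vapply(clinical$stage, function(s) {
    if (is.na(s) || !nzchar(s) || tolower(s) == "unknown") return(NA_integer_)
    core <- sub("^\\s*stage\\s*", "", tolower(s))
    m <- regmatches(core, regexpr("^(iv|iii|ii|i)", core))
    if (!length(m)) stopf("unparseable stage value '%s'", s)
    as.integer(m %in% c("iii", "iv"))
  }, integer(1), USE.NAMES = FALSE)
  out <- data.frame(sample_id = clinical$sample_id, age_high = age_high,
                    sex_male = sex_male, smoker = smoker,
                    stage_high = stage_high, stringsAsFactors = FALSE)
  attr(out, "age_cutoff") <- age_cut
  out
}

# one pass over the risk sets: partial log-likelihood, score, information
# (Efron tie correction), optionally Schoenfeld residuals at beta
.coxPass <- function(Xc, time, event, beta, schoenfeld = FALSE) {
  n <- nrow(Xc); p <- ncol(Xc)
  eta <- drop(Xc %*% beta)
  ord <- order(time, decreasing = TRUE)
  t_ <- time[ord]; e_ <- event[ord]
  Xo <- Xc[ord, , drop = FALSE]; eo <- eta[ord]; wo <- exp(eo)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  loglik <- 0; U <- numeric(p); I <- matrix(0, p, p)
  sres <- if (schoenfeld) matrix(NA_real_, sum(e_), p) else NULL
  stimes <- if (schoenfeld) numeric(sum(e_)) else NULL
  sk <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && t_[j] == t_[i]) j <- j + 1L
    idx <- i:(j - 1L)
    Xi <- Xo[idx, , drop = FALSE]; wi <- wo[idx]
    S0 <- S0 + sum(wi)
    S1 <- S1 + drop(crossprod(Xi, wi))
    S2 <- S2 + crossprod(Xi * sqrt(wi))
    didx <- idx[e_[idx] == 1L]
    d <- length(didx)
    if (d > 0L) {
      Xd <- Xo[didx, , drop = FALSE]; wd <- wo[didx]
      S0d <- sum(wd); S1d <- drop(crossprod(Xd, wd))
      S2d <- crossprod(Xd * sqrt(wd))
      loglik <- loglik + sum(eo[didx])
      U <- U + colSums(Xd)
      for (k in seq_len(d) - 1L) {
        f <- k / d
        den <- S0 - f * S0d
        xb <- (S1 - f * S1d) / den
        loglik <- loglik - log(den)
        U <- U - xb
        I <- I + (S2 - f * S2d) / den - tcrossprod(xb)
      }
      if (schoenfeld) {
        xbar0 <- S1 / S0
        for (k in seq_len(d)) {
          sk <- sk + 1L
          sres[sk, ] <- Xd[k, ] - xbar0
          stimes[sk] <- t_[i]
        }
      }
    }
    i <- j
  }
  list(loglik = loglik, U = U, I = I, sres = sres, stimes = stimes)
}

#' Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with the Efron
#' correction for tied event times.  Reports per-covariate log hazard
#' coefficients, hazard ratios with 95% Wald confidence intervals and Wald
#' p-values, plus the score test at the null (which for a single binary
#' covariate with untied event times equals the log-rank chi-square).
#' Monotone partial likelihoods (perfect separation) are flagged as
#' non-converged and no estimates are reported for them.
#'
#' @param X design matrix (samples in rows, covariates in columns; rows with
#'   missing values are dropped).
#' @param time,event the survival outcome.
#' @param max_iter,tol Newton-Raphson iteration cap and relative
#'   log-likelihood convergence tolerance.
#' @return object of class `coxFit`: a list with `coefficients`,
#'   `hazard_ratio`, `se`, `ci_lower`, `ci_upper`, `wald_p`, `loglik`
#'   (null, final), `score_chisq`, `score_p`, `converged`, `iterations`,
#'   `n`, `n_events`, and internals used by [phTest()].
#' @examples
#' set.seed(1)
#' x <- rbinom(60, 1, 0.5)
#' t <- rexp(60, 0.01 * exp(0.7 * x))
#' fit <- coxFit(cbind(group = x), pmin(t, 100), as.integer(t <= 100))
#' fit$hazard_ratio
#' @export
coxFit <- function(X, time, event, max_iter = 50L, tol = 1e-9) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- complete.cases(X) & is.finite(time) & !is.na(event)
  X <- X[ok, , drop = FALSE]
  time <- time[ok]; event <- as.integer(event[ok])
  n <- nrow(X); p <- ncol(X)
  if (any(apply(X, 2, function(v) max(v) == min(v))))
    stopf("constant covariate in the design matrix")
  if (sum(event) < p)
    stopf("fewer events (%d) than covariates (%d)", sum(event), p)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)

  beta <- numeric(p)
  pass0 <- .coxPass(Xc, time, event, beta)
  loglik0 <- pass0$loglik
  score_chisq <- tryCatch(
    drop(crossprod(pass0$U, solve(pass0$I, pass0$U))),
    error = function(e) NA_real_)
  converged <- FALSE
  pass <- pass0
  ll_old <- loglik0
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(pass$I, pass$U), error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + step
    pass_new <- .coxPass(Xc, time, event, beta_new)
    halvings <- 0L
    while ((!is.finite(pass_new$loglik) || pass_new$loglik < ll_old) &&
           halvings < 20L) {
      halvings <- halvings + 1L
      beta_new <- beta + (beta_new - beta) / 2
      pass_new <- .coxPass(Xc, time, event, beta_new)
    }
    beta <- beta_new; pass <- pass_new
    if (abs(pass$loglik - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- pass$loglik
  }
  if (max(abs(beta)) > 15) converged <- FALSE  # monotone likelihood

  if (converged) {
    vcov <- solve(pass$I)
    se <- sqrt(diag(vcov))
    z <- beta / se
    zq <- qnorm(0.975)
    pass_s <- .coxPass(Xc, time, event, beta, schoenfeld = TRUE)
    est <- list(
      coefficients = setNames(beta, colnames(X)),
      hazard_ratio = setNames(exp(beta), colnames(X)),
      se = setNames(se, colnames(X)),
      ci_lower = setNames(exp(beta - zq * se), colnames(X)),
      ci_upper = setNames(exp(beta + zq * se), colnames(X)),
      wald_p = setNames(2 * pnorm(-abs(z)), colnames(X)),
      vcov = vcov, imat = pass$I,
      sres = pass_s$sres, stimes = pass_s$stimes
    )
  } else {
    nac <- setNames(rep(NA_real_, p), colnames(X))
    est <- list(coefficients = nac, hazard_ratio = nac, se = nac,
                ci_lower = nac, ci_upper = nac, wald_p = nac,
                vcov = NULL, imat = pass$I, sres = NULL, stimes = NULL)
  }
  structure(c(est, list(
    loglik = c(null = loglik0, final = pass$loglik),
    score_chisq = score_chisq,
    score_p = pchisq(score_chisq, df = p, lower.tail = FALSE),
    converged = converged, iterations = iter,
    n = n, n_events = sum(event)
  )), class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit: n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (x$converged) "" else " (NOT CONVERGED)"))
  if (x$converged) {
    tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratio,
                      lower95 = x$ci_lower, upper95 = x$ci_upper,
                      p = x$wald_p)
    print(tab, digits = 4)
  }
  invisible(x)
}

#' Proportional hazards assumption test
#'
#' Per-covariate test of a zero slope of the scaled Schoenfeld residuals
#' against the rank of event time (chi-square, 1 df) — the standard
#' scaled-residual diagnostic for time-varying hazard ratios.
#'
#' @param fit a converged [coxFit()] object with >= 2 events.
#' @return `data.frame` with one row per covariate: `covariate`, `chisq`, `p`.
#' @export
phTest <- function(fit) {
  stopifnot(inherits(fit, "coxFit"))
  if (!fit$converged) stopf("phTest requires a converged model")
  d <- fit$n_events
  if (d < 2L) stopf("phTest requires at least 2 events")
  sres <- fit$sres
  g <- rank(fit$stimes, ties.method = "average")
  gt <- g - mean(g)
  varinv <- fit$vcov
  r2 <- sres %*% varinv * d  # scaled Schoenfeld residuals (constant offset drops)
  u <- drop(crossprod(gt, r2))
  chisq <- u^2 / (d * diag(varinv) * sum(gt^2))
  data.frame(covariate = names(fit$coefficients), chisq = unname(chisq),
             p = pchisq(unname(chisq), df = 1, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-miRNA prognostic screen
#'
#' For each candidate miRNA: dichotomizes expression at the median over the
#' survival-eligible Sq cohort, runs the log-rank test between the high and
#' low groups, and BH-adjusts the p-values across candidates.  A candidate
#' is selected when p < `logrank_p_max`, q < `logrank_q_max`, and the high
#' group has worse survival (more deaths than expected under the null) —
#' the direction check keeps the screen onco-specific.  Log-rank p-values
#' of the all-members-high combination group are then reported for every
#' non-empty subset of the selected set.
#'
#' @param cpm CPM matrix (mature accessions in rows, samples in columns).
#' @param clinical `data.frame` from [readClinical()]; only survival-eligible
#'   Sq records with positive survival times enter the screen.
#' @param candidates mature accessions to screen (the DEMI-passing set).
#' @param thresholds a [ScreenThresholds-class].
#' @param cutoff_rule passed to [dichotomize()].
#' @return list with `per_mirna` (accession, cutoff, group sizes, chisq, p,
#'   q, `worse_high`, `selected`), `combos` (subset, size, chisq, p),
#'   `selected` (accessions), `labels` (samples x selected high/low matrix),
#'   and `cohort` (sample_id, time, event used).
#' @export
survivalScreen <- function(cpm, clinical, candidates,
                           thresholds = screenThresholds(),
                           cutoff_rule = "median") {
  elig <- clinical$survival_eligible & clinical$histology == "Sq" &
    clinical$sample_id %in% colnames(cpm)
  drop0 <- elig & !is.na(clinical$os_time) & clinical$os_time <= 0
  if (any(drop0)) {
    warnf("%d survival-eligible samples with non-positive os_time dropped",
          sum(drop0))
    elig <- elig & !drop0
  }
  coh <- clinical[elig, , drop = FALSE]
  if (nrow(coh) < 2L) stopf("fewer than 2 survival-eligible Sq samples")
  time <- coh$os_time; event <- as.integer(coh$os_event)
  ids <- coh$sample_id
  candidates <- intersect(candidates, rownames(cpm))

  res <- data.frame(
    mature_accession = candidates, cutoff = NA_real_,
    n_high = NA_integer_, n_low = NA_integer_,
    chisq = NA_real_, p = NA_real_, q = NA_real_,
    worse_high = NA, selected = FALSE, stringsAsFactors = FALSE
  )
  labels <- matrix(NA_character_, nrow = length(ids),
                   ncol = length(candidates),
                   dimnames = list(ids, candidates))
  for (i in seq_along(candidates)) {
    vals <- cpm[candidates[i], ids]
    lab <- tryCatch(dichotomize(vals, cutoff_rule), error = function(e) NULL)
    if (is.null(lab)) {
      warnf("candidate %s skipped: degenerate split", candidates[i])
      next
    }
    labels[, i] <- lab
    lt <- logrankTest(time, event, lab)
    res$cutoff[i] <- attr(lab, "cutoff")
    res$n_high[i] <- sum(lab == "high"); res$n_low[i] <- sum(lab == "low")
    res$chisq[i] <- lt$chisq; res$p[i] <- lt$p
    res$worse_high[i] <- lt$observed["high"] > lt$expected["high"]
  }
  tested <- !is.na(res$p)
  if (any(tested)) res$q[tested] <- bhAdjust(res$p[tested])
  res$selected <- tested & res$p < thresholds@logrank_p_max &
    res$q < thresholds@logrank_q_max & res$worse_high %in% TRUE
  selected <- res$mature_accession[res$selected]

  combos <- data.frame(subset = character(), size = integer(),
                       n_high = integer(), chisq = numeric(), p = numeric(),
                       stringsAsFactors = FALSE)
  if (length(selected) >= 1L && length(selected) <= 10L) {
    for (k in seq_along(selected)) {
      for (sub in utils::combn(selected, k, simplify = FALSE)) {
        lab <- comboGroup(labels[, sub, drop = FALSE])
        row <- data.frame(subset = paste(sub, collapse = ","),
                          size = k, n_high = sum(lab == "high"),
                          chisq = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE)
        if (length(unique(lab)) == 2L) {
          lt <- logrankTest(time, event, lab)
          row$chisq <- lt$chisq; row$p <- lt$p
        }
        combos <- rbind(combos, row)
      }
    }
  } else if (length(selected) > 10L) {
    warnf("%d selected miRNAs: subset enumeration skipped", length(selected))
  }
  list(per_mirna = res, combos = combos, selected = selected,
       labels = labels[, selected, drop = FALSE],
       cohort = data.frame(sample_id = ids, time = time, event = event,
                           stringsAsFactors = FALSE))
}

#' Cohort summary table
#'
#' Per-histology clinical characteristics in the conventional Table-1
#' layout: sample count, age range/mean/sd, and counts with
#' integer-rounded percentages (half away from zero) for sex, smoking
#' status (smoker / nonsmoker / unknown) and stage group (I-IV / Unknown).
#'
#' @param clinical `data.frame` from [readClinical()].
#' @return list with elements `n` (named vector), `age`, `sex`, `smoking`,
#'   `stage` (long `data.frame`s with `histology`, `level`, `count`,
#'   `percent`).
#' @export
cohortSummary <- function(clinical) {
  hists <- c("Ad", "Sq", "Normal")
  smok_class <- function(s) {
    s <- tolower(ifelse(is.na(s), "", s))
    ifelse(s == "" | s == "unknown", "unknown",
           ifelse(grepl("^(non|never)", s), "nonsmoker", "smoker"))
  }
  stage_class <- function(s) {
    vapply(s, function(v) {
      if (is.na(v) || !nzchar(v) || tolower(v) == "unknown") return("Unknown")
      core <- sub("^\\s*stage\\s*", "", tolower(v))
      m <- regmatches(core, regexpr("^(iv|iii|ii|i)", core))
      if (!length(m)) "Unknown" else toupper(m)
    }, character(1), USE.NAMES = FALSE)
  }
  cat_table <- function(values, levels_) {
    out <- list()
    for (h in hists) {
      v <- values[clinical$histology == h]
      n <- length(v)
      cnt <- vapply(levels_, function(l) sum(v == l, na.rm = TRUE), integer(1))
      pct <- if (n > 0) roundHalfUp(100 * cnt / n) else rep(0, length(levels_))
      out[[h]] <- data.frame(histology = h, level = levels_,
                             count = unname(cnt), percent = unname(pct),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
  n <- vapply(hists, function(h) sum(clinical$histology == h), integer(1))
  age <- do.call(rbind, lapply(hists, function(h) {
    a <- clinical$age[clinical$histology == h]
    a <- a[!is.na(a)]
    data.frame(histology = h, n = length(a),
               min = if (length(a)) min(a) else NA_real_,
               max = if (length(a)) max(a) else NA_real_,
               mean = if (length(a)) mean(a) else NA_real_,
               sd = if (length(a) > 1) sd(a) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(
    n = n,
    age = age,
    sex = cat_table(clinical$sex, c("male", "female")),
    smoking = cat_table(smok_class(clinical$smoking_status),
                        c("smoker", "nonsmoker", "unknown")),
    stage = cat_table(stage_class(clinical$stage),
                      c("I", "II", "III", "IV", "Unknown"))
  )
}
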
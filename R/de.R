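#' CPM normalization
#'
#' Normalizes read counts to counts per million mapped reads:
#' `cpm(s, m) = count(s, m) / total_mapped_reads(s) * 1e6`.  The per-sample
#' totals are taken from the `colData` of a
#' [SummarizedExperiment::SummarizedExperiment] (as produced by
#' [aggregateMatureCounts()]) or supplied directly for a plain matrix.
#' When the totals equal the column sums (no fragments were excluded), each
#' sample's CPM column sums to exactly 1e6.
#'
#' @param counts count matrix (features in rows) or a
#'   `SummarizedExperiment` with a `counts` assay and a
#'   `total_mapped_reads` column in `colData`.
#' @param total_mapped_reads per-sample totals (ignored for a
#'   `SummarizedExperiment`); must be positive.
#' @return numeric CPM matrix with the same dimnames, or the input
#'   `SummarizedExperiment` with an added `cpm` assay.
#' @export
setGeneric("cpmNormalize", function(counts, total_mapped_reads) {
  standardGeneric("cpmNormalize")
})

#' @rdname cpmNormalize
#' @export
setMethod("cpmNormalize", "matrix", function(counts, total_mapped_reads) {
  if (length(total_mapped_reads) != ncol(counts))
    stopf("need one total per sample (%d totals, %d samples)",
          length(total_mapped_reads), ncol(counts))
  zero <- which(!(total_mapped_reads > 0))
  if (length(zero)) {
    nm <- colnames(counts)[zero[1]]
    stopf("sample '%s' has non-positive total mapped reads",
          if (is.null(nm)) as.character(zero[1]) else nm)
  }
  sweep(counts, 2, total_mapped_reads, "/") * 1e6
})

#' @rdname cpmNormalize
#' @export
setMethod("cpmNormalize", "SummarizedExperiment",
  function(counts, total_mapped_reads) {
    se <- counts
    totals <- colData(se)$total_mapped_reads
    if (is.null(totals))
      stopf("SummarizedExperiment lacks colData$total_mapped_reads")
    assay(se, "cpm") <- cpmNormalize(assay(se, "counts"), totals)
    se
  })

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U test with midrank tie handling, normal
#' approximation with tie-corrected variance, and continuity correction —
#' the standard large-sample form for comparing expression between two
#' histology groups.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `statistic` (U of `x`) and `p`.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q(i) = min over j >= i of p(j) * n / j`
#' on the sorted p-values, clamped to at most 1, returned in input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, elementwise >= the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Squamous-specific differential expression filter (DEMI)
#'
#' For each candidate miRNA, compares CPM expression in Sq against Ad and
#' against Normal.  The log2 fold change uses arithmetic group means with a
#' pseudocount: `log2((mean_Sq + c) / (mean_other + c))`; p-values come from
#' the Wilcoxon rank-sum test and are BH-adjusted within each comparison
#' across the candidate set.  A candidate passes when log2FC > 0 and
#' q < `q_max` in *both* comparisons (strict inequalities).
#'
#' @param cpm CPM matrix, mature accessions in rows, samples in columns.
#' @param groups histology label (`Sq`, `Ad`, `Normal`) per sample, named by
#'   sample id or aligned with `colnames(cpm)`.
#' @param candidates mature accessions to test (the CNV-correlated set).
#' @param thresholds a [ScreenThresholds-class].
#' @param pseudocount CPM pseudocount `c` used in the fold-change means.
#' @return `data.frame` with one row per candidate: log2FC, raw p and BH q
#'   for each comparison, and `passes`.
#' @export
demiFilter <- function(cpm, groups, candidates,
                       thresholds = screenThresholds(), pseudocount = 1) {
  if (!is.null(names(groups))) {
    groups <- groups[colnames(cpm)]
  } else if (length(groups) != ncol(cpm)) {
    stopf("groups must be named by sample or aligned with cpm columns")
  }
  for (g in c("Sq", "Ad", "Normal"))
    if (!any(groups == g, na.rm = TRUE))
      stopf("histology group '%s' absent", g)
  candidates <- intersect(candidates, rownames(cpm))
  if (!length(candidates)) stopf("no candidates present in the CPM matrix")
  sq <- which(groups == "Sq"); ad <- which(groups == "Ad")
  nrm <- which(groups == "Normal")
  one <- function(acc, other_idx) {
    v <- cpm[acc, ]
    lfc <- log2((mean(v[sq]) + pseudocount) / (mean(v[other_idx]) + pseudocount))
    w <- wilcoxonRankSum(v[sq], v[other_idx])
    c(lfc = lfc, p = w$p)
  }
  sq_ad <- t(vapply(candidates, one, numeric(2), other_idx = ad))
  sq_n <- t(vapply(candidates, one, numeric(2), other_idx = nrm))
  q_sq_ad <- bhAdjust(sq_ad[, "p"])
  q_sq_n <- bhAdjust(sq_n[, "p"])
  passes <- sq_ad[, "lfc"] > 0 & q_sq_ad < thresholds@q_max &
    sq_n[, "lfc"] > 0 & q_sq_n < thresholds@q_max
  data.frame(
    mature_accession = candidates,
    log2fc_sq_ad = sq_ad[, "lfc"], p_sq_ad = sq_ad[, "p"], q_sq_ad = q_sq_ad,
    log2fc_sq_n = sq_n[, "lfc"], p_sq_n = sq_n[, "p"], q_sq_n = q_sq_n,
    passes = unname(passes),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
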
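#' ROC curve and AUC for a single marker
#'
#' Sweeps thresholds over the distinct score values and reports the ROC
#' curve (false-positive rate, true-positive rate) from (0, 0) to (1, 1)
#' together with the AUC computed as the Mann-Whitney probability
#' U / (n1 * n2), with tied score pairs contributing 1/2.  Because tied
#' scores are grouped into single sweep steps, the trapezoidal area under
#' the returned curve equals the U-based AUC.
#'
#' @param scores numeric marker values (here: CPM expression).
#' @param labels group label per sample (two classes required).
#' @param positive the label treated as positive (default `"Sq"` if
#'   present, otherwise the first level).
#' @return object of class `rocResult`: list with `auc`, `curve`
#'   (`data.frame` of `fpr`, `tpr`), `positive_label`, `n_positive`,
#'   `n_negative`.
#' @examples
#' rocAuc(c(3, 5, 1, 4), c("Sq", "Sq", "Normal", "Normal"))
#' @export
rocAuc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stopf("ROC requires exactly 2 classes (got %d)", length(lev))
  if (is.null(positive)) positive <- if ("Sq" %in% lev) "Sq" else lev[1]
  if (!positive %in% lev) stopf("positive label '%s' not present", positive)
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)

  r <- rank(scores)  # midranks
  U <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)

  # threshold sweep, descending scores, ties grouped
  ord <- order(scores, decreasing = TRUE)
  ps <- pos[ord]; ss <- scores[ord]
  step_end <- c(which(diff(ss) != 0), length(ss))
  tp <- cumsum(ps)[step_end]
  fp <- cumsum(!ps)[step_end]
  curve <- data.frame(fpr = c(0, fp / n2), tpr = c(0, tp / n1))

  structure(list(auc = auc, curve = curve, positive_label = positive,
                 n_positive = n1, n_negative = n2),
            class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: positive = %s (n = %d vs %d), AUC = %.4f\n",
              x$positive_label, x$n_positive, x$n_negative, x$auc))
  invisible(x)
}

#' Per-miRNA AUC tables for histology discrimination
#'
#' Computes the AUC of each candidate miRNA's CPM expression for separating
#' Sq from Normal and Sq from Ad samples (Sq is the positive class).
#'
#' @param cpm CPM matrix (mature accessions in rows, samples in columns).
#' @param groups histology label per sample (named or aligned with columns).
#' @param candidates mature accessions to evaluate.
#' @return `data.frame` with `mature_accession`, `auc_sq_vs_normal`,
#'   `auc_sq_vs_ad`.
#' @export
aucTable <- function(cpm, groups, candidates) {
  if (!is.null(names(groups))) groups <- groups[colnames(cpm)]
  candidates <- intersect(candidates, rownames(cpm))
  one <- function(acc, other) {
    idx <- groups %in% c("Sq", other)
    rocAuc(cpm[acc, idx], groups[idx], positive = "Sq")$auc
  }
  data.frame(
    mature_accession = candidates,
    auc_sq_vs_normal = vapply(candidates, one, numeric(1), other = "Normal"),
    auc_sq_vs_ad = vapply(candidates, one, numeric(1), other = "Ad"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
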
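#' Assign segment-mean copy ratios to miRNA precursor loci
#'
#' For every (sample, precursor locus) pair, computes the length-weighted
#' mean of the segment-mean values (log2 copy ratio, log2(CN/2)) of all
#' segments overlapping the precursor interval, with overlap measured in
#' bases on 1-based inclusive coordinates.  A locus with no overlapping
#' segment in a sample (including loci on chromosomes absent from that
#' sample's segmentation) gets `NA`.  The weighted mean always lies within
#' the range of the overlapping segment means, so a locus fully contained
#' in one segment inherits that segment's value unchanged.
#'
#' @param segments `GRanges` of per-sample segments ([readSegments()]).
#' @param annotation `GRanges` of (precursor, mature) records
#'   ([readMirnaAnnotation()]); the precursor interval columns are used.
#' @return numeric matrix of copy ratios, precursor accessions in rows and
#'   sample identifiers in columns (`NA` where no segment overlaps).
#' @export
assignSegmentMeans <- function(segments, annotation) {
  md <- mcols(annotation)
  keep <- !duplicated(md$precursor_accession)
  prec <- GRanges(
    seqnames = as.character(seqnames(annotation))[keep],
    ranges = IRanges(md$precursor_start[keep], md$precursor_end[keep])
  )
  prec_acc <- md$precursor_accession[keep]
  samples <- sort(unique(mcols(segments)$sample_id))
  out <- matrix(NA_real_, nrow = length(prec), ncol = length(samples),
                dimnames = list(prec_acc, samples))
  hits <- findOverlaps(prec, segments, ignore.strand = TRUE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- width(pintersect(prec[qi], segments[si], ignore.strand = TRUE))
    sm <- mcols(segments)$segment_mean[si]
    samp <- mcols(segments)$sample_id[si]
    g <- paste(qi, samp, sep = "\r")
    num <- rowsum(w * sm, g)
    den <- rowsum(w, g)
    parts <- strsplit(rownames(num), "\r", fixed = TRUE)
    ridx <- as.integer(vapply(parts, `[`, "", 1L))
    cidx <- match(vapply(parts, `[`, "", 2L), samples)
    out[cbind(ridx, cidx)] <- num[, 1] / den[, 1]
  }
  out
}

#' Aggregate isoform read counts to mature miRNAs
#'
#' Keeps only fragments annotated as mature arms (fragments classified
#' `precursor`, `stemloop` or `unannotated` are excluded), and sums read
#' counts per (sample, MIMAT accession) across all isoforms and precursor
#' loci — the expression of a mature miRNA is the sum of the expression of
#' its isoforms in distinct genomic loci.  Mature miRNAs whose miRBase
#' status is `dead` or `disputed`, or whose every annotated locus lies on
#' chromosome X or Y, are then dropped.  Per-sample totals
#' (`total_mapped_reads`) are the sums over all mature-region fragments
#' *before* these exclusions, so CPM normalization is relative to the full
#' mature miRNome of the sample.
#'
#' @param isoforms `data.frame` from [readIsoformCounts()].
#' @param annotation `GRanges` from [readMirnaAnnotation()].
#' @param sample_manifest optional character vector of expected sample ids;
#'   samples present in `isoforms` but absent from the manifest trigger a
#'   warning and are retained.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (mature accessions in rows, samples in columns), per-sample
#'   `total_mapped_reads` in `colData`, and mature/precursor identity in
#'   `rowData`.
#' @export
aggregateMatureCounts <- function(isoforms, annotation, sample_manifest = NULL) {
  mat <- isoforms[isoforms$region_type == "mature", , drop = FALSE]
  if (!nrow(mat)) stopf("no mature-region isoform records")
  if (!is.null(sample_manifest)) {
    extra <- setdiff(unique(mat$sample_id), sample_manifest)
    if (length(extra))
      warnf("%d samples present in isoform data but absent from the manifest (e.g. '%s'); retained",
            length(extra), extra[1])
  }
  samples <- sort(unique(mat$sample_id))
  totals <- rowsum(as.numeric(mat$read_count), mat$sample_id)
  totals <- setNames(totals[, 1], rownames(totals))[samples]

  md <- mcols(annotation)
  alive <- md$status == "alive"
  autosomal <- !as.character(seqnames(annotation)) %in% c("X", "Y")
  eligible <- unique(md$mature_accession[alive & autosomal])
  # a mature arm is dropped when *no* alive autosomal locus remains
  keep <- mat$mature_accession %in% eligible
  mat <- mat[keep, , drop = FALSE]

  accs <- sort(unique(mat$mature_accession))
  counts <- matrix(0, nrow = length(accs), ncol = length(samples),
                   dimnames = list(accs, samples))
  agg <- rowsum(as.numeric(mat$read_count),
                paste(mat$mature_accession, mat$sample_id, sep = "\r"))
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  ridx <- match(vapply(parts, `[`, "", 1L), accs)
  cidx <- match(vapply(parts, `[`, "", 2L), samples)
  counts[cbind(ridx, cidx)] <- agg[, 1]

  j <- match(accs, md$mature_accession)
  SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(sample_id = samples, total_mapped_reads = totals,
                        row.names = samples),
    rowData = DataFrame(mature_accession = accs,
                        mature_name = md$mature_name[j],
                        row.names = accs)
  )
}

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson correlation r = cov(x, y) / (sd(x) sd(y)) with the
#' two-sided p-value from t = r sqrt(n-2) / sqrt(1-r^2) on n-2 degrees of
#' freedom.  Incomplete pairs (NA in either vector) are dropped first.
#' A p-value that underflows to zero (perfect correlation) is reported as
#' the smallest representable positive double.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, and `n` (complete pairs used).
#' @examples
#' pearsonCorrelation(1:10, (1:10) + rnorm(10))
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("insufficient data: %d complete pairs (need >= 3)", n)
  if (var(x) == 0 || var(y) == 0)
    stopf("undefined correlation: constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = max(ct$p.value, .Machine$double.xmin),
       n = n)
}

#' Genome-wide CNV-expression correlation screen
#'
#' For every (mature miRNA, precursor locus) pair, correlates the miRNA's
#' CPM expression with the copy ratio assigned to the locus across the
#' samples shared by both matrices (pairs with missing copy ratios use
#' pairwise-complete samples).  A pair passes when r > `r_min` and
#' p < `p_max` (strict inequalities); a mature miRNA is called
#' CNV-correlated when at least one of its precursor loci passes.  Pairs
#' whose data are constant or have fewer than 3 complete samples are
#' reported with `NA` statistics and do not pass.
#'
#' @param cpm numeric CPM matrix, mature accessions in rows, samples in
#'   columns (see [cpmNormalize()]).
#' @param cnv copy-ratio matrix from [assignSegmentMeans()].
#' @param annotation `GRanges` from [readMirnaAnnotation()].
#' @param thresholds a [ScreenThresholds-class] object.
#' @return `data.frame` with one row per (mature, precursor) pair:
#'   `mature_accession`, `precursor_accession`, `n_samples`, `r`, `p`,
#'   `passes`.  Use [cnvCorrelatedMirnas()] for the passing mature set.
#' @export
correlationScreen <- function(cpm, cnv, annotation,
                              thresholds = screenThresholds()) {
  shared <- intersect(colnames(cpm), colnames(cnv))
  if (length(shared) < 3L)
    stopf("correlationScreen: %d shared samples between expression and CNV (need >= 3)",
          length(shared))
  md <- mcols(annotation)
  pairs <- unique(data.frame(mature_accession = md$mature_accession,
                             precursor_accession = md$precursor_accession,
                             stringsAsFactors = FALSE))
  pairs <- pairs[pairs$mature_accession %in% rownames(cpm) &
                 pairs$precursor_accession %in% rownames(cnv), , drop = FALSE]
  n_samples <- integer(nrow(pairs))
  r <- p <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    y <- cpm[pairs$mature_accession[i], shared]
    x <- cnv[pairs$precursor_accession[i], shared]
    res <- tryCatch(pearsonCorrelation(x, y), error = function(e) NULL)
    if (!is.null(res)) {
      r[i] <- res$r; p[i] <- res$p; n_samples[i] <- res$n
    } else {
      n_samples[i] <- sum(is.finite(x) & is.finite(y))
    }
  }
  passes <- !is.na(r) & r > thresholds@r_min & p < thresholds@p_max
  data.frame(pairs, n_samples = n_samples, r = r, p = p, passes = passes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname correlationScreen
#' @param results the per-pair table returned by `correlationScreen()`.
#' @return `cnvCorrelatedMirnas()` returns the sorted character vector of
#'   mature accessions with at least one passing locus.
#' @export
cnvCorrelatedMirnas <- function(results) {
  sort(unique(results$mature_accession[results$passes]))
}
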
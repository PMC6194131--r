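# fixture builders shared across test files (all data generated in code)

write_seg_file <- function(lines, path = tempfile(fileext = ".seg.txt")) {
  header <- "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean"
  writeLines(c(header, lines), path)
  path
}

# minimal miRBase-dialect GFF3: one precursor with two mature arms plus an
# extra precursor/arm pair on chromosome X
write_gff_fixture <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr17\t.\tmiRNA_primary_transcript\t1000\t1083\t.\t+\t.\tID=MI0000100;Name=fix-mir-100",
    "chrX\t.\tmiRNA_primary_transcript\t5000\t5083\t.\t-\t.\tID=MI0000200;Name=fix-mir-200",
    "chr17\t.\tmiRNA\t1010\t1031\t.\t+\t.\tID=MIMAT0000101;Name=fix-miR-100-5p;Derives_from=MI0000100",
    "chr17\t.\tmiRNA\t1050\t1071\t.\t+\t.\tID=MIMAT0000102;Name=fix-miR-100-3p;Derives_from=MI0000100",
    "chrX\t.\tmiRNA\t5010\t5031\t.\t-\t.\tID=MIMAT0000201;Name=fix-miR-200-5p;Derives_from=MI0000200"
  ), path)
  path
}

# in-memory annotation builder: n precursors on given chromosomes
make_annotation <- function(chrom, start = seq_along(chrom) * 10000L,
                            status = "alive") {
  n <- length(chrom)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start + 30L, start + 51L), strand = "+",
    mature_accession = sprintf("MIMAT%07d", seq_len(n)),
    mature_name = sprintf("t-miR-%d", seq_len(n)),
    precursor_accession = sprintf("MI%07d", seq_len(n)),
    precursor_name = sprintf("t-mir-%d", seq_len(n)),
    precursor_start = start, precursor_end = start + 83L,
    status = rep_len(status, n)
  )
}

write_isoform_file <- function(rows, path = tempfile(fileext = ".txt")) {
  header <- "sample_id\tmiRNA_ID\tisoform_coords\tread_count\tmiRNA_region"
  writeLines(c(header, rows), path)
  path
}

write_clinical_file <- function(rows, path = tempfile(fileext = ".tsv"),
                                header = "sample_id\thistology\tos_time\tos_event\tage\tsex\tsmoking_status\tstage") {
  writeLines(c(header, rows), path)
  path
}

# clinical data.frame builder (already-parsed form)
make_clinical <- function(n, histology = "Sq", os_time = NULL,
                          os_event = NULL, age = 65, sex = "male",
                          smoking = "current smoker", stage = "Stage I") {
  data.frame(
    sample_id = sprintf("%s-%03d", toupper(histology), seq_len(n)),
    histology = histology,
    os_time = if (is.null(os_time)) rep(NA_real_, n) else os_time,
    os_event = if (is.null(os_event)) rep(NA_integer_, n) else os_event,
    age = rep_len(age, n), sex = rep_len(sex, n),
    smoking_status = rep_len(smoking, n), stage = rep_len(stage, n),
    survival_eligible = !is.null(os_time),
    stringsAsFactors = FALSE
  )
}

# brute-force BH step-up oracle: q(i) = min_{j: p(j) >= p(i)} p(j) * n / rank(j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- ps[i:n] * n / (i:n)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force Pearson r via sums of products, p via the t distribution
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# construct y with an exact sample correlation r against x
make_exact_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(x))
  es <- scale(residuals(lm(z ~ x)))[, 1]  # unit-sd, orthogonal to x
  xs <- scale(x)[, 1]
  as.numeric(r * xs + sqrt(1 - r^2) * es)
}

# reduced cohort for fast end-to-end tests; large enough that the extreme
# differential q cut-off (1e-10) remains attainable by the rank test
small_config <- function(seed, ...) {
  generatorConfig(seed = seed, n_sq = 120, n_ad = 100, n_normal = 50,
                  n_onco = 2, n_cnv_only = 4, n_sq_up_only = 4, n_null = 40,
                  ...)
}
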
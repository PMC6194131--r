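test_that("segment means are assigned by length-weighted overlap", {
  ann <- GenomicRanges::GRanges(
    seqnames = c("1", "1", "9"),
    ranges = IRanges::IRanges(c(150, 150, 100), c(250, 250, 200)),
    strand = "+",
    mature_accession = c("MIMATA", "MIMATB", "MIMATC"),
    mature_name = c("a", "b", "c"),
    precursor_accession = c("MIA", "MIB", "MIC"),
    precursor_name = c("a", "b", "c"),
    precursor_start = c(150L, 150L, 100L),
    precursor_end = c(250L, 250L, 200L),
    status = "alive"
  )
  segs <- GenomicRanges::GRanges(
    seqnames = c("1", "1", "1"),
    ranges = IRanges::IRanges(c(100, 1, 201), c(400, 200, 400)),
    sample_id = c("S1", "S2", "S2"),
    num_probes = NA_integer_,
    segment_mean = c(0.5, 0.5, -0.1)
  )
  # restrict to one precursor each to isolate the two scenarios
  cnv <- assignSegmentMeans(segs, ann)
  # locus fully inside a single segment inherits its mean
  expect_equal(cnv["MIA", "S1"], 0.5)
  # split across two segments: 51 bp at 0.5 and 50 bp at -0.1
  expect_equal(cnv["MIA", "S2"], (51 * 0.5 + 50 * (-0.1)) / 101,
               tolerance = 1e-12)
  # chromosome with no segments for the sample: absent, not an error
  expect_true(is.na(cnv["MIC", "S1"]))
  expect_true(is.na(cnv["MIC", "S2"]))
})

test_that("assigned value always lies within the overlapping segment means", {
  set.seed(101)
  for (rep in 1:20) {
    breaks <- sort(sample(2000:9000, 4))
    means <- rnorm(5)
    segs <- GenomicRanges::GRanges(
      seqnames = "5",
      ranges = IRanges::IRanges(c(1, breaks + 1), c(breaks, 10000)),
      sample_id = "S1", num_probes = NA_integer_, segment_mean = means
    )
    st <- sample(1500:8000, 1)
    ann <- make_annotation("5", start = st)
    # widen the locus so it can straddle several segments
    S4Vectors::mcols(ann)$precursor_end <- st + sample(50:3000, 1)
    v <- assignSegmentMeans(segs, ann)[1, "S1"]
    ovl <- which(GenomicRanges::start(segs) <= S4Vectors::mcols(ann)$precursor_end &
                 GenomicRanges::end(segs) >= S4Vectors::mcols(ann)$precursor_start)
    expect_gte(v, min(means[ovl]) - 1e-9)
    expect_lte(v, max(means[ovl]) + 1e-9)
  }
})

test_that("mature aggregation sums isoforms and applies the exclusions", {
  ann <- make_annotation(c("7", "X", "3"))
  md <- S4Vectors::mcols(ann)
  iso <- data.frame(
    sample_id = c("S1", "S1", "S1", "S1", "S1", "S2"),
    precursor_name = "p",
    chromosome = "7", start = 1L, end = 22L, strand = "+",
    read_count = c(10L, 15L, 500L, 40L, 7L, 30L),
    region_type = c("mature", "mature", "stemloop", "mature", "mature",
                    "mature"),
    mature_accession = c(md$mature_accession[1], md$mature_accession[1],
                         NA, md$mature_accession[2], md$mature_accession[3],
                         md$mature_accession[1]),
    stringsAsFactors = FALSE
  )
  se <- aggregateMatureCounts(iso, ann)
  counts <- SummarizedExperiment::assay(se, "counts")
  # isoforms of one mature arm are summed (two loci, 10 + 15)
  expect_equal(counts[md$mature_accession[1], "S1"], 25)
  # stemloop fragments contribute nothing
  expect_false(md$mature_accession[2] %in% rownames(counts))  # chrX excluded
  expect_equal(counts[md$mature_accession[3], "S1"], 7)
  # totals include the chrX mature fragments (pre-exclusion totals)
  expect_equal(SummarizedExperiment::colData(se)$total_mapped_reads[["S1"]],
               10 + 15 + 40 + 7)
  # read conservation on the retained set
  keep <- iso$region_type == "mature" & iso$mature_accession %in% rownames(counts)
  expect_identical(sum(counts), as.numeric(sum(iso$read_count[keep])))
})

test_that("dead/disputed mature miRNAs are excluded", {
  ann <- make_annotation(c("7", "8"), status = c("alive", "dead"))
  md <- S4Vectors::mcols(ann)
  iso <- data.frame(
    sample_id = "S1", precursor_name = "p", chromosome = "7",
    start = 1L, end = 22L, strand = "+", read_count = c(5L, 9L),
    region_type = "mature",
    mature_accession = md$mature_accession, stringsAsFactors = FALSE
  )
  se <- aggregateMatureCounts(iso, ann)
  expect_identical(rownames(se), md$mature_accession[1])
  expect_equal(SummarizedExperiment::colData(se)$total_mapped_reads[["S1"]],
               14)
})

test_that("pearsonCorrelation matches a brute-force oracle", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    got <- pearsonCorrelation(x, y)
    exp_ <- pearson_oracle(x, y)
    expect_equal(got$r, exp_$r, tolerance = 1e-12)
    expect_equal(got$p, exp_$p, tolerance = 1e-12)
  }
  # perfect linearity: r = 1 with the underflowed p clamped positive
  got <- pearsonCorrelation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(got$r, 1)
  expect_gt(got$p, 0)
  # defined error cases
  expect_error(pearsonCorrelation(1:5, rep(2, 5)), "constant")
  expect_error(pearsonCorrelation(1:2, 1:2), "insufficient")
})

test_that("correlation screen applies strict thresholds per locus", {
  set.seed(12)
  x <- rnorm(20)
  ann <- make_annotation(c("1", "2"))
  md <- S4Vectors::mcols(ann)
  cnv <- rbind(x, x)
  rownames(cnv) <- md$precursor_accession
  colnames(cnv) <- sprintf("S%02d", 1:20)
  cpm <- rbind(make_exact_cor(x, 0.6, seed = 2),
               make_exact_cor(x, 0.2, seed = 3))
  rownames(cpm) <- md$mature_accession
  colnames(cpm) <- colnames(cnv)
  res <- correlationScreen(cpm, cnv, ann)
  r1 <- res[res$mature_accession == md$mature_accession[1], ]
  r2 <- res[res$mature_accession == md$mature_accession[2], ]
  expect_equal(r2$r, 0.2, tolerance = 1e-10)
  expect_true(r1$passes)       # r = 0.6, p = 0.0052
  expect_false(r2$passes)      # r = 0.2 exactly: strict inequality fails
  expect_identical(cnvCorrelatedMirnas(res), md$mature_accession[1])
})

test_that("correlation is invariant to sample order and positive scaling", {
  set.seed(13)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  base <- pearsonCorrelation(x, y)
  perm <- sample(30)
  expect_equal(pearsonCorrelation(x[perm], y[perm])$r, base$r,
               tolerance = 1e-12)
  expect_equal(pearsonCorrelation(x, 3.7 * y + 2)$r, base$r,
               tolerance = 1e-12)
  expect_equal(pearsonCorrelation(x, -y)$r, -base$r, tolerance = 1e-12)
})

test_that("the joint pass rule keeps the null false-positive rate below 5%", {
  set.seed(14)
  thr <- screenThresholds()
  n <- 500
  fp <- 0L
  for (i in 1:200) {
    x <- ifelse(rbinom(n, 1, 0.5) == 1, rnorm(n, 0.32, 0.1), rnorm(n, 0, 0.05))
    y <- rnorm(n, 5, 0.5)  # expression independent of copy ratio
    res <- pearsonCorrelation(x, y)
    if (res$r > thr@r_min && res$p < thr@p_max) fp <- fp + 1L
  }
  expect_lt(fp / 200, 0.05)
})
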
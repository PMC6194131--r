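#' Read a SEG-style copy-number segment table
#'
#' Parses a tab-delimited segmentation file in the TCGA SNP-array dialect
#' (`*hg19.seg.txt`): one row per segment with a sample identifier,
#' chromosome, 1-based inclusive start/end, optional probe count, and the
#' segment-mean value, i.e. the log2 copy ratio log2(CN/2) (0 = diploid,
#' positive = gain).  Chromosome labels are normalized by stripping any
#' `chr` prefix.  Segments of one sample on one chromosome must not overlap.
#'
#' @param path path to the tab-delimited file (with header).
#' @param column_map named character vector mapping the internal field names
#'   `sample_id`, `chromosome`, `start`, `end`, `num_probes`, `segment_mean`
#'   to the file's column headers.  `num_probes` is optional.
#' @return a `GRanges` (1-based inclusive) with metadata columns
#'   `sample_id`, `num_probes`, `segment_mean`.
#' @examples
#' f <- tempfile(fileext = ".seg.txt")
#' writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
#'              "S1\tchr17\t100\t5000\t20\t0.31"), f)
#' readSegments(f)
#' @export
readSegments <- function(path,
                         column_map = c(sample_id = "Sample",
                                        chromosome = "Chromosome",
                                        start = "Start", end = "End",
                                        num_probes = "Num_Probes",
                                        segment_mean = "Segment_Mean")) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              data.table = TRUE, showProgress = FALSE)
  required <- c("sample_id", "chromosome", "start", "end", "segment_mean")
  for (field in required) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(dt))
      stopf("segment file %s: missing required column '%s' (field %s)",
            path, if (is.null(col)) "<unmapped>" else col, field)
  }
  n <- nrow(dt)
  sample_id <- dt[[column_map[["sample_id"]]]]
  chrom <- normalizeChromosome(dt[[column_map[["chromosome"]]]])
  bad <- which(!chrom %in% .validChromosomes)
  if (length(bad))
    stopf("segment file %s: invalid chromosome label '%s' on line %d",
          path, dt[[column_map[["chromosome"]]]][bad[1]], bad[1] + 1L)
  numify <- function(field, integerish = FALSE) {
    raw <- dt[[column_map[[field]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad))
      stopf("segment file %s: non-numeric %s '%s' on line %d",
            path, field, raw[bad[1]], bad[1] + 1L)
    if (integerish) as.integer(round(val)) else val
  }
  start <- numify("start", TRUE)
  end <- numify("end", TRUE)
  segmean <- numify("segment_mean")
  if (!all(is.finite(segmean)))
    stopf("segment file %s: non-finite segment_mean", path)
  bad <- which(start > end)
  if (length(bad))
    stopf("segment file %s: start > end on line %d", path, bad[1] + 1L)
  num_probes <- if (!is.na(column_map["num_probes"]) &&
                    column_map[["num_probes"]] %in% names(dt)) {
    suppressWarnings(as.integer(dt[[column_map[["num_probes"]]]]))
  } else rep(NA_integer_, n)

  # non-overlap check within (sample, chromosome)
  key <- paste(sample_id, chrom, sep = "\r")
  ord <- order(key, start)
  ks <- key[ord]; ss <- start[ord]; ee <- end[ord]
  same <- ks[-1] == ks[-length(ks)]
  if (length(same)) {
    ovl <- which(same & ss[-1] <= ee[-length(ee)])
    if (length(ovl)) {
      i <- ord[ovl[1]]; j <- ord[ovl[1] + 1L]
      stopf(paste0("segment file %s: overlapping segments within sample '%s' ",
                   "chromosome %s (lines %d and %d: %d-%d vs %d-%d)"),
            path, sample_id[i], chrom[i], i + 1L, j + 1L,
            start[i], end[i], start[j], end[j])
    }
  }
  GRanges(seqnames = chrom, ranges = IRanges(start, end),
          sample_id = sample_id, num_probes = num_probes,
          segment_mean = segmean)
}

#' @rdname readSegments
#' @param segments a `GRanges` as returned by `readSegments()`.
#' @return `writeSegments()` invisibly returns `path` after writing the
#'   canonical tab-delimited form (round-trips through `readSegments()`).
#' @export
writeSegments <- function(segments, path) {
  df <- data.table(
    Sample = mcols(segments)$sample_id,
    Chromosome = as.character(seqnames(segments)),
    Start = start(segments), End = end(segments),
    Num_Probes = mcols(segments)$num_probes,
    Segment_Mean = mcols(segments)$segment_mean
  )
  fwrite(df, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a miRBase-style miRNA annotation
#'
#' Accepts either a miRBase-dialect GFF3 (features of type
#' `miRNA_primary_transcript` for precursor hairpins with `ID`/`Name`
#' attributes, and `miRNA` for mature arms with `ID`/`Name`/`Derives_from`)
#' or an equivalent tab-delimited table.  Each mature arm is linked to its
#' precursor through the derives-from relation; a mature feature naming an
#' absent precursor is a linkage error.  The `status` attribute/column
#' (miRBase entry status: alive, dead, disputed) defaults to `alive`.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (by extension), `"gff3"`, or `"tsv"`.
#' @return a `GRanges` with one record per (precursor, mature) pair.  The
#'   range is the mature arm locus; metadata columns carry
#'   `mature_accession` (MIMAT), `mature_name`, `precursor_accession` (MI),
#'   `precursor_name`, `precursor_start`, `precursor_end`, `status`.
#' @export
readMirnaAnnotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- mcols(gr)
    status <- if ("status" %in% names(md)) as.character(md$status) else
      rep(NA_character_, length(gr))
    status[is.na(status)] <- "alive"
    is_pre <- as.character(md$type) == "miRNA_primary_transcript"
    is_mat <- as.character(md$type) == "miRNA"
    pre_idx <- which(is_pre)
    pre_acc <- as.character(md$ID)[pre_idx]
    pre_tbl <- data.frame(
      precursor_accession = pre_acc,
      precursor_name = as.character(md$Name)[pre_idx],
      precursor_start = start(gr)[pre_idx],
      precursor_end = end(gr)[pre_idx],
      stringsAsFactors = FALSE
    )
    mat_idx <- which(is_mat)
    derives <- vapply(md$Derives_from[mat_idx], function(v)
      if (length(v)) as.character(v)[1] else NA_character_, character(1))
    missing_pre <- which(is.na(derives) | !derives %in% pre_acc)
    if (length(missing_pre))
      stopf("annotation %s: mature '%s' derives from absent precursor '%s'",
            path, as.character(md$ID)[mat_idx][missing_pre[1]],
            derives[missing_pre[1]])
    j <- match(derives, pre_tbl$precursor_accession)
    ann <- GRanges(
      seqnames = normalizeChromosome(seqnames(gr)[mat_idx]),
      ranges = IRanges(start(gr)[mat_idx], end(gr)[mat_idx]),
      strand = strand(gr)[mat_idx],
      mature_accession = as.character(md$ID)[mat_idx],
      mature_name = as.character(md$Name)[mat_idx],
      precursor_accession = pre_tbl$precursor_accession[j],
      precursor_name = pre_tbl$precursor_name[j],
      precursor_start = pre_tbl$precursor_start[j],
      precursor_end = pre_tbl$precursor_end[j],
      status = status[mat_idx]
    )
  } else {
    dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                showProgress = FALSE)
    need <- c("mature_accession", "mature_name", "precursor_accession",
              "precursor_name", "chromosome", "start", "end", "strand",
              "precursor_start", "precursor_end")
    miss <- setdiff(need, names(dt))
    if (length(miss))
      stopf("annotation %s: missing column '%s'", path, miss[1])
    if (!"status" %in% names(dt)) dt$status <- "alive"
    ann <- GRanges(
      seqnames = normalizeChromosome(dt$chromosome),
      ranges = IRanges(dt$start, dt$end), strand = dt$strand,
      mature_accession = dt$mature_accession, mature_name = dt$mature_name,
      precursor_accession = dt$precursor_accession,
      precursor_name = dt$precursor_name,
      precursor_start = dt$precursor_start,
      precursor_end = dt$precursor_end,
      status = dt$status
    )
  }
  key <- paste(mcols(ann)$precursor_accession, mcols(ann)$mature_accession)
  if (anyDuplicated(key))
    stopf("annotation %s: duplicate (precursor, mature) pair %s",
          path, key[duplicated(key)][1])
  if (any(mcols(ann)$start > mcols(ann)$precursor_end))
    stopf("annotation %s: invalid precursor interval", path)
  ann
}

#' @rdname readMirnaAnnotation
#' @param annotation a `GRanges` as returned by `readMirnaAnnotation()`.
#' @return `writeMirnaAnnotation()` invisibly returns `path` after writing
#'   miRBase-dialect GFF3 (round-trips through `readMirnaAnnotation()`).
#' @export
writeMirnaAnnotation <- function(annotation, path) {
  md <- mcols(annotation)
  chrom <- as.character(seqnames(annotation))
  str <- as.character(strand(annotation))
  pre <- !duplicated(md$precursor_accession)
  pre_lines <- sprintf(
    "chr%s\t.\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Alias=%s;Name=%s",
    chrom[pre], md$precursor_start[pre], md$precursor_end[pre], str[pre],
    md$precursor_accession[pre], md$precursor_accession[pre],
    md$precursor_name[pre]
  )
  mat_lines <- sprintf(
    paste0("chr%s\t.\tmiRNA\t%d\t%d\t.\t%s\t.\t",
           "ID=%s;Alias=%s;Name=%s;Derives_from=%s;status=%s"),
    chrom, start(annotation), end(annotation), str,
    md$mature_accession, md$mature_accession, md$mature_name,
    md$precursor_accession, md$status
  )
  writeLines(c("##gff-version 3", pre_lines, mat_lines), path)
  invisible(path)
}

#' Read a TCGA-dialect miRNA isoform quantification table
#'
#' Parses the `*isoform.quantification.txt` dialect: one row per miRNA
#' isoform with precursor name, isoform genomic coordinates, read count and
#' a region descriptor.  Region strings of the form `mature,MIMAT0000690`
#' yield `region_type = "mature"` with the MIMAT accession extracted;
#' `precursor` and `stemloop` are kept as such; anything unparseable is
#' classified `unannotated` with a warning (such fragments are excluded
#' downstream in any case).
#'
#' @param path path to the tab-delimited file.
#' @param column_map named character vector mapping `sample_id` (optional if
#'   `sample_id=` is given), `precursor_name`, `isoform_coords`,
#'   `read_count`, `region` to column headers.
#' @param sample_id single sample identifier to use when the file carries no
#'   sample column (per-sample TCGA files).
#' @return a `data.frame` with columns `sample_id`, `precursor_name`,
#'   `chromosome`, `start`, `end`, `strand`, `read_count`, `region_type`,
#'   `mature_accession` (`NA` for non-mature rows).
#' @export
readIsoformCounts <- function(path,
                              column_map = c(sample_id = "sample_id",
                                             precursor_name = "miRNA_ID",
                                             isoform_coords = "isoform_coords",
                                             read_count = "read_count",
                                             region = "miRNA_region"),
                              sample_id = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
              showProgress = FALSE)
  for (field in c("precursor_name", "isoform_coords", "read_count", "region")) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(dt))
      stopf("isoform file %s: missing required column '%s' (field %s)",
            path, if (is.null(col)) "<unmapped>" else col, field)
  }
  sid <- if (!is.na(column_map["sample_id"]) &&
             column_map[["sample_id"]] %in% names(dt)) {
    as.character(dt[[column_map[["sample_id"]]]])
  } else if (!is.null(sample_id)) {
    rep(as.character(sample_id), nrow(dt))
  } else {
    stopf("isoform file %s: no sample column and no sample_id= given", path)
  }
  count_raw <- dt[[column_map[["read_count"]]]]
  count <- suppressWarnings(as.numeric(count_raw))
  bad <- which(is.na(count))
  if (length(bad))
    stopf("isoform file %s: non-numeric read_count '%s' on line %d",
          path, count_raw[bad[1]], bad[1] + 1L)
  bad <- which(count < 0)
  if (length(bad))
    stopf("isoform file %s: negative read_count %s on line %d",
          path, count_raw[bad[1]], bad[1] + 1L)

  # coords "hg19:chr9:96938239-96938260:+" (genome tag optional)
  coords <- as.character(dt[[column_map[["isoform_coords"]]]])
  cparts <- regmatches(coords,
    regexec("^(?:[^:]+:)?(?:chr)?([^:]+):([0-9]+)-([0-9]+):([+-])$", coords))
  okc <- lengths(cparts) == 5L
  if (any(!okc))
    stopf("isoform file %s: unparseable isoform_coords '%s' on line %d",
          path, coords[which(!okc)[1]], which(!okc)[1] + 1L)
  cm <- do.call(rbind, cparts)

  region <- as.character(dt[[column_map[["region"]]]])
  rparts <- strsplit(region, ",", fixed = TRUE)
  rtype <- vapply(rparts, function(p) if (length(p)) p[1] else "", character(1))
  acc <- vapply(rparts, function(p) if (length(p) > 1) p[2] else NA_character_,
                character(1))
  known <- rtype %in% c("mature", "precursor", "stemloop", "unannotated")
  mature_no_acc <- rtype == "mature" & (is.na(acc) | !grepl("^MIMAT", acc))
  reclass <- (!known) | mature_no_acc
  if (any(reclass)) {
    warnf("isoform file %s: %d rows with unparseable region strings (e.g. '%s') classified unannotated",
          path, sum(reclass), region[which(reclass)[1]])
    rtype[reclass] <- "unannotated"
    acc[reclass] <- NA_character_
  }
  acc[rtype != "mature"] <- NA_character_
  data.frame(
    sample_id = sid,
    precursor_name = as.character(dt[[column_map[["precursor_name"]]]]),
    chromosome = normalizeChromosome(cm[, 2]),
    start = as.integer(cm[, 3]), end = as.integer(cm[, 4]),
    strand = cm[, 5],
    read_count = as.integer(round(count)),
    region_type = rtype, mature_accession = acc,
    stringsAsFactors = FALSE
  )
}

#' @rdname readIsoformCounts
#' @param isoforms a `data.frame` as returned by `readIsoformCounts()`.
#' @return `writeIsoformCounts()` invisibly returns `path` after writing the
#'   canonical dialect (round-trips through `readIsoformCounts()`).
#' @export
writeIsoformCounts <- function(isoforms, path) {
  region <- ifelse(isoforms$region_type == "mature",
                   paste0("mature,", isoforms$mature_accession),
                   isoforms$region_type)
  df <- data.table(
    sample_id = isoforms$sample_id,
    miRNA_ID = isoforms$precursor_name,
    isoform_coords = sprintf("hg19:chr%s:%d-%d:%s", isoforms$chromosome,
                             isoforms$start, isoforms$end, isoforms$strand),
    read_count = isoforms$read_count,
    miRNA_region = region
  )
  fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Parses a tab-delimited clinical table with histology, overall survival,
#' and raw covariates.  Histology values are translated through an alias
#' map (TCGA project codes `LUSC`/`LUAD` map to `Sq`/`Ad` by default) and
#' must resolve to one of `Sq`, `Ad`, `Normal`.  Missing values are empty
#' strings (or `NA`); records lacking survival fields are retained but
#' flagged survival-ineligible.  A record with an event indicator but no
#' survival time (or vice versa) is a validation error.
#'
#' @param path path to the tab-delimited file.
#' @param column_map named character vector mapping `sample_id`, `histology`,
#'   `os_time`, `os_event`, `age`, `sex`, `smoking_status`, `stage` to
#'   column headers.
#' @param histology_aliases named character vector of extra histology labels.
#' @return a `data.frame` with normalized columns plus a logical
#'   `survival_eligible` flag.
#' @export
readClinical <- function(path,
                         column_map = c(sample_id = "sample_id",
                                        histology = "histology",
                                        os_time = "os_time",
                                        os_event = "os_event",
                                        age = "age", sex = "sex",
                                        smoking_status = "smoking_status",
                                        stage = "stage"),
                         histology_aliases = c(LUSC = "Sq", LUAD = "Ad",
                                               N = "Normal", NT = "Normal")) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              data.table = FALSE, na.strings = c("", "NA"),
              showProgress = FALSE)
  for (field in c("sample_id", "histology")) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(dt))
      stopf("clinical file %s: missing required column '%s' (field %s)",
            path, if (is.null(col)) "<unmapped>" else col, field)
  }
  getcol <- function(field) {
    col <- column_map[field]
    if (!is.na(col) && col %in% names(dt)) dt[[col]] else
      rep(NA_character_, nrow(dt))
  }
  histology <- getcol("histology")
  if (anyNA(histology))
    stopf("clinical file %s: missing histology on line %d",
          path, which(is.na(histology))[1] + 1L)
  aliased <- histology %in% names(histology_aliases)
  histology[aliased] <- histology_aliases[histology[aliased]]
  bad <- which(!histology %in% c("Sq", "Ad", "Normal"))
  if (length(bad))
    stopf("clinical file %s: histology '%s' on line %d is not one of Sq/Ad/Normal",
          path, histology[bad[1]], bad[1] + 1L)
  os_time <- suppressWarnings(as.numeric(getcol("os_time")))
  os_event <- suppressWarnings(as.integer(getcol("os_event")))
  mism <- which(is.na(os_time) != is.na(os_event))
  if (length(mism))
    stopf("clinical file %s: os_time/os_event present without the other on line %d",
          path, mism[1] + 1L)
  bad <- which(!is.na(os_event) & !os_event %in% c(0L, 1L))
  if (length(bad))
    stopf("clinical file %s: os_event must be 0/1 (line %d)", path, bad[1] + 1L)
  bad <- which(!is.na(os_time) & os_time < 0)
  if (length(bad))
    stopf("clinical file %s: negative os_time (line %d)", path, bad[1] + 1L)
  sex <- tolower(getcol("sex"))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  bad <- which(!is.na(sex) & !sex %in% c("male", "female"))
  if (length(bad))
    stopf("clinical file %s: unrecognized sex '%s' (line %d)",
          path, sex[bad[1]], bad[1] + 1L)
  smoking <- getcol("smoking_status")
  smoking[!is.na(smoking) & tolower(smoking) == "unknown"] <- NA_character_
  data.frame(
    sample_id = getcol("sample_id"),
    histology = histology,
    os_time = os_time, os_event = os_event,
    age = suppressWarnings(as.numeric(getcol("age"))),
    sex = sex,
    smoking_status = smoking,
    stage = getcol("stage"),
    survival_eligible = !is.na(os_time) & !is.na(os_event),
    stringsAsFactors = FALSE
  )
}

#' @rdname readClinical
#' @param clinical a `data.frame` as returned by `readClinical()`.
#' @return `writeClinical()` invisibly returns `path` after writing the
#'   canonical dialect (round-trips through `readClinical()`).
#' @export
writeClinical <- function(clinical, path) {
  cols <- c("sample_id", "histology", "os_time", "os_event", "age", "sex",
            "smoking_status", "stage")
  fwrite(as.data.table(clinical[, cols]), path, sep = "\t", quote = FALSE,
         na = "")
  invisible(path)
}
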
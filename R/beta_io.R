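#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with unique probe IDs as rownames
#' and unique sample IDs as colnames; all non-NA entries must lie in
#' \[0, 1\]. This is the universal currency of every analysis stage.
#'
#' @param bm numeric matrix (probes x samples).
#' @return the matrix, invisibly, after validation.
#' @export
validate_beta_matrix <- function(bm) {
  if (!is.matrix(bm) || !is.numeric(bm)) {
    stop("beta matrix must be a numeric matrix")
  }
  if (is.null(rownames(bm)) || anyDuplicated(rownames(bm))) {
    stop("beta matrix requires unique probe IDs as rownames")
  }
  if (is.null(colnames(bm)) || anyDuplicated(colnames(bm))) {
    stop("beta matrix requires unique sample IDs as colnames")
  }
  bad <- which(!is.na(bm) & (bm < 0 | bm > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      rownames(bm)[bad[1, 1]], colnames(bm)[bad[1, 2]], bm[bad[1, , drop = FALSE]]
    ))
  }
  invisible(bm)
}

#' Read a beta-value matrix from TSV/CSV
#'
#' First column holds probe IDs, header row holds sample IDs. Empty cells,
#' "NA" and "NaN" denote missing; any other non-numeric cell is an error
#' (loud failure over silent coercion). Values outside \[0, 1\] are rejected
#' with probe/sample coordinates.
#'
#' @param path file path.
#' @param dialect "tsv" (default) or "csv".
#' @return validated beta matrix.
#' @export
read_beta_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = TRUE)
  if (ncol(dt) < 2) stop("malformed beta matrix header: need probe column plus samples")
  probe_ids <- dt[[1]]
  vals <- as.matrix(dt[, -1, with = FALSE])
  miss <- vals == "" | vals == "NA" | vals == "NaN"
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(num) & !miss)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(vals))
    stop(sprintf("non-numeric beta '%s' at probe '%s', sample '%s'",
                 vals[bad[1]], probe_ids[i[1]], colnames(vals)[i[2]]))
  }
  num[miss] <- NA_real_
  bm <- matrix(num, nrow = nrow(vals), ncol = ncol(vals),
               dimnames = list(probe_ids, colnames(vals)))
  validate_beta_matrix(bm)
  bm
}

#' Write a beta-value matrix to TSV/CSV
#'
#' Inverse of [read_beta_matrix()]; round-trips values to full double
#' precision and NA positions exactly.
#'
#' @param bm beta matrix.
#' @param path output path.
#' @param dialect "tsv" or "csv".
#' @export
write_beta_matrix <- function(bm, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_beta_matrix(bm)
  dt <- data.table::data.table(probe_id = rownames(bm))
  for (j in colnames(bm)) dt[[j]] <- bm[, j]
  data.table::fwrite(dt, path, sep = if (dialect == "tsv") "\t" else ",",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with required columns `sample_id` and `tissue`; optional `age`
#' (years, NA allowed), `sex` ("F"/"M", NA allowed), `modality`
#' ("5modC"/"5hmC") and `donor` (pairing key between modalities).
#'
#' @param path CSV path.
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "tissue")
  miss <- setdiff(req, names(sheet))
  if (length(miss) > 0) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet")
  if ("age" %in% names(sheet) && any(sheet$age < 0, na.rm = TRUE)) {
    stop("negative age in sample sheet")
  }
  if ("sex" %in% names(sheet)) {
    bad <- setdiff(unique(sheet$sex[!is.na(sheet$sex)]), c("F", "M"))
    if (length(bad) > 0) stop("sex must be F/M, found: ", paste(bad, collapse = ", "))
  }
  sheet
}

#' Read a probe manifest (BED4+)
#'
#' Tab-separated, 0-based half-open coordinates: `chrom start end probe_id`
#' plus optional named columns `replicate_prefix`, `sequence`,
#' `cpg_count_extra`, `snp_offsets_from_3prime` (comma-separated integers).
#' Sources with 1-based coordinates must be converted before entering the
#' package; everything downstream assumes the BED convention.
#'
#' @param path TSV path with a header line.
#' @return data.frame manifest; `snp_offsets_from_3prime` is a list column.
#' @export
read_manifest <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  req <- c("chrom", "start", "end", "probe_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if ("snp_offsets_from_3prime" %in% names(df)) {
    df$snp_offsets_from_3prime <- lapply(
      strsplit(as.character(df$snp_offsets_from_3prime), ","),
      function(x) as.integer(x[x != "" & x != "NA"])
    )
  }
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest data.frame to validate.
#' @export
validate_manifest <- function(manifest) {
  if (any(manifest$start >= manifest$end)) stop("manifest intervals must satisfy start < end")
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe_id in manifest")
  if ("replicate_prefix" %in% names(manifest)) {
    ok <- startsWith(manifest$probe_id, manifest$replicate_prefix)
    if (!all(ok)) {
      stop("replicate_prefix must be a prefix of probe_id; offenders: ",
           paste(head(manifest$probe_id[!ok], 3), collapse = ", "))
    }
  }
  manifest
}

#' Read/write genomic interval sets (BED)
#'
#' Intervals are records of (chrom, start, end, name) in 0-based half-open
#' coordinates, the convention used throughout the package.
#'
#' @param path BED path (3 or 4+ columns, no header).
#' @return data.frame with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name" else df$name <- paste0("iv", seq_len(nrow(df)))
  if (any(df$start > df$end)) stop("malformed interval: start > end")
  if (any(df$start < 0)) stop("malformed interval: negative start")
  df[, c("chrom", "start", "end", "name")]
}

#' @rdname read_bed
#' @param ivs interval data.frame.
#' @export
write_bed <- function(ivs, path) {
  data.table::fwrite(ivs[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write probe-set lists (one ID per line)
#' @param path text file path.
#' @return character vector of probe IDs.
#' @export
read_probe_set <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_probe_set
#' @param ids character vector of probe IDs.
#' @export
write_probe_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
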
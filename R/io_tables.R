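#' Read a log2 ratio table
#'
#' The ratio table holds per-clone log2 tumor:reference ratios, one column
#' per case. The file's first column must be `clone_id`; the returned
#' matrix is re-aligned to the clone map's canonical order. The literal
#' string `NA` marks a missing (failed) clone measurement.
#'
#' @param path TSV path; header row `clone_id` then one column per case.
#' @param map A `clone_map` covering every clone in the file.
#' @return Numeric matrix (clones x cases) with `rownames` = clone ids in
#'   map order and `colnames` = case ids.
#' @export
read_ratio_table <- function(path, map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", colClasses = "character")
  if (names(df)[1] != "clone_id")
    stop("first column of a ratio table must be clone_id", call. = FALSE)
  if (ncol(df) < 2) stop("ratio table has no case columns", call. = FALSE)
  missing_from_map <- setdiff(df$clone_id, map$clone_id)
  if (length(missing_from_map) > 0)
    stop("clone(s) absent from map: ",
         paste(missing_from_map, collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at clone %s, case %s: '%s'",
                 df$clone_id[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  if (any(!is.finite(num) & !is.na(num)))
    stop("ratio values must be finite or NA", call. = FALSE)
  dimnames(num) <- list(df$clone_id, colnames(vals))
  all_missing <- colSums(!is.na(num)) == 0
  if (any(all_missing))
    stop("case column(s) entirely missing: ",
         paste(colnames(num)[all_missing], collapse = ", "), call. = FALSE)
  ratio_matrix(num[match(map$clone_id, rownames(num)), , drop = FALSE], map)
}

#' Validate/align a ratio matrix against a clone map
#' @param values numeric matrix, rownames = clone ids, colnames = case ids.
#' @param map A `clone_map`.
#' @return The matrix aligned to map order.
#' @export
ratio_matrix <- function(values, map) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  extra <- setdiff(rownames(values), map$clone_id)
  if (length(extra) > 0)
    stop("clone(s) absent from map: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (nrow(values) != nrow(map))
    stop("ratio matrix does not cover the clone map", call. = FALSE)
  values[match(map$clone_id, rownames(values)), , drop = FALSE]
}

#' Write a ratio table TSV
#' @param values clones x cases matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(values, path) {
  df <- data.frame(clone_id = rownames(values),
                   round(values, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tumor_locations <- c("one_internal_organ", "multiple_internal_organs",
                     "lymph_node_only", "limb_only", "skin_only", "unknown")

#' Read per-case clinical metadata
#'
#' Columns: `case_id`, `breed` (BMD/FCR), `geography` (USA/France), `sex`
#' (M/F/unknown), `age_years` (positive or NA), `tumor_location` (the five
#' recorded anatomical categories, or unknown).
#'
#' @param path TSV path.
#' @return data.frame of validated metadata.
#' @export
read_case_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  validate_case_meta(df)
}

validate_case_meta <- function(df) {
  req <- c("case_id", "breed", "geography", "sex", "age_years",
           "tumor_location")
  if (!all(req %in% names(df)))
    stop("metadata needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  df <- df[, req, drop = FALSE]
  df$case_id <- as.character(df$case_id)
  if (anyDuplicated(df$case_id))
    stop("duplicate case_id in metadata", call. = FALSE)
  if (!all(df$breed %in% c("BMD", "FCR")))
    stop("breed must be BMD or FCR", call. = FALSE)
  if (!all(df$geography %in% c("USA", "France")))
    stop("geography must be USA or France", call. = FALSE)
  if (!all(df$sex %in% c("M", "F", "unknown")))
    stop("sex must be M, F or unknown", call. = FALSE)
  df$age_years <- as.numeric(df$age_years)
  if (any(df$age_years <= 0, na.rm = TRUE))
    stop("age_years must be positive or NA", call. = FALSE)
  if (!all(df$tumor_location %in% tumor_locations))
    stop("tumor_location must be one of: ",
         paste(tumor_locations, collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Write case metadata TSV
#' @param meta data.frame as from [read_case_meta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case_meta <- function(meta, path) {
  utils::write.table(validate_case_meta(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

segment_columns <- c("case_id", "chrom", "start_mb", "end_mb", "state",
                     "mean_log2", "homozygous_flag", "n_clones")

#' Canonicalize a segment table
#'
#' Segments are SEG-style rows: one called run of contiguous aberrant
#' clones with half-open extent `[start_mb, end_mb)`, a gain/loss state,
#' the mean raw log2 over member clones, and a homozygous-deletion flag.
#'
#' @param df data.frame with the segment columns.
#' @return Validated data.frame sorted by (case, chrom, start).
#' @export
as_segments <- function(df) {
  if (nrow(df) == 0) {
    df <- data.frame(case_id = character(), chrom = character(),
                     start_mb = numeric(), end_mb = numeric(),
                     state = character(), mean_log2 = numeric(),
                     homozygous_flag = logical(), n_clones = integer(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  if (!all(segment_columns %in% names(df)))
    stop("segments need columns: ", paste(segment_columns, collapse = ", "),
         call. = FALSE)
  df <- df[, segment_columns, drop = FALSE]
  df$case_id <- as.character(df$case_id)
  df$chrom <- as.character(df$chrom)
  df$state <- as.character(df$state)
  df$homozygous_flag <- as.logical(df$homozygous_flag)
  df$n_clones <- as.integer(df$n_clones)
  if (!all(df$state %in% c("gain", "loss")))
    stop("segment state must be gain or loss", call. = FALSE)
  if (any(df$end_mb <= df$start_mb))
    stop("segments must have end_mb > start_mb", call. = FALSE)
  if (any(df$homozygous_flag & df$state != "loss"))
    stop("homozygous_flag requires state == loss", call. = FALSE)
  ord <- order(df$case_id, factor(df$chrom, levels = chrom_levels()),
               df$start_mb)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write segments to a SEG-style TSV
#' @param segments data.frame of segments (possibly empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  df <- as_segments(segments)
  df$start_mb <- round(df$start_mb, 6)
  df$end_mb <- round(df$end_mb, 6)
  df$mean_log2 <- round(df$mean_log2, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segments from a SEG-style TSV
#' @param path File written by [write_segments()].
#' @return Segment data.frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(case_id = "character"))
  as_segments(df)
}

#' Read a microsatellite peak-area table
#'
#' One row per (case, marker, sample type): two allele sizes (bp) and the
#' corresponding electropherogram peak areas. Homozygous genotypes carry a
#' single allele duplicated in both slots or NA in the second slot. Rows
#' are canonicalized so `allele1_size <= allele2_size`, swapping areas
#' along with sizes; the same ordering is applied to tumor and blood so
#' allele orientation cancels in the allelic-imbalance ratio.
#'
#' @param path TSV path with columns `case_id`, `marker_id`, `sample_type`,
#'   `allele1_size`, `allele1_area`, `allele2_size`, `allele2_area`.
#' @return Canonicalized data.frame.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  as_peak_table(df)
}

as_peak_table <- function(df) {
  req <- c("case_id", "marker_id", "sample_type", "allele1_size",
           "allele1_area", "allele2_size", "allele2_area")
  if (!all(req %in% names(df)))
    stop("peak table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  df <- df[, req, drop = FALSE]
  df$case_id <- as.character(df$case_id)
  df$marker_id <- as.character(df$marker_id)
  if (!all(df$sample_type %in% c("tumor", "blood")))
    stop("sample_type must be tumor or blood", call. = FALSE)
  for (col in c("allele1_size", "allele1_area", "allele2_size",
                "allele2_area"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$allele1_area < 0 | df$allele2_area < 0, na.rm = TRUE))
    stop("peak areas must be non-negative", call. = FALSE)
  key <- paste(df$case_id, df$marker_id, df$sample_type)
  if (anyDuplicated(key))
    stop("duplicate (case, marker, sample_type) row(s)", call. = FALSE)
  swap <- !is.na(df$allele2_size) & df$allele2_size < df$allele1_size
  if (any(swap)) {
    tmp_sz <- df$allele1_size[swap]; tmp_ar <- df$allele1_area[swap]
    df$allele1_size[swap] <- df$allele2_size[swap]
    df$allele1_area[swap] <- df$allele2_area[swap]
    df$allele2_size[swap] <- tmp_sz
    df$allele2_area[swap] <- tmp_ar
  }
  ord <- order(df$case_id, df$marker_id, df$sample_type)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a peak table TSV
#' @param peaks data.frame as from [read_peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(as_peak_table(peaks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
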
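#' @keywords internal
chrom_levels <- function(include_x = TRUE) {
  lv <- paste0("CFA", 1:38)
  if (include_x) lv <- c(lv, "CFAX")
  lv
}

#' Canine chromosome lengths
#'
#' Approximate lengths (megabases, rounded) of the 38 canine autosomes and
#' CFAX in the canFam2 assembly, bundled as a plain-text table. These are
#' deliberately coarse: the pipeline only needs them to bound clone
#' positions and to lay out the synthetic 1-Mb grid.
#'
#' @param include_x Keep CFAX? The copy-number analyses run on autosomes.
#' @return A data.frame with columns `chrom`, `length_mb`.
#' @export
chrom_lengths <- function(include_x = FALSE) {
  path <- system.file("extdata", "canfam2_chrom_lengths_mb.tsv",
                      package = "hscna", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$chrom <- factor(tab$chrom, levels = chrom_levels())
  tab <- tab[order(tab$chrom), , drop = FALSE]
  if (!include_x) tab <- tab[tab$chrom != "CFAX", , drop = FALSE]
  tab$chrom <- as.character(tab$chrom)
  rownames(tab) <- NULL
  tab
}

#' Construct a clone map
#'
#' A clone map is the ordered set of BAC probe positions defining the 1-Mb
#' genome grid on which all copy-number work happens. Rows are
#' canonicalized to (chromosome, position) order; positions are megabases,
#' 0-based, and each clone represents the half-open grid cell
#' `[pos_mb, pos_mb + 1)`.
#'
#' @param df data.frame with columns `clone_id`, `chrom`, `pos_mb`.
#' @return The canonicalized data.frame with class `clone_map`.
#' @export
clone_map <- function(df) {
  req <- c("clone_id", "chrom", "pos_mb")
  if (!all(req %in% names(df)))
    stop("clone map needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  df <- df[, req, drop = FALSE]
  df$clone_id <- as.character(df$clone_id)
  df$pos_mb <- as.numeric(df$pos_mb)
  bad_chrom <- setdiff(unique(as.character(df$chrom)), chrom_levels())
  if (length(bad_chrom) > 0)
    stop("unknown chromosome label(s): ", paste(bad_chrom, collapse = ", "),
         call. = FALSE)
  dup <- unique(df$clone_id[duplicated(df$clone_id)])
  if (length(dup) > 0)
    stop("duplicate clone_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$pos_mb)) || any(df$pos_mb < 0))
    stop("pos_mb must be non-negative and non-missing", call. = FALSE)
  chrom_f <- factor(as.character(df$chrom), levels = chrom_levels())
  ord <- order(chrom_f, df$pos_mb)
  df <- df[ord, , drop = FALSE]
  df$chrom <- as.character(df$chrom)
  # positions strictly increasing within chromosome
  by_chr <- split(df$pos_mb, df$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), TRUE)))
    stop("pos_mb must be strictly increasing within a chromosome",
         call. = FALSE)
  lens <- chrom_lengths(include_x = TRUE)
  maxlen <- lens$length_mb[match(df$chrom, lens$chrom)]
  over <- df$pos_mb > maxlen
  if (any(over))
    stop("clone(s) beyond declared chromosome length: ",
         paste(df$clone_id[over], collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("clone_map", "data.frame")
  df
}

#' Read a clone map TSV
#'
#' @param path TSV with header columns `clone_id`, `chrom`, `pos_mb`.
#'   Row order is irrelevant; the result is canonically sorted.
#' @return A `clone_map`.
#' @export
read_clone_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  clone_map(df)
}

#' Write a clone map TSV
#' @param map A `clone_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Regular 1-Mb clone grid over the autosomes
#'
#' Lays one clone per megabase on every autosome, emulating the 1-Mb BAC
#' array design. Clone ids encode chromosome and position.
#'
#' @param spacing_mb Grid spacing (default 1 Mb).
#' @return A `clone_map`.
#' @export
make_grid_map <- function(spacing_mb = 1) {
  lens <- chrom_lengths(include_x = FALSE)
  rows <- lapply(seq_len(nrow(lens)), function(i) {
    pos <- seq(0, lens$length_mb[i] - spacing_mb, by = spacing_mb)
    data.frame(
      clone_id = sprintf("%s_%04.0f", lens$chrom[i], pos * 10),
      chrom = lens$chrom[i],
      pos_mb = pos,
      stringsAsFactors = FALSE
    )
  })
  clone_map(do.call(rbind, rows))
}
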
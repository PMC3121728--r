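#' Genome-wide CNA penetrance track
#'
#' For every 1-Mb grid cell `[pos_mb, pos_mb + 1)` of the clone map,
#' computes the percentage of aberrant cases with a gain segment and with
#' a loss segment overlapping the cell (half-open interval overlap). The
#' denominator is the number of aberrant cases in the chosen stratum;
#' flat (no-CNA) cases never enter it. Percentages are rounded to one
#' decimal. CFAX is excluded by default.
#'
#' @param cohort A `cohort_call`.
#' @param map A `clone_map`.
#' @param meta Optional metadata for stratum filtering.
#' @param breed Optional breed filter ("BMD" or "FCR").
#' @param include_x Include CFAX cells (default FALSE).
#' @return data.frame: chrom, start_mb, end_mb, pct_gain, pct_loss,
#'   n_cases (attribute `n_cases` also set).
#' @export
compute_penetrance <- function(cohort, map, meta = NULL, breed = NULL,
                               include_x = FALSE) {
  ids <- cohort$aberrant_ids
  if (!is.null(breed)) {
    stopifnot(!is.null(meta))
    meta <- validate_case_meta(meta)
    ids <- intersect(ids, meta$case_id[meta$breed == breed])
  }
  if (length(ids) == 0) stop("no aberrant cases in stratum", call. = FALSE)
  cells <- as.data.frame(map)[, c("chrom", "pos_mb")]
  if (!include_x) {
    keep <- cells$chrom != "CFAX"
    cells <- cells[keep, , drop = FALSE]
  }
  names(cells)[2] <- "start_mb"
  cells$end_mb <- cells$start_mb + 1.0
  n_cells <- nrow(cells)
  gain_n <- integer(n_cells)
  loss_n <- integer(n_cells)
  segs <- cohort$segments
  segs <- segs[segs$case_id %in% ids, , drop = FALSE]
  # per case and state, mark covered cells once
  cell_key <- split(seq_len(n_cells), cells$chrom)
  for (cid in ids) {
    s_case <- segs[segs$case_id == cid, , drop = FALSE]
    for (st in c("gain", "loss")) {
      s <- s_case[s_case$state == st, , drop = FALSE]
      if (nrow(s) == 0) next
      covered <- logical(n_cells)
      for (k in seq_len(nrow(s))) {
        ix <- cell_key[[s$chrom[k]]]
        if (is.null(ix)) next
        hit <- cells$start_mb[ix] < s$end_mb[k] &
               cells$end_mb[ix] > s$start_mb[k]
        covered[ix[hit]] <- TRUE
      }
      if (st == "gain") gain_n <- gain_n + covered
      else loss_n <- loss_n + covered
    }
  }
  out <- cells
  out$pct_gain <- round(100 * gain_n / length(ids), 1)
  out$pct_loss <- round(100 * loss_n / length(ids), 1)
  out$n_cases <- length(ids)
  rownames(out) <- NULL
  attr(out, "n_cases") <- length(ids)
  out
}

#' Label cells by recurrence
#'
#' Per state, a cell is `highly_recurrent` when its penetrance is at or
#' above `100 * highly_recurrent_frac` (default 50%), else `recurrent` at
#' or above `100 * recurrent_frac` (default 30%), else `none`. Boundaries
#' are inclusive.
#'
#' @param track Penetrance track from [compute_penetrance()].
#' @param cfg An [hs_config()].
#' @return `track` with added `label_gain`, `label_loss` columns.
#' @export
classify_cells <- function(track, cfg = hs_config()) {
  lab <- function(pct) {
    ifelse(pct >= 100 * cfg$highly_recurrent_frac, "highly_recurrent",
           ifelse(pct >= 100 * cfg$recurrent_frac, "recurrent", "none"))
  }
  track$label_gain <- lab(track$pct_gain)
  track$label_loss <- lab(track$pct_loss)
  track
}

#' Merge qualifying cells into recurrent regions
#'
#' Maximal runs of adjacent same-chromosome cells whose penetrance for the
#' given state is at or above `threshold_pct` merge into one region; a
#' single sub-threshold cell breaks a run (no gap tolerance). The region's
#' `peak_pct` is the maximum penetrance inside it, and its label reflects
#' the config's recurrence fractions.
#'
#' @param track Penetrance track.
#' @param state "gain" or "loss".
#' @param threshold_pct Inclusion threshold in percent (0, 100].
#' @param cfg An [hs_config()] (for the labels).
#' @return data.frame: chrom, start_mb, end_mb, state, peak_pct, label.
#' @export
merge_regions <- function(track, state = c("loss", "gain"),
                          threshold_pct = 30, cfg = hs_config()) {
  state <- match.arg(state)
  if (!(threshold_pct > 0 && threshold_pct <= 100))
    stop("threshold_pct must be in (0, 100]", call. = FALSE)
  pct <- if (state == "gain") track$pct_gain else track$pct_loss
  empty <- data.frame(chrom = character(), start_mb = numeric(),
                      end_mb = numeric(), state = character(),
                      peak_pct = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  if (nrow(track) == 0) return(empty)
  rows <- list()
  for (chr in unique(track$chrom)) {
    ix <- which(track$chrom == chr)
    qual <- pct[ix] >= threshold_pct
    # adjacency on the grid: cells whose intervals abut
    adjacent <- c(FALSE, abs(track$start_mb[ix][-1] -
                               track$end_mb[ix][-length(ix)]) < 1e-9)
    run_id <- cumsum(!(qual & adjacent) | !qual)
    run_id[!qual] <- NA
    for (rid in unique(run_id[!is.na(run_id)])) {
      members <- ix[!is.na(run_id) & run_id == rid]
      peak <- max(pct[members])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chr,
        start_mb = min(track$start_mb[members]),
        end_mb = max(track$end_mb[members]),
        state = state,
        peak_pct = peak,
        label = if (peak >= 100 * cfg$highly_recurrent_frac)
          "highly_recurrent" else if (peak >= 100 * cfg$recurrent_frac)
            "recurrent" else "none",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  ord <- order(factor(out$chrom, levels = chrom_levels()), out$start_mb)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a penetrance track TSV
#' @param track Penetrance track (classified or not).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_penetrance <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write recurrent regions as a BED-style TSV
#' @param regions data.frame from [merge_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED-style region file
#' @param path TSV with columns chrom, start_mb, end_mb, state.
#' @return data.frame of regions.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start_mb", "end_mb", "state")
  if (!all(req %in% names(df)))
    stop("region file needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(df$end_mb <= df$start_mb))
    stop("regions must have end_mb > start_mb", call. = FALSE)
  df
}
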
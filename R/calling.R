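#' Moving-median smoothing of one chromosome's log2 profile
#'
#' Stand-in for the breakpoint smoother used on the original arrays: a
#' running median with symmetric windows that shrink (staying odd) at the
#' chromosome ends, i.e. clone `i` is smoothed over
#' `[i - k, i + k]` with `k = min((window-1)/2, i-1, n-i)`. Missing clones
#' are excluded from each window rather than imputed; a window with no
#' observed values yields NA.
#'
#' @param values Numeric vector of log2 ratios, ordered by position.
#' @param window Odd positive integer window width (clones).
#' @return Numeric vector, same length as `values`.
#' @export
smooth_profile <- function(values, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  n <- length(values)
  if (n == 0) return(values)
  if (all(is.na(values))) {
    warning("all-missing chromosome: smoothing returns all NA")
    return(values)
  }
  if (window == 1L || n == 1L) return(values)
  h <- (window - 1L) %/% 2L
  win_median <- function(i) {
    k <- min(h, i - 1L, n - i)
    w <- values[(i - k):(i + k)]
    w <- w[!is.na(w)]
    if (length(w) == 0) NA_real_ else stats::median(w)
  }
  if (!anyNA(values) && n > window) {
    # fast path: runmed for the interior, explicit shrinking (odd,
    # symmetric) windows at the ends -- runmed's own "median" end rule is
    # Tukey's, which is not the documented convention here
    out <- as.numeric(stats::runmed(values, window, endrule = "keep"))
    for (i in c(seq_len(h), (n - h + 1L):n)) out[i] <- win_median(i)
    return(out)
  }
  vapply(seq_len(n), win_median, 0)
}

#' Threshold smoothed values into per-clone states
#'
#' Gain where the smoothed log2 is at or above `log2(gain_ratio)`
#' (default log2(1.15)), loss at or below `log2(loss_ratio)` (default
#' log2(0.85)), neutral otherwise. Missing values are neutral.
#'
#' @param smoothed Numeric vector of smoothed log2 ratios.
#' @param cfg An [hs_config()].
#' @return Character vector in `c("gain", "neutral", "loss")`.
#' @export
call_states <- function(smoothed, cfg = hs_config()) {
  states <- rep("neutral", length(smoothed))
  states[!is.na(smoothed) & smoothed >= log2(cfg$gain_ratio)] <- "gain"
  states[!is.na(smoothed) & smoothed <= log2(cfg$loss_ratio)] <- "loss"
  states
}

#' Collapse per-clone states into called segments
#'
#' Maximal runs of identical non-neutral state with at least
#' `min_segment_clones` members become segments. The extent convention is
#' half-open on the 1-Mb grid: `start_mb` is the first member clone's
#' position and `end_mb` the last member's position + 1, so a k-clone run
#' spans k Mb. `mean_log2` is computed from the *raw* (unsmoothed) ratios
#' of member clones, and a loss segment whose raw mean falls below
#' `homozygous_log2_cut` is flagged as a putative homozygous deletion.
#'
#' @param states Per-clone states (one chromosome).
#' @param raw Raw log2 values, aligned to `states`.
#' @param map_chr The clone-map rows for this chromosome.
#' @param cfg An [hs_config()].
#' @param case_id Case identifier stamped on the segments.
#' @return Segment data.frame (possibly empty).
#' @export
extract_segments <- function(states, raw, map_chr, cfg = hs_config(),
                             case_id = "case") {
  stopifnot(length(states) == nrow(map_chr), length(raw) == length(states))
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "neutral" & r$lengths >= cfg$min_segment_clones
  if (!any(keep)) return(as_segments(data.frame()))
  idx <- which(keep)
  rows <- lapply(idx, function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    m <- mean(raw[i1:i2], na.rm = TRUE)
    data.frame(
      case_id = case_id,
      chrom = map_chr$chrom[1],
      start_mb = map_chr$pos_mb[i1],
      end_mb = map_chr$pos_mb[i2] + 1.0,
      state = r$values[j],
      mean_log2 = m,
      homozygous_flag = r$values[j] == "loss" &&
        !is.na(m) && m < cfg$homozygous_log2_cut,
      n_clones = i2 - i1 + 1L,
      stringsAsFactors = FALSE
    )
  })
  as_segments(do.call(rbind, rows))
}

#' Call CNAs for one case
#'
#' Per chromosome: smooth, threshold, extract segments; concatenate. A
#' case is aberrant iff it has at least one called segment.
#'
#' @param values Named numeric vector (or one-column matrix) of log2 ratios
#'   aligned to `map`.
#' @param map A `clone_map`.
#' @param cfg An [hs_config()].
#' @param case_id Case identifier.
#' @return List of class `case_call` with `case_id`, `segments`, `aberrant`.
#' @export
call_case <- function(values, map, cfg = hs_config(), case_id = "case") {
  values <- as.numeric(values)
  stopifnot(length(values) == nrow(map))
  segs <- lapply(split(seq_len(nrow(map)), factor(map$chrom,
                                                  levels = unique(map$chrom))),
                 function(ix) {
    sm <- smooth_profile(values[ix], cfg$smoothing_window)
    extract_segments(call_states(sm, cfg), values[ix],
                     map[ix, , drop = FALSE], cfg, case_id)
  })
  segs <- as_segments(do.call(rbind, segs))
  out <- list(case_id = case_id, segments = segs, aberrant = nrow(segs) > 0)
  class(out) <- "case_call"
  out
}

#' Call CNAs for a whole cohort
#'
#' @param values clones x cases matrix aligned to `map` (as returned by
#'   [read_ratio_table()] or [simulate_cohort()]).
#' @param map A `clone_map`.
#' @param cfg An [hs_config()].
#' @return List of class `cohort_call`: `results` (per-case `case_call`),
#'   `segments` (all segments, one data.frame), `aberrant_ids`.
#' @export
call_cohort <- function(values, map, cfg = hs_config()) {
  values <- ratio_matrix(values, map)
  results <- lapply(colnames(values), function(cid) {
    call_case(values[, cid], map, cfg, case_id = cid)
  })
  names(results) <- colnames(values)
  segments <- as_segments(do.call(rbind, lapply(results, `[[`, "segments")))
  out <- list(results = results, segments = segments,
              aberrant_ids = names(results)[vapply(results, `[[`, TRUE,
                                                   "aberrant")])
  class(out) <- "cohort_call"
  out
}

#' @export
print.cohort_call <- function(x, ...) {
  cat(sprintf("cohort_call: %d cases, %d aberrant, %d segments\n",
              length(x$results), length(x$aberrant_ids), nrow(x$segments)))
  invisible(x)
}

#' Cohort copy-number summary
#'
#' Per-breed and combined means/sds of CNA counts and sizes over aberrant
#' cases only, mirroring the usual cohort summary table: mean number of
#' CNAs, losses, gains (each +/- sd), the loss:gain ratio of the mean
#' counts, and mean segment size by state (pooled over segments).
#'
#' @param cohort A `cohort_call`.
#' @param meta Case metadata (for breed); rows for at least the aberrant
#'   cases.
#' @return data.frame, one row per stratum (BMD, FCR, combined).
#' @export
summarize_cohort <- function(cohort, meta) {
  meta <- validate_case_meta(meta)
  segs <- cohort$segments
  strata <- list(BMD = "BMD", FCR = "FCR", combined = c("BMD", "FCR"))
  rows <- lapply(names(strata), function(sn) {
    ids <- intersect(cohort$aberrant_ids,
                     meta$case_id[meta$breed %in% strata[[sn]]])
    if (length(ids) == 0) {
      warning("empty stratum omitted: ", sn)
      return(NULL)
    }
    s <- segs[segs$case_id %in% ids, , drop = FALSE]
    n_tot <- tabulate(factor(s$case_id, levels = ids), nbins = length(ids))
    n_loss <- tabulate(factor(s$case_id[s$state == "loss"], levels = ids),
                       nbins = length(ids))
    n_gain <- n_tot - n_loss
    loss_sizes <- s$end_mb[s$state == "loss"] - s$start_mb[s$state == "loss"]
    gain_sizes <- s$end_mb[s$state == "gain"] - s$start_mb[s$state == "gain"]
    sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
    data.frame(
      stratum = sn, n_cases = length(ids),
      mean_n_cnas = mean(n_tot), sd_n_cnas = sd0(n_tot),
      mean_n_losses = mean(n_loss), sd_n_losses = sd0(n_loss),
      mean_n_gains = mean(n_gain), sd_n_gains = sd0(n_gain),
      loss_gain_ratio = if (mean(n_gain) > 0) mean(n_loss) / mean(n_gain)
                        else NA_real_,
      mean_size_loss_mb = if (length(loss_sizes)) mean(loss_sizes)
                          else NA_real_,
      sd_size_loss_mb = sd0(loss_sizes),
      mean_size_gain_mb = if (length(gain_sizes)) mean(gain_sizes)
                          else NA_real_,
      sd_size_gain_mb = sd0(gain_sizes),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Segment size histogram
#'
#' Counts segments per (state, size bin) with left-closed, right-open bins.
#'
#' @param segments Segment data.frame.
#' @param bin_edges_mb Increasing numeric bin edges.
#' @return data.frame: state, bin_start, bin_end, count.
#' @export
size_histogram <- function(segments, bin_edges_mb) {
  if (is.unsorted(bin_edges_mb, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  nb <- length(bin_edges_mb) - 1L
  out <- expand.grid(state = c("gain", "loss"), bin = seq_len(nb),
                     stringsAsFactors = FALSE)
  out$bin_start <- bin_edges_mb[out$bin]
  out$bin_end <- bin_edges_mb[out$bin + 1L]
  out$count <- 0L
  if (nrow(segments) > 0) {
    sz <- segments$end_mb - segments$start_mb
    bin <- findInterval(sz, bin_edges_mb, left.open = FALSE,
                        rightmost.closed = FALSE)
    ok <- bin >= 1 & bin <= nb
    tab <- table(state = segments$state[ok], bin = bin[ok])
    for (i in seq_len(nrow(out))) {
      s <- out$state[i]; b <- as.character(out$bin[i])
      if (s %in% rownames(tab) && b %in% colnames(tab))
        out$count[i] <- as.integer(tab[s, b])
    }
  }
  out[, c("state", "bin_start", "bin_end", "count")]
}
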
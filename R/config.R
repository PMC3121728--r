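#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults reproduce the
#' published analysis settings: CNA detection thresholds equivalent to
#' tumor:reference ratios of 1.15:1 (gain) and 0.85:1 (loss) applied to
#' smoothed log2 values, a homozygous-deletion flag at raw segment mean
#' log2 < -1.0, recurrence at >= 30% and high recurrence at >= 50% of
#' aberrant cases, allelic-imbalance deletion calls at AI >= 1.5 or
#' AI <= 0.67, and a permutation family-wise error rate of 0.05.
#'
#' @param gain_ratio Tumor:reference ratio above which (on the log2 scale,
#'   i.e. smoothed log2 >= log2(gain_ratio)) a clone is called gained.
#' @param loss_ratio Ratio below which a clone is called lost.
#' @param homozygous_log2_cut Raw segment mean log2 below which a loss
#'   segment is flagged as a putative homozygous deletion.
#' @param recurrent_frac Minimum fraction of aberrant cases for an interval
#'   to be labelled recurrent.
#' @param highly_recurrent_frac Likewise for the highly recurrent label.
#' @param ai_upper,ai_lower Allelic-imbalance deletion-call boundaries
#'   (inclusive).
#' @param fwer_alpha Family-wise error rate for the permutation cutoff.
#' @param n_permutations Number of breed-label permutations.
#' @param smoothing_window Odd moving-median window (number of clones).
#' @param min_segment_clones Minimum clones per called segment.
#' @param rng_seed Seed recorded in run logs and used by the CLI.
#' @return A validated list of class `hs_config`.
#' @export
hs_config <- function(gain_ratio = 1.15,
                      loss_ratio = 0.85,
                      homozygous_log2_cut = -1.0,
                      recurrent_frac = 0.30,
                      highly_recurrent_frac = 0.50,
                      ai_upper = 1.5,
                      ai_lower = 0.67,
                      fwer_alpha = 0.05,
                      n_permutations = 10000L,
                      smoothing_window = 5L,
                      min_segment_clones = 2L,
                      rng_seed = 42L) {
  cfg <- list(
    gain_ratio = as.numeric(gain_ratio),
    loss_ratio = as.numeric(loss_ratio),
    homozygous_log2_cut = as.numeric(homozygous_log2_cut),
    recurrent_frac = as.numeric(recurrent_frac),
    highly_recurrent_frac = as.numeric(highly_recurrent_frac),
    ai_upper = as.numeric(ai_upper),
    ai_lower = as.numeric(ai_lower),
    fwer_alpha = as.numeric(fwer_alpha),
    n_permutations = as.integer(n_permutations),
    smoothing_window = as.integer(smoothing_window),
    min_segment_clones = as.integer(min_segment_clones),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "hs_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "hs_config"))
  if (!(cfg$loss_ratio > 0 && cfg$loss_ratio < 1 && cfg$gain_ratio > 1))
    stop("require 0 < loss_ratio < 1 < gain_ratio", call. = FALSE)
  if (!(cfg$ai_lower < 1 && cfg$ai_upper > 1))
    stop("require ai_lower < 1 < ai_upper", call. = FALSE)
  if (!(cfg$recurrent_frac > 0 &&
        cfg$recurrent_frac <= cfg$highly_recurrent_frac))
    stop("require 0 < recurrent_frac <= highly_recurrent_frac", call. = FALSE)
  if (cfg$smoothing_window < 1L || cfg$smoothing_window %% 2L == 0L)
    stop("smoothing_window must be a positive odd integer", call. = FALSE)
  if (cfg$min_segment_clones < 1L)
    stop("min_segment_clones must be >= 1", call. = FALSE)
  if (!(cfg$fwer_alpha > 0 && cfg$fwer_alpha < 1))
    stop("fwer_alpha must be in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read a configuration file
#'
#' The config format is a flat `key: value` file (a YAML subset; one
#' scalar per line, `#` comments allowed). Unknown keys are an error so
#' typos do not silently fall back to defaults.
#'
#' @param path File path.
#' @return An `hs_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- names(formals(hs_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) stop("non-numeric config value: ", v, call. = FALSE)
    num
  })
  names(args) <- keys
  do.call(hs_config, args)
}

#' Write a configuration (run log)
#'
#' Serializes the fully resolved config, including the RNG seed, so every
#' stochastic result can be reproduced from the log alone.
#'
#' @param cfg An `hs_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  lines <- vapply(names(unclass(cfg)), function(k) {
    sprintf("%s: %s", k, format(cfg[[k]], scientific = FALSE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
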
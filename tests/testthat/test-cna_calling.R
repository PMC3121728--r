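test_that("smooth_profile matches direct moving-median evaluation", {
  # window 1 is the identity; constants are invariant
  x <- c(0.1, -0.2, 0.3, 0)
  expect_equal(smooth_profile(x, 1L), x)
  expect_equal(smooth_profile(rep(0.07, 9), 5L), rep(0.07, 9))

  # documented 7-point example, window 3: plateau preserved, flanks 0
  y <- c(0, 0, -0.32, -0.32, -0.32, 0, 0)
  expect_equal(smooth_profile(y, 3L), y)

  # direct evaluation oracle with shrinking odd end windows
  set.seed(1)
  for (w in c(3L, 5L, 7L)) {
    z <- rnorm(25)
    h <- (w - 1L) / 2L
    expected <- vapply(seq_along(z), function(i) {
      k <- min(h, i - 1L, length(z) - i)
      median(z[(i - k):(i + k)])
    }, 0)
    expect_equal(smooth_profile(z, w), expected, info = paste("window", w))
  }

  # NA values are excluded from windows, not imputed
  z <- c(0, NA, 0.5, 0.5, 0.5)
  expect_equal(smooth_profile(z, 3L)[2], 0.25)   # median(0, 0.5)
  expect_equal(smooth_profile(z, 3L)[3], 0.5)    # median(0.5, 0.5)
  expect_warning(out <- smooth_profile(c(NA_real_, NA_real_), 3L),
                 "all-missing")
  expect_true(all(is.na(out)))

  # NA path agrees with the runmed fast path on NA-free input
  set.seed(2)
  z <- rnorm(40)
  z_na <- c(z, NA)
  expect_equal(smooth_profile(z_na, 5L)[1:38], smooth_profile(z, 5L)[1:38])

  expect_error(smooth_profile(x, 4L), "odd")
})

test_that("call_states applies the published ratio thresholds", {
  cfg <- hs_config()
  # log2(1.15) ~ 0.2016; log2(0.85) ~ -0.2345
  expect_equal(call_states(c(0, 0.25, -0.30, NA, log2(1.15), log2(0.85)), cfg),
               c("neutral", "gain", "loss", "neutral", "gain", "loss"))

  # threshold equivalence: ratio scale vs log2 scale
  set.seed(3)
  r <- exp(rnorm(500, 0, 0.4))   # ratios > 0
  log2_calls <- call_states(log2(r), cfg)
  ratio_calls <- ifelse(r >= 1.15, "gain",
                        ifelse(r <= 0.85, "loss", "neutral"))
  expect_equal(log2_calls, ratio_calls)

  # monotonicity: stricter thresholds never call more clones
  x <- rnorm(500, 0, 0.3)
  for (g in c(1.1, 1.2, 1.3)) {
    n1 <- sum(call_states(x, hs_config(gain_ratio = g)) == "gain")
    n2 <- sum(call_states(x, hs_config(gain_ratio = g + 0.05)) == "gain")
    expect_gte(n1, n2)
  }
  for (l in c(0.9, 0.8, 0.7)) {
    n1 <- sum(call_states(x, hs_config(loss_ratio = l)) == "loss")
    n2 <- sum(call_states(x, hs_config(loss_ratio = l - 0.05)) == "loss")
    expect_gte(n1, n2)
  }
})

test_that("extract_segments applies run, size and homozygous-flag rules", {
  cfg <- hs_config()
  map3 <- toy_map(3, "CFA16", start = 47)
  segs <- extract_segments(rep("loss", 3), rep(-0.4, 3), map3, cfg, "c1")
  expect_equal(segs$start_mb, 47)
  expect_equal(segs$end_mb, 50)
  expect_equal(segs$end_mb - segs$start_mb, 3)

  # interrupted run too short for min_segment_clones = 2
  segs <- extract_segments(c("loss", "neutral", "loss"),
                           c(-0.4, 0, -0.4), map3, cfg, "c1")
  expect_equal(nrow(segs), 0)

  # homozygous flag from raw mean below -1.0
  segs <- extract_segments(rep("loss", 3), c(-1.3, -1.2, -1.1), map3, cfg)
  expect_true(segs$homozygous_flag)
  segs <- extract_segments(rep("gain", 3), c(1.2, 1.2, 1.2), map3, cfg)
  expect_false(segs$homozygous_flag)
})

test_that("extract_segments matches brute-force run enumeration", {
  cfg <- hs_config(min_segment_clones = 2L)
  set.seed(7)
  for (rep_i in 1:40) {
    n <- sample(3:20, 1)
    states <- sample(c("gain", "neutral", "loss"), n, replace = TRUE)
    raw <- rnorm(n, 0, 0.3)
    map_n <- toy_map(n)
    segs <- extract_segments(states, raw, map_n, cfg, "c")
    runs <- oracle_runs(states, cfg$min_segment_clones)
    expect_equal(nrow(segs), length(runs))
    if (length(runs) > 0) {
      oracle_df <- do.call(rbind, lapply(runs, function(r) {
        i <- as.integer(r["start"]); j <- as.integer(r["end"])
        data.frame(start_mb = map_n$pos_mb[i], end_mb = map_n$pos_mb[j] + 1,
                   state = unname(r["state"]),
                   mean_log2 = mean(raw[i:j]), stringsAsFactors = FALSE)
      }))
      oracle_df <- oracle_df[order(oracle_df$start_mb), ]
      expect_equal(segs$start_mb, oracle_df$start_mb)
      expect_equal(segs$end_mb, oracle_df$end_mb)
      expect_equal(segs$state, oracle_df$state)
      expect_equal(segs$mean_log2, oracle_df$mean_log2)
    }
  }
})

test_that("pure-noise profiles are never called aberrant at default settings", {
  map <- toy_map(120, "CFA1")
  set.seed(11)
  false_calls <- 0L
  for (i in 1:100) {
    v <- rnorm(120, 0, 0.05)
    cc <- call_case(v, map, case_id = "noise")
    false_calls <- false_calls + nrow(cc$segments)
  }
  expect_equal(false_calls, 0L)
})

test_that("summarize_cohort arithmetic on hand-built cohorts", {
  seg <- function(cid, chrom, s, e, state) {
    data.frame(case_id = cid, chrom = chrom, start_mb = s, end_mb = e,
               state = state, mean_log2 = ifelse(state == "loss", -0.4, 0.4),
               homozygous_flag = FALSE, n_clones = as.integer(e - s),
               stringsAsFactors = FALSE)
  }
  segs <- rbind(seg("a", "CFA1", 0, 3, "loss"), seg("a", "CFA2", 0, 3, "loss"),
                seg("a", "CFA3", 0, 3, "gain"), seg("b", "CFA1", 10, 13, "loss"),
                seg("b", "CFA2", 10, 13, "gain"))
  cohort <- cohort_from_segments(segs)
  meta <- toy_meta(c("a", "b"), c("BMD", "BMD"))
  expect_warning(summ <- summarize_cohort(cohort, meta), "FCR")
  comb <- summ[summ$stratum == "combined", ]
  expect_equal(comb$mean_n_cnas, 2.5)
  expect_equal(comb$mean_n_losses, 1.5)
  expect_equal(comb$mean_n_gains, 1.0)
  expect_equal(comb$loss_gain_ratio, 1.5)
  expect_equal(comb$mean_size_loss_mb, 3)
  expect_equal(comb$sd_size_loss_mb, 0)
})

test_that("size_histogram bins left-closed right-open", {
  segs <- data.frame(case_id = "a", chrom = "CFA1", start_mb = c(0, 20),
                     end_mb = c(3, 35), state = c("loss", "gain"),
                     mean_log2 = c(-0.4, 0.4), homozygous_flag = FALSE,
                     n_clones = c(3L, 15L), stringsAsFactors = FALSE)
  h <- size_histogram(segs, c(0, 15, 30, 45))
  expect_equal(h$count[h$state == "loss"], c(1L, 0L, 0L))
  expect_equal(h$count[h$state == "gain"], c(0L, 1L, 0L))  # 15 Mb: 2nd bin
  h0 <- size_histogram(data.frame(), c(0, 15, 30))
  expect_true(all(h0$count == 0L))
  # boundary value 15 falls in the second bin
  segs$end_mb[1] <- 15
  h <- size_histogram(segs, c(0, 15, 30, 45))
  expect_equal(h$count[h$state == "loss"], c(0L, 1L, 0L))
  expect_error(size_histogram(segs, c(0, 0, 10)), "increasing")
})
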
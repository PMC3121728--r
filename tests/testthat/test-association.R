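test_that("fisher_exact_2x2 worked examples and degenerate margins", {
  expect_equal(fisher_exact_2x2(2, 2, 2, 2), 1.0)
  # complete separation of 5 vs 5: only the two extreme tables qualify
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_warning(p <- fisher_exact_2x2(0, 0, 3, 3), "degenerate")
  expect_equal(p, 1.0)
  expect_error(fisher_exact_2x2(-1, 2, 2, 2), "non-negative")
  expect_error(fisher_exact_2x2(1.5, 2, 2, 2), "non-negative")
})

test_that("fisher_exact_2x2 matches the enumeration oracle on random tables", {
  set.seed(17)
  for (i in 1:200) {
    tab <- as.integer(sample(0:10, 4, replace = TRUE))
    if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0 ||
        tab[1] + tab[3] == 0 || tab[2] + tab[4] == 0) next
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
  }
  # spot agreement with stats::fisher.test (same two-sided convention)
  for (tab in list(c(24, 6, 6, 50), c(3, 9, 7, 2), c(10, 10, 9, 11))) {
    expect_equal(fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4]),
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("mann_whitney_u worked examples and enumeration oracle", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p_value, oracle_mw(c(1, 2, 3), c(4, 5, 6)))

  x <- c(2, 4, 4, 7)
  expect_equal(mann_whitney_u(x, x)$p_value, 1)

  # exact mode equals brute-force labeling enumeration, with and without ties
  set.seed(19)
  for (i in 1:25) {
    x <- sample(1:6, 3, replace = TRUE)
    y <- sample(1:6, 3, replace = TRUE)
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$p_value, oracle_mw(x, y),
                 info = paste(c(x, "|", y), collapse = " "))
  }

  # normal approximation matches wilcox.test's tie-corrected,
  # continuity-corrected two-sided p
  for (i in 1:25) {
    x <- rnorm(sample(9:15, 1)) + rbinom(1, 1, 0.5)
    y <- rnorm(sample(9:15, 1))
    x[1] <- y[1]   # force a tie
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$method, "normal")
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-9)
  }
})

null_region_matrix <- function(n_bmd = 56, n_fcr = 30, n_regions = 10,
                               probs = NULL) {
  n <- n_bmd + n_fcr
  if (is.null(probs)) probs <- runif(n_regions, 0.2, 0.7)
  ind <- sapply(probs, function(p) rbinom(n, 1, p))
  dimnames(ind) <- list(sprintf("c%03d", seq_len(n)),
                        sprintf("r%02d", seq_len(n_regions)))
  regions <- data.frame(chrom = "CFA1",
                        start_mb = 3 * (seq_len(n_regions) - 1),
                        end_mb = 3 * seq_len(n_regions) - 1,
                        state = "loss", stringsAsFactors = FALSE)
  out <- list(indicator = ind,
              breed = factor(rep(c("BMD", "FCR"), c(n_bmd, n_fcr)),
                             levels = c("BMD", "FCR")),
              regions = regions)
  class(out) <- "region_matrix"
  out
}

test_that("build_region_matrix scores half-open overlap on aberrant cases", {
  segs <- data.frame(
    case_id = c("a", "b"), chrom = "CFA1", start_mb = c(47, 40),
    end_mb = c(50, 48), state = "loss", mean_log2 = -0.4,
    homozygous_flag = FALSE, n_clones = c(3L, 8L), stringsAsFactors = FALSE)
  cohort <- cohort_from_segments(segs)
  meta <- toy_meta(c("a", "b", "flat"), c("BMD", "FCR", "BMD"))
  regions <- data.frame(chrom = "CFA1", start_mb = c(48, 50, 30),
                        end_mb = c(52, 55, 35), state = "loss",
                        stringsAsFactors = FALSE)
  rm_ <- build_region_matrix(cohort, regions, meta)
  expect_equal(rownames(rm_$indicator), c("a", "b"))   # flat case excluded
  expect_equal(unname(rm_$indicator[, 1]), c(1L, 0L))  # b ends at 48: half-open
  expect_equal(unname(rm_$indicator[, 2]), c(0L, 0L))  # a ends at 50
  expect_equal(unname(rm_$indicator[, 3]), c(0L, 0L))
  expect_error(
    build_region_matrix(cohort, transform(regions, end_mb = 9999), meta),
    "off-genome")
})

test_that("permutation cutoff is monotone in alpha and needs two breeds", {
  set.seed(23)
  rm_ <- null_region_matrix()
  cut5 <- permutation_fwer(rm_, hs_config(n_permutations = 2000,
                                          rng_seed = 1))
  cut1 <- permutation_fwer(rm_, hs_config(fwer_alpha = 0.01,
                                          n_permutations = 2000,
                                          rng_seed = 1))
  expect_lte(cut1$cutoff, cut5$cutoff)
  expect_lte(cut5$cutoff, 0.05)

  one_breed <- rm_
  one_breed$breed <- factor(rep("BMD", nrow(rm_$indicator)),
                            levels = c("BMD", "FCR"))
  expect_error(permutation_fwer(one_breed), "both breeds")
  expect_error(permutation_fwer(rm_, hs_config(n_permutations = 0)))
})

test_that("cutoff for independent balanced regions tracks the Sidak form", {
  # with m independent regions the FWER cutoff should approximate
  # 1 - (1 - alpha)^(1/m); Fisher p-values on 2x2 tables are discrete and
  # conservative, which shifts the empirical min-p quantile upward by a
  # modest factor (~1.2-1.4x here), so agreement is asserted as a band
  set.seed(71)
  for (m in c(5L, 10L, 20L)) {
    ind <- sapply(seq_len(m), function(j) rbinom(86, 1, 0.5))
    dimnames(ind) <- list(sprintf("c%d", 1:86), sprintf("r%d", seq_len(m)))
    rm_ <- structure(
      list(indicator = ind,
           breed = factor(rep(c("BMD", "FCR"), c(56, 30)),
                          levels = c("BMD", "FCR")),
           regions = data.frame(chrom = "CFA1",
                                start_mb = 3 * (seq_len(m) - 1),
                                end_mb = 3 * seq_len(m) - 1, state = "loss",
                                stringsAsFactors = FALSE)),
      class = "region_matrix")
    cut <- permutation_fwer(rm_, hs_config(n_permutations = 5000,
                                           rng_seed = 100 + m))
    sidak <- 1 - (1 - 0.05)^(1 / m)
    expect_gt(cut$cutoff, 0.8 * sidak)
    expect_lt(cut$cutoff, 1.8 * sidak)
  }
})

test_that("swapping all breed labels leaves every p-value unchanged", {
  set.seed(29)
  rm_ <- null_region_matrix(n_bmd = 20, n_fcr = 15, n_regions = 6)
  assoc1 <- suppressWarnings(associate_regions(rm_, 0.05))
  rm_sw <- rm_
  rm_sw$breed <- factor(ifelse(rm_$breed == "BMD", "FCR", "BMD"),
                        levels = c("BMD", "FCR"))
  assoc2 <- suppressWarnings(associate_regions(rm_sw, 0.05))
  expect_equal(assoc1$p_value, assoc2$p_value)
})

test_that("permutation FWER is controlled over 200 null cohorts", {
  # scaled down to 1000 permutations per replicate to stay fast; the
  # acceptance run of the F2 scan itself uses the default 10,000
  set.seed(31)
  cfg <- hs_config(n_permutations = 1000)
  any_flagged <- logical(200)
  for (r in seq_len(200)) {
    rm_ <- null_region_matrix()
    cfg$rng_seed <- 1000L + r
    cut <- permutation_fwer(rm_, cfg)
    assoc <- suppressWarnings(associate_regions(rm_, cut))
    any_flagged[r] <- any(assoc$significant)
  }
  # alpha + 2 binomial SE at alpha = 0.05, n = 200: 0.05 + 2*0.0154 = 0.081
  expect_lte(mean(any_flagged), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("epidemiology report reproduces the breed contrasts", {
  set.seed(37)
  sim <- f1_run()$sim
  rep_ <- compare_epidemiology(sim$meta)
  expect_gt(rep_$age$mean_fcr, rep_$age$mean_bmd)   # 8.6 vs 7.7 by design
  expect_gt(rep_$location$internal_frac_bmd,
            rep_$location$internal_frac_fcr)        # 0.87 vs 0.48 by design
  expect_lt(rep_$location$p_value, 0.05)
  expect_gt(rep_$location$localized_frac_fcr,
            rep_$location$localized_frac_bmd)

  # identical location distributions: balanced table, p = 1
  meta <- toy_meta(sprintf("c%02d", 1:20), rep(c("BMD", "FCR"), each = 10))
  meta$tumor_location <- rep(c("one_internal_organ", "limb_only"), 10)
  rep0 <- compare_epidemiology(meta)
  expect_equal(rep0$location$p_value, 1.0)

  expect_error(compare_epidemiology(meta[meta$breed == "BMD", ]), "FCR")
})
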
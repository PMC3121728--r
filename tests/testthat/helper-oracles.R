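# Independent oracles used across test files. Each deliberately avoids the
# code path it checks.

# Fisher two-sided p by direct enumeration over all tables with the
# observed margins, probabilities from binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  x <- max(0, k - n):min(m, k)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  pr <- exp(logp)
  p_obs <- pr[x == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact Mann-Whitney two-sided p by enumeration of all group labelings,
# with U computed from pairwise comparisons (not ranks).
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  u_pairwise <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    ux <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    min(ux, n1 * n2 - ux)
  }
  u_obs <- u_pairwise(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, u_pairwise)
  mean(u_all <= u_obs + 1e-9)
}

# Brute-force maximal qualifying runs of non-neutral states.
oracle_runs <- function(states, min_clones) {
  n <- length(states)
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- states[i:j]
      if (length(unique(s)) != 1 || s[1] == "neutral") next
      maximal <- (i == 1 || states[i - 1] != s[1]) &&
                 (j == n || states[j + 1] != s[1])
      if (maximal && length(s) >= min_clones)
        runs[[length(runs) + 1]] <- c(start = i, end = j, state = s[1])
    }
  }
  runs
}

# Per-cell penetrance by per-case interval arithmetic over a toy genome.
oracle_penetrance <- function(case_segments, cell_starts) {
  n <- length(case_segments)
  counts <- sapply(cell_starts, function(p) {
    hits <- vapply(case_segments, function(segs) {
      if (is.null(segs) || nrow(segs) == 0) return(FALSE)
      any(segs$start_mb < p + 1 & segs$end_mb > p)
    }, TRUE)
    sum(hits)
  })
  round(100 * counts / n, 1)
}

# Lightweight builders ------------------------------------------------------

toy_map <- function(n, chrom = "CFA1", start = 0) {
  clone_map(data.frame(
    clone_id = sprintf("%s_c%02d", chrom, seq_len(n)),
    chrom = chrom,
    pos_mb = start + seq_len(n) - 1,
    stringsAsFactors = FALSE))
}

toy_meta <- function(case_ids, breeds) {
  data.frame(case_id = case_ids, breed = breeds, geography = "USA",
             sex = "M", age_years = 8, tumor_location = "one_internal_organ",
             stringsAsFactors = FALSE)
}

# Memoized heavy fixtures so multiple test files share one run ---------------

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, build) {
  if (!exists(key, envir = .run_cache))
    assign(key, build(), envir = .run_cache)
  get(key, envir = .run_cache)
}

f1_run <- function() cached_run("f1", function() {
  sim <- simulate_cohort(fixture("F1", seed = 42))
  list(sim = sim, cohort = call_cohort(sim$ratios, sim$map))
})

f2_run <- function() cached_run("f2", function() {
  sim <- simulate_cohort(fixture("F2", seed = 42))
  list(sim = sim, cohort = call_cohort(sim$ratios, sim$map))
})

f2_region_inventory <- function() {
  f1_regions <- data.frame(
    chrom = c("CFA16", "CFA16", "CFA11", "CFA22", "CFA26", "CFA5", "CFA31"),
    start_mb = c(47, 41.8, 43, 59, 36, 34, 20),
    end_mb = c(53, 44.2, 46, 62, 40, 37, 26),
    state = c("loss", "loss", "loss", "loss", "loss", "gain", "loss"),
    stringsAsFactors = FALSE)
  rbind(table3_regions(), f1_regions)
}

f3_run <- function() cached_run("f3", function() {
  fx <- fixture("F3", seed = 42)
  plan <- do.call(build_loh_plan, fx[setdiff(names(fx), "name")])
  peaks <- simulate_peak_table(plan, seed = 42)
  list(fx = fx, plan = plan, peaks = peaks,
       ai = score_loh(peaks),
       cases = unique(plan[, c("case_id", "group", "breed")]))
})
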
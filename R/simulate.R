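#' Declare a planted copy-number segment
#'
#' A planted segment is applied to a deterministic, exact-count subset of
#' the aberrant cases: either `carrier_count` carriers drawn from the
#' combined cohort, or per-breed counts `round(frac * n_breed_aberrant)`
#' when `carrier_frac_by_breed` is given. Carriers are chosen by seeded
#' shuffle inside [simulate_cohort()].
#'
#' @param chrom Chromosome label (CFA1..CFA38).
#' @param start_mb,end_mb Half-open extent in megabases.
#' @param state "gain", "loss" or "homozygous_loss".
#' @param carrier_count Exact combined carrier count (mutually exclusive
#'   with `carrier_frac_by_breed`).
#' @param carrier_frac_by_breed Named numeric (BMD/FCR) carrier fractions.
#' @param true_log2 Planted log2 magnitude; defaults to the fixture-level
#'   magnitudes when NA.
#' @param n_homozygous How many carriers get the homozygous-deletion
#'   magnitude instead of the single-copy one (loss segments only).
#' @return List of class `planted_segment`.
#' @export
planted_segment <- function(chrom, start_mb, end_mb,
                            state = c("loss", "gain", "homozygous_loss"),
                            carrier_count = NULL,
                            carrier_frac_by_breed = NULL,
                            true_log2 = NA_real_,
                            n_homozygous = 0L) {
  state <- match.arg(state)
  if (end_mb <= start_mb) stop("end_mb must exceed start_mb", call. = FALSE)
  lens <- chrom_lengths(include_x = TRUE)
  len <- lens$length_mb[match(chrom, lens$chrom)]
  if (is.na(len)) stop("unknown chromosome: ", chrom, call. = FALSE)
  if (start_mb < 0 || end_mb > len)
    stop("planted segment off-chromosome: ", chrom, call. = FALSE)
  if (is.null(carrier_count) == is.null(carrier_frac_by_breed))
    stop("give exactly one of carrier_count or carrier_frac_by_breed",
         call. = FALSE)
  if (!is.null(carrier_frac_by_breed)) {
    if (!all(sort(names(carrier_frac_by_breed)) == c("BMD", "FCR")) ||
        any(carrier_frac_by_breed < 0) || any(carrier_frac_by_breed > 1))
      stop("carrier_frac_by_breed must name BMD and FCR with values in [0,1]",
           call. = FALSE)
  }
  out <- list(chrom = chrom, start_mb = start_mb, end_mb = end_mb,
              state = state, carrier_count = carrier_count,
              carrier_frac_by_breed = carrier_frac_by_breed,
              true_log2 = true_log2, n_homozygous = as.integer(n_homozygous))
  class(out) <- "planted_segment"
  out
}

#' Declare a synthetic aCGH cohort
#'
#' The generator's statistical world: per-breed aberrant/flat case counts,
#' planted recurrent segments, Gaussian probe noise, a negative-binomial
#' background-CNA count model with gamma segment sizes, and per-breed
#' clinical models (age, anatomical location, geography, sex).
#'
#' Default planted magnitudes are +/-0.45 log2 for single-copy events
#' (tumor:reference ratios of about 1.37 and 0.73, i.e. single-copy
#' change at 63-73% tumor content) and -1.2 for homozygous deletions.
#'
#' @param name Fixture name.
#' @param n_aberrant,n_flat Named integer vectors (BMD, FCR).
#' @param planted List of [planted_segment()]s.
#' @param noise_sd Per-clone Gaussian noise sd in log2 units.
#' @param background NULL, or list with `mean`, `size` (negative-binomial
#'   count model over background segments per aberrant case), `p_loss`,
#'   and gamma size models `loss_shape`, `loss_scale`, `gain_shape`,
#'   `gain_scale` (Mb).
#' @param magnitudes Named numeric: gain, loss, homozygous_loss log2 values.
#' @param age_model Per-breed list(mean, sd, min, max) for truncated-normal
#'   ages.
#' @param location_model Per-breed probability vectors over the five
#'   anatomical categories.
#' @param geography_model Per-breed probability of France.
#' @param sex_model Per-breed probability of male.
#' @param seed RNG seed; identical (spec, seed) gives identical output.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(name,
                         n_aberrant = c(BMD = 56L, FCR = 30L),
                         n_flat = c(BMD = 0L, FCR = 0L),
                         planted = list(),
                         noise_sd = 0.05,
                         background = NULL,
                         magnitudes = c(gain = 0.45, loss = -0.45,
                                        homozygous_loss = -1.2),
                         age_model = list(
                           BMD = list(mean = 7.7, sd = 1.9, min = 2, max = 12),
                           FCR = list(mean = 8.6, sd = 1.7, min = 5, max = 12)),
                         location_model = list(
                           BMD = c(one_internal_organ = 0.362,
                                   multiple_internal_organs = 0.508,
                                   lymph_node_only = 0.065,
                                   limb_only = 0.032, skin_only = 0.033),
                           FCR = c(one_internal_organ = 0.224,
                                   multiple_internal_organs = 0.256,
                                   lymph_node_only = 0.059,
                                   limb_only = 0.384, skin_only = 0.077)),
                         geography_model = c(BMD = 33 / 101, FCR = 0),
                         sex_model = c(BMD = 33 / 68, FCR = 20 / 45),
                         seed = 42L) {
  stopifnot(all(c("BMD", "FCR") %in% names(n_aberrant)),
            all(c("BMD", "FCR") %in% names(n_flat)),
            noise_sd >= 0)
  for (p in planted) stopifnot(inherits(p, "planted_segment"))
  out <- list(name = name, n_aberrant = n_aberrant, n_flat = n_flat,
              planted = planted, noise_sd = noise_sd,
              background = background, magnitudes = magnitudes,
              age_model = age_model, location_model = location_model,
              geography_model = geography_model, sex_model = sex_model,
              seed = as.integer(seed))
  class(out) <- "fixture_spec"
  out
}

# truncated-normal draw by rejection; vectorized over n
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

overlaps_any <- function(blocked, chrom, start, end) {
  b <- blocked[blocked$chrom == chrom, , drop = FALSE]
  nrow(b) > 0 && any(b$start_mb < end & b$end_mb > start)
}

#' Simulate an aCGH cohort from a fixture spec
#'
#' Builds the 1-Mb autosome clone map, plants segments into exact-count
#' carrier subsets, adds per-case background CNAs placed uniformly at
#' random while avoiding all planted loci (1 Mb margin) and keeping at
#' least a 3 Mb gap between a case's own segments (so the moving-median
#' smoother never merges or bridges them), and finally adds N(0, noise_sd)
#' per clone. Flat cases are pure noise.
#'
#' @param spec A [fixture_spec()].
#' @return List: `map` (clone_map), `ratios` (clones x cases matrix),
#'   `meta` (clinical metadata data.frame), `truth` (planted segments per
#'   case, for tests).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  map <- make_grid_map()
  case_tab <- do.call(rbind, lapply(c("BMD", "FCR"), function(b) {
    n_ab <- spec$n_aberrant[[b]]; n_fl <- spec$n_flat[[b]]
    if (n_ab + n_fl == 0) return(NULL)
    data.frame(
      case_id = sprintf("%s_%03d", b, seq_len(n_ab + n_fl)),
      breed = b,
      aberrant = rep(c(TRUE, FALSE), c(n_ab, n_fl)),
      stringsAsFactors = FALSE
    )
  }))
  n_cases <- nrow(case_tab)
  ab_ids <- case_tab$case_id[case_tab$aberrant]
  signal <- matrix(0, nrow = nrow(map), ncol = n_cases,
                   dimnames = list(map$clone_id, case_tab$case_id))
  clone_ix <- function(chrom, start, end)
    which(map$chrom == chrom & map$pos_mb >= start & map$pos_mb < end)

  truth <- list()
  for (p in spec$planted) {
    if (!is.null(p$carrier_count)) {
      if (p$carrier_count > length(ab_ids))
        stop("carrier_count exceeds aberrant cohort size", call. = FALSE)
      carriers <- sample(ab_ids, p$carrier_count)
    } else {
      carriers <- unlist(lapply(c("BMD", "FCR"), function(b) {
        pool <- case_tab$case_id[case_tab$aberrant & case_tab$breed == b]
        sample(pool, round(p$carrier_frac_by_breed[[b]] * length(pool)))
      }), use.names = FALSE)
    }
    mag <- if (!is.na(p$true_log2)) p$true_log2
           else spec$magnitudes[[p$state]]
    hom <- character(0)
    if (p$n_homozygous > 0) {
      hom <- carriers[seq_len(min(p$n_homozygous, length(carriers)))]
    }
    ix <- clone_ix(p$chrom, p$start_mb, p$end_mb)
    for (cid in carriers) {
      v <- if (cid %in% hom) spec$magnitudes[["homozygous_loss"]] else mag
      signal[ix, cid] <- v
    }
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = p$chrom, start_mb = p$start_mb, end_mb = p$end_mb,
      state = sub("homozygous_", "", p$state),
      carrier = carriers,
      homozygous = carriers %in% hom,
      stringsAsFactors = FALSE
    )
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL

  if (!is.null(spec$background)) {
    bg <- spec$background
    lens <- chrom_lengths(include_x = FALSE)
    planted_block <- if (length(spec$planted)) {
      data.frame(
        chrom = vapply(spec$planted, `[[`, "", "chrom"),
        start_mb = vapply(spec$planted, `[[`, 0, "start_mb") - 3,
        end_mb = vapply(spec$planted, `[[`, 0, "end_mb") + 3,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(chrom = character(), start_mb = numeric(),
                 end_mb = numeric(), stringsAsFactors = FALSE)
    }
    planted_per_case <- if (is.null(truth)) rep(0L, length(ab_ids)) else
      tabulate(factor(truth$carrier, levels = ab_ids), nbins = length(ab_ids))
    for (ci in seq_along(ab_ids)) {
      cid <- ab_ids[ci]
      n_bg <- stats::rnbinom(1, size = bg$size, mu = bg$mean)
      if (planted_per_case[ci] == 0 && n_bg == 0) n_bg <- 1L
      if (n_bg == 0) next
      states <- ifelse(stats::runif(n_bg) < bg$p_loss, "loss", "gain")
      sizes <- ifelse(states == "loss",
                      stats::rgamma(n_bg, shape = bg$loss_shape,
                                    scale = bg$loss_scale),
                      stats::rgamma(n_bg, shape = bg$gain_shape,
                                    scale = bg$gain_scale))
      sizes <- pmax(3, round(sizes))
      ord <- order(-sizes)
      states <- states[ord]; sizes <- sizes[ord]
      blocked <- planted_block
      for (k in seq_len(n_bg)) {
        sz <- min(sizes[k], max(lens$length_mb))
        fits <- lens[lens$length_mb >= sz, , drop = FALSE]
        for (try in seq_len(400L)) {
          chrom <- sample(fits$chrom, 1, prob = fits$length_mb)
          clen <- fits$length_mb[fits$chrom == chrom]
          start <- sample.int(clen - sz + 1L, 1) - 1L
          if (!overlaps_any(blocked, chrom, start, start + sz)) {
            ix <- clone_ix(chrom, start, start + sz)
            signal[ix, cid] <- spec$magnitudes[[states[k]]]
            blocked <- rbind(blocked, data.frame(
              chrom = chrom, start_mb = start - 3, end_mb = start + sz + 3,
              stringsAsFactors = FALSE))
            break
          }
        }
        # an unplaced segment (saturated genome) is skipped, not retried
      }
    }
  }

  noise <- matrix(stats::rnorm(length(signal), 0, spec$noise_sd),
                  nrow = nrow(signal))
  ratios <- signal + noise
  dimnames(ratios) <- dimnames(signal)

  meta <- case_tab[, c("case_id", "breed"), drop = FALSE]
  meta$geography <- ifelse(
    stats::runif(n_cases) < spec$geography_model[meta$breed],
    "France", "USA")
  meta$sex <- ifelse(stats::runif(n_cases) < spec$sex_model[meta$breed],
                     "M", "F")
  meta$age_years <- NA_real_
  meta$tumor_location <- NA_character_
  for (b in c("BMD", "FCR")) {
    bi <- which(meta$breed == b)
    am <- spec$age_model[[b]]
    meta$age_years[bi] <- round(
      rtruncnorm(length(bi), am$mean, am$sd, am$min, am$max), 1)
    lm <- spec$location_model[[b]]
    meta$tumor_location[bi] <- sample(names(lm), length(bi), replace = TRUE,
                                      prob = lm)
  }
  meta <- validate_case_meta(meta)
  # preserve simulation order, not alphabetical
  meta <- meta[match(case_tab$case_id, meta$case_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(map = map, ratios = ratios, meta = meta, truth = truth)
}

#' Simulate a paired tumor/blood microsatellite peak table
#'
#' Realizes an LOH plan: for every (case, marker) row, a heterozygous
#' blood genotype gets two equal-area peaks (AR(blood) = 1) and a tumor
#' genotype whose peak areas realize the planted allelic imbalance
#' exactly; a homozygous blood genotype is emitted as a single allele
#' (uninformative downstream).
#'
#' @param plan data.frame: case_id, marker_id, blood_het (logical),
#'   planted_ai (positive; ignored for homozygous rows).
#' @param seed RNG seed for sizes/areas.
#' @return Peak table data.frame (see [read_peak_table()]).
#' @export
simulate_peak_table <- function(plan, seed = 42L) {
  stopifnot(all(c("case_id", "marker_id", "blood_het", "planted_ai") %in%
                  names(plan)))
  if (any(plan$blood_het & (is.na(plan$planted_ai) | plan$planted_ai <= 0)))
    stop("planted AI must be positive", call. = FALSE)
  set.seed(seed)
  marker_ids <- sort(unique(plan$marker_id))
  base_size <- stats::setNames(
    150 + 12 * seq_along(marker_ids), marker_ids)
  rows <- vector("list", 2L * nrow(plan))
  for (i in seq_len(nrow(plan))) {
    mk <- plan$marker_id[i]
    a1 <- base_size[[mk]]
    a2 <- a1 + 2 * sample(1:5, 1)
    if (plan$blood_het[i]) {
      blood_area <- round(stats::runif(1, 400, 900), 1)
      tumor_total <- round(stats::runif(1, 800, 1800), 1)
      ai <- plan$planted_ai[i]
      t2 <- tumor_total / (1 + ai)
      rows[[2 * i - 1]] <- data.frame(
        case_id = plan$case_id[i], marker_id = mk, sample_type = "blood",
        allele1_size = a1, allele1_area = blood_area,
        allele2_size = a2, allele2_area = blood_area,
        stringsAsFactors = FALSE)
      rows[[2 * i]] <- data.frame(
        case_id = plan$case_id[i], marker_id = mk, sample_type = "tumor",
        allele1_size = a1, allele1_area = ai * t2,
        allele2_size = a2, allele2_area = t2,
        stringsAsFactors = FALSE)
    } else {
      area_b <- round(stats::runif(1, 700, 1600), 1)
      area_t <- round(stats::runif(1, 700, 1600), 1)
      rows[[2 * i - 1]] <- data.frame(
        case_id = plan$case_id[i], marker_id = mk, sample_type = "blood",
        allele1_size = a1, allele1_area = area_b,
        allele2_size = NA_real_, allele2_area = NA_real_,
        stringsAsFactors = FALSE)
      rows[[2 * i]] <- data.frame(
        case_id = plan$case_id[i], marker_id = mk, sample_type = "tumor",
        allele1_size = a1, allele1_area = area_t,
        allele2_size = NA_real_, allele2_area = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  as_peak_table(do.call(rbind, rows))
}

#' Build the LOH plan for a synthetic paired cohort
#'
#' @param n_paired Named integer vector (BMD, FCR) of paired cases, each
#'   guaranteed at least one informative marker carrying planted LOH.
#' @param n_additional Additional paired cases without aCGH-visible loss.
#' @param n_additional_loh How many of the additional cases carry planted
#'   LOH at one or more markers.
#' @param markers Marker panel data.frame (marker_id, chrom, pos_mb).
#' @param p_het Per-marker probability of a heterozygous (informative)
#'   germline.
#' @param seed RNG seed.
#' @return data.frame plan for [simulate_peak_table()], plus columns
#'   `group` ("paired"/"additional") and `breed`.
#' @export
build_loh_plan <- function(n_paired = c(BMD = 26L, FCR = 20L),
                           n_additional = 11L, n_additional_loh = 6L,
                           markers = cfa11_marker_panel(),
                           p_het = 0.75, seed = 42L) {
  set.seed(seed)
  paired_ids <- c(sprintf("BMD_L%02d", seq_len(n_paired[["BMD"]])),
                  sprintf("FCR_L%02d", seq_len(n_paired[["FCR"]])))
  paired_breed <- rep(c("BMD", "FCR"), n_paired[c("BMD", "FCR")])
  add_ids <- sprintf("EXT_L%02d", seq_len(n_additional))
  loh_ai <- function(n) {
    up <- stats::runif(n) < 0.5
    ifelse(up, stats::runif(n, 1.6, 2.8), stats::runif(n, 0.4, 0.62))
  }
  plan_case <- function(cid, with_loh) {
    het <- stats::runif(nrow(markers)) < p_het
    if (!any(het)) het[ceiling(nrow(markers) / 2)] <- TRUE
    ai <- stats::runif(nrow(markers), 0.85, 1.18)
    if (with_loh) {
      het_ix <- which(het)
      n_loh <- min(length(het_ix), sample(1:3, 1))
      loh_ix <- sample(het_ix, n_loh)
      ai[loh_ix] <- loh_ai(n_loh)
    }
    ai[!het] <- NA_real_
    data.frame(case_id = cid, marker_id = markers$marker_id,
               blood_het = het, planted_ai = ai, stringsAsFactors = FALSE)
  }
  plans <- c(
    lapply(seq_along(paired_ids), function(i) {
      p <- plan_case(paired_ids[i], with_loh = TRUE)
      p$group <- "paired"; p$breed <- paired_breed[i]; p
    }),
    lapply(seq_len(n_additional), function(i) {
      p <- plan_case(add_ids[i], with_loh = i <= n_additional_loh)
      p$group <- "additional"; p$breed <- "BMD"; p
    })
  )
  do.call(rbind, plans)
}

#' Synthetic seven-marker panel flanking the CFA11 CDKN2A/B region
#'
#' The published marker names and positions live in supplementary
#' material that is not reproduced here; this synthetic stand-in panel
#' spans the recurrently deleted CFA11 interval at ~41.5-47.5 Mb.
#'
#' @return data.frame: marker_id, chrom, pos_mb.
#' @export
cfa11_marker_panel <- function() {
  data.frame(
    marker_id = sprintf("MS11_%02d", 1:7),
    chrom = "CFA11",
    pos_mb = c(41.5, 42.5, 43.5, 44.5, 45.5, 46.5, 47.5),
    stringsAsFactors = FALSE
  )
}

#' Frozen fixtures
#'
#' Three cohorts whose planted structure encodes the published cohort
#' frequencies:
#'
#' * `F1` "cohort profile": 104 cases (56 BMD + 30 FCR aberrant, 15 BMD +
#'   3 FCR flat). Seven recurrent segments planted with exact combined
#'   carrier counts out of 86 (CFA16 47-53 loss in 74; CFA16 41.8-44.2
#'   loss in 73; CFA11 43-46 loss in 54, two of them homozygous; CFA22
#'   59-62 loss in 48; CFA26 36-40 loss in 35; CFA5 34-37 gain in 23;
#'   CFA31 20-26 loss in 53). Background CNA counts follow a
#'   negative-binomial model parameterized so total per-case CNA counts
#'   target mean 30.7, sd 17.6, with gamma segment sizes targeting mean
#'   32.5 (loss) and 23.1 Mb (gain).
#' * `F2` "breed differential": 56 BMD + 30 FCR aberrant; the 13
#'   breed-associated loss regions planted at carrier fractions 0.80
#'   (FCR) vs 0.10 (BMD); the seven F1 regions re-planted breed-balanced
#'   as decoys; same background model.
#' * `F3` "LOH cohort": returned as a list with the LOH plan arguments
#'   (46 paired cases = 26 BMD + 20 FCR, each with planted LOH at >= 1
#'   informative marker; 11 additional cases of which 6 carry LOH).
#'
#' @param name "F1", "F2" or "F3".
#' @param seed RNG seed stamped into the spec (default 42).
#' @return A `fixture_spec` (F1, F2) or a list of LOH-plan arguments (F3).
#' @export
fixture <- function(name = c("F1", "F2", "F3"), seed = 42L) {
  name <- match.arg(name)
  n_ab <- 86L
  f1_counts <- c(74L, 73L, 54L, 48L, 35L, 23L, 53L)
  f1_regions <- data.frame(
    chrom = c("CFA16", "CFA16", "CFA11", "CFA22", "CFA26", "CFA5", "CFA31"),
    start_mb = c(47, 41.8, 43, 59, 36, 34, 20),
    end_mb = c(53, 44.2, 46, 62, 40, 37, 26),
    state = c("loss", "loss", "loss", "loss", "loss", "gain", "loss"),
    stringsAsFactors = FALSE
  )
  # background model from the published cohort summary moments:
  # total counts mean 30.7 sd 17.6; count composition 16.7 losses / 13.9
  # gains; sizes mean 32.5 sd 21 (loss), 23.1 sd 22.6 (gain)
  p <- f1_counts / n_ab
  mu_bg <- 30.7 - sum(p)
  var_bg <- 17.6^2 - sum(p * (1 - p))
  bg <- list(
    mean = mu_bg,
    size = mu_bg^2 / (var_bg - mu_bg),
    p_loss = (16.7 - sum(p[f1_regions$state == "loss"])) /
      (30.6 - sum(p)),
    loss_shape = (32.5 / 21)^2, loss_scale = 21^2 / 32.5,
    gain_shape = (23.1 / 22.6)^2, gain_scale = 22.6^2 / 23.1
  )
  if (name == "F1") {
    planted <- lapply(seq_len(nrow(f1_regions)), function(i) {
      planted_segment(f1_regions$chrom[i], f1_regions$start_mb[i],
                      f1_regions$end_mb[i], f1_regions$state[i],
                      carrier_count = f1_counts[i],
                      n_homozygous = if (f1_regions$chrom[i] == "CFA11") 2L
                                     else 0L)
    })
    return(fixture_spec("F1",
                        n_aberrant = c(BMD = 56L, FCR = 30L),
                        n_flat = c(BMD = 15L, FCR = 3L),
                        planted = planted, background = bg, seed = seed))
  }
  if (name == "F2") {
    t3 <- table3_regions()
    # planted lesions must span >= 3 grid clones to be recoverable by the
    # moving-median smoother; the association scan still tests the
    # unpadded region coordinates (real deletions extend beyond the
    # reported significant interval)
    lens <- chrom_lengths(include_x = FALSE)
    planted <- c(
      lapply(seq_len(nrow(t3)), function(i) {
        s <- t3$start_mb[i]; e <- t3$end_mb[i]
        clen <- lens$length_mb[lens$chrom == t3$chrom[i]]
        while (e - s < 3) {
          if (e < clen) e <- e + 1 else s <- s - 1
        }
        planted_segment(t3$chrom[i], s, e, "loss",
                        carrier_frac_by_breed = c(BMD = 0.10, FCR = 0.80))
      }),
      lapply(seq_len(nrow(f1_regions)), function(i) {
        fr <- f1_counts[i] / n_ab
        planted_segment(f1_regions$chrom[i], f1_regions$start_mb[i],
                        f1_regions$end_mb[i], f1_regions$state[i],
                        carrier_frac_by_breed = c(BMD = fr, FCR = fr))
      })
    )
    # F2 exists to exercise breed association and the breed PCA component;
    # its declared structure is the 13 differential regions plus balanced
    # decoys. Background is kept light so the breed contrast (between-group
    # eigenvalue ~ n_b n_f / n^2 * |delta|^2 ~ 11) dominates the top of the
    # scree instead of random long-segment covariance; region indicators
    # are unaffected either way because background avoids planted loci.
    bg_f2 <- list(mean = 6, size = 2,
                  p_loss = bg$p_loss,
                  loss_shape = bg$loss_shape, loss_scale = bg$loss_scale,
                  gain_shape = bg$gain_shape, gain_scale = bg$gain_scale)
    return(fixture_spec("F2",
                        n_aberrant = c(BMD = 56L, FCR = 30L),
                        n_flat = c(BMD = 0L, FCR = 0L),
                        planted = planted, background = bg_f2, seed = seed))
  }
  list(name = "F3",
       n_paired = c(BMD = 26L, FCR = 20L),
       n_additional = 11L, n_additional_loh = 6L,
       markers = cfa11_marker_panel(), p_het = 0.75, seed = as.integer(seed))
}

#' The thirteen breed-associated loss regions
#'
#' Region inventory used by the breed-differential fixture and as the
#' default explicit region file for association scans.
#'
#' @return data.frame: chrom, start_mb, end_mb, state.
#' @export
table3_regions <- function() {
  data.frame(
    chrom = paste0("CFA", c(10, 15, 15, 15, 22, 22, 22, 25, 25, 30, 30,
                            34, 36)),
    start_mb = c(25, 19, 29, 52, 0, 31, 54, 9, 14, 26, 30, 45, 0),
    end_mb = c(30, 22, 49, 54, 12, 48, 57, 12, 18, 28, 33, 46, 20),
    state = "loss",
    stringsAsFactors = FALSE
  )
}
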
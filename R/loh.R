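#' Allelic ratio from two peak areas
#'
#' AR = (peak area 1) / (peak area 2), with peak 1 the shorter allele
#' under the package's canonical allele ordering (applied identically to
#' tumor and blood of the same marker, so the orientation cancels in the
#' allelic imbalance).
#'
#' @param area1 Area of the shorter allele's peak (non-negative).
#' @param area2 Area of the longer allele's peak (must be positive).
#' @return area1 / area2.
#' @export
allelic_ratio <- function(area1, area2) {
  if (any(area2 <= 0))
    stop("allelic ratio undefined: denominator peak area is zero",
         call. = FALSE)
  if (any(area1 < 0)) stop("peak areas must be non-negative", call. = FALSE)
  area1 / area2
}

#' Allelic imbalance
#'
#' AI = AR(tumor) / AR(blood). Values far from 1 indicate loss of one
#' allele in the tumor.
#'
#' @param ar_tumor Tumor allelic ratio.
#' @param ar_blood Blood (germline) allelic ratio; must be positive.
#' @return ar_tumor / ar_blood.
#' @export
allelic_imbalance <- function(ar_tumor, ar_blood) {
  if (any(ar_blood <= 0))
    stop("allelic imbalance undefined: blood AR is zero", call. = FALSE)
  ar_tumor / ar_blood
}

#' LOH call from an allelic imbalance value
#'
#' Deletion (LOH) is called when AI >= `ai_upper` (default 1.5) or
#' AI <= `ai_lower` (default 0.67); both boundaries inclusive.
#'
#' @param ai Allelic imbalance value(s), finite and positive.
#' @param cfg An [hs_config()].
#' @return Logical vector.
#' @export
call_loh <- function(ai, cfg = hs_config()) {
  stopifnot(all(is.finite(ai)), all(ai > 0))
  ai >= cfg$ai_upper | ai <= cfg$ai_lower
}

#' Is a blood genotype informative?
#'
#' A marker is informative for LOH when the germline is heterozygous with
#' two distinct allele sizes, both peaks observed, and a minor/major area
#' ratio of at least 0.2 (a guard against stutter artifacts masquerading
#' as a second allele).
#'
#' @param allele1_size,allele2_size Allele sizes (bp); NA or equal sizes
#'   mean homozygous.
#' @param allele1_area,allele2_area Peak areas.
#' @param min_minor_frac Minor/major area guard (default 0.2).
#' @return Logical vector.
#' @export
assess_informative <- function(allele1_size, allele2_size,
                               allele1_area, allele2_area,
                               min_minor_frac = 0.2) {
  het <- !is.na(allele1_size) & !is.na(allele2_size) &
    allele2_size != allele1_size
  ok_area <- !is.na(allele1_area) & !is.na(allele2_area) &
    allele1_area > 0 & allele2_area > 0
  ratio <- pmin(allele1_area, allele2_area) /
    pmax(allele1_area, allele2_area)
  het & ok_area & !is.na(ratio) & ratio >= min_minor_frac
}

#' Score allelic imbalance for every paired (case, marker)
#'
#' Joins tumor and blood rows of a peak table, assesses blood
#' informativeness, and computes AR(tumor), AR(blood), AI and the LOH call
#' for informative markers. Uninformative or unpaired markers are retained
#' with NA statistics and `loh_call = FALSE`.
#'
#' @param peaks Peak table (see [read_peak_table()]).
#' @param cfg An [hs_config()].
#' @return data.frame: case_id, marker_id, informative, ar_tumor,
#'   ar_blood, ai, loh_call.
#' @export
score_loh <- function(peaks, cfg = hs_config()) {
  peaks <- as_peak_table(peaks)
  blood <- peaks[peaks$sample_type == "blood", , drop = FALSE]
  tumor <- peaks[peaks$sample_type == "tumor", , drop = FALSE]
  key_b <- paste(blood$case_id, blood$marker_id, sep = "\r")
  key_t <- paste(tumor$case_id, tumor$marker_id, sep = "\r")
  m <- match(key_b, key_t)
  out <- data.frame(
    case_id = blood$case_id,
    marker_id = blood$marker_id,
    informative = assess_informative(blood$allele1_size, blood$allele2_size,
                                     blood$allele1_area, blood$allele2_area),
    ar_tumor = NA_real_, ar_blood = NA_real_, ai = NA_real_,
    loh_call = FALSE,
    stringsAsFactors = FALSE
  )
  paired <- out$informative & !is.na(m)
  if (any(paired)) {
    tb <- tumor[m[paired], , drop = FALSE]
    bb <- blood[paired, , drop = FALSE]
    usable <- tb$allele2_area > 0 & bb$allele2_area > 0
    idx <- which(paired)[usable]
    tb <- tb[usable, , drop = FALSE]
    bb <- bb[usable, , drop = FALSE]
    out$ar_tumor[idx] <- allelic_ratio(tb$allele1_area, tb$allele2_area)
    out$ar_blood[idx] <- allelic_ratio(bb$allele1_area, bb$allele2_area)
    out$ai[idx] <- allelic_imbalance(out$ar_tumor[idx], out$ar_blood[idx])
    out$loh_call[idx] <- call_loh(out$ai[idx], cfg)
  }
  # markers with no tumor pair are not scorable
  out$informative[is.na(m)] <- FALSE
  out
}

#' Per-case region LOH summary
#'
#' A case shows region LOH when at least one informative marker of the
#' panel carries an LOH call. Cases with no informative marker are
#' indeterminate (`region_loh = NA`) and are excluded from cohort LOH
#' percentages rather than counted as negative.
#'
#' @param ai_results Output of [score_loh()] (optionally pre-filtered to a
#'   marker panel).
#' @param region_label Label stamped on the summary rows.
#' @return data.frame: case_id, region, n_informative, n_loh, region_loh.
#' @export
summarize_region <- function(ai_results, region_label = "region") {
  by_case <- split(ai_results, ai_results$case_id)
  rows <- lapply(by_case, function(d) {
    n_inf <- sum(d$informative)
    n_loh <- sum(d$loh_call[d$informative])
    data.frame(
      case_id = d$case_id[1],
      region = region_label,
      n_informative = n_inf,
      n_loh = n_loh,
      region_loh = if (n_inf == 0) NA else n_loh >= 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$region_loh)))
    warning("case(s) with no informative marker: region LOH indeterminate")
  rownames(out) <- NULL
  out[order(out$case_id), , drop = FALSE]
}
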
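#' Case x interval aberration-state matrix
#'
#' Codes each 1-Mb grid cell as -1 (overlapped by a loss segment), +1
#' (gain) or 0 (neutral) per aberrant case. One case's segments never
#' overlap, so the coding is unambiguous. CFAX is excluded by default,
#' matching the penetrance analyses.
#'
#' @param cohort A `cohort_call`.
#' @param map A `clone_map`.
#' @param include_x Include CFAX cells (default FALSE).
#' @return Integer matrix (aberrant cases x cells) with dimnames.
#' @export
build_state_matrix <- function(cohort, map, include_x = FALSE) {
  ids <- cohort$aberrant_ids
  cells <- as.data.frame(map)[, c("chrom", "pos_mb")]
  if (!include_x) cells <- cells[cells$chrom != "CFAX", , drop = FALSE]
  n_cells <- nrow(cells)
  cell_ix <- split(seq_len(n_cells), cells$chrom)
  mat <- matrix(0L, nrow = length(ids), ncol = n_cells,
                dimnames = list(ids, sprintf("%s:%g", cells$chrom,
                                             cells$pos_mb)))
  segs <- cohort$segments
  segs <- segs[segs$case_id %in% ids, , drop = FALSE]
  for (k in seq_len(nrow(segs))) {
    ix <- cell_ix[[segs$chrom[k]]]
    if (is.null(ix)) next
    hit <- cells$pos_mb[ix] < segs$end_mb[k] &
           cells$pos_mb[ix] + 1 > segs$start_mb[k]
    mat[segs$case_id[k], ix[hit]] <- if (segs$state[k] == "gain") 1L else -1L
  }
  mat
}

#' PCA of the aberration-state matrix
#'
#' Columns are centered but not scaled (all cells share the -1/0/+1
#' scale). Eigenvalues are squared singular values divided by (n - 1), so
#' they sum to the total variance of the centered matrix. Each component's
#' sign is canonicalized by making its largest-magnitude loading positive.
#'
#' @param mat Case x cell matrix from [build_state_matrix()].
#' @param n_components Components to retain (truncated to the matrix rank
#'   with a warning if larger).
#' @return List of class `hs_pca`: `eigenvalues` (all), `scores` (cases x
#'   retained components), `loadings`, `n_components`.
#' @export
run_pca <- function(mat, n_components = 10L) {
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("PCA needs at least 2 cases and 2 intervals", call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank) {
    warning("n_components exceeds rank; truncated to ", rank)
    n_components <- rank
  }
  keep <- seq_len(n_components)
  flip <- vapply(keep, function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, keep, drop = FALSE], 2, flip, `*`)
  out <- list(eigenvalues = ev, scores = scores, loadings = loadings,
              n_components = n_components)
  class(out) <- "hs_pca"
  out
}

#' Test component scores against a two-level grouping
#'
#' Mann-Whitney U test of each retained component's scores between the two
#' groups (e.g. geography for substructure, breed or tumor location for
#' global aberration differences).
#'
#' @param pca An `hs_pca`.
#' @param grouping Vector (two levels after dropping NA) aligned to the
#'   score rows.
#' @param components Component indices to test (default first 5).
#' @return data.frame: component, U, p_value.
#' @export
component_association <- function(pca, grouping, components = 1:5) {
  grouping <- as.factor(grouping)
  stopifnot(length(grouping) == nrow(pca$scores))
  keep <- !is.na(grouping)
  grouping <- droplevels(grouping[keep])
  if (nlevels(grouping) != 2)
    stop("grouping must have exactly two levels", call. = FALSE)
  components <- components[components <= ncol(pca$scores)]
  rows <- lapply(components, function(j) {
    s <- pca$scores[keep, j]
    mw <- mann_whitney_u(s[grouping == levels(grouping)[1]],
                         s[grouping == levels(grouping)[2]])
    data.frame(component = j, U = mw$U, p_value = mw$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
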
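#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) squared deviation between two matched point sets. The SVD
#' reflection branch is corrected so the returned rotation always has
#' determinant +1.
#'
#' @param mobile,reference `K x 3` coordinate matrices (nm), `K >= 3`,
#'   matched row by row.
#' @param weights Optional non-negative weights of length K (default
#'   uniform); must not all be zero.
#' @return A list of class `superposition` with elements `rotation` (3 x 3,
#'   det +1), `translation` (length-3, nm; the fit maps `p` to
#'   `rotation %*% p + translation`), and `rmsd_after_fit` (nm).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  k <- nrow(mobile)
  if (k < 3L || nrow(reference) != k || ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("kabsch_fit(): need matched K x 3 coordinate sets with K >= 3", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0) {
    stop("kabsch_fit(): weights must be non-negative, length K, not all zero", call. = FALSE)
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  pm <- sweep(mobile, 2L, cm)
  pr <- sweep(reference, 2L, cr)
  # collinearity check on the mobile set: need at least rank 2
  sv_m <- svd(pm * sqrt(w), nu = 0L, nv = 0L)$d
  if (sv_m[2L] < 1e-10 * max(sv_m[1L], 1e-300)) {
    stop("kabsch_fit(): degenerate (collinear) point set", call. = FALSE)
  }
  h <- crossprod(pm * w, pr) # 3x3 weighted covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- pm %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - pr)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cr - rot %*% cm), rmsd_after_fit = rmsd),
    class = "superposition"
  )
}

apply_superposition <- function(fit, coords) {
  sweep(coords %*% t(fit$rotation), 2L, fit$translation, `+`)
}

#' Superpose every frame of an ensemble onto a reference
#'
#' Each frame gets its own [kabsch_fit()] computed over `fit_selection`
#' against the reference; the resulting rigid transform is applied to all
#' atoms of the frame. This is the standard preparation before RMSF and
#' DCCM calculations (conventionally fitting on the conserved region).
#'
#' @param x An [ensemble()].
#' @param fit_selection Integer atom indices used for the superposition.
#' @param reference `A x 3` matrix (full roster, nm); defaults to frame 1.
#' @param weights Optional weights over `fit_selection`.
#' @return A new, fitted [ensemble()].
#' @export
fit_ensemble <- function(x, fit_selection, reference = NULL, weights = NULL) {
  stopifnot(inherits(x, "ensemble"))
  if (length(fit_selection) == 0L) stop("fit_ensemble(): empty fit selection", call. = FALSE)
  if (is.null(reference)) reference <- frame_coords(x, 1L)
  ref_sel <- reference[fit_selection, , drop = FALSE]
  out <- x$coords
  for (f in seq_len(n_frames(x))) {
    fr <- matrix(x$coords[f, , ], ncol = 3L)
    fit <- kabsch_fit(fr[fit_selection, , drop = FALSE], ref_sel, weights)
    out[f, , ] <- apply_superposition(fit, fr)
  }
  ensemble(out, x$atoms, times = x$times, label = x$label)
}

#' Coordinate RMSD between a frame and a reference
#'
#' Root-mean-square per-atom displacement over a selection. No fitting is
#' performed here; superpose first with [fit_ensemble()] if desired.
#'
#' @param frame,reference `A x 3` coordinate matrices (nm).
#' @param selection Integer atom indices (non-empty).
#' @return RMSD in nm.
#' @export
coordinate_rmsd <- function(frame, reference, selection = seq_len(nrow(frame))) {
  if (length(selection) == 0L) stop("coordinate_rmsd(): empty selection", call. = FALSE)
  f <- as.matrix(frame)[selection, , drop = FALSE]
  r <- as.matrix(reference)[selection, , drop = FALSE]
  if (!all(dim(f) == dim(r))) stop("coordinate_rmsd(): mismatched dimensions", call. = FALSE)
  sqrt(mean(rowSums((f - r)^2)))
}

#' Distance-matrix RMSD between a frame and a reference
#'
#' RMS deviation of all intra-selection atom-pair distances,
#' `sqrt(mean over pairs i<j of (d_ij - d_ij_ref)^2)`. Because only internal
#' distances enter, the value is invariant under any rigid motion of either
#' structure and needs no prior superposition (the fit-free deviation
#' measure behind GROMACS `rmsdist`).
#'
#' @inheritParams coordinate_rmsd
#' @return Distance RMSD in nm.
#' @export
distance_rmsd <- function(frame, reference, selection = seq_len(nrow(frame))) {
  if (length(selection) < 2L) stop("distance_rmsd(): selection must have >= 2 atoms", call. = FALSE)
  f <- as.matrix(frame)[selection, , drop = FALSE]
  r <- as.matrix(reference)[selection, , drop = FALSE]
  if (!all(dim(f) == dim(r))) stop("distance_rmsd(): mismatched dimensions", call. = FALSE)
  df <- stats::dist(f)
  dr <- stats::dist(r)
  sqrt(mean((df - dr)^2))
}

#' Per-frame RMSD series for a region
#'
#' Computes, for every frame, either the fitted-coordinate RMSD or the
#' fit-free distance-matrix RMSD of a region against a reference structure.
#' The default mode is `"distance"`; `"fitted"` assumes the ensemble has
#' already been superposed (e.g. on the conserved region).
#'
#' @param x An [ensemble()] (already fitted if `mode = "fitted"`).
#' @param selection Integer atom indices defining the region.
#' @param reference `A x 3` matrix (full roster, nm); defaults to frame 1.
#' @param mode `"distance"` (default) or `"fitted"`.
#' @param region_name Label stored with the series.
#' @return A tibble of class `rmsd_series` with columns `frame`, `time_ps`,
#'   `rmsd_nm` and attributes `mode`, `region_name`.
#' @export
rmsd_series <- function(x, selection, reference = NULL,
                        mode = c("distance", "fitted"), region_name = "region") {
  stopifnot(inherits(x, "ensemble"))
  mode <- match.arg(mode)
  if (is.null(reference)) reference <- frame_coords(x, 1L)
  metric <- if (mode == "fitted") coordinate_rmsd else distance_rmsd
  vals <- vapply(seq_len(n_frames(x)), function(f) {
    metric(frame_coords(x, f), reference, selection)
  }, numeric(1))
  out <- tibble::tibble(
    frame = seq_len(n_frames(x)),
    time_ps = if (is.null(x$times)) NA_real_ else x$times,
    rmsd_nm = vals
  )
  attr(out, "mode") <- mode
  attr(out, "region_name") <- region_name
  class(out) <- c("rmsd_series", class(out))
  out
}

#' Two-dimensional RMSD landscape
#'
#' Joint histogram of two per-frame RMSD series used as reaction
#' coordinates, with a pseudo free-energy surface
#' `-ln(count / F)` shifted so the minimum over occupied bins is zero.
#' Empty bins are flagged explicitly rather than set to infinity.
#'
#' @param series_x,series_y [rmsd_series()] tibbles (or numeric vectors) of
#'   equal length.
#' @param n_bins Number of bins per axis (default 50).
#' @return A list of class `rmsd_landscape` with `x_edges`, `y_edges`
#'   (length `n_bins + 1`), `counts` (integer matrix), `neg_log_p` (numeric
#'   matrix, `NA` where empty), `empty` (logical matrix).
#' @export
rmsd_landscape <- function(series_x, series_y, n_bins = 50L) {
  vx <- if (is.data.frame(series_x)) series_x$rmsd_nm else as.numeric(series_x)
  vy <- if (is.data.frame(series_y)) series_y$rmsd_nm else as.numeric(series_y)
  if (length(vx) != length(vy)) stop("rmsd_landscape(): series lengths differ", call. = FALSE)
  stopifnot(n_bins >= 1L)
  nf <- length(vx)
  bin_edges <- function(v) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5) * max(1e-9, abs(rng[1L]) * 1e-9 + 1e-9)
    seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  }
  xe <- bin_edges(vx); ye <- bin_edges(vy)
  ix <- pmin(pmax(findInterval(vx, xe, rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(vy, ye, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (f in seq_len(nf)) counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  empty <- counts == 0L
  nlp <- matrix(NA_real_, n_bins, n_bins)
  nlp[!empty] <- -log(counts[!empty] / nf)
  nlp[!empty] <- nlp[!empty] - min(nlp[!empty])
  structure(
    list(x_edges = xe, y_edges = ye, counts = counts, neg_log_p = nlp, empty = empty),
    class = "rmsd_landscape"
  )
}

#' @export
print.rmsd_landscape <- function(x, ...) {
  cat("<rmsd_landscape> ", nrow(x$counts), "x", ncol(x$counts), " bins, ",
    sum(x$counts), " frames, ", sum(!x$empty), " occupied bins\n", sep = "")
  invisible(x)
}

#' Tidy a 2D RMSD landscape into a long tibble
#'
#' @param x An `rmsd_landscape`.
#' @param ... Unused.
#' @return Tibble with bin centers `x`, `y`, `count`, `neg_log_p`, `empty`.
#' @exportS3Method generics::tidy
tidy.rmsd_landscape <- function(x, ...) {
  lands <- x
  cx <- (lands$x_edges[-1L] + lands$x_edges[-length(lands$x_edges)]) / 2
  cy <- (lands$y_edges[-1L] + lands$y_edges[-length(lands$y_edges)]) / 2
  grid <- tidyr::expand_grid(i = seq_along(cx), j = seq_along(cy))
  idx <- cbind(grid$i, grid$j)
  tibble::tibble(
    x = cx[grid$i], y = cy[grid$j],
    count = lands$counts[idx],
    neg_log_p = lands$neg_log_p[idx],
    empty = lands$empty[idx]
  )
}
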
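#' Displacement cross-correlation matrix of Calpha atoms
#'
#' For each pair of selected atoms the normalized covariance of displacement
#' vectors about their time means,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`,
#' computed on a superposed ensemble (conventionally fitted on the conserved
#' region first; see [fit_ensemble()]). Values span -1 (strong
#' anti-correlation) through 0 (none) to +1 (strong correlation); the
#' diagonal is 1.
#'
#' @param x A fitted [ensemble()] with at least two frames.
#' @param ca_selection Integer atom indices, one Calpha per residue (from
#'   [select_atoms()] with `atom_names = "CA"`).
#' @return An `n x n` matrix of class `dccm_matrix` with residue numbers as
#'   dimnames and attributes `residue_index`, `chain`, `label`.
#' @export
dccm <- function(x, ca_selection) {
  stopifnot(inherits(x, "ensemble"))
  if (n_frames(x) < 2L) stop("dccm(): need >= 2 frames", call. = FALSE)
  if (length(ca_selection) == 0L) stop("dccm(): empty selection", call. = FALSE)
  f <- n_frames(x)
  cx <- x$coords[, ca_selection, 1L, drop = TRUE]
  cy <- x$coords[, ca_selection, 2L, drop = TRUE]
  cz <- x$coords[, ca_selection, 3L, drop = TRUE]
  if (is.null(dim(cx))) { cx <- matrix(cx, nrow = f); cy <- matrix(cy, nrow = f); cz <- matrix(cz, nrow = f) }
  cx <- scale(cx, scale = FALSE); cy <- scale(cy, scale = FALSE); cz <- scale(cz, scale = FALSE)
  s <- (crossprod(cx) + crossprod(cy) + crossprod(cz)) / f
  v <- diag(s)
  if (any(v < 1e-15)) {
    bad <- x$atoms$resno[ca_selection][v < 1e-15]
    stop("dccm(): zero displacement variance at residue(s) ",
      paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  cmat <- s / tcrossprod(sqrt(v))
  cmat <- pmin(pmax(cmat, -1), 1)
  resno <- x$atoms$resno[ca_selection]
  dimnames(cmat) <- list(resno, resno)
  structure(cmat,
    class = c("dccm_matrix", "matrix", "array"),
    residue_index = resno,
    chain = x$atoms$chain[ca_selection],
    label = x$label
  )
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat("<dccm_matrix> ", nrow(x), " residues (", attr(x, "label"), ")\n", sep = "")
  invisible(x)
}

#' Tidy a correlation matrix into a long tibble
#' @param x A `dccm_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `residue_i`, `residue_j`, `cij`.
#' @exportS3Method generics::tidy
tidy.dccm_matrix <- function(x, ...) {
  resno <- attr(x, "residue_index")
  grid <- tidyr::expand_grid(i = seq_along(resno), j = seq_along(resno))
  tibble::tibble(
    residue_i = resno[grid$i], residue_j = resno[grid$j],
    cij = as.numeric(unclass(x)[cbind(grid$i, grid$j)])
  )
}

#' Loop-mean correlation profile over tail residues
#'
#' For every residue of one region (the C-terminal tail) the unweighted mean
#' of its correlation with each residue of another region (the 15-residue
#' active site loop). This collapses the loop block of the DCCM to one value
#' per tail residue, the quantity differenced between protomers.
#'
#' @param cmat A [dccm()] matrix.
#' @param loop_region,tail_region Region names.
#' @param regions A [region_set()].
#' @param aggregate `"mean"` (default) or `"max_magnitude"` (the entry of
#'   largest absolute value).
#' @return Tibble with columns `residue` (tail residue numbers, increasing)
#'   and `mean_cij`.
#' @export
region_mean_correlation <- function(cmat, loop_region, tail_region, regions,
                                    aggregate = c("mean", "max_magnitude")) {
  aggregate <- match.arg(aggregate)
  resno <- attr(cmat, "residue_index")
  chain <- attr(cmat, "chain")
  pick <- function(region_name) {
    rr <- region_residues(regions, region_name)
    idx <- which(paste(chain, resno) %in% paste(rr$chain, rr$resno))
    if (length(idx) == 0L) {
      stop("region_mean_correlation(): region '", region_name,
        "' lies outside the matrix", call. = FALSE)
    }
    if (length(idx) < nrow(rr)) {
      stop("region_mean_correlation(): region '", region_name,
        "' is only partially covered by the matrix", call. = FALSE)
    }
    idx[order(resno[idx])]
  }
  li <- pick(loop_region)
  ti <- pick(tail_region)
  block <- unclass(cmat)[li, ti, drop = FALSE]
  vals <- if (aggregate == "mean") {
    colMeans(block)
  } else {
    apply(block, 2L, function(col) col[which.max(abs(col))])
  }
  tibble::tibble(residue = resno[ti], mean_cij = as.numeric(vals))
}

#' Protomer difference profiles (chain B minus chain A)
#'
#' Elementwise differences, per tail residue, of the loop-mean correlation
#' and of the tail RMSF between the two protomers of a homodimer. The sign
#' convention is fixed as B - A for both quantities.
#'
#' @param profile_a,profile_b Loop-mean correlation profiles from
#'   [region_mean_correlation()] for protomers A and B.
#' @param rmsf_a,rmsf_b [backbone_rmsf()] profiles restricted to the tail
#'   residues of protomers A and B.
#' @return A tibble of class `asymmetry_profile` with columns `residue`,
#'   `delta_cij`, `delta_rmsf_nm`.
#' @export
delta_profiles <- function(profile_a, profile_b, rmsf_a, rmsf_b) {
  ra <- profile_a$residue; rb <- profile_b$residue
  fa <- rmsf_a$residue_number; fb <- rmsf_b$residue_number
  if (!identical(ra, rb) || !identical(as.integer(ra), as.integer(fa)) ||
      !identical(as.integer(fa), as.integer(fb))) {
    stop("delta_profiles(): residue axes differ across the four inputs", call. = FALSE)
  }
  out <- tibble::tibble(
    residue = as.integer(ra),
    delta_cij = profile_b$mean_cij - profile_a$mean_cij,
    delta_rmsf_nm = rmsf_b$rmsf_nm - rmsf_a$rmsf_nm
  )
  class(out) <- c("asymmetry_profile", class(out))
  out
}

#' Ordinary least-squares regression with slope inference
#'
#' Fits `y = alpha + beta * x` by least squares (via [stats::lm()]),
#' reporting the two-sided p-value of the slope's t statistic on `n - 2`
#' degrees of freedom and the adjusted R-squared
#' `1 - (1 - R^2) (n - 1) / (n - 2)`. An exact fit (zero residual variance)
#' is reported with `p_value = 0` and `exact_fit = TRUE` rather than as a
#' numerical failure.
#'
#' @param x,y Numeric vectors, length `n >= 3`; `x` must not be constant.
#' @param label Free-text provenance label.
#' @return A list of class `ols_fit`: `intercept`, `slope`, `p_value`,
#'   `r2_adjusted`, `n`, `exact_fit`, `label`, and the underlying `model`.
#' @export
ols_regress <- function(x, y, label = "") {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("ols_regress(): x and y lengths differ", call. = FALSE)
  if (n < 3L) stop("ols_regress(): need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("ols_regress(): x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  exact <- rss <= max(1e-24, 1e-14 * tss)
  if (exact) {
    p <- 0
    r2a <- 1
  } else {
    sm <- summary(fit)
    p <- sm$coefficients["x", "Pr(>|t|)"]
    r2a <- sm$adj.r.squared
  }
  structure(
    list(intercept = unname(cf[1L]), slope = unname(cf[2L]), p_value = p,
      r2_adjusted = r2a, n = n, exact_fit = exact, label = label, model = fit),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit%s> y = %.4g + %.4g x, p = %.3g, adj R2 = %.3g, n = %d%s\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    x$intercept, x$slope, x$p_value, x$r2_adjusted, x$n,
    if (x$exact_fit) " (exact fit)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ols_fit <- function(x, ...) {
  if (x$exact_fit) {
    return(tibble::tibble(
      term = c("(Intercept)", "x"),
      estimate = c(x$intercept, x$slope),
      std.error = c(0, 0), statistic = c(Inf, Inf), p.value = c(0, 0)
    ))
  }
  cf <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(cf), estimate = cf[, "Estimate"], std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"], p.value = cf[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.ols_fit <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept, slope = x$slope, p_value = x$p_value,
    r2_adjusted = x$r2_adjusted, n = x$n, exact_fit = x$exact_fit
  )
}

#' Regress protomer correlation differences on fluctuation differences
#'
#' The homodimer-asymmetry statistic: ordinary least squares of the
#' per-tail-residue `delta C_ij` (y) on `delta RMSF` (x), both as chain B
#' minus chain A. A significantly negative slope means the protomer whose
#' tail fluctuates more shows the stronger loop-tail anti-correlation.
#'
#' @param profile An [delta_profiles()] asymmetry profile.
#' @param label Provenance label for the result.
#' @return An [ols_regress()] `ols_fit`.
#' @export
asymmetry_regression <- function(profile, label = "asymmetry") {
  stopifnot(inherits(profile, "asymmetry_profile"))
  ols_regress(profile$delta_rmsf_nm, profile$delta_cij, label = label)
}
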
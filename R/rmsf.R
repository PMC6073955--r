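#' Per-residue backbone RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its time-mean
#' position (or about a fixed reference structure), aggregated to residues
#' as the unweighted mean of the residue's selected-atom RMSFs. The ensemble
#' must already be superposed (see [fit_ensemble()]); fluctuation is
#' undefined for fewer than two frames.
#'
#' For an atom whose per-axis displacement is an independent Gaussian with
#' standard deviation sigma, the expected RMSF is `sqrt(3) * sigma`.
#'
#' @param x A fitted [ensemble()] with at least two frames.
#' @param selection Integer atom indices (typically backbone N, CA, C from
#'   [select_atoms()]).
#' @param per_residue Aggregate atoms to residues (default `TRUE`); with
#'   `FALSE` one row per atom is returned.
#' @param center `"mean"` (default) computes fluctuations about the
#'   time-averaged structure; `"reference"` uses `reference` instead.
#' @param reference Full-roster `A x 3` matrix (nm) when
#'   `center = "reference"`.
#' @return A tibble of class `rmsf_profile` with columns `chain`,
#'   `residue_number`, `rmsf_nm` (plus `name` when `per_residue = FALSE`)
#'   and attribute `label`.
#' @export
backbone_rmsf <- function(x, selection, per_residue = TRUE,
                          center = c("mean", "reference"), reference = NULL) {
  stopifnot(inherits(x, "ensemble"))
  center <- match.arg(center)
  if (n_frames(x) < 2L) stop("backbone_rmsf(): need >= 2 frames", call. = FALSE)
  if (length(selection) == 0L) stop("backbone_rmsf(): empty selection", call. = FALSE)
  sub <- x$coords[, selection, , drop = FALSE] # F x K x 3
  ctr <- if (center == "mean") {
    apply(sub, c(2L, 3L), mean)
  } else {
    if (is.null(reference)) stop("backbone_rmsf(): reference required", call. = FALSE)
    as.matrix(reference)[selection, , drop = FALSE]
  }
  dev2 <- sweep(sub, c(2L, 3L), ctr)^2
  msf <- apply(dev2, 2L, sum) / n_frames(x) # per-atom mean squared fluctuation
  per_atom <- tibble::tibble(
    chain = x$atoms$chain[selection],
    residue_number = x$atoms$resno[selection],
    name = x$atoms$name[selection],
    rmsf_nm = sqrt(msf)
  )
  out <- if (per_residue) {
    dplyr::summarise(
      dplyr::group_by(per_atom, .data$chain, .data$residue_number),
      rmsf_nm = mean(.data$rmsf_nm), .groups = "drop"
    ) |> dplyr::arrange(.data$chain, .data$residue_number)
  } else {
    per_atom
  }
  attr(out, "label") <- x$label
  class(out) <- c("rmsf_profile", class(out))
  out
}
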
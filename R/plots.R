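#' Heat map of a displacement cross-correlation matrix
#'
#' @param object A [dccm()] matrix.
#' @param ... Unused.
#' @return A ggplot object (blue-white-red scale over \[-1, 1\]).
#' @exportS3Method ggplot2::autoplot
autoplot.dccm_matrix <- function(object, ...) {
  df <- tidy.dccm_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_i, y = .data$residue_j,
    fill = .data$cij)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
      limits = c(-1, 1), name = expression(C[ij])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue i", y = "residue j", title = attr(object, "label"))
}

#' Per-residue RMSF profile plot
#'
#' @param object A [backbone_rmsf()] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue_number, y = .data$rmsf_nm,
    colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (nm)", title = attr(object, "label"))
}

#' Two-dimensional RMSD landscape plot
#'
#' @param object An [rmsd_landscape()].
#' @param ... Unused.
#' @return A ggplot object of the shifted `-ln p` surface (empty bins blank).
#' @exportS3Method ggplot2::autoplot
autoplot.rmsd_landscape <- function(object, ...) {
  df <- tidy.rmsd_landscape(object)
  ggplot2::ggplot(df[!df$empty, ], ggplot2::aes(x = .data$x, y = .data$y,
    fill = .data$neg_log_p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "-ln p") +
    ggplot2::labs(x = "RMSD x (nm)", y = "RMSD y (nm)")
}

#' Asymmetry profile scatter with fitted line
#'
#' @param object A [delta_profiles()] asymmetry profile.
#' @param ... Unused.
#' @return A ggplot object of `delta C_ij` against `delta RMSF` with the
#'   least-squares line.
#' @exportS3Method ggplot2::autoplot
autoplot.asymmetry_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_rmsf_nm, y = .data$delta_cij)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = expression(Delta * "RMSF (nm)"), y = expression(Delta * C[ij]))
}
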
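#' Configuration for a full analysis run
#'
#' @param input Either a [dimer_scenario()] (ensembles are generated), a
#'   single [ensemble()], or a named list of one or two ensembles (for a
#'   homodimer, names `"A"` and `"B"`).
#' @param regions A [region_set()] applied to every ensemble, or a named
#'   list of region sets (one per protomer, matching the input names). For
#'   scenario input the scenario's own regions are used. Must define
#'   `conserved`, `loop`, `beta13` (for hydrogen-bond counting) and
#'   `c_tail` where applicable.
#' @param rmsd_mode `"distance"` (default) or `"fitted"`.
#' @param criteria [hbond_criteria()] used by the hydrogen-bond stage.
#' @param count_bridge Count isolated-bridge residues as beta-strand-forming
#'   (default `FALSE`).
#' @param cluster_cutoff Single-linkage cutoff, nm (default 0.1).
#' @param landscape_bins Bins per landscape axis (default 50).
#' @param output_dir Directory for delimited-text outputs, or `NULL` to
#'   return results without writing.
#' @param seed Integer seed, echoed into every output header.
#' @param run_hbonds,run_ss Toggle the hydrogen-bond / secondary-structure
#'   stages (they require amide hydrogens and full backbones; Calpha-only
#'   synthetic ensembles cannot run them).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, regions = NULL, rmsd_mode = c("distance", "fitted"),
                       criteria = hbond_criteria(), count_bridge = FALSE,
                       cluster_cutoff = 0.1, landscape_bins = 50L,
                       output_dir = NULL, seed = 1L,
                       run_hbonds = NA, run_ss = NA) {
  structure(
    list(input = input, regions = regions, rmsd_mode = match.arg(rmsd_mode),
      criteria = criteria, count_bridge = count_bridge,
      cluster_cutoff = cluster_cutoff, landscape_bins = as.integer(landscape_bins),
      output_dir = output_dir, seed = as.integer(seed),
      run_hbonds = run_hbonds, run_ss = run_ss),
    class = "run_config"
  )
}

config_header <- function(config, extra = character()) {
  c(
    paste0("# dimerdyn ", as.character(utils::packageVersion("dimerdyn"))),
    paste0("# seed: ", config$seed),
    paste0("# rmsd_mode: ", config$rmsd_mode),
    paste0("# hbond_criteria: d_DA <= ", config$criteria$max_donor_acceptor_distance,
      " nm, angle_HDA <= ", config$criteria$max_hda_angle, " deg"),
    paste0("# cluster_cutoff_nm: ", config$cluster_cutoff),
    extra
  )
}

write_table_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

ensemble_has_backbone <- function(x) {
  all(c("N", "C", "O") %in% unique(x$atoms$name))
}

analyse_protomer <- function(x, regions, config) {
  ca_all <- which(x$atoms$name == "CA")
  conserved_ca <- select_atoms(x, regions, "conserved", "CA")
  ref <- frame_coords(x, 1L)
  fitted <- fit_ensemble(x, conserved_ca, reference = ref)
  out <- list()
  out$rmsd <- purrr::map(
    rlang::set_names(intersect(unique(regions$region), c("conserved", "loop", "c_tail", "n_helix"))),
    function(rg) {
      sel <- select_atoms(x, regions, rg, intersect(c("N", "CA", "C"), unique(x$atoms$name)))
      rmsd_series(fitted, sel, reference = ref, mode = config$rmsd_mode, region_name = rg)
    }
  )
  if (all(c("conserved", "c_tail") %in% names(out$rmsd))) {
    out$landscape <- rmsd_landscape(out$rmsd$conserved, out$rmsd$c_tail,
      n_bins = config$landscape_bins)
  }
  all_bb <- which(x$atoms$name %in% c("N", "CA", "C"))
  out$rmsf <- backbone_rmsf(fitted, all_bb)
  run_hb <- isTRUE(config$run_hbonds) ||
    (is.na(config$run_hbonds) && ensemble_has_backbone(x) &&
       all(c("loop", "beta13") %in% regions$region))
  if (run_hb) {
    out$hbonds <- hbond_count_series(x, "loop", "beta13", regions, config$criteria)
  }
  run_ss <- isTRUE(config$run_ss) ||
    (is.na(config$run_ss) && ensemble_has_backbone(x) && "loop" %in% regions$region)
  if (run_ss) {
    out$beta <- beta_count_series(x, "loop", regions, count_bridge = config$count_bridge)
  }
  out$dccm <- dccm(fitted, ca_all)
  if (all(c("loop", "c_tail") %in% regions$region)) {
    out$loop_tail_profile <- region_mean_correlation(out$dccm, "loop", "c_tail", regions)
    tail_res <- region_residues(regions, "c_tail")
    out$tail_rmsf <- out$rmsf[
      paste(out$rmsf$chain, out$rmsf$residue_number) %in%
        paste(tail_res$chain, tail_res$resno), , drop = FALSE]
  }
  m <- pairwise_rmsd_matrix(
    ensemble(x$coords[seq_len(min(n_frames(x), 60L)), , , drop = FALSE], x$atoms,
      label = x$label),
    conserved_ca, mode = "distance")
  out$clusters <- representative(linkage_cluster(m, config$cluster_cutoff), m)
  out
}

#' Run the full analysis pipeline
#'
#' Executes the conventional stage order on one ensemble or on the two
#' protomers of a homodimer: superposition on the conserved region,
#' per-region RMSD series and a 2D RMSD landscape (conserved vs tail),
#' per-residue RMSF, loop-beta13 hydrogen-bond counts and beta-strand
#' residue counts (when backbones with hydrogens are present), the Calpha
#' DCCM, single-linkage clustering, and - when two protomers are given -
#' the per-tail-residue difference profiles and their asymmetry
#' regression. With a [dimer_scenario()] as input the synthetic ensembles
#' are generated first and the planted profile is carried in the report.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report`: per-protomer stage results
#'   (`protomers`), and for dimers `asymmetry` (profile) and `regression`
#'   (an `ols_fit`). When `output_dir` is set, every table is also written
#'   as delimited text with a header echoing the configuration.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  input <- config$input
  planted <- NULL
  if (inherits(input, "dimer_scenario")) {
    dim_ <- make_asymmetric_dimer(input)
    ensembles <- list(A = dim_$chain_a, B = dim_$chain_b)
    region_sets <- list(A = dim_$regions_a, B = dim_$regions_b)
    planted <- dim_$planted
  } else if (inherits(input, "ensemble")) {
    ensembles <- list(A = input)
    region_sets <- list(A = config$regions)
  } else {
    ensembles <- input
    if (is.null(names(ensembles))) names(ensembles) <- LETTERS[seq_along(ensembles)]
    region_sets <- if (inherits(config$regions, "region_set") || is.null(config$regions)) {
      rlang::set_names(
        purrr::map(names(ensembles), function(nm) config$regions), names(ensembles))
    } else {
      config$regions[names(ensembles)] # one region set per protomer
    }
  }
  if (any(purrr::map_lgl(region_sets, is.null))) {
    stop("run_pipeline(): a region set is required", call. = FALSE)
  }
  results <- purrr::imap(ensembles, function(e, nm) {
    message("dimerdyn: analysing protomer ", nm, " (", n_frames(e), " frames)")
    analyse_protomer(e, region_sets[[nm]], config)
  })
  report <- list(protomers = results, planted = planted, config = config)
  if (length(results) == 2L &&
      !is.null(results[[1L]]$loop_tail_profile) && !is.null(results[[2L]]$loop_tail_profile)) {
    prof <- delta_profiles(
      results[[1L]]$loop_tail_profile, results[[2L]]$loop_tail_profile,
      results[[1L]]$tail_rmsf, results[[2L]]$tail_rmsf
    )
    report$asymmetry <- prof
    report$regression <- tryCatch(
      asymmetry_regression(prof),
      error = function(e) {
        message("dimerdyn: asymmetry regression undefined (", conditionMessage(e), ")")
        NULL
      }
    )
  } else if (length(results) == 1L) {
    message("dimerdyn: single protomer - asymmetry stage skipped")
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", length(x$protomers), " protomer(s)\n", sep = "")
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- report$config
  for (nm in names(report$protomers)) {
    pr <- report$protomers[[nm]]
    for (rg in names(pr$rmsd)) {
      write_table_with_header(pr$rmsd[[rg]], file.path(dir, paste0("rmsd_", nm, "_", rg, ".tsv")),
        config_header(config, paste0("# region: ", rg)))
    }
    write_table_with_header(
      dplyr::rename(pr$rmsf, rmsf_nm = "rmsf_nm"),
      file.path(dir, paste0("rmsf_", nm, ".tsv")), config_header(config))
    if (!is.null(pr$hbonds)) {
      write_table_with_header(pr$hbonds, file.path(dir, paste0("hbonds_", nm, ".tsv")),
        config_header(config))
    }
    if (!is.null(pr$beta)) {
      write_table_with_header(pr$beta, file.path(dir, paste0("beta_", nm, ".tsv")),
        config_header(config))
    }
    if (!is.null(pr$landscape)) {
      write_table_with_header(tidy.rmsd_landscape(pr$landscape),
        file.path(dir, paste0("landscape_", nm, ".tsv")), config_header(config))
    }
    utils::write.table(unclass(pr$dccm), file.path(dir, paste0("dccm_", nm, ".tsv")),
      sep = "\t", quote = FALSE)
    write_table_with_header(tidy.cluster_result(pr$clusters),
      file.path(dir, paste0("clusters_", nm, ".tsv")),
      config_header(config, paste0("# representatives: ",
        paste(pr$clusters$representatives, collapse = ","))))
  }
  if (!is.null(report$asymmetry)) {
    write_table_with_header(report$asymmetry, file.path(dir, "asymmetry_profile.tsv"),
      config_header(config))
  }
  if (!is.null(report$regression)) {
    write_table_with_header(glance.ols_fit(report$regression),
      file.path(dir, "asymmetry_regression.tsv"), config_header(config))
  }
  invisible(dir)
}

#' Cross-system regression of mean beta counts on mean hydrogen-bond counts
#'
#' Across several analysed systems, regresses the mean number of
#' beta-strand-forming residues on the mean loop hydrogen-bond count (one
#' point per system) - the summary relating strand formation to
#' loop-strand hydrogen bonding.
#'
#' @param systems A data frame with columns `label`, `mean_hbond`,
#'   `mean_beta`, or a list of `list(label =, hbond =, beta =)` entries
#'   whose `hbond`/`beta` are `count_series` objects.
#' @return A list with `table` (the per-system tibble) and `fit`
#'   (an [ols_regress()] result of `mean_beta ~ mean_hbond`).
#' @export
means_correlation_report <- function(systems) {
  tbl <- if (is.data.frame(systems)) {
    tibble::as_tibble(systems)
  } else {
    purrr::map(systems, function(s) {
      tibble::tibble(label = s$label,
        mean_hbond = attr(s$hbond, "mean"), mean_beta = attr(s$beta, "mean"))
    }) |> purrr::list_rbind()
  }
  if (nrow(tbl) < 3L) {
    stop("means_correlation_report(): need >= 3 systems", call. = FALSE)
  }
  fit <- ols_regress(tbl$mean_hbond, tbl$mean_beta, label = "means-correlation")
  list(table = tbl, fit = fit)
}
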
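# All generators are pure functions of (parameters, seed): the global RNG
# state is saved and restored around every draw.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# non-degenerate mean chain for Calpha beads (nm): a compact 3D Lissajous
# curve, never collinear or planar. Compactness matters: a globule-sized
# mean structure (like a folded domain, a few nm across) keeps rigid-body
# lever arms short, so least-squares superposition cannot absorb planted
# internal modes the way it could on a long extended chain.
mean_chain_coords <- function(n) {
  i <- seq_len(n)
  cbind(2 * sin(0.5 * i), 2 * sin(0.7 * i + 1), 2 * sin(0.9 * i + 2))
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Generate a Calpha ensemble with a planted correlation structure
#'
#' Draws per-residue displacements independently per Cartesian axis from a
#' zero-mean Gaussian with the given residue-level correlation matrix and
#' per-residue standard deviations, added to a fixed non-degenerate extended
#' mean chain. Because the three axes share the residue-level correlation,
#' the expected displacement cross-correlation matrix equals `corr` exactly
#' (`<dr_i . dr_j> = 3 rho sigma_i sigma_j`, `<|dr_i|^2> = 3 sigma_i^2`) and
#' the expected RMSF of residue i is `sqrt(3) * sigma_i`. Optionally each
#' frame is contaminated by a random rigid motion (rotation uniform over
#' SO(3), translation uniform in a 1 nm box) that a subsequent
#' [fit_ensemble()] must remove.
#'
#' @param residues Integer vector of residue numbers, or a [region_set()]
#'   whose covered residues (union over regions) define the chain.
#' @param sigma Per-residue displacement standard deviation(s), nm (> 0);
#'   recycled to the residue count.
#' @param corr Residue-level target correlation matrix (symmetric, unit
#'   diagonal, positive definite).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param rigid_contamination Add per-frame random rigid motions (default
#'   `FALSE`).
#' @param chain Chain identifier for the roster.
#' @param dt_ps Frame spacing in ps (default 100, the conventional
#'   trajectory sampling interval).
#' @param label Ensemble label.
#' @param repair If `TRUE`, a correlation matrix that fails the positive
#'   definiteness check is repaired by the smallest sufficient diagonal
#'   jitter (never silent: the default is to error).
#' @return An [ensemble()] with one CA atom per residue.
#' @export
generate_correlated_ensemble <- function(residues, sigma, corr, n_frames, seed,
                                         rigid_contamination = FALSE, chain = "A",
                                         dt_ps = 100, label = "synthetic",
                                         repair = FALSE) {
  if (inherits(residues, "region_set")) {
    residues <- sort(unique(unlist(
      purrr::map(unique(residues$region), function(r) region_residues(residues, r)$resno)
    )))
  }
  n <- length(residues)
  stopifnot(n >= 1L, n_frames >= 1L)
  sigma <- rep_len(sigma, n)
  if (any(sigma <= 0)) stop("generate_correlated_ensemble(): sigma must be > 0", call. = FALSE)
  corr <- as.matrix(corr)
  if (nrow(corr) != n || max(abs(corr - t(corr))) > 1e-10 ||
      max(abs(diag(corr) - 1)) > 1e-10) {
    stop("generate_correlated_ensemble(): corr must be a symmetric unit-diagonal ",
      "matrix matching the residue count", call. = FALSE)
  }
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(ch)) {
    ev_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
    if (!repair) {
      stop("generate_correlated_ensemble(): corr is not positive definite ",
        "(smallest eigenvalue ", signif(ev_min, 3), "); set repair = TRUE to add ",
        "diagonal jitter explicitly", call. = FALSE)
    }
    jitter <- abs(ev_min) + 1e-8
    corr <- (corr + diag(jitter, n)) / (1 + jitter)
    ch <- chol(corr)
  }
  mean_xyz <- mean_chain_coords(n)
  coords <- with_seed(seed, {
    out <- array(0, dim = c(n_frames, n, 3L))
    for (ax in 1:3) {
      z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
      out[, , ax] <- sweep(z %*% ch, 2L, sigma, `*`) + matrix(mean_xyz[, ax], n_frames, n, byrow = TRUE)
    }
    if (rigid_contamination) {
      for (f in seq_len(n_frames)) {
        rot <- random_rotation_matrix()
        tr <- stats::runif(3, -0.5, 0.5)
        out[f, , ] <- sweep(matrix(out[f, , ], ncol = 3L) %*% t(rot), 2L, tr, `+`)
      }
    }
    out
  })
  atoms <- tibble::tibble(
    serial = seq_len(n), name = "CA", element = "C", resname = "GLY",
    resno = as.integer(residues), chain = chain
  )
  ensemble(coords, atoms, times = (seq_len(n_frames) - 1L) * dt_ps, label = label)
}

#' Factor-model correlation matrix with a planted loop-tail block
#'
#' Builds a positive definite residue-level correlation matrix from a
#' single latent factor: loop residues load `loop_loading` (default 0.9,
#' giving within-loop correlation 0.81), tail residue j loads
#' `rho[j] / loop_loading` so that its correlation with every loop residue
#' is exactly `rho[j]`, and all remaining residues are uncorrelated. The
#' implied tail-tail correlations are the loading products. Positive
#' definiteness holds by construction whenever all |loadings| < 1.
#'
#' @param n Total residue count.
#' @param loop_idx,tail_idx Integer positions (1-based within the matrix) of
#'   the loop and tail residues.
#' @param rho Planted loop-tail correlation, scalar or per tail residue;
#'   requires `|rho| < loop_loading`.
#' @param loop_loading Factor loading of loop residues (default 0.9).
#' @return An `n x n` correlation matrix.
#' @export
planted_block_correlation <- function(n, loop_idx, tail_idx, rho, loop_loading = 0.9) {
  rho <- rep_len(rho, length(tail_idx))
  if (any(abs(rho) >= loop_loading)) {
    stop("planted_block_correlation(): need |rho| < loop_loading", call. = FALSE)
  }
  load <- numeric(n)
  load[loop_idx] <- loop_loading
  load[tail_idx] <- rho / loop_loading
  cmat <- tcrossprod(load)
  diag(cmat) <- 1
  cmat
}

#' Specify a synthetic asymmetric homodimer scenario
#'
#' Bundles every parameter of a two-protomer synthetic ensemble: the region
#' spans (author numbering; a compact protomer whose conserved scaffold
#' 441-499 plus 515-552 flanks the active site loop 500-514 and beta13
#' 515-518, with the 35-residue tail 553-587), per-region fluctuation
#' amplitudes, the planted
#' loop-tail correlation of protomer A, and the exact line on which the
#' noise-free (delta RMSF, delta C_ij) pairs are planted. Defaults mirror
#' conventional study conditions: 1001 frames at 100 ps spacing and a
#' planted negative slope.
#'
#' @param n_frames Frames per protomer (default 1001).
#' @param seed Integer seed.
#' @param slope,intercept The planted asymmetry line
#'   `delta_cij = intercept + slope * delta_rmsf`; set both to `NULL` to
#'   instead give `rho_tail_b` directly.
#' @param rho_tail_a Loop-tail correlation of protomer A (scalar or per
#'   tail residue; default -0.25).
#' @param rho_tail_b Loop-tail correlation of protomer B; ignored when a
#'   line is given (then derived as
#'   `rho_tail_a + intercept + slope * delta_rmsf`).
#' @param sigma_tail_a,sigma_tail_b Tail displacement SDs in nm (scalar or
#'   per residue; defaults 0.10 and a 0.11..0.17 ramp, so protomer B's tail
#'   fluctuates more).
#' @param sigma_conserved,sigma_loop Displacement SDs (nm) of conserved-core
#'   and loop residues (defaults 0.05, 0.08).
#' @param loop_loading Factor loading of the loop block (default 0.9).
#' @param rigid_contamination Per-frame rigid-motion contamination (default
#'   `TRUE`, so the fitting stage is always exercised).
#' @param dt_ps Frame spacing in ps (default 100).
#' @return A list of class `dimer_scenario`.
#' @export
dimer_scenario <- function(n_frames = 1001L, seed = 1L,
                           slope = -1.10, intercept = -0.04,
                           rho_tail_a = -0.25, rho_tail_b = NULL,
                           sigma_tail_a = 0.10,
                           sigma_tail_b = seq(0.11, 0.17, length.out = 35L),
                           sigma_conserved = 0.05, sigma_loop = 0.08,
                           loop_loading = 0.9, rigid_contamination = TRUE,
                           dt_ps = 100) {
  # The conserved (fit) region is the rigid scaffold flanking the loop.
  # Excluding the loaded loop from the superposition region keeps the fit
  # from absorbing any part of the planted collective mode, so the post-fit
  # DCCM matches the planted matrix in expectation.
  regions <- list(
    conserved = list(c(441L, 499L), c(515L, 552L)),
    loop = list(c(500L, 514L)),
    beta13 = list(c(515L, 518L)),
    c_tail = list(c(553L, 587L))
  )
  n_tail <- regions$c_tail[[1L]][2L] - regions$c_tail[[1L]][1L] + 1L
  sigma_tail_a <- rep_len(sigma_tail_a, n_tail)
  sigma_tail_b <- rep_len(sigma_tail_b, n_tail)
  rho_a <- rep_len(rho_tail_a, n_tail)
  delta_rmsf <- sqrt(3) * (sigma_tail_b - sigma_tail_a)
  rho_b <- if (!is.null(slope) && !is.null(intercept)) {
    rho_a + intercept + slope * delta_rmsf
  } else {
    rep_len(if (is.null(rho_tail_b)) rho_tail_a else rho_tail_b, n_tail)
  }
  if (any(abs(c(rho_a, rho_b)) >= loop_loading)) {
    stop("dimer_scenario(): planted correlations must satisfy |rho| < loop_loading",
      call. = FALSE)
  }
  structure(
    list(
      regions = regions, n_frames = as.integer(n_frames), seed = as.integer(seed),
      rho_tail_a = rho_a, rho_tail_b = rho_b,
      sigma_tail_a = sigma_tail_a, sigma_tail_b = sigma_tail_b,
      sigma_conserved = sigma_conserved, sigma_loop = sigma_loop,
      loop_loading = loop_loading, rigid_contamination = rigid_contamination,
      dt_ps = dt_ps
    ),
    class = "dimer_scenario"
  )
}

#' Region set of a dimer scenario for one chain
#' @param scenario A [dimer_scenario()].
#' @param chain Chain identifier.
#' @return A [region_set()].
#' @export
scenario_regions <- function(scenario, chain = "A") {
  args <- purrr::map(scenario$regions, function(ranges) {
    purrr::map(ranges, function(sp) list(chain = chain, start = sp[1L], end = sp[2L]))
  })
  do.call(region_set, args)
}

#' Generate a synthetic asymmetric homodimer
#'
#' Builds the two protomer ensembles of a [dimer_scenario()] together with
#' the exact planted asymmetry profile: per tail residue,
#' `delta_rmsf = sqrt(3) * (sigma_B - sigma_A)` and
#' `delta_cij = rho_B - rho_A` (which, when the scenario was given a line,
#' lie exactly on `intercept + slope * delta_rmsf`). Running the full
#' pipeline (fit, DCCM, RMSF, [delta_profiles()],
#' [asymmetry_regression()]) on the generated ensembles recovers the
#' planted relation up to finite-sampling noise, while
#' [asymmetry_regression()] on the returned planted profile recovers it
#' exactly.
#'
#' @param scenario A [dimer_scenario()].
#' @return A list with elements `chain_a`, `chain_b` (ensembles, chains
#'   `"A"`/`"B"`), `planted` (an `asymmetry_profile` tibble), `regions_a`,
#'   `regions_b` (region sets), and `scenario`.
#' @export
make_asymmetric_dimer <- function(scenario) {
  stopifnot(inherits(scenario, "dimer_scenario"))
  sp <- scenario$regions
  residues <- seq.int(sp$conserved[[1L]][1L], sp$c_tail[[1L]][2L])
  n <- length(residues)
  loop_idx <- which(residues >= sp$loop[[1L]][1L] & residues <= sp$loop[[1L]][2L])
  tail_idx <- which(residues >= sp$c_tail[[1L]][1L] & residues <= sp$c_tail[[1L]][2L])
  sigma_base <- rep(scenario$sigma_conserved, n)
  sigma_base[loop_idx] <- scenario$sigma_loop
  seeds <- with_seed(scenario$seed, sample.int(.Machine$integer.max - 1L, 2L))
  build <- function(rho_tail, sigma_tail, chain, seed) {
    sigma <- sigma_base
    sigma[tail_idx] <- sigma_tail
    corr <- planted_block_correlation(n, loop_idx, tail_idx, rho_tail,
      loop_loading = scenario$loop_loading)
    generate_correlated_ensemble(
      residues, sigma, corr, scenario$n_frames, seed,
      rigid_contamination = scenario$rigid_contamination, chain = chain,
      dt_ps = scenario$dt_ps, label = paste0("synthetic-dimer-", chain)
    )
  }
  chain_a <- build(scenario$rho_tail_a, scenario$sigma_tail_a, "A", seeds[1L])
  chain_b <- build(scenario$rho_tail_b, scenario$sigma_tail_b, "B", seeds[2L])
  planted <- tibble::tibble(
    residue = residues[tail_idx],
    delta_cij = scenario$rho_tail_b - scenario$rho_tail_a,
    delta_rmsf_nm = sqrt(3) * (scenario$sigma_tail_b - scenario$sigma_tail_a)
  )
  class(planted) <- c("asymmetry_profile", class(planted))
  list(
    chain_a = chain_a, chain_b = chain_b, planted = planted,
    regions_a = scenario_regions(scenario, "A"),
    regions_b = scenario_regions(scenario, "B"),
    scenario = scenario
  )
}
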
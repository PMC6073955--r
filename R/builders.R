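# Ideal backbone geometry (nm): standard bond lengths and angles
.bb_geom <- list(
  b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329, b_c_o = 0.1231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Natural extension reference frame (NeRF): place atom d bonded to c with
# given bond length, angle at c (b-c-d) and dihedral a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an ideal backbone chain with uniform (phi, psi); returns a list of
# per-residue atom positions (N, CA, C, O, H), all in nm.
build_backbone_chain <- function(n_residues, phi, psi, omega = 180) {
  g <- .bb_geom
  res <- vector("list", n_residues)
  # seed residue in the xy-plane
  n1 <- c(0, 0, 0)
  ca1 <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  c1 <- ca1 + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  res[[1L]] <- list(N = n1, CA = ca1, C = c1)
  for (i in 2:n_residues) {
    p <- res[[i - 1L]]
    ni <- place_atom(p$N, p$CA, p$C, g$b_c_n, g$a_ca_c_n, psi)
    cai <- place_atom(p$CA, p$C, ni, g$b_n_ca, g$a_c_n_ca, omega)
    ci <- place_atom(p$C, ni, cai, g$b_ca_c, g$a_n_ca_c, phi)
    res[[i]] <- list(N = ni, CA = cai, C = ci)
  }
  for (i in seq_len(n_residues)) {
    if (i < n_residues) {
      # carbonyl O anti to the next amide N across the sp2 carbon
      res[[i]]$O <- place_atom(res[[i + 1L]]$N, res[[i]]$CA, res[[i]]$C,
        g$b_c_o, g$a_ca_c_o, 180)
    } else {
      res[[i]]$O <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
        g$b_c_o, g$a_ca_c_o, psi + 180)
    }
    c_prev <- if (i > 1L) res[[i - 1L]]$C else NULL
    res[[i]]$H <- place_amide_h(res[[i]]$N, res[[i]]$CA, c_prev)
  }
  res
}

residues_to_ensemble <- function(res_list, resno, chain = "A", label = "built") {
  order_names <- c("N", "CA", "C", "O", "H")
  rows <- purrr::imap(res_list, function(r, k) {
    tibble::tibble(
      name = order_names,
      element = c("N", "C", "C", "O", "H"),
      resname = "ALA", resno = resno[k], chain = chain
    )
  }) |> purrr::list_rbind()
  rows$serial <- seq_len(nrow(rows))
  coords <- do.call(rbind, purrr::map(res_list, function(r) {
    rbind(r$N, r$CA, r$C, r$O, r$H)
  }))
  ensemble(coords, rows[, c("serial", "name", "element", "resname", "resno", "chain")],
    label = label)
}

#' Build an ideal alpha-helix
#'
#' A single-frame backbone (N, CA, C, O plus deterministic amide H) chained
#' by internal coordinates with phi = -57, psi = -47, omega = 180 degrees
#' and standard bond lengths/angles. Interior residues of the result
#' satisfy the Kabsch-Sander i -> i+4 hydrogen-bond pattern, so
#' [assign_secondary_structure()] labels them `H`.
#'
#' @param n_residues Helix length (>= 6; shorter chains cannot host a
#'   4-turn).
#' @param chain Chain identifier.
#' @return A single-frame [ensemble()].
#' @export
build_ideal_helix <- function(n_residues, chain = "A") {
  if (n_residues < 6L) stop("build_ideal_helix(): need n_residues >= 6", call. = FALSE)
  res <- build_backbone_chain(n_residues, phi = -57, psi = -47)
  residues_to_ensemble(res, seq_len(n_residues), chain = chain, label = "ideal-helix")
}

#' Build an ideal antiparallel beta-hairpin
#'
#' Two extended strands (phi = -139, psi = 135 degrees) of equal length
#' joined by a two-residue turn. The second strand is the first rotated
#' 180 degrees about the sheet normal (the local dyad of an antiparallel
#' pair) and translated into hydrogen-bond register; the registration is a
#' deterministic grid search followed by a local refinement maximizing
#' inter-strand Kabsch-Sander bonds. Strand interiors are labeled `E` by
#' [assign_secondary_structure()], and the paired amide-carbonyl N...O
#' separations sit near 0.29 nm.
#'
#' @param strand_length Residues per strand (>= 3).
#' @param chain Chain identifier.
#' @return A single-frame [ensemble()] with `2 * strand_length + 2`
#'   residues (strand 1, two turn residues, strand 2).
#' @export
build_antiparallel_hairpin <- function(strand_length, chain = "A") {
  if (strand_length < 3L) {
    stop("build_antiparallel_hairpin(): need strand_length >= 3", call. = FALSE)
  }
  s1 <- build_backbone_chain(strand_length, phi = -139, psi = 135)
  # centre strand 1 on its CA centroid, principal axis along x already
  ca1 <- t(vapply(s1, function(r) r$CA, numeric(3)))
  ctr <- colMeans(ca1)
  s1 <- purrr::map(s1, function(r) purrr::map(r, function(p) p - ctr))
  rot_z <- diag(c(-1, -1, 1)) # 180 degrees about z: the sheet dyad
  transform_strand <- function(tr) {
    purrr::map(s1, function(r) purrr::map(r, function(p) as.numeric(rot_z %*% p) + tr))
  }
  ks_pairs <- function(sa, sb) {
    # count inter-strand KS bonds (either donor direction), with a clash guard
    n_bonds <- 0L
    for (i in seq_along(sa)) {
      for (j in seq_along(sb)) {
        ab <- tryCatch(ks_energy_from_distances(
          dist3(sa[[i]]$O, sb[[j]]$N), dist3(sa[[i]]$C, sb[[j]]$H),
          dist3(sa[[i]]$O, sb[[j]]$H), dist3(sa[[i]]$C, sb[[j]]$N)
        ), error = function(e) Inf)
        ba <- tryCatch(ks_energy_from_distances(
          dist3(sb[[j]]$O, sa[[i]]$N), dist3(sb[[j]]$C, sa[[i]]$H),
          dist3(sb[[j]]$O, sa[[i]]$H), dist3(sb[[j]]$C, sa[[i]]$N)
        ), error = function(e) Inf)
        min_d <- min(dist3(sa[[i]]$CA, sb[[j]]$CA), dist3(sa[[i]]$N, sb[[j]]$N))
        if (min_d < 0.15) return(-Inf) # clash: reject this placement
        n_bonds <- n_bonds + (ab < .ks_bond_cutoff) + (ba < .ks_bond_cutoff)
      }
    }
    n_bonds
  }
  # placement parameters: translation plus a tilt about the strand axis that
  # trims the H-N...O angles of the paired amides
  transform_tilted <- function(par) {
    th <- par[4L]
    rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3L, 3L,
      byrow = TRUE)
    rr <- rx %*% rot_z
    purrr::map(s1, function(r) purrr::map(r, function(p) as.numeric(rr %*% p) + par[1:3]))
  }
  placement_score <- function(par) {
    s2 <- transform_tilted(par)
    pen <- 0; n_geo <- 0
    for (i in seq_along(s1)) {
      for (j in seq_along(s2)) {
        for (dir in 1:2) {
          don <- if (dir == 1L) s2[[j]] else s1[[i]]
          acc <- if (dir == 1L) s1[[i]] else s2[[j]]
          d <- dist3(don$N, acc$O)
          if (d < 0.45) {
            cosang <- sum((don$H - don$N) * (acc$O - don$N)) / (dist3(don$H, don$N) * d)
            ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
            pen <- pen + (d - 0.29)^2 + 4e-4 * max(0, ang - 15)^2
            if (d <= 0.35 && ang <= 30) n_geo <- n_geo + 1L
          }
          if (dist3(don$CA, acc$CA) < 0.15) pen <- pen + 10
        }
      }
    }
    pen - 0.5 * n_geo - 0.25 * max(ks_pairs(s1, s2), 0)
  }
  # deterministic coarse grid over the in-sheet translation, then refine
  best <- NULL; best_score <- Inf
  for (tx in seq(-0.35, 0.35, by = 0.05)) {
    for (ty in seq(0.35, 0.60, by = 0.025)) {
      sc <- placement_score(c(tx, ty, 0, 0))
      if (sc < best_score) { best_score <- sc; best <- c(tx, ty, 0, 0) }
    }
  }
  refine <- stats::optim(best, placement_score, method = "Nelder-Mead",
    control = list(maxit = 2000))
  refine <- stats::optim(refine$par, placement_score, method = "Nelder-Mead",
    control = list(maxit = 2000))
  s2 <- transform_tilted(refine$par)
  # two-residue turn bridging strand 1 C-terminus to strand 2 N-terminus,
  # lifted out of the sheet plane; geometry is deliberately coil-like
  p_from <- s1[[strand_length]]$C
  p_to <- s2[[1L]]$N
  turn <- purrr::map(1:2, function(k) {
    t0 <- k / 3
    base <- (1 - t0) * p_from + t0 * p_to + c(0, 0, 0.45)
    list(
      N = base, CA = base + c(0.10, 0.05, 0.05), C = base + c(0.20, -0.05, 0.02),
      O = base + c(0.22, -0.16, 0.06), H = base + c(-0.02, 0.09, -0.02)
    )
  })
  all_res <- c(s1, turn, s2)
  residues_to_ensemble(all_res, seq_along(all_res), chain = chain,
    label = "ideal-antiparallel-hairpin")
}
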
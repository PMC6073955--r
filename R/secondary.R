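#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' The electrostatic model underlying DSSP: with the four inter-group
#' distances in Angstrom,
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol,
#' where the donor group is the amide N-H and the acceptor group the
#' carbonyl C=O. A hydrogen bond is assigned when `E < -0.5` kcal/mol.
#'
#' @param donor `2 x 3` matrix (nm) with rows named `N`, `H`.
#' @param acceptor `2 x 3` matrix (nm) with rows named `C`, `O`.
#' @return Energy in kcal/mol.
#' @export
ks_hbond_energy <- function(donor, acceptor) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  n <- donor["N", ]; h <- donor["H", ]
  cc <- acceptor["C", ]; o <- acceptor["O", ]
  ks_energy_from_distances(
    r_on = dist3(o, n), r_ch = dist3(cc, h),
    r_oh = dist3(o, h), r_cn = dist3(cc, n)
  )
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# distances in nm; converted to Angstrom inside the formula
ks_energy_from_distances <- function(r_on, r_ch, r_oh, r_cn) {
  if (min(r_on, r_ch, r_oh, r_cn) <= 0.05) {
    stop("ks_hbond_energy(): atomic clash (distance below 0.05 nm)", call. = FALSE)
  }
  q <- 0.084 * 332
  q * (1 / (10 * r_on) + 1 / (10 * r_ch) - 1 / (10 * r_oh) - 1 / (10 * r_cn))
}

.ks_bond_cutoff <- -0.5

# Deterministic amide-H placement: 1.0 Angstrom from N along the direction
# opposite the bisector of the N->CA and N->C(prev) bonds; for a chain-start
# residue (no previous C) the N->CA direction alone is mirrored.
place_amide_h <- function(n, ca, c_prev = NULL) {
  u <- (ca - n) / dist3(ca, n)
  dir <- if (is.null(c_prev)) -u else {
    v <- (c_prev - n) / dist3(c_prev, n)
    b <- u + v
    if (dist3(b, c(0, 0, 0)) < 1e-8) -u else -b / sqrt(sum(b^2))
  }
  n + 0.10 * dir
}

# Per-residue backbone table for one chain: N, CA, C, O (and H, placed when
# absent). Errors when a required heavy atom is missing.
chain_backbone <- function(coords, atoms, chain) {
  sel <- atoms$chain == chain
  at <- atoms[sel, , drop = FALSE]
  xyz <- as.matrix(coords)[sel, , drop = FALSE]
  resnos <- sort(unique(at$resno))
  get <- function(rn, nm) {
    i <- which(at$resno == rn & at$name == nm)
    if (length(i) != 1L) return(NULL)
    xyz[i, ]
  }
  bb <- vector("list", length(resnos))
  for (k in seq_along(resnos)) {
    rn <- resnos[k]
    n <- get(rn, "N"); ca <- get(rn, "CA"); cc <- get(rn, "C"); o <- get(rn, "O")
    if (is.null(n) || is.null(ca) || is.null(cc) || is.null(o)) {
      stop("assign_secondary_structure(): missing backbone atom in residue ",
        chain, ":", rn, call. = FALSE)
    }
    h <- get(rn, "H")
    bb[[k]] <- list(resno = rn, N = n, CA = ca, C = cc, O = o, H = h)
  }
  # place missing amide hydrogens deterministically
  for (k in seq_along(bb)) {
    if (is.null(bb[[k]]$H)) {
      c_prev <- if (k > 1L && bb[[k - 1L]]$resno == bb[[k]]$resno - 1L) bb[[k - 1L]]$C else NULL
      bb[[k]]$H <- place_amide_h(bb[[k]]$N, bb[[k]]$CA, c_prev)
    }
  }
  bb
}

#' Assign secondary structure to one chain of a frame
#'
#' A reduced Kabsch-Sander assignment over the alphabet `H` (alpha helix),
#' `E` (extended strand, i.e. a ladder of two or more consecutive bridges),
#' `B` (isolated beta bridge) and `C` (everything else; 3-10/pi helices,
#' turns and bends are not distinguished). Hydrogen bonds are the
#' Kabsch-Sander electrostatic bonds (`E < -0.5` kcal/mol); helices require
#' two consecutive i -> i+4 turns, bridges follow the parallel/antiparallel
#' bridge patterns for residue pairs separated by at least three positions.
#'
#' @param coords `A x 3` coordinate matrix (nm) for one frame.
#' @param atoms Atom roster tibble (as in [ensemble()]).
#' @param chain Chain identifier to assign.
#' @return A tibble with columns `chain`, `residue_number`, `ss`
#'   (one of `"H"`, `"E"`, `"B"`, `"C"`).
#' @export
assign_secondary_structure <- function(coords, atoms, chain) {
  bb <- chain_backbone(coords, atoms, chain)
  nres <- length(bb)
  resnos <- vapply(bb, function(r) r$resno, numeric(1))
  ss <- rep("C", nres)
  if (nres >= 3L) {
    # hb[i, j]: Kabsch-Sander bond from carbonyl of residue i to amide of j.
    # Only sequence-contiguous neighbours are excluded; CA distance prefilter
    # (9 A) keeps the scan linear in practice.
    hb <- matrix(FALSE, nres, nres)
    ca <- t(vapply(bb, function(r) r$CA, numeric(3)))
    for (i in seq_len(nres)) {
      for (j in seq_len(nres)) {
        if (abs(resnos[i] - resnos[j]) < 2) next
        if (dist3(ca[i, ], ca[j, ]) > 0.9) next
        e <- tryCatch(
          ks_energy_from_distances(
            r_on = dist3(bb[[i]]$O, bb[[j]]$N), r_ch = dist3(bb[[i]]$C, bb[[j]]$H),
            r_oh = dist3(bb[[i]]$O, bb[[j]]$H), r_cn = dist3(bb[[i]]$C, bb[[j]]$N)
          ),
          error = function(e) Inf
        )
        hb[i, j] <- e < .ks_bond_cutoff
      }
    }
    contiguous <- function(i, j) resnos[j] - resnos[i] == j - i
    turn4 <- vapply(seq_len(nres), function(i) {
      i + 4L <= nres && contiguous(i, i + 4L) && hb[i, i + 4L]
    }, logical(1))
    # bridges
    bridge_partner <- vector("list", nres)
    for (i in seq_len(nres)) {
      for (j in seq_len(nres)) {
        if (j - i < 3L) next
        anti <- (hb[i, j] && hb[j, i]) ||
          (i > 1L && j < nres && hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
        para <- FALSE
        if (i > 1L && i < nres && hb[i - 1L, j] && hb[j, i + 1L]) para <- TRUE
        if (j > 1L && j < nres && hb[j - 1L, i] && hb[i, j + 1L]) para <- TRUE
        if (anti || para) {
          bridge_partner[[i]] <- c(bridge_partner[[i]], j)
          bridge_partner[[j]] <- c(bridge_partner[[j]], i)
        }
      }
    }
    bridged <- lengths(bridge_partner) > 0L
    # ladders: a bridge at i extends to a ladder when residue i-1 or i+1 also
    # bridges to a partner adjacent to one of i's partners
    in_ladder <- logical(nres)
    for (i in which(bridged)) {
      for (nb in c(i - 1L, i + 1L)) {
        if (nb < 1L || nb > nres || !bridged[nb]) next
        if (any(outer(bridge_partner[[i]], bridge_partner[[nb]],
          function(a, b) abs(a - b) == 1L))) {
          in_ladder[i] <- TRUE
        }
      }
    }
    ss[bridged] <- "B"
    ss[in_ladder] <- "E"
    # alpha helix: two consecutive 4-turns at i-1 and i mark i+1 .. i+4
    for (i in seq_len(nres)) {
      if (i > 1L && turn4[i - 1L] && turn4[i]) {
        ss[(i + 1L):min(i + 4L, nres)] <- "H"
      }
    }
  }
  tibble::tibble(chain = chain, residue_number = resnos, ss = ss)
}

#' Per-frame count of beta-strand residues in a region
#'
#' For every frame, assigns secondary structure to the chain(s) the region
#' lives on and counts region residues labeled `E` (extended strand).
#' Isolated bridges (`B`) are excluded by default; set
#' `count_bridge = TRUE` to include them. The count can never exceed the
#' region's residue count (15 for an active-site loop spanning 500-514).
#'
#' @param x An [ensemble()].
#' @param loop_region Region name to count within.
#' @param regions A [region_set()].
#' @param count_bridge Also count isolated-bridge residues (default `FALSE`).
#' @return A `count_series` tibble (see [hbond_count_series()]).
#' @export
beta_count_series <- function(x, loop_region, regions, count_bridge = FALSE) {
  stopifnot(inherits(x, "ensemble"))
  res <- region_residues(regions, loop_region)
  chains <- unique(res$chain)
  labels <- if (count_bridge) c("E", "B") else "E"
  counts <- integer(n_frames(x))
  for (f in seq_len(n_frames(x))) {
    fc <- frame_coords(x, f)
    n <- 0L
    for (ch in chains) {
      ssa <- assign_secondary_structure(fc, x$atoms, ch)
      want <- res$resno[res$chain == ch]
      n <- n + sum(ssa$ss %in% labels & ssa$residue_number %in% want)
    }
    counts[f] <- n
  }
  count_series(counts, x$times, label = paste0(x$label, ": beta residues in ", loop_region))
}
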
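#' Geometric hydrogen-bond criteria
#'
#' The conventional geometric definition: a donor-acceptor pair is bonded
#' when the donor-acceptor distance and the hydrogen-donor-acceptor angle
#' both fall within their cutoffs (boundary equality counts). The defaults,
#' 0.35 nm and 30 degrees, follow common trajectory-analysis practice; both
#' are echoed into every output so they are never implicit.
#'
#' @param max_donor_acceptor_distance Distance cutoff in nm (> 0).
#' @param max_hda_angle Angle cutoff in degrees, in (0, 180].
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 0.35, max_hda_angle = 30) {
  if (max_donor_acceptor_distance <= 0) {
    stop("hbond_criteria(): distance cutoff must be > 0", call. = FALSE)
  }
  if (max_hda_angle <= 0 || max_hda_angle > 180) {
    stop("hbond_criteria(): angle cutoff must lie in (0, 180]", call. = FALSE)
  }
  structure(
    list(max_donor_acceptor_distance = max_donor_acceptor_distance,
         max_hda_angle = max_hda_angle),
    class = "hbond_criteria"
  )
}

# Backbone donor/acceptor typing plus a small side-chain table.
# Donors are (heavy atom, attached hydrogen name) pairs; acceptors are heavy
# atoms with lone pairs. Synthetic fixtures exercise the backbone entries.
.sidechain_donors <- list(
  SER = list(c("OG", "HG")), THR = list(c("OG1", "HG1")), TYR = list(c("OH", "HH")),
  TRP = list(c("NE1", "HE1")), LYS = list(c("NZ", "HZ1"), c("NZ", "HZ2"), c("NZ", "HZ3")),
  ARG = list(c("NE", "HE"), c("NH1", "HH11"), c("NH1", "HH12"),
             c("NH2", "HH21"), c("NH2", "HH22")),
  ASN = list(c("ND2", "HD21"), c("ND2", "HD22")),
  GLN = list(c("NE2", "HE21"), c("NE2", "HE22")),
  HIS = list(c("ND1", "HD1"), c("NE2", "HE2"))
)
.sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"), GLN = c("OE1"),
  SER = c("OG"), THR = c("OG1"), TYR = c("OH"), HIS = c("ND1", "NE2"), MET = c("SD")
)

# Enumerate donors ((D, H) index pairs) and acceptor indices for a residue
# subset of the roster. Backbone N requires an H in the same residue.
hbond_participants <- function(atoms, residue_keys, sidechains = TRUE,
                               require_backbone_h = FALSE) {
  atoms$idx <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno)
  sub <- atoms[key %in% residue_keys, , drop = FALSE]
  donors <- NULL
  missing_h <- character()
  for (k in unique(paste(sub$chain, sub$resno))) {
    res <- sub[paste(sub$chain, sub$resno) == k, , drop = FALSE]
    n_i <- res$idx[res$name == "N"]
    h_i <- res$idx[res$name == "H"]
    if (length(n_i) == 1L) {
      if (length(h_i) == 1L) {
        donors <- rbind(donors, c(n_i, h_i))
      } else if (require_backbone_h) {
        missing_h <- c(missing_h, k)
      }
    }
    if (sidechains) {
      rn <- res$resname[1L]
      for (dh in .sidechain_donors[[rn]]) {
        d_i <- res$idx[res$name == dh[1L]]
        hh_i <- res$idx[res$name == dh[2L]]
        if (length(d_i) == 1L && length(hh_i) == 1L) donors <- rbind(donors, c(d_i, hh_i))
      }
    }
  }
  if (length(missing_h)) {
    stop("hydrogen bonds: donor N without amide H in residue(s): ",
      paste(missing_h, collapse = ", "), call. = FALSE)
  }
  acc <- sub$idx[sub$name == "O"]
  if (sidechains) {
    for (k in unique(paste(sub$chain, sub$resno))) {
      res <- sub[paste(sub$chain, sub$resno) == k, , drop = FALSE]
      acc <- c(acc, res$idx[res$name %in% .sidechain_acceptors[[res$resname[1L]]]])
    }
  }
  list(donors = donors, acceptors = sort(unique(acc)))
}

#' Detect hydrogen bonds in a single frame
#'
#' Reports a (donor, hydrogen, acceptor) triple whenever the donor-acceptor
#' distance is at most the distance cutoff and the H-D-A angle (at the
#' donor, between the D-H and D-A directions) is at most the angle cutoff;
#' boundary equality counts in both tests.
#'
#' @param coords `A x 3` coordinate matrix (nm).
#' @param donors Two-column integer matrix of (donor heavy atom, hydrogen)
#'   index pairs; every donor must have its hydrogen present.
#' @param acceptors Integer vector of acceptor atom indices.
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance_nm`, `angle_deg`.
#' @export
find_hbonds <- function(coords, donors, acceptors, criteria = hbond_criteria()) {
  coords <- as.matrix(coords)
  if (is.null(donors) || length(donors) == 0L || length(acceptors) == 0L) {
    return(tibble::tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
      distance_nm = numeric(), angle_deg = numeric()))
  }
  donors <- matrix(as.integer(donors), ncol = 2L)
  out <- vector("list", nrow(donors))
  for (di in seq_len(nrow(donors))) {
    d <- donors[di, 1L]; h <- donors[di, 2L]
    dv <- sweep(coords[acceptors, , drop = FALSE], 2L, coords[d, ])
    dist <- sqrt(rowSums(dv^2))
    ok <- dist <= criteria$max_donor_acceptor_distance & acceptors != d & acceptors != h
    if (!any(ok)) next
    hv <- coords[h, ] - coords[d, ]
    cosang <- (dv[ok, , drop = FALSE] %*% hv) / (dist[ok] * sqrt(sum(hv^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    keep <- ang <= criteria$max_hda_angle
    if (!any(keep)) next
    out[[di]] <- tibble::tibble(
      donor = d, hydrogen = h, acceptor = acceptors[ok][keep],
      distance_nm = dist[ok][keep], angle_deg = as.numeric(ang[keep])
    )
  }
  res <- purrr::list_rbind(purrr::compact(out))
  if (nrow(res) == 0L) {
    res <- tibble::tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
      distance_nm = numeric(), angle_deg = numeric())
  }
  res
}

#' Per-frame hydrogen-bond count between two regions
#'
#' Counts, in each frame, hydrogen bonds whose donor lies in one region and
#' acceptor in the other (either direction); intra-region bonds are
#' excluded. The two regions must be disjoint. The summary mean and sample
#' standard deviation (n - 1) are attached as attributes, matching the
#' mean-plus-error-bar presentation conventional for such counts.
#'
#' @param x An [ensemble()] with hydrogens present.
#' @param region_a,region_b Region names (e.g. the active site loop and the
#'   beta13 strand).
#' @param regions A [region_set()].
#' @param criteria An [hbond_criteria()].
#' @param sidechains Include the side-chain donor/acceptor table (default
#'   `TRUE`; backbone N-H donors and carbonyl O acceptors are always used).
#' @return A tibble of class `count_series` with columns `frame`, `time_ps`,
#'   `count` and attributes `mean`, `sd`, `label`, `criteria`.
#' @export
hbond_count_series <- function(x, region_a, region_b, regions,
                               criteria = hbond_criteria(), sidechains = TRUE) {
  stopifnot(inherits(x, "ensemble"))
  res_a <- region_residues(regions, region_a)
  res_b <- region_residues(regions, region_b)
  key_a <- paste(res_a$chain, res_a$resno)
  key_b <- paste(res_b$chain, res_b$resno)
  if (length(intersect(key_a, key_b)) > 0L) {
    stop("hbond_count_series(): regions '", region_a, "' and '", region_b,
      "' overlap", call. = FALSE)
  }
  pa <- hbond_participants(x$atoms, key_a, sidechains = sidechains)
  pb <- hbond_participants(x$atoms, key_b, sidechains = sidechains)
  atom_key <- paste(x$atoms$chain, x$atoms$resno)
  in_a <- which(atom_key %in% key_a)
  in_b <- which(atom_key %in% key_b)
  donors <- rbind(pa$donors, pb$donors)
  acceptors <- c(pa$acceptors, pb$acceptors)
  counts <- integer(n_frames(x))
  for (f in seq_len(n_frames(x))) {
    hb <- find_hbonds(frame_coords(x, f), donors, acceptors, criteria)
    inter <- (hb$donor %in% in_a & hb$acceptor %in% in_b) |
      (hb$donor %in% in_b & hb$acceptor %in% in_a)
    counts[f] <- sum(inter)
  }
  count_series(counts, x$times,
    label = paste0(x$label, ": hbonds ", region_a, "<->", region_b),
    criteria = criteria)
}

count_series <- function(counts, times = NULL, label = "", criteria = NULL) {
  out <- tibble::tibble(
    frame = seq_along(counts),
    time_ps = if (is.null(times)) NA_real_ else times,
    count = as.integer(counts)
  )
  attr(out, "mean") <- mean(counts)
  attr(out, "sd") <- if (length(counts) > 1L) stats::sd(counts) else 0
  attr(out, "label") <- label
  attr(out, "criteria") <- criteria
  class(out) <- c("count_series", class(out))
  out
}

#' Summarise one or more count series
#'
#' @param ... `count_series` objects (optionally named).
#' @return Tibble with columns `label`, `mean`, `sd`, `n_frames`.
#' @export
count_summary <- function(...) {
  series <- list(...)
  if (length(series) == 1L && is.list(series[[1L]]) && !inherits(series[[1L]], "count_series")) {
    series <- series[[1L]]
  }
  purrr::imap(series, function(s, nm) {
    tibble::tibble(
      label = if (is.character(nm) && nzchar(nm)) nm else attr(s, "label"),
      mean = attr(s, "mean"), sd = attr(s, "sd"), n_frames = nrow(s)
    )
  }) |> purrr::list_rbind()
}
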
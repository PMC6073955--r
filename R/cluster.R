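#' Pairwise frame-frame RMSD matrix
#'
#' Symmetric `F x F` matrix of RMSD between every pair of frames over a
#' selection. `mode = "fitted"` performs a fresh Kabsch superposition per
#' pair; `mode = "distance"` uses the fit-free distance-matrix RMSD.
#'
#' @param x An [ensemble()] with `F >= 2`.
#' @param selection Integer atom indices.
#' @param mode `"distance"` (default) or `"fitted"`.
#' @return `F x F` symmetric numeric matrix (nm) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(x, selection, mode = c("distance", "fitted")) {
  stopifnot(inherits(x, "ensemble"))
  mode <- match.arg(mode)
  nf <- n_frames(x)
  if (nf < 2L) stop("pairwise_rmsd_matrix(): need >= 2 frames", call. = FALSE)
  frames <- lapply(seq_len(nf), function(f) frame_coords(x, f)[selection, , drop = FALSE])
  m <- matrix(0, nf, nf)
  if (mode == "distance") {
    dists <- lapply(frames, stats::dist)
    for (i in seq_len(nf - 1L)) {
      for (j in (i + 1L):nf) {
        m[i, j] <- m[j, i] <- sqrt(mean((dists[[i]] - dists[[j]])^2))
      }
    }
  } else {
    for (i in seq_len(nf - 1L)) {
      for (j in (i + 1L):nf) {
        m[i, j] <- m[j, i] <- kabsch_fit(frames[[i]], frames[[j]])$rmsd_after_fit
      }
    }
  }
  m
}

#' Single-linkage clustering of frames at a distance cutoff
#'
#' Frames belong to one cluster exactly when they are connected by a chain
#' of pairwise distances at most the cutoff (the connected components of
#' the threshold graph, equivalently single-linkage clusters cut at that
#' height). Cluster ids are assigned by descending size; ties are broken by
#' the smallest member frame index. The merge structure is computed with
#' [stats::hclust()].
#'
#' @param m Symmetric `F x F` distance matrix (nm) with zero diagonal.
#' @param cutoff Distance cutoff in nm (> 0). No universal default exists;
#'   0.1 nm is a conventional starting point, and the value is carried in
#'   the result so downstream tables can echo it.
#' @return A list of class `cluster_result`: `labels` (F integers),
#'   `sizes` (named integer vector), `cutoff`, `representatives`
#'   (filled by [representative()], otherwise `NULL`).
#' @export
linkage_cluster <- function(m, cutoff) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9) {
    stop("linkage_cluster(): distance matrix must be symmetric", call. = FALSE)
  }
  if (cutoff <= 0) stop("linkage_cluster(): cutoff must be > 0", call. = FALSE)
  nf <- nrow(m)
  raw <- if (nf == 1L) {
    1L
  } else {
    tree <- stats::hclust(stats::as.dist(m), method = "single")
    stats::cutree(tree, h = cutoff)
  }
  # relabel by descending size, ties by smallest member frame index
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(g) min(which(raw == as.integer(g))), integer(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- relabel[raw]
  structure(
    list(labels = labels, sizes = table(labels), cutoff = cutoff, representatives = NULL),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$sizes), " cluster(s) at cutoff ", x$cutoff,
    " nm; sizes: ", paste(utils::head(as.integer(x$sizes), 10L), collapse = ", "),
    "\n", sep = "")
  invisible(x)
}

#' Representative frame of each cluster
#'
#' The representative is the member with the smallest mean distance to all
#' other members of its cluster (ties broken by the smallest frame index);
#' a singleton represents itself.
#'
#' @param result A [linkage_cluster()] result.
#' @param m The distance matrix the clustering used.
#' @return `result` with `representatives` filled (named integer vector,
#'   cluster id -> frame index).
#' @export
representative <- function(result, m) {
  stopifnot(inherits(result, "cluster_result"))
  m <- as.matrix(m)
  reps <- integer(length(result$sizes))
  for (cl in seq_along(result$sizes)) {
    members <- which(result$labels == cl)
    if (length(members) == 1L) {
      reps[cl] <- members
    } else {
      mean_d <- vapply(members, function(i) {
        mean(m[i, setdiff(members, i)])
      }, numeric(1))
      reps[cl] <- members[which.min(mean_d)] # which.min takes the first tie
    }
  }
  names(reps) <- seq_along(reps)
  result$representatives <- reps
  result
}

#' Tidy a clustering into a per-frame tibble
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble with columns `frame`, `cluster`.
#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$labels), cluster = x$labels)
}
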
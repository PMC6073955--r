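# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# O(n^2 F) double-loop Pearson cross-correlation of displacement vectors
oracle_dccm <- function(coords) {
  f <- dim(coords)[1L]; n <- dim(coords)[2L]
  mu <- apply(coords, c(2L, 3L), mean)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0; vi <- 0; vj <- 0
      for (t in seq_len(f)) {
        di <- coords[t, i, ] - mu[i, ]
        dj <- coords[t, j, ] - mu[j, ]
        num <- num + sum(di * dj); vi <- vi + sum(di^2); vj <- vj + sum(dj^2)
      }
      out[i, j] <- num / sqrt(vi * vj)
    }
  }
  out
}

# hand double-loop RMSD
oracle_coordinate_rmsd <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) s <- s + sum((a[i, ] - b[i, ])^2)
  sqrt(s / nrow(a))
}

# brute-force pair-distance RMSD
oracle_distance_rmsd <- function(a, b) {
  n <- nrow(a); s <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      da <- sqrt(sum((a[i, ] - a[j, ])^2))
      db <- sqrt(sum((b[i, ] - b[j, ])^2))
      s <- s + (da - db)^2; np <- np + 1
    }
  }
  sqrt(s / np)
}

# brute-force quaternion search for the minimal RMSD over proper rotations:
# a coarse quaternion grid followed by Nelder-Mead refinement of the
# quaternion components (independent of the SVD route under test)
oracle_min_rmsd_rotation <- function(mobile, reference, n_grid = 16) {
  pm <- sweep(mobile, 2, colMeans(mobile))
  pr <- sweep(reference, 2, colMeans(reference))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(mean(rowSums((pm %*% t(quat_rot(q)) - pr)^2)))
  best <- Inf; best_q <- c(1, 0, 0, 0)
  ang <- seq(0, pi, length.out = n_grid)
  az <- seq(0, 2 * pi, length.out = 2 * n_grid)
  th <- seq(0, 2 * pi, length.out = 2 * n_grid)
  for (a1 in ang) for (a2 in az) for (a3 in th) {
    axis <- c(sin(a1) * cos(a2), sin(a1) * sin(a2), cos(a1))
    q <- c(cos(a3 / 2), sin(a3 / 2) * axis)
    r <- obj(q)
    if (r < best) { best <- r; best_q <- q }
  }
  ref1 <- stats::optim(best_q, obj, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-15))
  ref2 <- stats::optim(ref1$par, obj, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-15))
  min(best, ref2$value)
}

# connected components of the threshold graph by breadth-first search
oracle_components <- function(m, cutoff) {
  n <- nrow(m)
  adj <- m <= cutoff
  diag(adj) <- TRUE
  comp <- rep(0L, n); k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# closed-form normal equations + textbook t inference
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  alpha <- mean(y) - beta * mean(x)
  resid <- y - alpha - beta * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(alpha = alpha, beta = beta, p = p, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
}

random_proper_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# small random ensemble around a compact mean structure
random_ensemble <- function(n_res, n_frames, sd = 0.05, seed = 1) {
  set.seed(seed)
  base <- cbind(sin(1:n_res), cos(0.7 * (1:n_res)), 0.3 * (1:n_res))
  coords <- array(0, dim = c(n_frames, n_res, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- base + matrix(rnorm(n_res * 3, sd = sd), n_res, 3)
  atoms <- tibble::tibble(
    serial = seq_len(n_res), name = "CA", element = "C", resname = "GLY",
    resno = seq_len(n_res), chain = "A"
  )
  ensemble(coords, atoms, label = "random")
}

ks_energy_direct <- function(r_on, r_ch, r_oh, r_cn) {
  # distances in Angstrom
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}
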
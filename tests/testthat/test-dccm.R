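test_that("dccm satisfies its matrix invariants and the definition limits", {
  e <- random_ensemble(6, 30, seed = 1)
  d <- dccm(e, 1:6)
  m <- unclass(d)
  expect_equal(max(abs(m - t(m))), 0, tolerance = 1e-12)
  expect_equal(unname(diag(m)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(m >= -1 & m <= 1))
  # identical displacement series -> +1; negated -> -1
  coords <- e$coords
  coords[, 2, ] <- coords[, 1, ] + 0.5 # same displacements, offset mean
  mu <- apply(coords[, 1, ], 2, mean)
  coords[, 3, ] <- -sweep(coords[, 1, ], 2, mu) + 2 # exactly negated
  e2 <- ensemble(coords, e$atoms)
  d2 <- unclass(dccm(e2, 1:6))
  expect_equal(d2[1, 2], 1, tolerance = 1e-12)
  expect_equal(d2[1, 3], -1, tolerance = 1e-12)
})

test_that("dccm equals the brute-force double-loop oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:12, 1); f <- sample(40:100, 1)
    e <- random_ensemble(n, f, sd = 0.08, seed = seed + 100)
    expect_equal(unclass(dccm(e, seq_len(n))), oracle_dccm(e$coords),
      ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("dccm agrees with the established reference implementation", {
  e <- random_ensemble(8, 50, seed = 42)
  ours <- unclass(dccm(e, 1:8))
  xyz <- t(apply(e$coords, 1, function(fr) as.vector(t(fr))))
  ref <- bio3d::dccm.xyz(xyz, pre.fit = FALSE)
  expect_equal(ours, unclass(ref), ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("dccm recovers a planted correlation block through the full fit", {
  n <- 150; loop <- 101:115; tail <- 116:150
  cm <- planted_block_correlation(n, loop, tail, -0.6)
  sig <- c(rep(0.05, 100), rep(0.08, 15), rep(0.10, 35))
  e <- generate_correlated_ensemble(1:n, sig, cm, 5000, seed = 17,
    rigid_contamination = TRUE)
  d <- dccm(fit_ensemble(e, 1:100), 1:n)
  expect_equal(mean(unclass(d)[loop, tail]), -0.6, tolerance = 0.05)
})

test_that("dccm is invariant under displacement scaling and pre-fit rigid motion", {
  e <- random_ensemble(7, 60, seed = 3)
  base <- unclass(dccm(e, 1:7))
  mu <- apply(e$coords, c(2, 3), mean)
  scaled <- e$coords
  for (f in seq_len(60)) scaled[f, , ] <- mu + 2.5 * (e$coords[f, , ] - mu)
  expect_equal(unclass(dccm(ensemble(scaled, e$atoms), 1:7)), base,
    ignore_attr = TRUE, tolerance = 1e-10)
  rot <- random_proper_rotation()
  moved <- e$coords
  for (f in seq_len(60)) {
    moved[f, , ] <- sweep(matrix(e$coords[f, , ], ncol = 3) %*% t(rot), 2, c(1, 2, 3), `+`)
  }
  em <- fit_ensemble(ensemble(moved, e$atoms), 1:7, reference = frame_coords(e, 1))
  ef <- fit_ensemble(e, 1:7, reference = frame_coords(e, 1))
  expect_equal(unclass(dccm(em, 1:7)), unclass(dccm(ef, 1:7)),
    ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("zero-variance atoms are reported", {
  e <- random_ensemble(5, 20, seed = 4)
  frozen <- e$coords
  frozen[, 3, ] <- rep(c(1, 2, 3), each = 20)
  expect_error(dccm(ensemble(frozen, e$atoms), 1:5), "residue")
})

test_that("region_mean_correlation averages the loop block per tail residue", {
  # constant matrix
  e <- random_ensemble(10, 40, seed = 5)
  d <- dccm(e, 1:10)
  regs <- region_set(loop = list(chain = "A", start = 1, end = 2),
    tail = list(chain = "A", start = 3, end = 5))
  prof <- region_mean_correlation(d, "loop", "tail", regs)
  m <- unclass(d)
  expect_equal(prof$mean_cij, unname(colMeans(m[1:2, 3:5])), tolerance = 1e-14)
  expect_equal(prof$residue, 3:5)
  # symmetry: swapping regions gives the transpose profile
  prof_T <- region_mean_correlation(d, "tail", "loop", regs)
  expect_equal(prof_T$mean_cij, unname(colMeans(t(m[1:2, 3:5]))), tolerance = 1e-14)
  # hand 2x3 toy block
  expect_equal(prof$mean_cij[1], mean(c(m[1, 3], m[2, 3])))
  expect_error(region_mean_correlation(d, "loop", "absent", regs), "not found")
  regs2 <- region_set(loop = list(chain = "A", start = 1, end = 2),
    out = list(chain = "A", start = 90, end = 95))
  expect_error(region_mean_correlation(d, "loop", "out", regs2), "outside")
})

test_that("profile length matches the 35-residue tail convention", {
  sc <- dimer_scenario(n_frames = 40, seed = 2, rigid_contamination = FALSE)
  dd <- make_asymmetric_dimer(sc)
  e <- dd$chain_a
  ca <- which(e$atoms$name == "CA")
  d <- dccm(fit_ensemble(e, select_atoms(e, dd$regions_a, "conserved", "CA")), ca)
  prof <- region_mean_correlation(d, "loop", "c_tail", dd$regions_a)
  expect_equal(nrow(prof), 35)
})

test_that("delta profiles subtract B minus A and are antisymmetric", {
  pa <- tibble::tibble(residue = 1:3, mean_cij = c(-0.2, -0.3, -0.4))
  pb <- tibble::tibble(residue = 1:3, mean_cij = c(-0.5, -0.2, -0.1))
  ra <- tibble::tibble(chain = "A", residue_number = 1:3, rmsf_nm = c(0.1, 0.2, 0.3))
  rb <- tibble::tibble(chain = "B", residue_number = 1:3, rmsf_nm = c(0.2, 0.2, 0.5))
  dp <- delta_profiles(pa, pb, ra, rb)
  expect_equal(dp$delta_cij, c(-0.3, 0.1, 0.3))
  expect_equal(dp$delta_rmsf_nm, c(0.1, 0, 0.2))
  swapped <- delta_profiles(pb, pa, rb, ra)
  expect_equal(swapped$delta_cij, -dp$delta_cij)
  expect_equal(swapped$delta_rmsf_nm, -dp$delta_rmsf_nm)
  # identical protomers -> all zeros
  zz <- delta_profiles(pa, pa, ra, ra)
  expect_true(all(zz$delta_cij == 0) && all(zz$delta_rmsf_nm == 0))
  rb_bad <- tibble::tibble(chain = "B", residue_number = 2:4, rmsf_nm = 1:3 / 10)
  expect_error(delta_profiles(pa, pb, ra, rb_bad), "residue axes")
})

test_that("ols_regress recovers exact construction lines to machine precision", {
  x <- seq(-0.2, 0.4, length.out = 35)
  fit1 <- ols_regress(x, 0.17 - 0.40 * x)
  expect_equal(fit1$intercept, 0.17, tolerance = 1e-12)
  expect_equal(fit1$slope, -0.40, tolerance = 1e-12)
  expect_true(fit1$exact_fit)
  expect_equal(fit1$p_value, 0)
  fit2 <- ols_regress(x, -0.04 + 1.41 * x)
  expect_equal(fit2$intercept, -0.04, tolerance = 1e-12)
  expect_equal(fit2$slope, 1.41, tolerance = 1e-12)
})

test_that("ols_regress matches the closed-form oracle and the t distribution", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.3 + 0.8 * x + rnorm(n)
    fit <- ols_regress(x, y)
    o <- oracle_ols(x, y)
    expect_equal(fit$intercept, o$alpha, tolerance = 1e-10)
    expect_equal(fit$slope, o$beta, tolerance = 1e-10)
    expect_equal(fit$p_value, o$p, tolerance = 1e-10)
    expect_equal(fit$r2_adjusted, o$r2_adj, tolerance = 1e-10)
  }
  expect_error(ols_regress(rep(1, 5), rnorm(5)), "constant")
  expect_error(ols_regress(1:2, 1:2), "n >= 3")
})

test_that("ols_regress slope is order-invariant and equivariant under x scaling", {
  set.seed(10)
  x <- rnorm(20); y <- 1 - 2 * x + rnorm(20, sd = 0.3)
  f1 <- ols_regress(x, y)
  perm <- sample(20)
  f2 <- ols_regress(x[perm], y[perm])
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-12)
  f3 <- ols_regress(3 * x, y)
  expect_equal(f3$slope, f1$slope / 3, tolerance = 1e-12)
})

test_that("under the null the slope p-value is uniform", {
  set.seed(123)
  pvals <- replicate(400, {
    x <- rnorm(20); y <- rnorm(20)
    ols_regress(x, y)$p_value
  })
  rej <- mean(pvals < 0.05)
  # binomial 99.9% band around 0.05 at 400 replicates
  expect_gt(rej, 0.05 - 3.29 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rej, 0.05 + 3.29 * sqrt(0.05 * 0.95 / 400))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("tidy and glance methods expose broom-style summaries", {
  set.seed(11)
  fit <- ols_regress(rnorm(15), rnorm(15), label = "toy")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  gl <- glance(fit)
  expect_named(gl, c("intercept", "slope", "p_value", "r2_adjusted", "n", "exact_fit"))
  expect_equal(gl$n, 15)
})

test_that("asymmetry regression on a noise-free planted profile is exact", {
  sc <- dimer_scenario(seed = 1, slope = -1.10, intercept = -0.04)
  dd <- make_asymmetric_dimer(dimer_scenario(n_frames = 2, seed = 1,
    slope = -1.10, intercept = -0.04))
  fit <- asymmetry_regression(dd$planted)
  expect_equal(fit$slope, -1.10, tolerance = 1e-10)
  expect_equal(fit$intercept, -0.04, tolerance = 1e-10)
  expect_true(fit$exact_fit)
})
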
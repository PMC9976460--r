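test_that("init_sarw honours step length, exclusion and determinism", {
  x1 <- init_sarw(50, 55, 50, seed = 7)
  d <- sqrt(rowSums((x1[-1, ] - x1[-50, ])^2))
  expect_equal(d, rep(55, 49), tolerance = 1e-9)
  dm <- as.matrix(dist(x1))
  nonadj <- abs(row(dm) - col(dm)) > 1
  expect_gte(min(dm[nonadj]), 50)
  expect_identical(x1, init_sarw(50, 55, 50, seed = 7))
  expect_false(identical(x1, init_sarw(50, 55, 50, seed = 8)))
  expect_equal(init_sarw(1, 10, 5, seed = 1), matrix(0, 1, 3))
  expect_error(init_sarw(5, 10, 20, seed = 1), "exclusion")
})

test_that("force terms evaluate the spring equations and conserve momentum", {
  p <- sim_params(r_bead = 1, k_rep = 10)       # d_rep0 = 2
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  f <- force_repulsion(two, p)
  expect_equal(f[1, ], c(-10, 0, 0))            # pushed apart, magnitude 10
  expect_equal(f[2, ], c(10, 0, 0))
  at_rest <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(force_repulsion(at_rest, p), matrix(0, 2, 3))  # strict d < d0

  pt <- sim_params(k_ten = 5, r_bead = 1)       # c2 = 2
  stretched <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  ft <- force_tension(stretched, pt)
  expect_equal(ft[1, ], c(5, 0, 0))             # pulled together, magnitude 5
  rest_chain <- cbind(seq(0, 8, by = 2), 0, 0)
  expect_equal(force_tension(rest_chain, pt), matrix(0, 5, 3))
  # symmetric over-stretch: middle bead cancels
  tri <- cbind(c(0, 3, 6), 0, 0)
  expect_equal(force_tension(tri, pt)[2, ], c(0, 0, 0))

  ph <- sim_params(k_hic = 2, d_hic0 = 100)
  far <- matrix(c(0, 0, 0, 500, 0, 0), 2, 3, byrow = TRUE)
  fh <- force_hic(far, data.frame(i = 0, j = 1), ph)
  expect_equal(fh[1, ], c(800, 0, 0))           # K (d - d0) = 2 * 400
  expect_equal(force_hic(far, NULL, ph), matrix(0, 2, 3))
  at_d0 <- matrix(c(0, 0, 0, 100, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(force_hic(at_d0, data.frame(i = 0, j = 1), ph), matrix(0, 2, 3))
  expect_error(force_hic(far, data.frame(i = 0, j = 5), ph), "out of range")

  # Newton's third law on random configurations, all three terms
  p2 <- sim_params(r_bead = 60)                 # large radius: many active pairs
  for (s in 1:5) {
    conf <- random_conf(30, seed = s, spread = 100)
    cons <- data.frame(i = c(0, 3, 10), j = c(20, 25, 29))
    for (f in list(force_repulsion(conf, p2), force_tension(conf, p2),
                   force_hic(conf, cons, p2)))
      expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("step_verlet integrates the damped equation of motion", {
  p <- sim_params()
  # zero force, zero velocity: nothing moves
  chain <- cbind(seq(0, by = p$c2, length.out = 4), 0, 0)
  st <- sim_state(chain)
  st1 <- step_verlet(st, NULL, p)
  expect_equal(st1$x, chain)

  # terminal velocity F / gamma of a single dragged bead
  st <- sim_state(matrix(0, 1, 3))
  fext <- matrix(c(2, 0, 0), 1, 3)
  for (k in 1:3000) st <- step_verlet(st, NULL, p, f_ext = fext)
  expect_equal(st$v[1, 1], 2 / p$gamma, tolerance = 0.01)

  # two-bead tension spring equilibrates to c2
  st <- sim_state(matrix(c(0, 0, 0, 200, 0, 0), 2, 3, byrow = TRUE))
  for (k in 1:5000) st <- step_verlet(st, NULL, p)
  expect_equal(sqrt(sum((st$x[2, ] - st$x[1, ])^2)), p$c2, tolerance = 1e-3)
})

test_that("pseudo_energy sums kinetic and engaged-spring potential terms", {
  p <- sim_params(k_ten = 5, r_bead = 1)        # c2 = 2
  rest <- sim_state(cbind(c(0, 2, 4), 0, 0))
  expect_equal(pseudo_energy(rest, NULL, p), 0)

  stretched <- sim_state(matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(pseudo_energy(stretched, NULL, p), 2.5)   # 1/2 * 5 * 1^2

  moving <- sim_state(cbind(c(0, 2), 0, 0))
  moving$v <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(pseudo_energy(moving, NULL, p), 0.5)      # 1/2 m v^2
})

test_that("rmsd removes rigid motions and matches a rotation-grid oracle", {
  a <- random_conf(10, seed = 3, spread = 2)
  expect_equal(rmsd(a, a), 0)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  expect_lt(rmsd(a, a %*% rot + 5), 1e-9)
  expect_equal(rmsd(a, a %*% rot + 5), rmsd(a %*% rot + 5, a))
  expect_error(rmsd(a, a[1:5, ]), "shape")

  # brute-force minimisation over an Euler-angle grid on 4-bead toys
  set.seed(11)
  x <- matrix(rnorm(12), 4, 3)
  y <- matrix(rnorm(12), 4, 3)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  half <- seq(0, pi, length.out = 13)
  best <- Inf
  for (a1 in ang) for (a2 in half) for (a3 in ang) {
    r1 <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    r2 <- matrix(c(1, 0, 0, 0, cos(a2), -sin(a2), 0, sin(a2), cos(a2)), 3, 3, byrow = TRUE)
    r3 <- matrix(c(cos(a3), -sin(a3), 0, sin(a3), cos(a3), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    val <- sqrt(mean(rowSums((yc - xc %*% (r1 %*% r2 %*% r3))^2)))
    if (val < best) best <- val
  }
  k <- rmsd(x, y)
  expect_lte(k, best + 1e-9)        # Kabsch is the true minimum
  expect_lt(best - k, 0.1)          # grid gets close at 15-degree resolution
})

test_that("reconstruct relaxes a free chain and is seed-deterministic", {
  p <- sim_params(n_steps = 3000L, n_replicates = 2L, seed = 5L)
  fit <- reconstruct(NULL, params = p, n_beads = 20L)
  expect_length(fit$replicates, 2L)
  for (rep in fit$replicates) {
    conf <- rep$conformation
    d <- sqrt(rowSums((conf[-1, ] - conf[-20, ])^2))
    expect_equal(d, rep(p$c2, 19), tolerance = 0.02)
    expect_equal(rep$metrics$rmsd_to_final[nrow(rep$metrics)], 0,
                 tolerance = 1e-9)
  }
  fit2 <- reconstruct(NULL, params = p, n_beads = 20L)
  expect_identical(fit$replicates[[1]]$conformation,
                   fit2$replicates[[1]]$conformation)
})

test_that("validate_model returns the documented correlations", {
  conf <- cbind(seq(0, 900, by = 100), 0, 0)    # distances grow with |i-j|
  cons <- data.frame(i = c(0, 0, 0), j = c(1, 2, 3), IF = c(30, 20, 10))
  v <- validate_model(conf, cons)
  expect_equal(v$spearman, -1)                  # distance decreasing in IF

  d <- sqrt(rowSums((conf[cons$j + 1, ] - conf[cons$i + 1, ])^2))
  vp <- validate_model(conf, data.frame(i = cons$i, j = cons$j, IF = 7 / d))
  expect_equal(vp$cosine, 1)                    # IF proportional to 1/d

  expect_error(validate_model(conf, cons[1:2, ]), "at least 3")

  # null: random distances independent of IF
  set.seed(99)
  conf2 <- random_conf(300, seed = 1, spread = 300)
  cons2 <- data.frame(i = sample(0:149, 1000, TRUE))
  cons2$j <- cons2$i + sample(2:150, 1000, TRUE)
  cons2$IF <- rexp(1000)
  expect_lt(abs(validate_model(conf2, cons2)$spearman), 0.1)
})
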
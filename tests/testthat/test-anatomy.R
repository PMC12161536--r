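square4 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)

test_that("layer pairing of identical layers is the identity bijection", {
  st <- cross_section_stack(list(square4, square4), c(0, 10))
  paths <- build_fiber_paths(st)
  expect_length(paths, 4L)
  for (f in 1:4) {
    expect_equal(paths[[f]][1, 1:2], paths[[f]][2, 1:2],
                 ignore_attr = TRUE)  # each point pairs with itself
  }
  # every point used exactly once
  ends <- t(vapply(paths, function(p) p[2, 1:2], numeric(2)))
  expect_equal(ends[order(ends[, 1], ends[, 2]), ],
               square4[order(square4[, 1], square4[, 2]), ],
               ignore_attr = TRUE)
})

test_that("pairing is a bijection that matches recursive-cell geometry", {
  set.seed(42)
  for (n in c(2, 8, 16, 33, 64)) {
    a <- matrix(runif(2 * n), ncol = 2)
    perm <- sample.int(n)
    b <- a[perm, , drop = FALSE]  # same geometry, shuffled indices
    st <- cross_section_stack(list(a, b), c(0, 5))
    paths <- build_fiber_paths(st)
    # bijection: each second-layer point used exactly once
    ends <- t(vapply(paths, function(p) p[2, 1:2], numeric(2)))
    expect_equal(nrow(unique(ends)), n)
    # identical geometry across layers -> each point maps to itself
    starts <- t(vapply(paths, function(p) p[1, 1:2], numeric(2)))
    expect_equal(starts, ends, ignore_attr = TRUE)
  }
})

test_that("a stack of k layers yields k waypoints per fiber and errors on bad stacks", {
  set.seed(1)
  a <- matrix(runif(24), ncol = 2)
  st <- cross_section_stack(rep(list(a), 7), seq(0, 120, by = 20))
  paths <- build_fiber_paths(st)
  expect_true(all(vapply(paths, nrow, integer(1)) == 7L))
  # single-point layers: one fiber whose path is the stacked points
  st1 <- cross_section_stack(list(matrix(c(1, 2), 1), matrix(c(3, 4), 1)),
                             c(0, 9))
  p1 <- build_fiber_paths(st1)
  expect_length(p1, 1L)
  expect_equal(p1[[1]][, "z"], c(0, 9), ignore_attr = TRUE)
  expect_error(cross_section_stack(list(a, a[-1, ]), c(0, 1)), "unequal")
  expect_error(cross_section_stack(list(a, a), c(1, 1)), "increasing")
})

test_that("motor-unit dispersion scales linearly with R and has std R*lambda", {
  d0 <- disperse_motor_unit(1, 1e-9, 50, seed = 1)
  expect_lt(max(abs(d0)), 1e-6)  # zero-variance limit collapses to origin
  d1 <- disperse_motor_unit(1, 0.3, 40, seed = 7)
  d2 <- disperse_motor_unit(2, 0.3, 40, seed = 7)
  expect_equal(d2, 2 * d1)
  big <- disperse_motor_unit(1, 0.3, 10000, seed = 3)
  expect_equal(sd(big[, 1]), 0.3, tolerance = 0.03)
  expect_equal(sd(big[, 2]), 0.3, tolerance = 0.03)
  expect_equal(colMeans(big), c(x = 0, y = 0), tolerance = 0.02)
  expect_error(disperse_motor_unit(-1, 0.3, 5), "positive")
  expect_error(disperse_motor_unit(1, 0, 5), "positive")
})

test_that("unit-to-position assignment is a perfect matching that respects clusters", {
  # two tight clusters, two units of matching sizes
  set.seed(5)
  cl1 <- cbind(rnorm(6, 0, 0.1), rnorm(6, 0, 0.1))
  cl2 <- cbind(rnorm(6, 30, 0.1), rnorm(6, 30, 0.1))
  pts <- rbind(cl1, cl2)
  layout <- structure(list(mu_sizes = c(6L, 6L), R_pct = c(1, 1),
                           lambda_frac = c(0.2, 0.2)), class = "mu_layout")
  got <- assign_mus_to_positions(layout, pts, seed = 9)
  expect_equal(sort(unlist(got)), 1:12)  # every point owned exactly once
  # tight dispersion on clustered points: each unit stays in one cluster
  cluster_of <- rep(1:2, each = 6)
  purity <- vapply(got, function(ix) max(table(cluster_of[ix])) / length(ix),
                   numeric(1))
  expect_true(all(purity == 1))
  # a single unit covering all points owns them all
  lay1 <- structure(list(mu_sizes = 12L, R_pct = 50, lambda_frac = 0.3),
                    class = "mu_layout")
  got1 <- assign_mus_to_positions(lay1, pts, seed = 2)
  expect_equal(sort(got1[[1]]), 1:12)
  expect_error(assign_mus_to_positions(lay1, pts[-1, ], seed = 2), "count")
})

test_that("unit layout conserves fiber counts and scales dispersion with size", {
  cfg <- tiny_config()
  for (seed in 1:3) {
    lay <- make_mu_layout(cfg, n_fib = 300L, seed = seed)
    expect_equal(sum(lay$mu_sizes), 300L)
    expect_true(all(lay$mu_sizes >= 1L))
    expect_true(all(lay$R_pct >= 4 & lay$R_pct <= 40))
    expect_true(all(lay$lambda_frac >= 0.2 & lay$lambda_frac <= 0.5))
    # dispersion means track unit size
    if (length(unique(lay$mu_sizes)) > 2L)
      expect_gt(cor(lay$mu_sizes, lay$R_pct), 0)
  }
})

test_that("fiber-type conversion reaches targets and concentrates slow fibers in small units", {
  set.seed(10)
  mu_sizes <- sample(c(rep(20, 5), rep(60, 5)))
  size_per_fiber <- rep(mu_sizes, times = mu_sizes)
  ft <- assign_fiber_types(size_per_fiber, c(I = 100, IIa = 0, IIx = 0), seed = 2)
  expect_true(all(ft == "I"))
  for (seed in 1:4) {
    ft <- assign_fiber_types(size_per_fiber, c(I = 50, IIa = 28, IIx = 22),
                             seed = seed)
    pct <- as.numeric(table(ft)) / length(ft) * 100
    expect_true(all(abs(pct - c(50, 28, 22)) <= 1),
                label = sprintf("seed %d realized within 1 pp", seed))
    expect_lte(mean(size_per_fiber[ft == "I"]),
               mean(size_per_fiber[ft == "IIx"]))
  }
  expect_error(assign_fiber_types(size_per_fiber, c(I = 60, IIa = 60, IIx = -20)),
               "non-negative")
})

test_that("per-fiber parameters follow their type distributions and the cv map", {
  cfg <- tiny_config()
  n <- 10000L
  path <- cbind(x = 0, y = 0, z = c(0, 150))
  paths <- rep(list(path), n)
  ft <- factor(rep("I", n), levels = c("I", "IIa", "IIx"))
  a <- sample_fiber_parameters(ft, paths, rep(1L, n), cfg, seed = 4)
  f <- a$fibers
  expect_equal(mean(f$r), 20, tolerance = 0.02)
  expect_equal(sd(f$r), 5, tolerance = 0.05)
  expect_true(all(f$r > 0 & f$sigma_ic > 0 & f$thr > 0))
  expect_equal(f$d, 2 * f$r)
  # cv is the affine image of r*sigma_ic on [3, 5]
  prod <- f$r * f$sigma_ic
  expect_equal(f$cv[which.min(prod)], 3)
  expect_equal(f$cv[which.max(prod)], 5)
  expect_true(all(diff(f$cv[order(prod)]) >= 0))
  # NMJ lies on the fiber polyline at the drawn z-plane
  expect_true(all(f$nmj_z >= 0 & f$nmj_z <= 150))
  expect_equal(f$nmj_z, 150 - f$nmj_frac * 150, tolerance = 1e-9)
  expect_equal(f$nmj_arc, f$nmj_z, tolerance = 1e-9)  # straight vertical fiber
  # degenerate population: constant product maps to the midpoint
  ft2 <- factor(rep("I", 3), levels = c("I", "IIa", "IIx"))
  cfg2 <- cfg
  cfg2$table1$fiber$I$r <- c(20, 1e-12)
  cfg2$table1$fiber$I$sigma_ic <- c(0.35, 1e-12)
  a2 <- sample_fiber_parameters(ft2, paths[1:3], rep(1L, 3), cfg2, seed = 1)
  expect_equal(a2$fibers$cv, rep(4, 3), tolerance = 1e-6)
  expect_error(sample_fiber_parameters(ft[0], list(), integer(), cfg), "empty")
})

test_that("a full anatomy build is consistent and persists through text round-trip", {
  a <- tiny_anatomy()
  f <- a$fibers
  expect_equal(nrow(f), 300L)
  expect_equal(sort(unique(f$mu_id)), seq_along(a$layout$mu_sizes))
  expect_equal(as.numeric(table(f$mu_id)), a$layout$mu_sizes)
  pct <- as.numeric(table(f$ftype)) / nrow(f) * 100
  expect_true(all(abs(pct - c(50, 28, 22)) <= 1))
  dir <- tempfile("anat")
  write_anatomy(a, dir)
  b <- read_anatomy(dir)
  expect_equal(b$fibers$thr, f$thr, tolerance = 1e-12)
  expect_equal(b$paths[[17]], a$paths[[17]], tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
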
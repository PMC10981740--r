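test_that("kernel rate is k exp(-w^b) inside D_max and zero beyond", {
  kp <- kernel_params(D_max = 5, b = 1, k_value = 0.01314)
  expect_equal(kernel_delta(6, kp), 0)
  expect_equal(kernel_delta(0, kp), 0.01314)
  expect_equal(kernel_delta(1, kp), 0.004833936, tolerance = 1e-7)
  # shape constant bends the decay
  kp2 <- kernel_params(D_max = 5, b = 2, k_value = 1)
  expect_equal(kernel_delta(2, kp2), exp(-4))
  expect_equal(kernel_delta(5.0001, kp2), 0)
})

test_that("two cells 4 km apart exchange k*exp(-4)", {
  rmap <- planar_grid(0.1, 1, 2, km = 4)
  kp <- kernel_params(D_max = 5, b = 1, k_value = 0.1, distance = "planar")
  D <- build_dispersal_matrix(rmap, kp)
  expect_equal(D[1, 2], 0.1 * exp(-4), tolerance = 1e-12)
  expect_equal(D[2, 1], 0.1 * exp(-4), tolerance = 1e-12)
  expect_equal(D[1, 1], 0)
})

test_that("at ~4.6 km spacing only rook neighbours connect", {
  rmap <- planar_grid(0.1, 3, 3, km = 4.6)
  D <- build_dispersal_matrix(rmap, kernel_params(distance = "planar",
                                                  k_value = 0.01))
  expect_equal(length(D@x), 24)  # 12 rook edges, both directions
  # diagonal neighbours are ~6.5 km apart: excluded
  expect_equal(D[1, 5], 0)
  expect_gt(D[1, 2], 0)
})

test_that("sparse construction equals a brute-force O(n^2) oracle", {
  sc <- synthetic_scenario(seed = 3)
  land <- synth_landscape(sc, corridors = TRUE)
  rmap <- build_r_map(sc$growth_truth, land$temperature, land$suitability)
  # restrict to a 20 x 18 block for the oracle
  sub <- grid_raster(rmap$values[1:20, 1:18], rmap$xll,
                     rmap$yll + (nrow(rmap$values) - 20) * rmap$cellsize,
                     rmap$cellsize)
  kp <- kernel_params(D_max = 5, b = 1, k_value = 0.013)
  D <- build_dispersal_matrix(sub, kp)
  co <- grid_coords(sub)
  n <- nrow(co)
  oracle <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- geosphere::distHaversine(c(co$lon[i], co$lat[i]),
                                  cbind(co$lon, co$lat)) / 1000
    row <- ifelse(w <= 5, 0.013 * exp(-w), 0)
    row[i] <- 0
    oracle[i, ] <- row
  }
  expect_lt(max(abs(as.matrix(D) - oracle)), 1e-12)
  # symmetry in global-k mode
  expect_lt(max(abs(D - Matrix::t(D))), 1e-12)
})

test_that("per-source mode scales outflow by the source growth rate", {
  rmap <- planar_grid(0.1, 1, 2, km = 4)
  rmap$values[1, 2] <- 0.05
  kp <- kernel_params(distance = "planar", k_mode = "per_source")
  D <- build_dispersal_matrix(rmap, kp)
  expect_equal(D[1, 2], 0.01 * exp(-4), tolerance = 1e-12)
  expect_equal(D[2, 1], 0.005 * exp(-4), tolerance = 1e-12)
})

test_that("a D_max below the cell spacing yields a loud all-zero matrix", {
  rmap <- planar_grid(0.1, 2, 2, km = 8)
  expect_warning(D <- build_dispersal_matrix(
    rmap, kernel_params(D_max = 5, distance = "planar", k_value = 0.01)),
    "all-zero")
  expect_equal(length(D@x), 0)
})

test_that("isolated cell follows the closed-form logistic to 0.1%", {
  rmap <- grid_raster(matrix(0.13), -100, 17, 0.05)
  D0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  res <- simulate_invasion(rmap, D0, a = 1e-6,
                           seeds = data.frame(cell = 1, x0 = 100),
                           t_end = 400, dt_out = 10)
  K <- 0.13 / 1e-6
  analytic <- K / (1 + ((K - 100) / 100) * exp(-0.13 * res$times))
  expect_lt(max(abs(res$x[, 1] - analytic) / analytic), 0.001)
  # equilibrium r/a reached
  expect_equal(res$x[length(res$times), 1], K, tolerance = 1e-3)
})

test_that("pure dispersal conserves total abundance on random sparse matrices", {
  set.seed(17)
  for (trial in 1:3) {
    n <- 60
    D <- Matrix::rsparsematrix(n, n, density = 0.08,
                               rand.x = function(m) runif(m, 0, 0.05))
    D <- Matrix::drop0(abs(D))
    diag(D) <- 0
    rmap <- grid_raster(matrix(0, 6, 10), -100, 17, 0.05)
    res <- simulate_invasion(rmap, D, a = 0,
                             seeds = data.frame(cell = sample(n, 1), x0 = 100),
                             t_end = 100, dt_out = 20)
    expect_lt(abs(res$total[length(res$total)] - 100) / 100, 1e-6)
  }
})

test_that("symmetric kernel with zero growth equilibrates to uniform", {
  rmap <- planar_grid(0, 3, 3, km = 1)
  D <- build_dispersal_matrix(rmap, kernel_params(D_max = 1.5,
                                                  distance = "planar",
                                                  k_value = 0.1))
  expect_lt(max(abs(D - Matrix::t(D))), 1e-12)
  res <- simulate_invasion(rmap, D, a = 0,
                           seeds = data.frame(cell = 1, x0 = 90),
                           t_end = 4000, dt_out = 500, dt = 0.5)
  final <- res$x[nrow(res$x), ]
  expect_equal(unname(final), rep(10, 9), tolerance = 1e-4)
})

test_that("small populations decay without dispersal and never go negative", {
  rmap <- grid_raster(matrix(c(0, 0), 1, 2), -100, 17, 0.05)
  rmap$values[1, 1] <- -0.05  # decaying cell
  D0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(2, 2))
  res <- simulate_invasion(rmap, D0, a = 1e-7,
                           seeds = data.frame(cell = 1, x0 = 0.5),
                           t_end = 200, dt_out = 10)
  expect_true(all(res$x >= 0))
  expect_lt(res$x[nrow(res$x), 1], 0.5)
})

test_that("halving the step leaves the final state within solver tolerance", {
  sc <- synthetic_scenario(seed = 3)
  land <- synth_landscape(sc, corridors = TRUE)
  rmap <- build_r_map(sc$growth_truth, land$temperature, land$suitability)
  D <- build_dispersal_matrix(rmap, kernel_params())
  seeds <- data.frame(cell = which(land$masks$warm)[1], x0 = 100)
  r1 <- simulate_invasion(rmap, D, seeds = seeds, t_end = 200, dt_out = 50,
                          dt = 0.5)
  r2 <- simulate_invasion(rmap, D, seeds = seeds, t_end = 200, dt_out = 50,
                          dt = 0.25)
  denom <- pmax(abs(r2$x[nrow(r2$x), ]), 1)
  expect_lt(max(abs(r1$x[nrow(r1$x), ] - r2$x[nrow(r2$x), ]) / denom), 1e-4)
})

test_that("adaptive solver agrees with fixed-step RK4", {
  rmap <- grid_raster(matrix(0.13), -100, 17, 0.05)
  D0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  seeds <- data.frame(cell = 1, x0 = 100)
  r1 <- simulate_invasion(rmap, D0, a = 1e-6, seeds = seeds, t_end = 300,
                          dt_out = 50)
  r2 <- simulate_invasion(rmap, D0, a = 1e-6, seeds = seeds, t_end = 300,
                          dt_out = 50, solver = "adaptive")
  expect_equal(r1$x[, 1], r2$x[, 1], tolerance = 1e-5)
})

test_that("arrival times start at 0 on seeds and grow with graph distance", {
  rmap <- planar_grid(0.1, 1, 15, km = 4)
  D <- build_dispersal_matrix(rmap, kernel_params(distance = "planar",
                                                  k_value = 0.01))
  res <- simulate_invasion(rmap, D, a = 1e-6,
                           seeds = data.frame(cell = 1, x0 = 100),
                           t_end = 900, dt_out = 5)
  at <- arrival_times(res)
  expect_equal(at[1], 0)
  expect_true(all(is.finite(at)))
  expect_true(all(diff(at) >= 0))
  # never-colonized isolated cell gets Inf
  D2 <- isolate_cells(D, 15)
  res2 <- simulate_invasion(rmap, D2, a = 1e-6,
                            seeds = data.frame(cell = 1, x0 = 100),
                            t_end = 300, dt_out = 10)
  expect_identical(arrival_times(res2)[15], Inf)
})

test_that("coverage curve reports the time to target coverage", {
  rmap <- planar_grid(0.1, 1, 10, km = 4)
  D <- build_dispersal_matrix(rmap, kernel_params(distance = "planar",
                                                  k_value = 0.01))
  res <- simulate_invasion(rmap, D, a = 1e-6,
                           seeds = data.frame(cell = 1, x0 = 100),
                           t_end = 700, dt_out = 5)
  # seed-only mask is covered immediately
  m1 <- rep(FALSE, 10); m1[1] <- TRUE
  expect_equal(coverage_curve(res, m1)$t_cover, 0)
  cc <- coverage_curve(res, rep(TRUE, 10))
  expect_true(all(diff(cc$fraction) >= 0))
  expect_true(is.finite(cc$t_cover))
  # unreachable region stays at zero coverage
  D3 <- isolate_cells(D, 8:10)
  res3 <- simulate_invasion(rmap, D3, a = 1e-6,
                            seeds = data.frame(cell = 1, x0 = 100),
                            t_end = 300, dt_out = 10)
  m2 <- rep(FALSE, 10); m2[8:10] <- TRUE
  cc3 <- coverage_curve(res3, m2)
  expect_true(all(cc3$fraction == 0))
  expect_identical(cc3$t_cover, Inf)
  expect_error(coverage_curve(res, rep(FALSE, 10)), "empty region")
})

test_that("coordinate seeds snap to the nearest positive-growth cell", {
  sc <- synthetic_scenario(seed = 3)
  land <- synth_landscape(sc, corridors = TRUE)
  rmap <- build_r_map(sc$growth_truth, land$temperature, land$suitability)
  co <- grid_coords(rmap)
  dead <- which(as.vector(rmap$values) == 0)[1]
  seeds <- ambrosiarisk:::resolve_seeds(
    rmap, data.frame(lon = co$lon[dead], lat = co$lat[dead], x0 = 100))
  expect_gt(rmap$values[seeds$cell], 0)
})
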
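test_that("thinning keeps the first of close pairs and is idempotent", {
  occ <- data.frame(longitude = c(-99, -99, -98), latitude = c(18, 18, 18),
                    year = 1990)
  th <- thin_occurrences(occ)
  expect_equal(nrow(th), 2)
  expect_equal(th$longitude, c(-99, -98))
  # points 1 degree apart both survive the default distance
  far <- data.frame(longitude = c(-99, -98), latitude = 18, year = 1990)
  expect_equal(nrow(thin_occurrences(far)), 2)
  # idempotence
  set.seed(11)
  rnd <- data.frame(longitude = -99 + runif(200, 0, 0.05),
                    latitude = 18 + runif(200, 0, 0.05), year = 1990)
  t1 <- thin_occurrences(rnd)
  t2 <- thin_occurrences(t1)
  expect_identical(t1, t2)
})

test_that("thinning matches a brute-force greedy oracle on a lattice", {
  g <- expand.grid(longitude = seq(-99, -99 + 9 * 0.005, by = 0.005),
                   latitude = seq(18, 18 + 9 * 0.005, by = 0.005))
  g$year <- 1990
  kept <- thin_occurrences(g, min_dist = 0.0083)
  # oracle: independent O(n^2) pass over the full distance matrix
  d <- as.matrix(dist(g[, c("longitude", "latitude")]))
  keep <- integer(0)
  for (i in seq_len(nrow(g))) {
    if (!length(keep) || all(d[i, keep] >= 0.0083)) keep <- c(keep, i)
  }
  expect_equal(nrow(kept), length(keep))
  expect_equal(kept$longitude, g$longitude[keep])
})

test_that("correlation filter drops duplicated and anti-correlated columns", {
  set.seed(21)
  x <- rnorm(100)
  m <- cbind(a = x, b = x, c = -x, d = rnorm(100))
  expect_equal(filter_variables_by_correlation(m), c("a", "d"))
  # two independent noise columns both retained
  m2 <- cbind(u = rnorm(200), v = rnorm(200))
  expect_lt(abs(cor(m2[, 1], m2[, 2])), 0.8)
  expect_equal(filter_variables_by_correlation(m2), c("u", "v"))
  # zero-variance column excluded with a warning
  m3 <- cbind(k = rep(1, 50), w = rnorm(50))
  expect_warning(kept <- filter_variables_by_correlation(m3), "zero-variance")
  expect_equal(kept, "w")
})

test_that("extraction samples the layer matching each record's year", {
  mk <- function(v) flat_raster(v, nr = 4, nc = 4)
  stacks <- list("1990" = list(x = mk(1990), y = mk(5)),
                 "1991" = list(x = mk(1991), y = mk(6)))
  occ <- data.frame(longitude = c(-99.95, -99.9), latitude = c(17.05, 17.1),
                    year = c(1990, 1991))
  env <- extract_time_specific_env(occ, stacks)
  expect_equal(env[, "x"], c(1990, 1991))
  expect_equal(env[, "y"], c(5, 6))
  expect_equal(attr(env, "dropped"), 0)
  # out-of-extent record dropped and reported
  occ2 <- rbind(occ, data.frame(longitude = 0, latitude = 0, year = 1990))
  env2 <- extract_time_specific_env(occ2, stacks)
  expect_equal(nrow(env2), 2)
  expect_equal(attr(env2, "dropped"), 1)
  # unknown year is an error naming the year
  occ3 <- data.frame(longitude = -99.9, latitude = 17.1, year = 1889)
  expect_error(extract_time_specific_env(occ3, stacks), "1889")
})

test_that("ellipsoid suitability is 1 at the centroid and decays with D^2", {
  set.seed(31)
  m <- cbind(a = rnorm(300), b = rnorm(300, 10, 2))
  ni <- fit_ellipsoid(m)
  expect_equal(unname(niche_suitability(ni, ni$centroid)), 1)
  # closed form at Mahalanobis distance D^2 = 2
  ev <- eigen(ni$covariance)
  dir <- ev$vectors[, 1] * sqrt(ev$values[1])
  q <- ni$centroid + sqrt(2) * dir
  expect_equal(unname(niche_suitability(ni, q)), exp(-1), tolerance = 1e-9)
  # ordering matches brute-force Mahalanobis distances
  qs <- cbind(rnorm(50), rnorm(50, 10, 2))
  s <- niche_suitability(ni, qs)
  d2 <- mahalanobis(qs, ni$centroid, ni$covariance)
  expect_equal(order(s), order(-d2))
  # singular covariance advises variable reduction
  bad <- cbind(x = rnorm(50), y = 0)
  bad <- cbind(bad, z = bad[, "x"])
  expect_error(fit_ellipsoid(bad), "singular")
})

test_that("binarization uses the linear-interpolation 10th percentile", {
  calib <- seq(0.1, 1, by = 0.1)
  expect_equal(suitability_threshold(calib), 0.19)
  sr <- grid_raster(matrix(seq(0, 1, length.out = 25), 5), -100, 17, 0.05)
  bin <- binarize(NULL, calib, sr)
  expect_equal(bin$threshold, 0.19)
  expect_true(all(bin$raster$values[sr$values < 0.19] == 0))
  expect_true(all(bin$raster$values[sr$values >= 0.19] == 1))
  # raising the threshold never converts a 0 to a 1
  bin2 <- binarize(NULL, calib, sr, percentile = 0.5)
  expect_true(all(bin2$raster$values <= bin$raster$values))
  # equal calibration values: suitable iff >= that value
  binc <- binarize(NULL, rep(0.4, 12), sr)
  expect_equal(unname(binc$raster$values), unname(1 * (sr$values >= 0.4)))
})

test_that("at least 90% of calibration points fall inside the binary prediction", {
  set.seed(41)
  m <- cbind(a = rnorm(200, 20), b = rnorm(200, 100, 5))
  ni <- fit_ellipsoid(m)
  calib <- niche_suitability(ni, m)
  thr <- suitability_threshold(calib)
  expect_gte(mean(calib >= thr), 0.9)
})

test_that("partial ROC behaves like a null on random suitability", {
  ratios <- vapply(1:10, function(s) {
    set.seed(s)
    sr <- grid_raster(matrix(runif(60 * 60), 60), -100, 17, 0.05)
    co <- grid_coords(sr)
    pick <- sample(nrow(co), 40)
    tocc <- data.frame(longitude = co$lon[pick], latitude = co$lat[pick],
                       year = 2000)
    partial_roc(sr, tocc, iterations = 1000, background_n = 3600,
                seed = s)$auc_ratio_mean
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("partial ROC detects points concentrated on high-suitability cells", {
  v <- outer(seq(-1, 1, length = 60), seq(-1, 1, length = 60),
             function(x, y) exp(-(x^2 + y^2)))
  sr <- grid_raster(v, -100, 17, 0.05)
  co <- grid_coords(sr)
  vv <- as.vector(sr$values)
  set.seed(9)
  pick <- sample(which(vv >= quantile(vv, 0.9)), 40)
  tocc <- data.frame(longitude = co$lon[pick], latitude = co$lat[pick],
                     year = 2000)
  pr <- partial_roc(sr, tocc, iterations = 500, background_n = 3600, seed = 3)
  expect_gt(pr$auc_ratio_mean, 1)
  expect_lt(pr$p_value, 0.05)
  # constant raster is flagged degenerate with ratio 1
  flat <- flat_raster(0.5, 20, 20)
  pick2 <- sample(400, 15)
  tocc2 <- data.frame(longitude = grid_coords(flat)$lon[pick2],
                      latitude = grid_coords(flat)$lat[pick2], year = 2000)
  expect_warning(pr2 <- partial_roc(flat, tocc2, iterations = 50,
                                    background_n = 400, seed = 1),
                 "degenerate|constant")
  expect_equal(pr2$auc_ratio_mean, 1)
})

test_that("E = 0 integrates the full curve (classic AUC ratio)", {
  v <- outer(seq(-1, 1, length = 50), seq(-1, 1, length = 50),
             function(x, y) exp(-(x^2 + y^2)))
  sr <- grid_raster(v, -100, 17, 0.05)
  co <- grid_coords(sr); vv <- as.vector(sr$values)
  set.seed(13)
  pick <- sample(which(vv >= quantile(vv, 0.8)), 30)
  tocc <- data.frame(longitude = co$lon[pick], latitude = co$lat[pick],
                     year = 2000)
  pr <- partial_roc(sr, tocc, E = 0, iterations = 2000,
                    background_n = 2500, seed = 2)
  # oracle: classic AUC of sensitivity vs area on the full test set,
  # divided by the 0.5 diagonal area
  s_test <- vv[cell_from_xy(sr, tocc$longitude, tocc$latitude)]
  th <- sort(unique(quantile(vv, seq(0, 1, 0.005))), decreasing = TRUE)
  area <- vapply(th, function(t) mean(vv >= t), numeric(1))
  sens <- vapply(th, function(t) mean(s_test >= t), numeric(1))
  o <- order(area)
  auc <- sum(diff(area[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  oracle <- auc / 0.5
  expect_equal(pr$auc_ratio_mean, oracle, tolerance = 0.05)
})

test_that("binary-model evaluation reports omission, prevalence and binomial p", {
  bm <- grid_raster(cbind(matrix(1, 10, 5), matrix(0, 10, 5)), -100, 17, 0.1)
  co <- grid_coords(bm)
  idx <- c(which(co$col <= 5)[1:8], which(co$col > 5)[1:2])
  tocc <- data.frame(longitude = co$lon[idx], latitude = co$lat[idx],
                     year = 2000)
  ev <- evaluate_binary_model(bm, tocc, tocc)
  expect_equal(ev$omission_test, 0.2)
  expect_equal(ev$prevalence, 0.5)
  expect_equal(ev$binomial_p, 0.0546875, tolerance = 1e-7)
  # all points on presence cells: omission 0
  tocc1 <- tocc[1:8, ]
  expect_equal(evaluate_binary_model(bm, tocc1, tocc1)$omission_test, 0)
  # all-suitable raster: prevalence 1, binomial p 1
  allsuit <- flat_raster(1, 10, 10, cellsize = 0.1)
  ev2 <- evaluate_binary_model(allsuit, tocc1, tocc1)
  expect_equal(ev2$prevalence, 1)
  expect_equal(ev2$binomial_p, 1)
})

test_that("seeded 70/30 split is reproducible and exhaustive", {
  occ <- data.frame(longitude = runif(40, -100, -99),
                    latitude = runif(40, 17, 18), year = 1990)
  s1 <- split_occurrences(occ, seed = 4)
  s2 <- split_occurrences(occ, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$train), 28)
  expect_equal(nrow(s1$test), 12)
  expect_equal(sort(c(rownames(s1$train), rownames(s1$test))),
               sort(rownames(occ)))
})
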
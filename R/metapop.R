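#' Dispersal kernel parameters
#'
#' Distance-truncated exponential kernel: the migration rate between two
#' cells at distance w km is k * exp(-w^b) when w <= D_max and 0 beyond the
#' maximum daily travel distance D_max. `k_mode = "global"` uses a single
#' maximum migration capacity k (default r_max / 10, preserving the kernel's
#' symmetry and the irreducibility of the dispersal graph); `"per_source"`
#' scales each cell's outflow by its own growth rate, k_i = r_i / 10.
#'
#' @param D_max maximum daily travel distance, km (default 5).
#' @param b positive shape constant (default 1).
#' @param k_mode `"global"` or `"per_source"`.
#' @param k_value maximum migration capacity per day; in global mode a
#'   scalar (e.g. r_max / 10); ignored in per_source mode (derived from the
#'   r_i map).
#' @param distance `"haversine"` (km between cell centres, default) or
#'   `"planar"` (degree distance x 111.32 km/deg).
#' @return list of class `kernel_params`.
#' @export
kernel_params <- function(D_max = 5, b = 1,
                          k_mode = c("global", "per_source"),
                          k_value = NULL,
                          distance = c("haversine", "planar")) {
  k_mode <- match.arg(k_mode)
  distance <- match.arg(distance)
  stopifnot(D_max > 0, b > 0)
  if (!is.null(k_value)) stopifnot(k_value >= 0)
  structure(list(D_max = D_max, b = b, k_mode = k_mode,
                 k_value = k_value, distance = distance),
            class = "kernel_params")
}

#' Dispersal rate at a distance
#'
#' k * exp(-w^b) within the distance cutoff, 0 beyond it.
#'
#' @param w distance(s), km (>= 0).
#' @param params `kernel_params`.
#' @param k maximum migration capacity per day (scalar or vector recycled
#'   over `w`); defaults to `params$k_value`.
#' @return migration rate(s), per day.
#' @export
kernel_delta <- function(w, params, k = params$k_value) {
  stopifnot(all(w >= 0), !is.null(k))
  ifelse(w <= params$D_max, k * exp(-w^params$b), 0)
}

#' Assemble the sparse dispersal matrix
#'
#' Pairwise distances between cell centres (haversine km by default),
#' truncated at D_max, passed through the exponential kernel. Entry (i, h)
#' is the migration rate from cell i to cell h; the diagonal is zero. In
#' global-k mode the matrix is symmetric. Barriers are honoured afterwards
#' with [apply_barrier()]. Cells with NoData r_i are excluded from dispersal
#' entirely (they are outside the simulated region).
#'
#' @param rmap `grid_raster` of r_i (defines the grid and, in per_source
#'   mode, the per-cell k_i = r_i / 10).
#' @param params `kernel_params`. In global mode with `k_value = NULL`, k
#'   defaults to max(r_i)/10.
#' @return `dgCMatrix` (cells x cells) of migration rates, with attributes
#'   `coords` (cell-centre lookup) and `params`.
#' @export
build_dispersal_matrix <- function(rmap, params = kernel_params()) {
  co <- grid_coords(rmap)
  nr <- nrow(rmap$values); nc <- ncol(rmap$values)
  n <- nr * nc
  rvals <- as.vector(rmap$values)
  active <- which(is.finite(rvals))
  # window of candidate neighbours in grid indices
  km_per_deg_lat <- 110.574
  dr <- ceiling(params$D_max / (rmap$cellsize * km_per_deg_lat)) + 1L
  ii <- integer(0); hh <- integer(0); ww <- numeric(0)
  act <- logical(n); act[active] <- TRUE
  for (i in active) {
    r0 <- co$row[i]; c0 <- co$col[i]
    rows <- max(1L, r0 - dr):min(nr, r0 + dr)
    cols <- max(1L, c0 - dr):min(nc, c0 + dr)
    cand <- as.vector(outer(rows, (cols - 1L) * nr, `+`))
    cand <- cand[cand != i & act[cand]]
    if (!length(cand)) next
    w <- if (params$distance == "haversine") {
      geosphere::distHaversine(
        c(co$lon[i], co$lat[i]),
        cbind(co$lon[cand], co$lat[cand])) / 1000
    } else {
      sqrt((co$lon[cand] - co$lon[i])^2 +
             (co$lat[cand] - co$lat[i])^2) * 111.32
    }
    keep <- w <= params$D_max
    if (any(keep)) {
      ii <- c(ii, rep.int(i, sum(keep)))
      hh <- c(hh, cand[keep])
      ww <- c(ww, w[keep])
    }
  }
  if (!length(ii)) {
    warning("D_max (", params$D_max,
            " km) is below the minimum cell spacing: dispersal matrix is all-zero, no dispersal possible")
    D <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  } else {
    k <- if (params$k_mode == "global") {
      kv <- params$k_value
      if (is.null(kv)) kv <- max(rvals[active]) / 10
      rep.int(kv, length(ii))
    } else {
      pmax(rvals[ii], 0) / 10   # outflow scaled by source-cell r_i
    }
    delta <- k * exp(-ww^params$b)
    D <- Matrix::sparseMatrix(i = ii, j = hh, x = delta, dims = c(n, n))
  }
  attr(D, "coords") <- co
  attr(D, "params") <- params
  D
}

#' Zero out dispersal between cell pairs (barriers)
#'
#' Simulates barriers that prevent migration between patches by setting
#' both directed rates between the listed pairs to zero.
#'
#' @param dmat dispersal matrix from [build_dispersal_matrix()].
#' @param pairs two-column matrix of cell indices (i, h); both (i, h) and
#'   (h, i) are zeroed.
#' @return modified sparse matrix.
#' @export
apply_barrier <- function(dmat, pairs) {
  pairs <- rbind(as.matrix(pairs), as.matrix(pairs)[, 2:1, drop = FALSE])
  dmat[pairs] <- 0
  Matrix::drop0(dmat)
}

#' Zero all dispersal into and out of a set of cells
#'
#' @param dmat dispersal matrix.
#' @param cells integer cell indices to isolate.
#' @return modified sparse matrix.
#' @export
isolate_cells <- function(dmat, cells) {
  dmat[cells, ] <- 0
  dmat[, cells] <- 0
  Matrix::drop0(dmat)
}

#' Simulate the coupled metapopulation ODE system
#'
#' Integrates, one equation per grid cell,
#' \deqn{\dot x_i = r_i x_i - a_i x_i^2 + \sum_h \delta_{hi} x_h - \sum_h \delta_{ih} x_i}
#' from a seeded initial state (all unseeded cells at zero). The default
#' integrator is a fixed-step classical RK4 with per-step clamping of
#' trace negatives (values above -1e-9 are set to 0; anything more negative
#' aborts); `solver = "adaptive"` delegates to [deSolve::ode] (lsoda)
#' without clamping. Masked (NoData) cells of the r_i map stay at zero.
#'
#' @param rmap `grid_raster` of r_i per day.
#' @param dmat dispersal matrix (cells x cells) from
#'   [build_dispersal_matrix()].
#' @param a density-dependence coefficient (per individual per day);
#'   scalar or per-cell vector. The paper-style presets are 1e-7 and 1e-6.
#' @param seeds data.frame with columns `cell` and `x0` (or `lon`, `lat`,
#'   `x0`; coordinates are mapped to the nearest cell, falling back to the
#'   nearest cell with positive r_i when the target cell has r_i = 0).
#' @param t_end simulation horizon, days.
#' @param dt_out output sampling interval, days.
#' @param dt RK4 step, days (default 0.25).
#' @param solver `"rk4"` (default) or `"adaptive"`.
#' @return object of class `simulation_result`: `times`, `x` (time x cell
#'   abundance matrix), `seeds`, `rmap`, `solver` metadata, `total`
#'   (total abundance per output step).
#' @export
simulate_invasion <- function(rmap, dmat, a = 1e-7, seeds,
                              t_end, dt_out = 10, dt = 0.25,
                              solver = c("rk4", "adaptive")) {
  solver <- match.arg(solver)
  stopifnot(all(a >= 0), t_end > 0, dt_out > 0, dt > 0)
  rvals <- as.vector(rmap$values)
  n <- length(rvals)
  stopifnot(nrow(dmat) == n, ncol(dmat) == n)
  r <- ifelse(is.finite(rvals), rvals, 0)
  if (length(a) == 1L) a <- rep(a, n)
  seeds <- resolve_seeds(rmap, seeds)
  x0 <- numeric(n)
  x0[seeds$cell] <- x0[seeds$cell] + seeds$x0
  out_flux <- Matrix::rowSums(dmat)
  Dt <- Matrix::t(dmat)
  deriv <- function(x) {
    r * x - a * x^2 + as.vector(Dt %*% x) - out_flux * x
  }
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  X <- matrix(0, nrow = length(times), ncol = n)
  clamp_tol <- -1e-9
  n_clamped <- 0L
  if (solver == "rk4") {
    x <- x0
    X[1, ] <- x
    t_now <- 0
    for (ti in 2:length(times)) {
      t_target <- times[ti]
      while (t_now < t_target - 1e-12) {
        h <- min(dt, t_target - t_now)
        k1 <- deriv(x)
        k2 <- deriv(x + h / 2 * k1)
        k3 <- deriv(x + h / 2 * k2)
        k4 <- deriv(x + h * k3)
        x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        if (anyNA(x) || any(!is.finite(x)))
          stop("integration failure: non-finite abundance at t = ",
               round(t_now + h, 3))
        neg <- x < 0
        if (any(neg)) {
          if (any(x < clamp_tol * 1e6)) { # far below tolerance: real blow-up
            worst <- min(x)
            if (worst < -1e-3)
              stop("integration failure: abundance ", signif(worst, 3),
                   " at t = ", round(t_now + h, 3),
                   "; reduce dt or use solver = 'adaptive'")
          }
          n_clamped <- n_clamped + sum(neg)
          x[neg] <- 0
        }
        t_now <- t_now + h
      }
      X[ti, ] <- x
    }
  } else {
    f <- function(t, x, parms) list(deriv(x))
    sol <- deSolve::ode(y = x0, times = times, func = f, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    if (anyNA(sol)) stop("adaptive integration failed (NaN in solution)")
    X <- unname(sol[, -1, drop = FALSE])
  }
  structure(
    list(times = times, x = X, seeds = seeds, rmap = rmap,
         solver = list(method = solver, dt = if (solver == "rk4") dt else NA,
                       dt_out = dt_out, clamped = n_clamped),
         total = rowSums(X)),
    class = "simulation_result"
  )
}

# Map seed specifications to grid cells. Seeds given as coordinates go to
# the containing cell; if that cell has r_i = 0 or NoData, the nearest cell
# with positive r_i is used instead (a port on an unsuitable pixel seeds the
# nearest suitable habitat).
resolve_seeds <- function(rmap, seeds) {
  stopifnot(is.data.frame(seeds), "x0" %in% names(seeds))
  if ("cell" %in% names(seeds)) {
    n <- length(rmap$values)
    stopifnot(all(seeds$cell >= 1), all(seeds$cell <= n))
    return(seeds[, c("cell", "x0")])
  }
  stopifnot(all(c("lon", "lat") %in% names(seeds)))
  co <- grid_coords(rmap)
  rv <- as.vector(rmap$values)
  good <- which(is.finite(rv) & rv > 0)
  cell <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    cl <- cell_from_xy(rmap, seeds$lon[i], seeds$lat[i])
    if (is.na(cl) || !is.finite(rv[cl]) || rv[cl] <= 0) {
      if (!length(good)) stop("no cells with positive r_i to seed")
      d2 <- (co$lon[good] - seeds$lon[i])^2 + (co$lat[good] - seeds$lat[i])^2
      cl <- good[which.min(d2)]
    }
    cell[i] <- cl
  }
  data.frame(cell = cell, x0 = seeds$x0)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Metapopulation simulation: %d cells, t in [0, %g] days (%d outputs), solver %s\n",
    ncol(x$x), max(x$times), length(x$times), x$solver$method))
  cat(sprintf("  total abundance: %.4g at t = 0, %.4g at t_end\n",
              x$total[1], x$total[length(x$total)]))
  invisible(x)
}

#' Per-cell arrival times
#'
#' First output time at which a cell's abundance reaches the threshold;
#' `Inf` for cells never colonized. Seeded cells at or above the threshold
#' get 0.
#'
#' @param result `simulation_result`.
#' @param threshold abundance defining "arrived" (default 1 individual).
#' @return numeric vector of arrival days per cell (`Inf` = never).
#' @export
arrival_times <- function(result, threshold = 1) {
  stopifnot(inherits(result, "simulation_result"))
  X <- result$x
  first <- apply(X >= threshold, 2L, function(col) {
    w <- which(col)
    if (length(w)) result$times[w[1]] else Inf
  })
  unname(first)
}

#' Arrival-time raster
#'
#' @param result `simulation_result`.
#' @param threshold abundance threshold.
#' @param never value written for never-colonized cells (default `NA`).
#' @return `grid_raster` of arrival days.
#' @export
arrival_raster <- function(result, threshold = 1, never = NA_real_) {
  at <- arrival_times(result, threshold)
  at[!is.finite(at)] <- never
  g <- result$rmap
  grid_raster(matrix(at, nrow = nrow(g$values)), g$xll, g$yll, g$cellsize, g$crs)
}

#' Coverage curve of a region
#'
#' Fraction of the region's cells at or above the abundance threshold at
#' each output time, and the first time that fraction reaches the target
#' coverage (default 90%).
#'
#' @param result `simulation_result`.
#' @param region logical vector/matrix over grid cells, or a `grid_raster`
#'   (cells with finite positive values form the region).
#' @param threshold abundance threshold (default 1).
#' @param target coverage fraction defining "covered" (default 0.9).
#' @return list: `time`, `fraction`, `t_cover` (first time fraction >=
#'   target; `Inf` if never).
#' @export
coverage_curve <- function(result, region, threshold = 1, target = 0.9) {
  stopifnot(inherits(result, "simulation_result"))
  if (inherits(region, "grid_raster"))
    region <- is.finite(region$values) & region$values > 0
  region <- as.vector(region)
  stopifnot(length(region) == ncol(result$x))
  idx <- which(region)
  if (!length(idx)) stop("empty region mask")
  frac <- rowMeans(result$x[, idx, drop = FALSE] >= threshold)
  hit <- which(frac >= target)
  list(time = result$times, fraction = frac,
       t_cover = if (length(hit)) result$times[hit[1]] else Inf)
}
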
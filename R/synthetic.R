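# Stable per-stage seed derivation: one global seed fans out to independent
# stage seeds via a fixed string hash, so re-ordering pipeline stages cannot
# silently change another stage's draws.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1976326319
  as.integer((seed + h) %% .Machine$integer.max)
}

#' Synthetic study scenario
#'
#' Bundles the ground truth for every generated artifact: per-temperature
#' demographic truth (stage survivals, fecundity, generation time), the
#' hatching quadratic, the thermal growth curve, the landscape geometry and
#' the niche ellipsoid. Given the same seed, every generator is bit-for-bit
#' reproducible. The defaults mirror the rearing design (temperatures 17,
#' 20, 26, 29, 35 °C; 10 tubes per opening; 9 openings every 4 days) and the
#' fitted growth-curve estimates (r_max 0.1314 / day, v_0 0.0521, T_opt
#' 26.2624 °C); 35 °C is non-viable (all survivals zero) as rearing at that
#' temperature produced no progeny.
#'
#' @param seed integer master seed.
#' @param temperatures rearing temperatures, °C.
#' @param growth_truth `growth_model` used as generating truth.
#' @param hatch_coef quadratic hatching coefficients `c(a, b, c)`; default a
#'   gentle concave curve peaking near 24 °C.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               temperatures = c(17, 20, 26, 29, 35),
                               growth_truth = growth_model(0.1314, 0.0521, 26.2624),
                               hatch_coef = c(a = -0.002, b = 0.096, c = -0.35)) {
  # per-temperature demographic truth: survivals shaped by the growth curve,
  # zero at the hottest (non-viable) treatment
  rel <- evaluate_growth(growth_truth, temperatures) / growth_truth$r_max
  s_base <- pmin(0.95, 0.35 + 0.6 * rel)
  viable <- temperatures < 34
  demo <- data.frame(
    temperature = temperatures,
    s_egg_larva = ifelse(viable, s_base, 0),
    s_larva_pupa = ifelse(viable, pmin(0.95, s_base + 0.05), 0),
    s_pupa_adult = ifelse(viable, pmin(0.95, s_base + 0.02), 0),
    s_adult_female = ifelse(viable, 0.85, 0),
    fecundity = ifelse(viable, 30 + 30 * rel, 15),
    generation_day = ifelse(viable, pmax(12, round(28 - 8 * (rel - 0.5))), NA)
  )
  structure(
    list(seed = as.integer(seed), temperatures = temperatures,
         growth_truth = growth_truth, hatch_coef = hatch_coef,
         demography = demo,
         landscape = list(nrow = 40, ncol = 40, cellsize = 2.5 / 60,
                          xll = -100, yll = 17)),
    class = "synthetic_scenario"
  )
}

# closed-form expected demographic outputs of synth_cohort
#' Expected demographic summary of a synthetic cohort
#'
#' Closed-form expectations implied by the scenario truth: p from the
#' hatching quadratic (clamped), H = fecundity, R0 = p * H * prod(S), G the
#' first opening at or after the scenario generation day minus the first
#' opening day (eggs are present from the first opening), r = ln(R0)/G.
#'
#' @param scenario `synthetic_scenario`.
#' @param opening_interval days between openings (default 4, matching
#'   [synth_cohort()]).
#' @return data.frame, one row per temperature.
#' @export
synth_cohort_expectation <- function(scenario, opening_interval = 4L) {
  hc <- scenario$hatch_coef
  d <- scenario$demography
  p <- pmin(1, pmax(0, hc[1] * d$temperature^2 + hc[2] * d$temperature + hc[3]))
  S <- d$s_egg_larva * d$s_larva_pupa * d$s_pupa_adult * d$s_adult_female
  R0 <- p * d$fecundity * S
  first_fem <- opening_interval * ceiling(d$generation_day / opening_interval)
  G <- first_fem - opening_interval
  r <- ifelse(R0 > 0, log(R0) / G, -Inf)
  data.frame(temperature = d$temperature, p = p, H = d$fecundity,
             R0 = R0, G = G, r = r)
}

#' Generate a synthetic cohort stage-count table
#'
#' Emulates the destructive rearing design: `openings` colony openings every
#' `opening_interval` days, `replicates` tubes opened per temperature per
#' opening. Counts are Poisson draws whose per-opening expectations are
#' chosen so the accumulated means recover the scenario truth in
#' expectation: eggs F/9 per opening, larvae s_el * F/9, pupae
#' s_el*s_lp*F/9, adult females (live + dead) s_el*s_lp*s_pa * F spread over
#' the openings at or after the generation day, split live/dead binomially
#' with the adult-female survival. Counts are progeny only (the foundress is
#' not tallied).
#'
#' @param scenario `synthetic_scenario`.
#' @param replicates tubes per opening (default 10).
#' @param openings number of openings (default 9).
#' @param opening_interval days between openings (default 4).
#' @return cohort data.frame (validated).
#' @export
synth_cohort <- function(scenario, replicates = 10L, openings = 9L,
                         opening_interval = 4L) {
  set.seed(derive_seed(scenario$seed, "cohort"))
  days <- seq_len(openings) * opening_interval
  d <- scenario$demography
  rows <- list()
  for (i in seq_len(nrow(d))) {
    tt <- d$temperature[i]
    F <- d$fecundity[i]
    lam_egg <- F / openings
    lam_lar <- d$s_egg_larva[i] * lam_egg
    lam_pup <- d$s_larva_pupa[i] * lam_lar
    fem_days <- if (is.na(d$generation_day[i])) integer(0)
      else days[days >= d$generation_day[i]]
    lam_fem_total <- d$s_pupa_adult[i] * d$s_larva_pupa[i] *
      d$s_egg_larva[i] * F
    lam_fem <- if (length(fem_days)) lam_fem_total / length(fem_days) else 0
    for (day in days) {
      n <- replicates
      egg <- stats::rpois(n, lam_egg)
      lar <- stats::rpois(n, lam_lar)
      pup <- stats::rpois(n, lam_pup)
      fem <- if (day %in% fem_days) stats::rpois(n, lam_fem) else integer(n)
      fl <- stats::rbinom(n, fem, d$s_adult_female[i])
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = tt, day = day, replicate = seq_len(n),
        egg = egg, larva = lar, pupa = pup,
        female_live = fl, female_dead = fem - fl,
        male = stats::rpois(n, 0.3 * lam_fem))
    }
  }
  validate_cohort(do.call(rbind, rows))
}

#' Generate a synthetic hatching table
#'
#' Hatching proportions from the scenario's quadratic truth (clamped to
#' \[0, 1\]) plus optional Gaussian noise, at surrogate-species temperatures.
#'
#' @param scenario `synthetic_scenario`.
#' @param temperatures default the surrogate design 10, 18, 20, 24, 27, 32,
#'   35 °C.
#' @param noise_sd Gaussian noise sd on the proportion (default 0.02).
#' @return data.frame `temperature, proportion_hatched`.
#' @export
synth_hatching_table <- function(scenario,
                                 temperatures = c(10, 18, 20, 24, 27, 32, 35),
                                 noise_sd = 0.02) {
  set.seed(derive_seed(scenario$seed, "hatching"))
  hc <- scenario$hatch_coef
  p <- hc[1] * temperatures^2 + hc[2] * temperatures + hc[3]
  p <- pmin(1, pmax(0, p + stats::rnorm(length(p), 0, noise_sd)))
  data.frame(temperature = temperatures, proportion_hatched = p)
}

#' Generate (temperature, r) points from a growth-curve truth
#'
#' r drawn as curve(T) + Gaussian(0, noise_sd); the default noise scale is
#' the fitted curve's residual standard error, 0.0377 / day.
#'
#' @param truth `growth_model` generating truth.
#' @param temps temperatures, °C.
#' @param reps replicates per temperature.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed RNG seed.
#' @return data.frame `temperature, r`.
#' @export
synth_growth_points <- function(truth, temps = c(17, 20, 26, 29, 35),
                                reps = 10L, noise_sd = 0.0377, seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  T <- rep(temps, each = reps)
  data.frame(temperature = T,
             r = evaluate_growth(truth, T) +
               stats::rnorm(length(T), 0, noise_sd))
}

#' Generate a synthetic landscape
#'
#' Co-registered toy rasters at 2.5 arc-minute resolution (cell spacing
#' ~4.6 km, just inside the default 5 km daily dispersal distance, so the
#' kernel connects rook neighbours exactly as at the simulation resolution
#' of the full-extent runs): a smooth mean-annual-temperature
#' field (south-north gradient plus Gaussian warm bumps centred near the
#' growth optimum, which create high-r_i corridors), a binary suitability
#' raster, optional horizontal corridors separated by an unsuitable band,
#' yearly two-variable environmental stacks for niche fitting, and named
#' region masks.
#'
#' @param scenario `synthetic_scenario`.
#' @param corridors if `TRUE`, the suitability mask is two east-west
#'   corridors ("warm" rows near T_opt and "cool" rows a few degrees below)
#'   separated by an unsuitable band; otherwise all cells are suitable.
#' @param years years for the environmental stacks (default 1990:1992).
#' @return list: `temperature`, `suitability` (`grid_raster`s),
#'   `yearly_stacks`, `masks` (named list of logical matrices), `corridor_info`.
#' @export
synth_landscape <- function(scenario, corridors = FALSE, years = 1990:1992) {
  set.seed(derive_seed(scenario$seed, "landscape"))
  L <- scenario$landscape
  nr <- L$nrow; nc <- L$ncol
  t_opt <- scenario$growth_truth$t_opt
  row_idx <- matrix(rep(seq_len(nr), nc), nrow = nr)
  col_idx <- matrix(rep(seq_len(nc), each = nr), nrow = nr)
  # gentle north-south gradient around T_opt, warm in the south (high rows)
  temp <- t_opt + 2.5 * (row_idx - nr / 2) / nr +
    1.5 * exp(-((row_idx - nr * 0.3)^2 + (col_idx - nc * 0.7)^2) / (2 * (nr / 6)^2))
  suit <- matrix(1, nr, nc)
  masks <- list(all = matrix(TRUE, nr, nc))
  corridor_info <- NULL
  if (corridors) {
    warm_rows <- seq(round(nr * 0.15), round(nr * 0.35))
    cool_rows <- seq(round(nr * 0.65), round(nr * 0.85))
    suit <- matrix(0, nr, nc)
    suit[warm_rows, ] <- 1
    suit[cool_rows, ] <- 1
    temp[warm_rows, ] <- t_opt      # corridor at the optimum: r_i = r_max
    temp[cool_rows, ] <- t_opt - 4  # cool corridor: roughly a third of r_max
    masks$warm <- matrix(FALSE, nr, nc); masks$warm[warm_rows, ] <- TRUE
    masks$cool <- matrix(FALSE, nr, nc); masks$cool[cool_rows, ] <- TRUE
    corridor_info <- list(warm_rows = warm_rows, cool_rows = cool_rows)
  }
  g <- function(m) grid_raster(m, L$xll, L$yll, L$cellsize)
  # two-variable yearly stacks: temperature plus an independent moisture-like
  # field, with small year-to-year offsets
  moisture <- 100 + 40 * (col_idx - nc / 2) / nc +
    8 * exp(-((row_idx - nr * 0.6)^2 + (col_idx - nc * 0.4)^2) / (2 * (nr / 5)^2))
  yearly_stacks <- lapply(years, function(y) {
    jit <- stats::rnorm(2, 0, 0.3)
    list(temp = g(temp + jit[1]), moist = g(moisture + jit[2]))
  })
  names(yearly_stacks) <- as.character(years)
  list(temperature = g(temp), suitability = g(suit),
       yearly_stacks = yearly_stacks, masks = masks,
       corridor_info = corridor_info)
}

#' Sample synthetic occurrences from a niche-ellipsoid truth
#'
#' Cell-year combinations are sampled with probability proportional to the
#' true ellipsoid's suitability of that cell's environment in that year;
#' record coordinates are the cell centres, years uniform over the stack
#' span (via the suitability-weighted draw).
#'
#' @param niche_truth `ellipsoid_niche` generating truth.
#' @param yearly_stacks named per-year lists of `grid_raster` layers.
#' @param n number of records (>= 20).
#' @param seed RNG seed.
#' @return occurrence data.frame `longitude, latitude, year`.
#' @export
synth_occurrences <- function(niche_truth, yearly_stacks, n = 100L, seed = 1L) {
  stopifnot(n >= 20)
  set.seed(seed)
  years <- names(yearly_stacks)
  base <- yearly_stacks[[1]][[1]]
  co <- grid_coords(base)
  pool <- do.call(rbind, lapply(years, function(y) {
    stack <- yearly_stacks[[y]]
    env <- sapply(niche_truth$vars, function(v) as.vector(stack[[v]]$values))
    w <- niche_suitability(niche_truth, env)
    data.frame(lon = co$lon, lat = co$lat, year = as.integer(y), w = w)
  }))
  pool <- pool[is.finite(pool$w) & pool$w > 0, , drop = FALSE]
  pick <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$w)
  data.frame(longitude = pool$lon[pick], latitude = pool$lat[pick],
             year = pool$year[pick])
}
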
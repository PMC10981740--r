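PIPELINE_STAGES <- c("demography", "growth", "niche", "riskmap",
                     "simulate", "analytics")

config_schema <- function() {
  list(
    seed = NULL, out_dir = NULL, stages = NULL,
    inputs = c("cohort", "hatching", "occurrences", "temperature",
               "suitability"),
    synthetic = c("corridors", "n_occurrences", "years"),
    growth = c("init"),
    niche = c("thin_dist", "cutoff", "percentile", "E", "iterations",
              "bootstrap_frac", "background_n", "split_frac", "method"),
    kernel = c("D_max", "b", "k_mode", "k_value", "distance"),
    sim = c("a", "t_end", "dt_out", "dt", "solver", "seeds", "threshold",
            "coverage_target")
  )
}

#' Validate a run configuration
#'
#' Rejects unknown keys (top-level and nested) and fills defaults. A config
#' is a plain list or a YAML file with the same structure.
#'
#' @param config list or path to a YAML file.
#' @return validated config list with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sect in names(schema)) {
    if (!is.null(schema[[sect]]) && !is.null(config[[sect]])) {
      bad <- setdiff(names(config[[sect]]), schema[[sect]])
      if (length(bad))
        stop("unknown config key(s) in '", sect, "': ",
             paste(bad, collapse = ", "))
    }
  }
  defaults <- list(
    seed = 1L, out_dir = "pipeline_out", stages = PIPELINE_STAGES,
    inputs = list(), synthetic = list(corridors = TRUE, n_occurrences = 120,
                                      years = 1990:1992),
    growth = list(init = NULL),
    niche = list(thin_dist = 0.0083, cutoff = 0.8, percentile = 0.10,
                 E = 0.10, iterations = 200, bootstrap_frac = 0.5,
                 background_n = 20000, split_frac = 0.7,
                 method = "covariance"),
    kernel = list(D_max = 5, b = 1, k_mode = "global", k_value = NULL,
                  distance = "haversine"),
    sim = list(a = 1e-7, t_end = 400, dt_out = 10, dt = 0.25,
               solver = "rk4", seeds = NULL, threshold = 1,
               coverage_target = 0.9)
  )
  out <- defaults
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      out[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]],
                                     keep.null = TRUE)
    } else out[[nm]] <- config[[nm]]
  }
  bad_stage <- setdiff(out$stages, PIPELINE_STAGES)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  out
}

#' Run the full invasion-modelling pipeline
#'
#' Executes, in order and skipping deselected stages: demographic
#' reconstruction, growth-curve fit, niche modelling, r_i map construction,
#' metapopulation simulation, and arrival/coverage analytics. Inputs are
#' read from `config$inputs` paths when given; otherwise every input is
#' generated by the seeded synthetic-data module, so a full desk-scale run
#' needs no external files. Writes all artifacts plus a reproducibility
#' manifest (parameters, outputs, md5 checksums) under `config$out_dir`.
#'
#' @param config list or YAML path; see [validate_config()].
#' @return the manifest, invisibly (list with `stages`, `files`, `params`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scenario <- synthetic_scenario(seed = cfg$seed)
  files <- character(0)
  stage_log <- list()
  state <- new.env(parent = emptyenv())

  emit <- function(path) files <<- c(files, path)
  stamp <- function(stage, ...) stage_log[[stage]] <<- list(...)

  if ("demography" %in% cfg$stages) {
    cohort <- if (!is.null(cfg$inputs$cohort)) read_cohort(cfg$inputs$cohort)
      else synth_cohort(scenario)
    hatch_tab <- if (!is.null(cfg$inputs$hatching))
        utils::read.csv(cfg$inputs$hatching)
      else synth_hatching_table(scenario)
    hm <- fit_hatching_polynomial(hatch_tab)
    summ <- suppressWarnings(demographic_summary(cohort, hm))
    p1 <- file.path(cfg$out_dir, "demography_summary.csv")
    utils::write.csv(summ, p1, row.names = FALSE)
    emit(p1)
    state$summary <- summ
    stamp("demography", n_temperatures = nrow(summ),
          hatching = list(a = hm$a, b = hm$b, c = hm$c))
  }

  if ("growth" %in% cfg$stages) {
    if (is.null(state$summary))
      stop("stage 'growth' failed: no demographic summary (run 'demography')")
    pts <- state$summary[state$summary$viable,
                         c("temperature", "r"), drop = FALSE]
    gm <- fit_growth_function(pts, init = cfg$growth$init)
    p2 <- file.path(cfg$out_dir, "growth_model.json")
    write_growth_model(gm, p2)
    emit(p2)
    state$growth <- gm
    st <- fit_statistics(gm)
    stamp("growth", r_max = gm$r_max, v_0 = gm$v_0, t_opt = gm$t_opt,
          r_squared = st$r_squared)
  }

  land <- synth_landscape(scenario, corridors = isTRUE(cfg$synthetic$corridors),
                          years = cfg$synthetic$years)
  state$land <- land

  if ("niche" %in% cfg$stages) {
    occ <- if (!is.null(cfg$inputs$occurrences))
        read_occurrences(cfg$inputs$occurrences)
      else {
        truth <- fit_ellipsoid(cbind(
          temp = c(26, 26.5, 25.8, 26.3, 27, 25.5, 26.1, 26.6),
          moist = c(100, 104, 97, 101, 106, 95, 99, 103)))
        synth_occurrences(truth, land$yearly_stacks,
                          n = cfg$synthetic$n_occurrences,
                          seed = derive_seed(cfg$seed, "occurrences"))
      }
    occ <- thin_occurrences(occ, cfg$niche$thin_dist)
    parts <- split_occurrences(occ, frac = cfg$niche$split_frac,
                               seed = derive_seed(cfg$seed, "split"))
    env_tr <- extract_time_specific_env(parts$train, land$yearly_stacks)
    keep_vars <- filter_variables_by_correlation(env_tr, cfg$niche$cutoff)
    niche <- fit_ellipsoid(env_tr[, keep_vars, drop = FALSE],
                           method = cfg$niche$method)
    mean_layers <- lapply(keep_vars, function(v) {
      stack_vals <- sapply(land$yearly_stacks,
                           function(s) as.vector(s[[v]]$values))
      base <- land$yearly_stacks[[1]][[v]]
      grid_raster(matrix(rowMeans(stack_vals), nrow = nrow(base$values)),
                  base$xll, base$yll, base$cellsize, base$crs)
    })
    names(mean_layers) <- keep_vars
    suit <- suitability_raster(niche, mean_layers)
    calib_suit <- niche_suitability(niche, env_tr[, keep_vars, drop = FALSE])
    bin <- binarize(niche, calib_suit, suit, cfg$niche$percentile)
    proc <- partial_roc(suit, parts$test, E = cfg$niche$E,
                        iterations = cfg$niche$iterations,
                        bootstrap_frac = cfg$niche$bootstrap_frac,
                        background_n = cfg$niche$background_n,
                        seed = derive_seed(cfg$seed, "proc"))
    ev <- evaluate_binary_model(bin$raster, parts$train, parts$test)
    p3 <- file.path(cfg$out_dir, "suitability.asc")
    p4 <- file.path(cfg$out_dir, "suitability_binary.asc")
    p5 <- file.path(cfg$out_dir, "niche_evaluation.json")
    write_asc(suit, p3); write_asc(bin$raster, p4)
    jsonlite::write_json(
      list(threshold = bin$threshold, variables = keep_vars,
           omission_train = ev$omission_train, omission_test = ev$omission_test,
           omission_mean = ev$omission_mean, prevalence = ev$prevalence,
           binomial_p = ev$binomial_p,
           partial_roc = list(auc_ratio_mean = proc$auc_ratio_mean,
                              p_value = proc$p_value)),
      p5, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(p3); emit(p4); emit(p5)
    state$binary <- bin$raster
    stamp("niche", variables = keep_vars, threshold = bin$threshold,
          auc_ratio = proc$auc_ratio_mean)
  }

  if ("riskmap" %in% cfg$stages) {
    if (is.null(state$growth))
      stop("stage 'riskmap' failed: no growth model (run 'growth')")
    suit_bin <- if (!is.null(cfg$inputs$suitability))
        read_asc(cfg$inputs$suitability)
      else land$suitability
    temp <- if (!is.null(cfg$inputs$temperature))
        read_asc(cfg$inputs$temperature)
      else land$temperature
    rmap <- build_r_map(state$growth, temp, suit_bin)
    p6 <- file.path(cfg$out_dir, "ri_map.asc")
    write_asc(rmap, p6)
    emit(p6)
    state$rmap <- rmap
    stamp("riskmap", max_r = max(rmap$values, na.rm = TRUE),
          suitable_cells = sum(rmap$values > 0, na.rm = TRUE))
  }

  if ("simulate" %in% cfg$stages) {
    if (is.null(state$rmap))
      stop("stage 'simulate' failed: no r_i map (run 'riskmap')")
    kp <- kernel_params(D_max = cfg$kernel$D_max, b = cfg$kernel$b,
                        k_mode = cfg$kernel$k_mode,
                        k_value = cfg$kernel$k_value,
                        distance = cfg$kernel$distance)
    dmat <- build_dispersal_matrix(state$rmap, kp)
    seeds <- cfg$sim$seeds
    if (is.null(seeds)) {
      co <- grid_coords(state$rmap)
      best <- which.max(as.vector(state$rmap$values))
      seeds <- data.frame(lon = co$lon[best], lat = co$lat[best], x0 = 100)
    } else if (!is.data.frame(seeds)) {
      seeds <- do.call(rbind, lapply(seeds, as.data.frame))
    }
    res <- simulate_invasion(state$rmap, dmat, a = cfg$sim$a, seeds = seeds,
                             t_end = cfg$sim$t_end, dt_out = cfg$sim$dt_out,
                             dt = cfg$sim$dt, solver = cfg$sim$solver)
    p7 <- file.path(cfg$out_dir, "total_abundance.csv")
    utils::write.csv(data.frame(time = res$times, total = res$total),
                     p7, row.names = FALSE)
    p8 <- file.path(cfg$out_dir, "arrival_times.asc")
    write_asc(arrival_raster(res, threshold = cfg$sim$threshold), p8)
    emit(p7); emit(p8)
    state$sim <- res
    stamp("simulate", cells = ncol(res$x), t_end = cfg$sim$t_end,
          final_total = res$total[length(res$total)])
  }

  if ("analytics" %in% cfg$stages) {
    if (is.null(state$sim))
      stop("stage 'analytics' failed: no simulation (run 'simulate')")
    masks <- land$masks
    cov <- lapply(masks, function(m)
      coverage_curve(state$sim, m, threshold = cfg$sim$threshold,
                     target = cfg$sim$coverage_target))
    at <- arrival_times(state$sim, cfg$sim$threshold)
    p9 <- file.path(cfg$out_dir, "analytics.json")
    jsonlite::write_json(
      list(coverage = lapply(cov, function(cc)
             list(t_cover = cc$t_cover,
                  final_fraction = cc$fraction[length(cc$fraction)])),
           arrival = list(median_finite = stats::median(at[is.finite(at)]),
                          reached_cells = sum(is.finite(at)))),
      p9, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(p9)
    stamp("analytics",
          t_cover = vapply(cov, function(cc) cc$t_cover, numeric(1)))
  }

  manifest <- list(
    stages = stage_log,
    params = cfg[setdiff(names(cfg), "out_dir")],
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
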
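STAGES <- c("egg", "larva", "pupa", "female_live", "female_dead", "male")

#' Read a cohort stage-count table
#'
#' Expected CSV header:
#' `temperature,day,replicate,egg,larva,pupa,female_live,female_dead,male`.
#' Counts are the numbers of individuals found at each destructive colony
#' opening, per rearing temperature, days-since-inoculation, and tube.
#'
#' @param path CSV file path.
#' @return validated data.frame (a cohort table).
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(x)
}

#' Validate a cohort table
#'
#' Checks column presence, non-negative integer counts, non-negative days and
#' uniqueness of (temperature, day, replicate) keys.
#'
#' @param x data.frame.
#' @return `x`, invisibly validated (returned for chaining).
#' @export
validate_cohort <- function(x) {
  need <- c("temperature", "day", "replicate", STAGES)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(x[need]))
    stop("cohort table contains missing cells")
  if (any(x$day < 0)) stop("cohort days must be non-negative")
  cnt <- as.matrix(x[STAGES])
  if (any(cnt < 0)) stop("stage counts must be non-negative")
  if (any(cnt != round(cnt))) stop("stage counts must be integers")
  key <- paste(x$temperature, x$day, x$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (temperature, day, replicate) keys in cohort table")
  x
}

#' Fit the egg-hatching quadratic
#'
#' Least-squares fit of the hatching proportion against temperature,
#' p(T) = a*T^2 + b*T + c. With exactly three distinct temperatures the
#' fit interpolates the points exactly.
#'
#' @param table data.frame with columns `temperature` and `proportion_hatched`
#'   (or a two-column data.frame in that order).
#' @return an object of class `hatching_model` with elements `a`, `b`, `c`,
#'   the fitted `lm` object, and the temperature range of the data.
#' @export
fit_hatching_polynomial <- function(table) {
  if (!all(c("temperature", "proportion_hatched") %in% names(table))) {
    if (ncol(table) >= 2) {
      names(table)[1:2] <- c("temperature", "proportion_hatched")
    } else stop("hatching table needs columns temperature, proportion_hatched")
  }
  T <- table$temperature
  p <- table$proportion_hatched
  if (any(p < 0 | p > 1))
    stop("hatching proportions must lie in [0, 1]")
  if (length(unique(T)) < 3)
    stop("degenerate design: need at least 3 distinct temperatures to fit a quadratic")
  fit <- stats::lm(p ~ I(T^2) + T)
  cf <- stats::coef(fit)
  structure(
    list(a = unname(cf["I(T^2)"]), b = unname(cf["T"]),
         c = unname(cf["(Intercept)"]), fit = fit, range = range(T)),
    class = "hatching_model"
  )
}

#' Predict hatching proportion at a temperature
#'
#' Evaluates the fitted quadratic and clamps the result to \[0, 1\].
#' Extrapolation outside the range of the data used to fit the curve
#' triggers a warning (the surrogate-species data cover a limited span).
#'
#' @param model a `hatching_model`.
#' @param T temperature(s), °C.
#' @param warn_extrapolation warn when T is outside the fitted range.
#' @return hatching proportion(s) in \[0, 1\].
#' @export
predict_hatching <- function(model, T, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "hatching_model"))
  if (warn_extrapolation && !is.null(model$range) &&
      any(T < model$range[1] | T > model$range[2])) {
    warning("hatching curve evaluated outside the fitted temperature range (",
            model$range[1], "-", model$range[2], " degC): quadratic extrapolation")
  }
  pmin(1, pmax(0, model$a * T^2 + model$b * T + model$c))
}

#' Accumulate stage counts over colony openings
#'
#' For each temperature and opening day, stage counts are averaged over the
#' replicate tubes opened that day; the per-day means are then summed over
#' all opening days, yielding the accumulated mean count per stage that
#' downstream survival and fecundity estimates use. (Averaging across tubes
#' first, then accumulating over the schedule, is one reading of an
#' "averaged and accumulated" destructive-count design; the alternative —
#' cumulative maxima — is deliberately not the default and would be swapped
#' here if ever needed.)
#'
#' @param cohort validated cohort table.
#' @return data.frame with one row per temperature: accumulated mean counts
#'   `N_egg, N_larva, N_pupa, N_female_live, N_female_dead, N_male`.
#' @export
accumulate_counts <- function(cohort) {
  cohort <- validate_cohort(cohort)
  temps <- sort(unique(cohort$temperature))
  if (!length(temps)) stop("empty cohort: no temperatures present")
  out <- lapply(temps, function(tt) {
    sub <- cohort[cohort$temperature == tt, , drop = FALSE]
    if (!nrow(sub)) stop("no cohort data at temperature ", tt)
    daily <- stats::aggregate(sub[STAGES], by = list(day = sub$day), FUN = mean)
    acc <- colSums(daily[STAGES])
    data.frame(temperature = tt, t(acc))
  })
  res <- do.call(rbind, out)
  names(res) <- c("temperature", paste0("N_", STAGES))
  rownames(res) <- NULL
  res
}

#' Stage-to-stage survival rates
#'
#' Survival of stage k is the quotient of the accumulated count of the next
#' stage and the count of stage k: egg-to-larva, larva-to-pupa, and
#' pupa-to-adult-female (live plus dead females). Adult-female survival is
#' the live fraction, live / (live + dead). Ratios above 1 — possible when
#' oviposition is still ongoing during the openings — are capped at 1 with a
#' warning rather than treated as errors.
#'
#' @param N named numeric vector or one-row data.frame with accumulated
#'   counts `N_egg, N_larva, N_pupa, N_female_live, N_female_dead` (or an
#'   unnamed ordered vector egg, larva, pupa, adult for the three
#'   stage-transition ratios only).
#' @return named numeric vector of survivals in \[0, 1\].
#' @export
stage_survival <- function(N) {
  if (is.data.frame(N)) N <- unlist(N[1, , drop = TRUE])
  if (is.null(names(N)) || !any(grepl("^N_", names(N)))) {
    # plain ordered vector: consecutive-stage ratios
    if (any(N[-length(N)] <= 0))
      stop("undefined survival: zero count in a denominator stage")
    s <- N[-1] / N[-length(N)]
    if (any(s > 1)) {
      warning("stage counts increase between consecutive stages; survival capped at 1")
      s <- pmin(s, 1)
    }
    return(unname(s))
  }
  g <- function(nm) {
    v <- N[[paste0("N_", nm)]]
    if (is.null(v)) stop("missing accumulated count N_", nm)
    v
  }
  n_egg <- g("egg"); n_lar <- g("larva"); n_pup <- g("pupa")
  n_fl <- g("female_live"); n_fd <- g("female_dead")
  n_fem <- n_fl + n_fd
  den <- c(egg = n_egg, larva = n_lar, pupa = n_pup)
  zero <- names(den)[den <= 0]
  if (length(zero))
    stop("undefined survival: zero accumulated count at stage(s) ",
         paste(zero, collapse = ", "))
  s <- c(
    egg_larva   = n_lar / n_egg,
    larva_pupa  = n_pup / n_lar,
    pupa_adult  = n_fem / n_pup,
    adult_female = if (n_fem > 0) n_fl / n_fem else NA_real_
  )
  if (any(s > 1, na.rm = TRUE)) {
    warning("stage counts increase between consecutive stages; survival capped at 1")
    s <- pmin(s, 1)
  }
  s
}

#' Net reproductive rate
#'
#' R0 = p * H * prod(S_k): hatching proportion times fecundity (eggs counted
#' per foundress) times the product of stage survivals.
#'
#' @param p hatching proportion in \[0, 1\].
#' @param H accumulated mean egg count (>= 0).
#' @param S numeric vector of stage survivals, each in \[0, 1\].
#' @return R0 (daughters per female per generation).
#' @export
net_reproductive_rate <- function(p, H, S) {
  stopifnot(p >= 0, p <= 1, H >= 0, all(S >= 0), all(S <= 1))
  p * H * prod(S)
}

#' Generation time from a cohort
#'
#' Days from the first observation of eggs (any replicate) to the first
#' record of adult females of the progeny (any replicate), at one
#' temperature.
#'
#' @param cohort validated cohort table restricted to (or containing) the
#'   temperature of interest.
#' @param temperature temperature to use; defaults to the single temperature
#'   present.
#' @return generation time G in days (> 0).
#' @export
generation_time <- function(cohort, temperature = NULL) {
  cohort <- validate_cohort(cohort)
  if (!is.null(temperature))
    cohort <- cohort[cohort$temperature == temperature, , drop = FALSE]
  if (!nrow(cohort)) stop("no cohort rows at the requested temperature")
  egg_days <- cohort$day[cohort$egg > 0]
  if (!length(egg_days)) stop("generation undefined: no eggs ever observed")
  fem_days <- cohort$day[(cohort$female_live + cohort$female_dead) > 0]
  if (!length(fem_days))
    stop("generation undefined: no progeny adult females ever observed",
         if (!is.null(temperature)) paste0(" at ", temperature, " degC") else "")
  G <- min(fem_days) - min(egg_days)
  if (G <= 0) stop("generation undefined: progeny females do not follow eggs in time")
  G
}

#' Intrinsic growth rate
#'
#' r = ln(R0) / G per day. A net reproductive rate of zero marks a
#' non-viable temperature: the function returns `-Inf` with attribute
#' `viable = FALSE` rather than a silent `NaN`.
#'
#' @param R0 net reproductive rate (>= 0).
#' @param G generation time, days (> 0).
#' @return r per day, with attribute `viable`.
#' @export
intrinsic_growth_rate <- function(R0, G) {
  stopifnot(R0 >= 0, G > 0)
  if (R0 == 0) {
    return(structure(-Inf, viable = FALSE))
  }
  structure(log(R0) / G, viable = TRUE)
}

#' Per-temperature demographic summary
#'
#' Runs the full demographic reconstruction for every temperature in a
#' cohort table: accumulated mean stage counts, stage survivals, hatching
#' proportion from the fitted hatching curve, fecundity H, net reproductive
#' rate R0, generation time G and intrinsic growth rate r.
#'
#' @param cohort cohort table (all temperatures).
#' @param hatching a fitted `hatching_model`.
#' @param warn_extrapolation passed to [predict_hatching()].
#' @return data.frame with one row per temperature (columns `temperature`,
#'   `N_*`, `S_*`, `p`, `H`, `R0`, `G`, `r`, `viable`). Temperatures where
#'   no progeny female was ever recorded get `NA` for `G` and `r` and
#'   `viable = FALSE`.
#' @export
demographic_summary <- function(cohort, hatching, warn_extrapolation = TRUE) {
  acc <- accumulate_counts(cohort)
  rows <- lapply(seq_len(nrow(acc)), function(i) {
    tt <- acc$temperature[i]
    N <- acc[i, -1]
    p <- predict_hatching(hatching, tt, warn_extrapolation = warn_extrapolation)
    H <- acc$N_egg[i]
    S <- tryCatch(stage_survival(N), error = function(e) NULL)
    R0 <- if (is.null(S)) 0 else net_reproductive_rate(p, H, S)
    G <- tryCatch(generation_time(cohort, temperature = tt),
                  error = function(e) NA_real_)
    if (!is.na(G) && R0 > 0) {
      r <- intrinsic_growth_rate(R0, G)
      viable <- attr(r, "viable")
    } else {
      r <- NA_real_; viable <- FALSE
    }
    data.frame(
      temperature = tt, N,
      S_egg_larva = if (is.null(S)) NA_real_ else S[["egg_larva"]],
      S_larva_pupa = if (is.null(S)) NA_real_ else S[["larva_pupa"]],
      S_pupa_adult = if (is.null(S)) NA_real_ else S[["pupa_adult"]],
      S_adult_female = if (is.null(S)) NA_real_ else S[["adult_female"]],
      p = p, H = H, R0 = R0, G = G, r = as.numeric(r), viable = viable
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
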
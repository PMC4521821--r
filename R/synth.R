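# Seeded generator of daily weather and ground-truth maturation kinetics
# emulating the study regime: multiple parcels and vintages, 4-5 weekly
# sampling points per kinetics, weather whose weekly aggregates respect the
# physical bounds of the maturation variables.

#' Scenario specification for the synthetic generator
#'
#' Defaults emulate the study regime: 28 parcels observed over the four
#' vintages 2006-2009, kinetics of 4 or 5 weekly points (3 or 4 weekly
#' transitions), vintage-specific season coefficients, and measurement
#' noise of 3 g/L on sugar and 0.15 g/L on acidity.
#'
#' @param n_parcels Number of parcels.
#' @param vintages Vector of vintage years.
#' @param weeks_range Range of weekly transitions per kinetics; each
#'   kinetics draws its length uniformly from this set (points = weeks + 1).
#' @param noise_s,noise_ac Gaussian observation noise scales, g/L (`>= 0`).
#' @param k Named season coefficients per vintage (default
#'   [season_coefficients()] values, 1 for unlisted vintages).
#' @param init_s_range,init_ac_range Uniform ranges for the week-1 state.
#' @param seed Integer seed.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_parcels = 28, vintages = 2006:2009,
                          weeks_range = c(3, 4),
                          noise_s = 3, noise_ac = 0.15,
                          k = NULL,
                          init_s_range = c(125, 160),
                          init_ac_range = c(6.5, 8.2),
                          seed = 1) {
  if (noise_s < 0 || noise_ac < 0) stop("noise must be >= 0", call. = FALSE)
  if (n_parcels < 1 || !length(vintages)) stop("need >= 1 parcel and vintage",
                                               call. = FALSE)
  if (is.null(k)) k <- season_coefficients(vintages)
  structure(list(n_parcels = n_parcels, vintages = vintages,
                 weeks_range = weeks_range, noise_s = noise_s,
                 noise_ac = noise_ac, k = k,
                 init_s_range = init_s_range, init_ac_range = init_ac_range,
                 seed = seed),
            class = "scenario_spec")
}

# one parcel-vintage window of daily weather (weeks x 7 days)
.daily_weather_block <- function(weeks, base_temp) {
  n <- weeks * 7L
  # autocorrelated mean temperature with a slow seasonal decline
  eps <- stats::rnorm(n, 0, 1.6)
  ar <- stats::filter(eps, 0.6, method = "recursive")
  tmean <- base_temp - 0.06 * seq_len(n) + as.numeric(ar)
  tmax <- tmean + 4 + abs(stats::rnorm(n, 3, 1.5))
  # bursty rainfall with wet-day persistence
  wet <- logical(n)
  wet[1] <- stats::runif(1) < 0.3
  for (i in 2:n) wet[i] <- stats::runif(1) < ifelse(wet[i - 1], 0.5, 0.25)
  pl <- ifelse(wet, stats::rexp(n, 1 / 4), 0)
  # insolation reduced on wet days; humidity anticorrelated with insolation
  ins <- pmax(0, (9 - 0.03 * seq_len(n)) * (1 - 0.7 * wet) +
                stats::rnorm(n, 0, 1.2))
  rh <- pmin(100, pmax(50, 72 + 8 * wet - 0.9 * (ins - 6) +
                         stats::rnorm(n, 0, 3)))
  data.frame(
    day = seq_len(n),
    week = rep(seq_len(weeks) + 1L, each = 7L),  # weather drives weeks 2..
    Tmeanday = tmean, Tmaxday = tmax, Insday = ins, RHday = rh, Plday = pl
  )
}

#' Generate seeded daily weather series
#'
#' Autocorrelated daily mean temperature with a seasonal decline, maximal
#' temperature above the mean, bursty persistent rainfall, insolation
#' reduced on wet days and relative humidity anticorrelated with
#' insolation. One block per parcel-vintage; weekly aggregates land inside
#' the physical bounds with high frequency.
#'
#' @param spec A [scenario_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return Data frame of daily weather with identifying columns `parcel`,
#'   `vintage`, `week` (weeks `2..weeks+1`; week 1 is the initial
#'   measurement week), `day`.
#' @export
generate_daily_weather <- function(spec = scenario_spec(), seed = NULL) {
  restore <- .local_seed(if (is.null(seed)) spec$seed else seed)
  on.exit(if (is.function(restore)) restore())
  pieces <- list()
  for (v in spec$vintages) {
    base_v <- stats::runif(1, 14, 17)  # vintage-level climate offset
    for (p in seq_len(spec$n_parcels)) {
      weeks <- if (length(spec$weeks_range) > 1L) {
        sample(seq(min(spec$weeks_range), max(spec$weeks_range)), 1L)
      } else {
        spec$weeks_range
      }
      block <- .daily_weather_block(weeks, base_v + stats::rnorm(1, 0, 0.7))
      block$parcel <- p
      block$vintage <- v
      pieces[[length(pieces) + 1L]] <- block
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[c("parcel", "vintage", "week", "day", "Tmeanday", "Tmaxday",
        "Insday", "RHday", "Plday")]
}

#' Weekly aggregates of a daily weather table
#'
#' Weekly temperature is the sum of daily means; insolation and rainfall
#' are weekly sums; relative humidity is the weekly mean.
#'
#' @param daily Daily weather with `parcel`, `vintage`, `week` columns.
#' @return Data frame `parcel`, `vintage`, `week`, `T`, `RH`, `Ins`, `Pl`.
#' @export
weekly_aggregates <- function(daily) {
  key <- interaction(daily$parcel, daily$vintage, daily$week, drop = TRUE)
  pieces <- lapply(split(daily, key), function(g) {
    data.frame(parcel = g$parcel[1], vintage = g$vintage[1], week = g$week[1],
               T = sum(g$Tmeanday), RH = mean(g$RHday),
               Ins = sum(g$Insday), Pl = sum(g$Plday))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$vintage, out$parcel, out$week), ]
  rownames(out) <- NULL
  out
}

# independent logistic-sugar / exponential-acid truth dynamics (not the
# fuzzy expert model) for non-circular testing of the expert model itself
.alt_truth_step <- function(state, days, k) {
  warm <- mean(pmax(days$Tmeanday - 10, 0)) / 5
  wet <- sum(days$Plday) / 20
  dS <- 18 * k * warm * (1 - state$S / 240) - 4 * wet
  dAc <- -0.12 * k * warm * (state$Ac - 2.5) + 0.08 * wet
  list(S = state$S + dS, Ac = state$Ac + dAc)
}

#' Generate ground-truth kinetics and noisy observations
#'
#' Runs the truth dynamics over each parcel-vintage's daily weather from a
#' randomly drawn initial state, then adds Gaussian observation noise. Both
#' the noise-free truth and the observations are returned so recovery can
#' be tested. The default truth is the fuzzy expert model with the
#' vintage's season coefficient; `truth = "logistic"` switches to an
#' independent logistic-sugar / exponential-acidity mode.
#'
#' @param daily Daily weather from [generate_daily_weather()].
#' @param spec The [scenario_spec()] used (noise scales, initial ranges, k).
#' @param truth `"fgrape"` (default) or `"logistic"`.
#' @param seed Optional seed overriding `spec$seed + 1`.
#' @return List with `truth` and `observed`, both data frames `parcel`,
#'   `vintage`, `week`, `S`, `Ac` (weeks `1..weeks+1`).
#' @export
generate_ground_truth_kinetics <- function(daily, spec = scenario_spec(),
                                           truth = c("fgrape", "logistic"),
                                           seed = NULL) {
  truth <- match.arg(truth)
  restore <- .local_seed(if (is.null(seed)) spec$seed + 1L else seed)
  on.exit(if (is.function(restore)) restore())
  base <- if (truth == "fgrape") fgrape_rule_base() else NULL
  unit <- interaction(daily$parcel, daily$vintage, drop = TRUE)
  truth_pieces <- list()
  for (g in split(daily, unit)) {
    kv <- spec$k[as.character(g$vintage[1])]
    if (is.na(kv)) kv <- 1
    init <- list(S = stats::runif(1, spec$init_s_range[1], spec$init_s_range[2]),
                 Ac = stats::runif(1, spec$init_ac_range[1],
                                   spec$init_ac_range[2]))
    blocks <- split(g, g$week)
    if (truth == "fgrape") {
      traj <- suppressWarnings(
        simulate_kinetics(init, blocks, k = kv, base = base))
    } else {
      n <- length(blocks)
      S <- numeric(n + 1); Ac <- numeric(n + 1)
      S[1] <- init$S; Ac[1] <- init$Ac
      state <- init
      for (t in seq_len(n)) {
        state <- .alt_truth_step(state, blocks[[t]], kv)
        S[t + 1] <- state$S; Ac[t + 1] <- state$Ac
      }
      traj <- data.frame(week = seq_len(n + 1), S = S, Ac = Ac)
    }
    traj$parcel <- g$parcel[1]
    traj$vintage <- g$vintage[1]
    truth_pieces[[length(truth_pieces) + 1L]] <- traj
  }
  truth_df <- do.call(rbind, truth_pieces)
  truth_df <- truth_df[c("parcel", "vintage", "week", "S", "Ac")]
  rownames(truth_df) <- NULL
  observed <- truth_df
  observed$S <- observed$S + stats::rnorm(nrow(observed), 0, spec$noise_s)
  observed$Ac <- observed$Ac + stats::rnorm(nrow(observed), 0, spec$noise_ac)
  list(truth = truth_df, observed = observed)
}

#' Generate a complete synthetic maturation dataset
#'
#' Convenience wrapper: daily weather, weekly aggregates, ground-truth
#' kinetics and noisy weekly observations, merged into the weekly table
#' consumed by the learning, coupling and validation functions. Week 1
#' carries the initial measurements with zero climate contribution (its
#' climate columns are those of week 2, used only as filter evidence).
#'
#' @param spec A [scenario_spec()].
#' @param truth Truth mode, see [generate_ground_truth_kinetics()].
#' @return List with `daily`, `weekly` (columns `parcel`, `vintage`,
#'   `week`, `T`, `RH`, `Ins`, `Pl`, `S`, `Ac`), `truth` and the `spec`.
#' @export
generate_maturation_dataset <- function(spec = scenario_spec(),
                                        truth = "fgrape") {
  daily <- generate_daily_weather(spec)
  kin <- generate_ground_truth_kinetics(daily, spec, truth = truth)
  agg <- weekly_aggregates(daily)
  # week-1 rows reuse week-2 climate (evidence only; no transition into
  # week 1 is ever formed)
  first <- agg[agg$week == 2L, ]
  first$week <- 1L
  agg <- rbind(first, agg)
  weekly <- merge(kin$observed, agg,
                  by = c("parcel", "vintage", "week"), all.x = TRUE)
  weekly <- weekly[order(weekly$vintage, weekly$parcel, weekly$week), ]
  rownames(weekly) <- NULL
  list(daily = daily, weekly = weekly, truth = kin$truth, spec = spec)
}
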
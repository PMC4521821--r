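# FGRAPEDBN coupling: expert-model simulations enrich the network's
# conditional tables, then the coupled network predicts week by week.

.local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  # restore in the caller's exit handler
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate random weekly climate configurations
#'
#' Samples `n` weekly climate tuples uniformly within the physical bounds,
#' to feed the expert model over climate cells never encountered in the
#' experimental database. A weekly maximal temperature is drawn alongside so
#' the week can be decomposed into days.
#'
#' @param n Number of configurations (`>= 1`).
#' @param seed Integer seed; the same seed reproduces the same scenarios.
#' @param bounds Sampling bounds (default [maturation_bounds()]).
#' @return Data frame with columns `scenario`, `T`, `RH`, `Ins`, `Pl`,
#'   `Tmax_week`.
#' @export
generate_configurations <- function(n = 100, seed = 1,
                                    bounds = maturation_bounds()) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (any(bounds$lower > bounds$upper)) stop("inverted bounds", call. = FALSE)
  restore <- .local_seed(seed)
  on.exit(if (is.function(restore)) restore())
  draw <- function(v) stats::runif(n, bounds[v, "lower"], bounds[v, "upper"])
  Tw <- draw("T")
  data.frame(
    scenario = seq_len(n),
    T = Tw, RH = draw("RH"), Ins = draw("Ins"), Pl = draw("Pl"),
    Tmax_week = Tw / 7 + stats::runif(n, 2, 12)
  )
}

#' Decompose a weekly climate into seven days
#'
#' Extensive quantities are split evenly (`/7`); the intensive relative
#' humidity is carried over; each day's maximal temperature adds a uniform
#' random increment to the mean, bounded by the week's maximal temperature.
#'
#' @param week Named list/one-row data frame with `T`, `RH`, `Ins`, `Pl`.
#' @param Tmax_week Maximal temperature of the week, degC
#'   (`>= T/7`).
#' @param seed Optional integer seed for the per-day increments.
#' @return Data frame of 7 [day_climate()] rows.
#' @export
weekly_to_daily <- function(week, Tmax_week, seed = NULL) {
  vals <- c(week$T, week$RH, week$Ins, week$Pl, Tmax_week)
  if (anyNA(vals) || any(!is.finite(vals))) stop("weekly values must be finite",
                                                 call. = FALSE)
  tmean <- week$T / 7
  if (Tmax_week < tmean) stop("Tmax_week must be >= the mean day temperature",
                              call. = FALSE)
  restore <- .local_seed(seed)
  on.exit(if (is.function(restore)) restore())
  data.frame(
    Tmeanday = rep(tmean, 7),
    Tmaxday = tmean + stats::runif(7, 0, Tmax_week - tmean),
    Insday = rep(week$Ins / 7, 7),
    RHday = rep(week$RH, 7),
    Plday = rep(week$Pl / 7, 7)
  )
}

#' Build a simulated transition database with the expert model
#'
#' Each scenario's weekly climate drives a full maturation window simulated
#' by the fuzzy expert model from a randomly drawn initial state; every
#' weekly transition is discretized into a record compatible with the
#' network's count tables and tagged as simulated. Out-of-bound simulated
#' levels are clamped to boundary bins (the expert dynamics are not clamped,
#' only their discretization).
#'
#' @param scenarios Output of [generate_configurations()].
#' @param disc A [discretizer()].
#' @param weeks Weeks simulated per scenario (default 5, one maturation
#'   window).
#' @param k Season coefficient for the simulations (default the neutral 1).
#' @param base,table Expert rule base and increment table.
#' @param seed Integer seed for initial states and day decomposition.
#' @param bounds Bounds for the initial state draw.
#' @return Data frame of integer state records (same columns as
#'   [make_transition_records()]) with a `provenance = "simulated"` column.
#' @export
build_simulated_database <- function(scenarios, disc = discretizer(),
                                     weeks = 5, k = 1,
                                     base = fgrape_rule_base(),
                                     table = index_increment_table(),
                                     seed = 1,
                                     bounds = maturation_bounds()) {
  if (!nrow_or_zero(scenarios)) {
    return(data.frame())
  }
  restore <- .local_seed(seed)
  on.exit(if (is.function(restore)) restore())
  pieces <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, , drop = FALSE]
    S <- stats::runif(1, bounds["S", "lower"], bounds["S", "upper"])
    Ac <- stats::runif(1, bounds["Ac", "lower"], bounds["Ac", "upper"])
    Sv <- numeric(weeks + 1); Acv <- numeric(weeks + 1)
    Sv[1] <- S; Acv[1] <- Ac
    state <- list(S = S, Ac = Ac)
    for (t in seq_len(weeks)) {
      days <- weekly_to_daily(sc, sc$Tmax_week)
      state <- weekly_update(state, days, k, base, table)
      Sv[t + 1] <- state$S; Acv[t + 1] <- state$Ac
    }
    d <- suppressWarnings(data.frame(
      T = rep(discretize(disc, "T", sc$T), weeks),
      RH = rep(discretize(disc, "RH", sc$RH), weeks),
      Ins = rep(discretize(disc, "Ins", sc$Ins), weeks),
      Pl = rep(discretize(disc, "Pl", sc$Pl), weeks),
      dS = discretize(disc, "dS", diff(Sv)),
      dAc = discretize(disc, "dAc", diff(Acv)),
      S = discretize(disc, "S", Sv[-1]),
      Ac = discretize(disc, "Ac", Acv[-1]),
      S.prev = discretize(disc, "S", Sv[-(weeks + 1)]),
      Ac.prev = discretize(disc, "Ac", Acv[-(weeks + 1)])
    ))
    d$scenario <- sc$scenario
    pieces[[i]] <- d
  }
  out <- do.call(rbind, pieces)
  out$provenance <- "simulated"
  rownames(out) <- NULL
  out
}

#' Update network parameters with a simulated database
#'
#' Adds the simulated occurrence counts on top of the experimental
#' posterior: with the experimental pseudo-counts `alpha' = N + alpha`
#' already in place, the refreshed estimate is
#' `theta_ijk = (N_sim_ijk + alpha'_ijk) / sum_k (N_sim_ijk + alpha'_ijk)`
#' (rows renormalized over the composed counts). With an empty simulated
#' database the parameters are unchanged, and rows untouched by the
#' simulations remain bit-identical. The two ledgers are kept separate so
#' the update is reversible.
#'
#' @param cpts A `cpt_set` (typically from [learn_parameters()]).
#' @param simdb Simulated records from [build_simulated_database()].
#' @return The updated `cpt_set`.
#' @export
update_parameters <- function(cpts, simdb) {
  stopifnot(inherits(cpts, "cpt_set"))
  if (!nrow_or_zero(simdb)) return(cpts)
  st <- cpts$structure
  for (v in names(st$nodes)) {
    cols <- .record_columns(st, v)
    missing_col <- setdiff(cols, names(simdb))
    if (length(missing_col)) {
      stop("simulated records incompatible with the structure; missing: ",
           paste(missing_col, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(simdb[cols])
    storage.mode(m) <- "integer"
    .check_states(m, .cpt_dims(st, v), v)
    cpts$n_sim[[v]] <- .count_into(cpts$n_sim[[v]], m)
  }
  cpts
}

#' Coupled weekly prediction
#'
#' The full decision-support prediction: sugar and acidity states are
#' initialized from the first week's measurements, then the network is
#' filtered week by week under the observed weekly climate, each week's
#' belief feeding the next. Posterior means convert the weekly marginals to
#' physical units.
#'
#' @param initial Named list with measured `S` (g/L) and `Ac` (g/L) at
#'   week 1.
#' @param weekly Data frame of weekly climate (`week`, `T`, `RH`, `Ins`,
#'   `Pl`), one row per week of the maturation window.
#' @param cpts A `cpt_set` (learnt, optionally updated with simulations).
#' @param disc The [discretizer()] shared with learning.
#' @return Object of class `fgrapedbn_prediction`: list with `means` (data
#'   frame `week`, `S`, `Ac`) and the underlying `belief` trajectory.
#' @export
fgrapedbn_predict <- function(initial, weekly, cpts, disc = discretizer()) {
  if (!nrow_or_zero(weekly)) stop("at least one week of weather is required",
                                  call. = FALSE)
  g <- weekly[order(weekly$week), , drop = FALSE]
  ev <- lapply(seq_len(nrow(g)), function(i) {
    c(T = discretize(disc, "T", g$T[i]),
      RH = discretize(disc, "RH", g$RH[i]),
      Ins = discretize(disc, "Ins", g$Ins[i]),
      Pl = discretize(disc, "Pl", g$Pl[i]))
  })
  ev[[1]] <- c(ev[[1]],
               S = discretize(disc, "S", initial$S),
               Ac = discretize(disc, "Ac", initial$Ac))
  belief <- dbn_filter(cpts, ev, tau = nrow(g), query = c("S", "Ac"))
  means <- posterior_mean(belief, disc)
  means$week <- g$week
  structure(list(means = means, belief = belief),
            class = "fgrapedbn_prediction")
}

#' @export
print.fgrapedbn_prediction <- function(x, ...) {
  cat("<fgrapedbn_prediction> posterior means over",
      nrow(x$means), "weeks\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}
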
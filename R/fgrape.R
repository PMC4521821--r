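#' FGRAPE linguistic variables for day climate
#'
#' The five fuzzy input variables of the expert model, with the reference
#' membership parameters used throughout: mean day temperature, maximal day
#' temperature, day insolation, mean day relative humidity, day rainfall.
#' Interior terms are trapezoids; the lowest/highest terms are shoulders so
#' each partition sums to one over the whole axis. Relative humidity has only
#' a "low"/"high" pair whose shoulders share the (70, 85) transition band.
#'
#' @return Named list of [linguistic_variable()]s, names `Tmeanday`,
#'   `Tmaxday`, `Insday`, `RHday`, `Plday`.
#' @export
fgrape_variables <- function() {
  ls_ <- function(a, b) membership_function("left-shoulder", c(a, b))
  rs_ <- function(a, b) membership_function("right-shoulder", c(a, b))
  tz_ <- function(a, b, c, d) membership_function("trapezoidal", c(a, b, c, d))
  list(
    Tmeanday = linguistic_variable("Tmeanday", "degC", list(
      low = ls_(7, 13), middle = tz_(7, 13, 15, 21), high = rs_(15, 21))),
    Tmaxday = linguistic_variable("Tmaxday", "degC", list(
      low = ls_(26, 30), middle = tz_(26, 30, 32, 35), high = rs_(32, 35))),
    Insday = linguistic_variable("Insday", "h", list(
      low = ls_(4.5, 5.5), middle = tz_(4.5, 5.5, 7.5, 8.5),
      high = rs_(7.5, 8.5))),
    RHday = linguistic_variable("RHday", "%", list(
      low = ls_(70, 85), high = rs_(70, 85))),
    Plday = linguistic_variable("Plday", "mm", list(
      low = ls_(4, 6), middleminus = tz_(4, 6, 13, 17),
      middleplus = tz_(13, 17, 25, 35), high = rs_(25, 35)))
  )
}

#' Day-index increment table
#'
#' Per-day sugar and total-acidity increments attached to the four day-index
#' levels: 0 = bad conditions (rain dilution), 1 = not favorable (limiting),
#' 2 = standard day for the region, 3 = exceptional day (concentration).
#'
#' @return List with elements `sugar` and `acidity`, each a named numeric
#'   vector over classes `"0".."3"`, in g/L per day.
#' @export
index_increment_table <- function() {
  list(sugar   = c(`0` = -1, `1` = 1, `2` = 3, `3` = 5),
       acidity = c(`0` = 0.3, `1` = 0, `2` = -0.2, `3` = -0.4))
}

#' Season adjustment coefficients
#'
#' Vintage-specific multiplier `k` applied to the weekly sum of day
#' increments, fixed by expert judgement of soil and global climate impact.
#'
#' @param vintage Optional vintage (year) to look up; unknown vintages get
#'   the neutral value 1.
#' @return Named numeric vector of coefficients, or a single coefficient if
#'   `vintage` is given.
#' @export
season_coefficients <- function(vintage = NULL) {
  k <- c(`2006` = 0.8, `2007` = 1, `2008` = 0.9, `2009` = 0.7)
  if (is.null(vintage)) return(k)
  out <- k[as.character(vintage)]
  out[is.na(out)] <- 1
  stats::setNames(as.numeric(out), as.character(vintage))
}

#' Seed rules of the FGRAPE base
#'
#' The expert rules recoverable verbatim: six printed standard-day (class 2)
#' combinations plus the two in-text examples (one class 1, one class 2).
#' Conclusions are shared across the sugar and acidity outputs (same index
#' level); rule 6's relative-humidity antecedent is taken as unconstrained
#' (its printed label does not exist in the humidity partition).
#'
#' @return List of [fuzzy_rule()]s.
#' @export
fgrape_seed_rules <- function() {
  rl <- function(tm, tx, ins, pl, rh, class) {
    fuzzy_rule(list(Tmeanday = tm, Tmaxday = tx, Insday = ins,
                    Plday = pl, RHday = rh),
               c(sugar = class, acidity = class))
  }
  all_rh <- c("low", "high")
  list(
    rl("middle", "low",    "middle", "low",         "low",  "2"),
    rl("middle", "low",    "high",   "low",         all_rh, "2"),
    rl("middle", "low",    "middle", "middleminus", "low",  "2"),
    rl("middle", "low",    "high",   "middleminus", all_rh, "2"),
    rl("middle", "middle", "middle", "low",         all_rh, "2"),
    rl("middle", "middle", "high",   "low",         all_rh, "2"),
    # in-text examples
    rl("middle", "low",    "low",    "low",         all_rh, "1"),
    rl("middle", "low",    "middle", "low",         "low",  "2")
  )
}

#' Default completion policy
#'
#' Additive favourability heuristic used to label the climate configurations
#' not covered by the seed rules: warmth and insolation are favourable, rain
#' strongly unfavourable, extreme heat unfavourable. The per-term scores and
#' class cut points reproduce every seed rule's class when applied to the
#' seed configurations, so policy and expert rules agree where both speak.
#'
#' @return List with `scores` (per variable, named numeric per term) and
#'   `cuts` (three increasing score thresholds separating classes 0|1|2|3).
#' @export
fgrape_completion_policy <- function() {
  list(
    scores = list(
      Tmeanday = c(low = 0, middle = 4, high = 5),
      Tmaxday  = c(low = 2, middle = 1, high = -2),
      Insday   = c(low = 0, middle = 2, high = 2),
      RHday    = c(low = 0, high = 0),
      Plday    = c(low = 2, middleminus = 1, middleplus = -1, high = -4)
    ),
    cuts = c(2, 8, 10)
  )
}

# all crisp term configurations, one row per configuration
.fgrape_config_grid <- function(variables) {
  grid <- expand.grid(lapply(variables, function(v) names(v$terms)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[do.call(order, grid), , drop = FALSE]
}

.policy_class <- function(config, policy) {
  score <- sum(vapply(names(config), function(v) policy$scores[[v]][[config[[v]]]],
                      numeric(1)))
  as.character(findInterval(score, policy$cuts + 0.5))
}

# does crisp configuration cfg (named character) match rule r?
.rule_matches <- function(r, cfg) {
  for (v in names(r$antecedent)) {
    if (!cfg[[v]] %in% r$antecedent[[v]]) return(FALSE)
  }
  TRUE
}

#' Complete a seed rule set to full coverage
#'
#' Expands the rule base so that every crisp configuration of the five day
#' climate variables (3 x 3 x 3 x 2 x 4 = 216) concludes exactly one index
#' class per output: configurations matched by a seed rule take the seed's
#' class (contradictory seeds are an error); the rest are scored by the
#' completion policy. The result is a deterministic base of 216 crisp rules,
#' and completing an already complete base returns it unchanged.
#'
#' @param seed_rules List of [fuzzy_rule()]s honoured verbatim
#'   (default [fgrape_seed_rules()]).
#' @param policy Completion policy (default [fgrape_completion_policy()]).
#' @param variables Linguistic variables (default [fgrape_variables()]).
#' @return A [rule_base()] of one crisp rule per configuration.
#' @export
complete_rule_base <- function(seed_rules = fgrape_seed_rules(),
                               policy = fgrape_completion_policy(),
                               variables = fgrape_variables()) {
  base_chk <- rule_base(seed_rules, variables)  # validates labels
  grid <- .fgrape_config_grid(base_chk$variables)
  outputs <- names(seed_rules[[1]]$conclusion)
  rules <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- as.list(grid[i, , drop = FALSE])
    cfg <- stats::setNames(as.character(unlist(cfg)), names(grid))
    hits <- Filter(function(r) .rule_matches(r, cfg), seed_rules)
    if (length(hits)) {
      concl <- unique(lapply(hits, `[[`, "conclusion"))
      if (length(concl) > 1L) {
        stop("contradictory seed rules for configuration (",
             paste(names(cfg), cfg, sep = "=", collapse = ", "), ")",
             call. = FALSE)
      }
      concl <- concl[[1]][outputs]
    } else {
      cl <- .policy_class(as.list(cfg), policy)
      concl <- stats::setNames(rep(cl, length(outputs)), outputs)
    }
    rules[[i]] <- fuzzy_rule(as.list(cfg), concl)
  }
  out <- rule_base(rules, base_chk$variables)
  # crisp index matrix for fast activation
  idx <- vapply(names(out$variables), function(v) {
    labs <- names(out$variables[[v]]$terms)
    match(vapply(rules, function(r) r$antecedent[[v]], character(1)), labs)
  }, integer(length(rules)))
  attr(out, "crisp_index") <- idx
  out
}

#' Number of crisp configurations covered by a rule base
#'
#' @param base A [rule_base()] over the day climate variables.
#' @return Integer count of configurations matched by at least one rule.
#' @export
rule_base_coverage <- function(base) {
  stopifnot(inherits(base, "rule_base"))
  grid <- .fgrape_config_grid(base$variables)
  covered <- 0L
  for (i in seq_len(nrow(grid))) {
    cfg <- stats::setNames(as.character(unlist(grid[i, ])), names(grid))
    if (any(vapply(base$rules, .rule_matches, logical(1), cfg = cfg))) {
      covered <- covered + 1L
    }
  }
  covered
}

# cached default complete base
.fgrape_env <- new.env(parent = emptyenv())

#' The default complete FGRAPE rule base
#'
#' [complete_rule_base()] applied to the seed rules, cached per session.
#' @return A [rule_base()] of 216 crisp rules.
#' @export
fgrape_rule_base <- function() {
  if (is.null(.fgrape_env$base)) .fgrape_env$base <- complete_rule_base()
  .fgrape_env$base
}

#' Day climate record
#'
#' Validates one day of climate inputs for the expert model.
#'
#' @param Tmeanday Mean day temperature, degC.
#' @param Tmaxday Maximal day temperature, degC (`>= Tmeanday`).
#' @param Insday Insolation duration, hours (`>= 0`).
#' @param RHday Mean relative humidity, percent, in `[0, 100]`.
#' @param Plday Rainfall, mm (`>= 0`).
#' @return Named list of the five values.
#' @export
day_climate <- function(Tmeanday, Tmaxday, Insday, RHday, Plday) {
  v <- c(Tmeanday = Tmeanday, Tmaxday = Tmaxday, Insday = Insday,
         RHday = RHday, Plday = Plday)
  if (anyNA(v) || any(!is.finite(v))) stop("day climate must be finite",
                                           call. = FALSE)
  if (RHday < 0 || RHday > 100) stop("RHday must be in [0, 100]", call. = FALSE)
  if (Insday < 0 || Plday < 0) stop("Insday and Plday must be >= 0",
                                    call. = FALSE)
  if (Tmaxday < Tmeanday) stop("Tmaxday must be >= Tmeanday", call. = FALSE)
  as.list(v)
}

#' Day-index class weights for one day of climate
#'
#' Fuzzifies the five inputs, activates every rule of the base by the product
#' t-norm and aggregates concluded classes into normalized weights over the
#' index levels 0..3 for each output. The base must cover all 216 crisp
#' configurations; an uncovered configuration is a configuration error.
#'
#' @param day A [day_climate()] (or named list with the five fields).
#' @param base A complete [rule_base()] (default [fgrape_rule_base()]).
#' @return List with named weight vectors `sugar` and `acidity` over
#'   classes `"0".."3"`, each summing to 1.
#' @export
day_index <- function(day, base = fgrape_rule_base()) {
  vars <- base$variables
  fz <- lapply(names(vars), function(v) fuzzify(vars[[v]], day[[v]]))
  names(fz) <- names(vars)
  idx <- attr(base, "crisp_index")
  if (!is.null(idx)) {
    alpha <- rep(1, nrow(idx))
    for (j in seq_along(vars)) alpha <- alpha * fz[[j]][idx[, j]]
  } else {
    alpha <- vapply(base$rules, activate_rule, numeric(1), fuzzified = fz)
  }
  if (sum(alpha) <= 0) {
    nearest <- vapply(fz, function(d) names(d)[which.max(d)], character(1))
    stop("no rule covers the configuration (",
         paste(names(nearest), nearest, sep = "=", collapse = ", "),
         "); the rule base is incomplete", call. = FALSE)
  }
  aggregate_classes(base$rules, alpha, classes = as.character(0:3))
}

#' Daily increment from index class weights
#'
#' Weighted defuzzification: the expected per-day increment under the class
#' weights, per output.
#'
#' @param weights Output of [day_index()] (normalized weights).
#' @param table Increment table (default [index_increment_table()]).
#' @return Named numeric vector `c(sugar = , acidity = )`, g/L per day.
#' @export
day_increment <- function(weights, table = index_increment_table()) {
  vapply(names(table), function(o) {
    w <- weights[[o]]
    sum(w * table[[o]][names(w)])
  }, numeric(1))
}

#' Weekly update of the maturity state
#'
#' Adds `k` times the sum of the seven daily increments to the previous
#' week's sugar and acidity.
#'
#' @param state Named list/vector with `S` (g/L) and `Ac` (g/L eq H2SO4).
#' @param days Data frame of exactly 7 rows with the [day_climate()] columns.
#' @param k Season coefficient (positive).
#' @param base,table Rule base and increment table.
#' @return Updated state list with fields `S`, `Ac`.
#' @export
weekly_update <- function(state, days, k = 1, base = fgrape_rule_base(),
                          table = index_increment_table()) {
  days <- as.data.frame(days)
  if (nrow(days) != 7L) stop("a week must contain exactly 7 days, got ",
                             nrow(days), call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("'k' must be positive", call. = FALSE)
  inc <- rowSums(vapply(seq_len(7L), function(i) {
    day_increment(day_index(as.list(days[i, , drop = FALSE]), base), table)
  }, numeric(2)))
  list(S = state$S + k * inc[["sugar"]], Ac = state$Ac + k * inc[["acidity"]])
}

#' Simulate a maturation kinetics with the expert model
#'
#' Iterates [weekly_update()] over ordered 7-day blocks of daily weather,
#' returning the weekly trajectory including the initial state. Values
#' leaving the physical validity bounds raise a warning (once per
#' trajectory) but are not clamped: the bounds are a validity check, not
#' part of the dynamics.
#'
#' @param initial Named list with `S` and `Ac` at week 1.
#' @param daily Data frame of daily climate with a `week` column (weeks
#'   `2..(n+1)`, 7 rows each) or a list of 7-row blocks.
#' @param k Season coefficient.
#' @param base,table Rule base and increment table.
#' @param bounds Validity bounds, default [maturation_bounds()].
#' @return Data frame with columns `week`, `S`, `Ac` (`n + 1` rows).
#' @export
simulate_kinetics <- function(initial, daily, k = 1,
                              base = fgrape_rule_base(),
                              table = index_increment_table(),
                              bounds = maturation_bounds()) {
  if (is.data.frame(daily)) {
    blocks <- if (nrow(daily)) split(daily, daily$week) else list()
  } else {
    blocks <- daily
  }
  n <- length(blocks)
  S <- numeric(n + 1); Ac <- numeric(n + 1)
  S[1] <- initial$S; Ac[1] <- initial$Ac
  state <- list(S = initial$S, Ac = initial$Ac)
  for (t in seq_len(n)) {
    state <- weekly_update(state, blocks[[t]], k, base, table)
    S[t + 1] <- state$S; Ac[t + 1] <- state$Ac
  }
  out <- data.frame(week = seq_len(n + 1), S = S, Ac = Ac)
  oob <- S < bounds["S", "lower"] | S > bounds["S", "upper"] |
    Ac < bounds["Ac", "lower"] | Ac > bounds["Ac", "upper"]
  if (any(oob)) {
    warning("trajectory leaves physical bounds at week(s) ",
            paste(which(oob), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a daily weather table
#'
#' Delimited text with columns `date`, `Tmeanday`, `Tmaxday`, `Insday`,
#' `RHday`, `Plday` (and optionally `week`).
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame with validated numeric columns.
#' @export
read_daily_weather <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("Tmeanday", "Tmaxday", "Insday", "RHday", "Plday")
  missing_col <- setdiff(need, names(tab))
  if (length(missing_col)) stop("missing column(s): ",
                                paste(missing_col, collapse = ", "),
                                call. = FALSE)
  for (v in need) tab[[v]] <- as.numeric(tab[[v]])
  if (anyNA(tab[need])) stop("non-numeric values in weather columns",
                             call. = FALSE)
  tab
}
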
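test_that("the completed rule base covers all 216 configurations exactly once", {
  base <- fgrape_rule_base()
  expect_equal(length(base), 216)
  expect_equal(rule_base_coverage(base), 216)
  # idempotent: completing the complete base returns the same conclusions
  again <- complete_rule_base(base$rules)
  for (i in seq_along(base$rules)) {
    expect_equal(again$rules[[i]]$conclusion, base$rules[[i]]$conclusion)
  }
})

test_that("seed rules are honoured and the policy labels the extremes", {
  base <- fgrape_rule_base()
  lookup <- function(cfg) {
    hit <- Filter(function(r) all(vapply(names(cfg), function(v) {
      cfg[[v]] %in% r$antecedent[[v]]
    }, logical(1))), base$rules)
    hit[[1]]$conclusion[["sugar"]]
  }
  # printed standard-day rule: middle/middle temperature, middle insolation,
  # low rain -> class 2 (any humidity)
  expect_equal(lookup(c(Tmeanday = "middle", Tmaxday = "middle",
                        Insday = "middle", Plday = "low", RHday = "low")), "2")
  expect_equal(lookup(c(Tmeanday = "middle", Tmaxday = "middle",
                        Insday = "middle", Plday = "low", RHday = "high")), "2")
  # in-text limiting rule: low insolation drops the day to class 1
  expect_equal(lookup(c(Tmeanday = "middle", Tmaxday = "low", Insday = "low",
                        Plday = "low", RHday = "low")), "1")
  expect_equal(lookup(c(Tmeanday = "middle", Tmaxday = "low", Insday = "low",
                        Plday = "low", RHday = "high")), "1")
  # all-worst configuration: heavy rain, no sun, cold, humid -> class 0
  for (tx in c("low", "middle", "high")) {
    expect_equal(lookup(c(Tmeanday = "low", Tmaxday = tx, Insday = "low",
                          Plday = "high", RHday = "high")), "0")
  }
})

test_that("contradictory seed rules are a configuration error", {
  seeds <- c(fgrape_seed_rules(),
             list(fuzzy_rule(list(Tmeanday = "middle", Tmaxday = "low",
                                  Insday = "middle", Plday = "low",
                                  RHday = "low"),
                             c(sugar = "0", acidity = "0"))))
  expect_error(complete_rule_base(seeds), "contradictory")
})

test_that("crisp plateau inputs recover the printed rule classes", {
  base <- fgrape_rule_base()
  # standard day (printed rule 1): every input on its plateau
  di <- day_index(day_climate(14, 20, 6.5, 60, 2), base)
  expect_equal(di$sugar, c(`0` = 0, `1` = 0, `2` = 1, `3` = 0))
  expect_equal(di$acidity, c(`0` = 0, `1` = 0, `2` = 1, `3` = 0))
  # in-text class-1 day regardless of humidity
  for (rh in c(50, 95)) {
    expect_equal(day_index(day_climate(14, 20, 2, rh, 2), base)$sugar[["1"]], 1)
  }
})

test_that("inputs between two covered configurations split their weights", {
  base <- fgrape_rule_base()
  # Insday = 5 sits halfway between low (class 1 config) and middle
  # (class 2 config); all other inputs crisp
  di <- day_index(day_climate(14, 20, 5, 60, 2), base)
  expect_equal(di$sugar[["1"]], 0.5, tolerance = 1e-12)
  expect_equal(di$sugar[["2"]], 0.5, tolerance = 1e-12)
  expect_equal(sum(di$sugar), 1, tolerance = 1e-12)
})

test_that("daily increments defuzzify the class weights against the table", {
  tab <- index_increment_table()
  w2 <- list(sugar = c(`2` = 1), acidity = c(`2` = 1))
  expect_equal(day_increment(w2, tab), c(sugar = 3, acidity = -0.2))
  w0 <- list(sugar = c(`0` = 1), acidity = c(`0` = 1))
  expect_equal(day_increment(w0, tab), c(sugar = -1, acidity = 0.3))
  w23 <- list(sugar = c(`2` = 0.5, `3` = 0.5), acidity = c(`2` = 0.5, `3` = 0.5))
  expect_equal(day_increment(w23, tab)[["sugar"]], 4)
})

test_that("daily increments stay inside the table's convex hull and vary
          continuously with the climate", {
  base <- fgrape_rule_base()
  set.seed(21)
  prev <- NULL
  for (x in seq(0, 40, by = 0.5)) {
    inc <- day_increment(day_index(day_climate(
      Tmeanday = x / 2, Tmaxday = x / 2 + 10, Insday = 6, RHday = 60,
      Plday = x), base))
    expect_gte(inc[["sugar"]], -1); expect_lte(inc[["sugar"]], 5)
    expect_gte(inc[["acidity"]], -0.4); expect_lte(inc[["acidity"]], 0.3)
    if (!is.null(prev)) expect_lt(abs(inc[["sugar"]] - prev), 1.0)
    prev <- inc[["sugar"]]
  }
})

test_that("the weekly update accumulates k times the seven daily increments", {
  wk <- standard_week()
  st <- weekly_update(list(S = 150, Ac = 7), wk, k = 1)
  expect_equal(st$S, 150 + 21)
  expect_equal(st$Ac, 7 - 1.4)
  st07 <- weekly_update(list(S = 150, Ac = 7), wk, k = 0.7)
  expect_equal(st07$S, 150 + 14.7)
  # linearity in k: doubling k doubles the weekly change
  st2 <- weekly_update(list(S = 150, Ac = 7), wk, k = 2)
  expect_equal(st2$S - 150, 2 * (st$S - 150))
  expect_error(weekly_update(list(S = 150, Ac = 7), wk[1:5, ], 1),
               "exactly 7 days")
})

test_that("kinetics simulation iterates weeks and is translation-equivariant", {
  wk <- standard_week()
  expect_equal(nrow(simulate_kinetics(list(S = 150, Ac = 7), list())), 1)
  two <- rbind(transform(wk, week = 2), transform(wk, week = 3))
  traj <- simulate_kinetics(list(S = 150, Ac = 7), two, k = 1)
  expect_equal(nrow(traj), 3)
  expect_equal(traj$S[3] - traj$S[1], 42)
  shifted <- simulate_kinetics(list(S = 160, Ac = 7), two, k = 1)
  expect_equal(shifted$S, traj$S + 10)
  # out-of-bounds trajectories warn but are not clamped
  expect_warning(
    big <- simulate_kinetics(list(S = 230, Ac = 7),
                             rbind(two, transform(wk, week = 4))),
    "bounds")
  expect_gt(max(big$S), 237)
})

test_that("season coefficients default to the neutral value for new vintages", {
  k <- season_coefficients()
  expect_equal(unname(k[c("2006", "2007", "2008", "2009")]),
               c(0.8, 1, 0.9, 0.7))
  expect_equal(unname(season_coefficients(2024)), 1)
})

test_that("daily weather tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- standard_week()
  df$date <- sprintf("2008-09-%02d", 1:7)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_daily_weather(path)
  expect_equal(back$Tmeanday, df$Tmeanday)
  utils::write.table(df[-1], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_daily_weather(path), "missing column")
})
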
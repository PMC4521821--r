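test_that("membership shapes evaluate piecewise-linearly with correct anchors", {
  tri <- membership_function("triangular", c(7, 13, 21))
  expect_equal(evaluate_membership(tri, 13), 1)
  expect_equal(evaluate_membership(tri, 5), 0)
  expect_equal(evaluate_membership(tri, 10), (10 - 7) / 6)
  trap <- membership_function("trapezoidal", c(7, 13, 15, 21))
  expect_equal(evaluate_membership(trap, 10.5), 3.5 / 6)
  expect_equal(evaluate_membership(trap, 14), 1)
  expect_equal(evaluate_membership(trap, 18), (21 - 18) / 6)
  ls <- membership_function("left-shoulder", c(7, 13))
  expect_equal(evaluate_membership(ls, -100), 1)  # unbounded plateau
  expect_equal(evaluate_membership(ls, 10), 0.5)
  expect_equal(evaluate_membership(ls, 13.5), 0)
  rs <- membership_function("right-shoulder", c(15, 21))
  expect_equal(evaluate_membership(rs, 100), 1)
  expect_equal(evaluate_membership(rs, 18), 0.5)
})

test_that("malformed breakpoints are rejected", {
  expect_error(membership_function("triangular", c(3, 2, 1)), "non-decreasing")
  expect_error(membership_function("triangular", c(1, 2)), "3 finite")
  expect_error(membership_function("trapezoidal", c(1, 2, 3)), "4 finite")
  expect_error(evaluate_membership(membership_function("triangular",
                                                       c(0, 1, 2)), NA_real_))
})

test_that("membership stays bounded and continuous for random breakpoints", {
  set.seed(101)
  grid <- seq(-50, 50, by = 0.25)
  for (i in 1:40) {
    b <- sort(stats::runif(4, -30, 30))
    shape <- sample(c("triangular", "trapezoidal", "left-shoulder",
                      "right-shoulder"), 1)
    nb <- switch(shape, triangular = 3, trapezoidal = 4, 2)
    mf <- membership_function(shape, b[seq_len(nb)])
    y <- evaluate_membership(mf, grid)
    expect_true(all(y >= 0 & y <= 1))
    # piecewise-linear with bounded slope => small steps move y little
    expect_true(max(abs(diff(y))) <= 0.25 / max(min(diff(b)), 1e-3) + 1e-9)
  }
})

test_that("fuzzification returns one degree per term; partitions sum to one", {
  v <- fgrape_variables()
  expect_equal(fuzzify(v$Tmeanday, 30),
               c(low = 0, middle = 0, high = 1))
  expect_equal(fuzzify(v$Plday, 0),
               c(low = 1, middleminus = 0, middleplus = 0, high = 0))
  expect_equal(unname(fuzzify(v$Tmeanday, 14)["middle"]), 1)  # apex
  # humidity pair interpolates linearly across the (70, 85) gap
  expect_equal(fuzzify(v$RHday, 77.5), c(low = 0.5, high = 0.5))
  set.seed(7)
  for (nm in names(v)) {
    lo <- c(Tmeanday = -5, Tmaxday = 10, Insday = 0, RHday = 0, Plday = 0)[nm]
    hi <- c(Tmeanday = 35, Tmaxday = 45, Insday = 14, RHday = 100,
            Plday = 60)[nm]
    for (x in stats::runif(25, lo, hi)) {
      expect_equal(sum(fuzzify(v[[nm]], x)), 1, tolerance = 1e-12)
    }
  }
})

test_that("rule activation is the product of per-variable max degrees", {
  fz <- list(A = c(low = 0.5, high = 0.5), B = c(low = 0.5, high = 0.5))
  r <- fuzzy_rule(list(A = "low", B = "low"), c(out = "1"))
  expect_equal(activate_rule(r, fz), 0.25)
  fz1 <- list(A = c(low = 1, high = 0), B = c(low = 1, high = 0))
  expect_equal(activate_rule(r, fz1), 1)
  fz0 <- list(A = c(low = 0, high = 1), B = c(low = 1, high = 0))
  expect_equal(activate_rule(r, fz0), 0)
  # disjunctive antecedent: max over the admissible terms
  r_or <- fuzzy_rule(list(A = c("low", "high"), B = "low"), c(out = "1"))
  expect_equal(activate_rule(r_or, fz), 0.5 * 0.5)
  expect_error(activate_rule(fuzzy_rule(list(A = "mid"), c(out = "1")), fz),
               "unknown term")
})

test_that("class aggregation normalizes the weighted vote", {
  r2 <- fuzzy_rule(list(A = "low"), c(out = "2"))
  r3 <- fuzzy_rule(list(A = "high"), c(out = "3"))
  w <- aggregate_classes(list(r2), 0.7)
  expect_equal(w$out, c(`2` = 1))
  w2 <- aggregate_classes(list(r2, r3), c(0.3, 0.1))
  expect_equal(w2$out, c(`2` = 0.75, `3` = 0.25))
  expect_warning(w0 <- aggregate_classes(list(r2, r3), c(0, 0),
                                         classes = as.character(0:3)),
                 "neutral class")
  expect_equal(w0$out, c(`0` = 0, `1` = 1, `2` = 0, `3` = 0))
  expect_error(aggregate_classes(list(), numeric(0)), "empty")
})

test_that("aggregation matches a brute-force oracle on random small systems", {
  set.seed(11)
  classes <- as.character(0:3)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    rules <- lapply(seq_len(n), function(j) {
      fuzzy_rule(list(A = "low"),
                 c(sugar = sample(classes, 1), acidity = sample(classes, 1)))
    })
    alpha <- stats::runif(n)
    got <- aggregate_classes(rules, alpha, classes = classes)
    want <- brute_force_aggregate(rules, alpha, classes)
    expect_equal(got$sugar, want$sugar, tolerance = 1e-12)
    expect_equal(got$acidity, want$acidity, tolerance = 1e-12)
    expect_equal(sum(got$sugar), 1, tolerance = 1e-12)
  }
})

test_that("raising a rule's activation cannot lower its concluded class weight", {
  set.seed(12)
  classes <- as.character(0:3)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    rules <- lapply(seq_len(n), function(j) {
      fuzzy_rule(list(A = "low"), c(out = sample(classes, 1)))
    })
    alpha <- stats::runif(n, 0.05, 1)
    j <- sample(n, 1)
    cl <- rules[[j]]$conclusion[["out"]]
    w_lo <- aggregate_classes(rules, alpha, classes = classes)$out[cl]
    alpha2 <- alpha; alpha2[j] <- alpha2[j] + 0.5
    w_hi <- aggregate_classes(rules, alpha2, classes = classes)$out[cl]
    expect_gte(w_hi, w_lo - 1e-12)
  }
})

test_that("rule base files round-trip through the delimited format", {
  vars <- fgrape_variables()
  rules <- fgrape_seed_rules()
  base <- rule_base(rules, vars)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rule_base(base, path)
  back <- read_rule_base(path, vars)
  expect_equal(length(back), length(rules))
  for (i in seq_along(rules)) {
    expect_setequal(back$rules[[i]]$antecedent$Plday, rules[[i]]$antecedent$Plday)
    expect_equal(back$rules[[i]]$conclusion, rules[[i]]$conclusion)
  }
  # wildcard written for full term sets
  tab <- utils::read.delim(path, colClasses = "character")
  expect_true("*" %in% tab$RHday)
})

test_that("rule base construction validates variables and labels", {
  vars <- fgrape_variables()
  expect_error(rule_base(list(fuzzy_rule(list(Nope = "low"), c(s = "1"))),
                         vars), "unknown variable")
  expect_error(rule_base(list(fuzzy_rule(list(Tmeanday = "warm"), c(s = "1"))),
                         vars), "unknown term")
})
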
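test_that("discretization maps values to half-open bins with midpoints", {
  disc <- discretizer()
  b185 <- discretize(disc, "S", 185)
  expect_equal(disc$edges$S[b185], 184)       # the 184-192 g/L bin
  expect_equal(disc$edges$S[b185 + 1], 192)
  expect_equal(undigitize(disc, "S", b185), 188)
  # a bin edge belongs to exactly one (the upper) bin
  expect_equal(discretize(disc, "S", 192), b185 + 1L)
  # round trip: the representative lands in the same bin
  set.seed(31)
  for (v in names(disc$edges)) {
    e <- disc$edges[[v]]
    x <- stats::runif(50, e[1], e[length(e)])
    s <- discretize(disc, v, x)
    expect_equal(discretize(disc, v, undigitize(disc, v, s)), s)
  }
  expect_warning(s_lo <- discretize(disc, "S", 50), "clamped")
  expect_equal(s_lo, 1L)
  expect_error(discretize(disc, "S", Inf), "non-finite")
  expect_error(discretizer(list(S = c(2, 1))), "strictly increasing")
})

test_that("structures validate parents and reject intra-slice cycles", {
  expect_error(dbn_structure(list(A = list(states = 2, parents_intra = "B"))),
               "unknown parent")
  expect_error(dbn_structure(list(
    A = list(states = 2, parents_intra = "B"),
    B = list(states = 2, parents_intra = "A"))), "cycle")
  st <- grape_dbn_structure()
  expect_setequal(st$interface, c("S", "Ac"))
  expect_equal(st$nodes$S$parents_intra, "dS")
})

test_that("parameter learning is Dirichlet-smoothed and retains counts", {
  st <- dbn_structure(list(A = list(states = 2)))
  # no data: exactly the uniform prior
  expect_equal(as.vector(cpt_theta(init_cpts(st), "A")), c(0.5, 0.5))
  # counts (3, 1) with alpha = 1/2: (3.5/5, 1.5/5)
  cp <- learn_parameters(st, data.frame(A = c(1L, 1L, 1L, 2L)))
  expect_equal(as.vector(cpt_theta(cp, "A")), c(0.7, 0.3))
  expect_equal(as.vector(cp$n_exp$A), c(3, 1))
  # the prior washes out asymptotically
  big <- learn_parameters(st, data.frame(A = rep(c(1L, 2L), c(3000, 1000))))
  expect_equal(as.vector(cpt_theta(big, "A")), c(0.75, 0.25), tolerance = 1e-3)
  expect_error(learn_parameters(st, data.frame(A = 3L)), "out of range")
})

test_that("every CPT row sums to one after learning and updating", {
  set.seed(32)
  disc <- discretizer()
  st <- grape_dbn_structure(disc)
  spec <- scenario_spec(n_parcels = 3, vintages = 2007:2008, seed = 5)
  ds <- suppressWarnings(generate_maturation_dataset(spec))
  cp <- learn_parameters(st, suppressWarnings(
    make_transition_records(ds$weekly, disc)))
  simdb <- build_simulated_database(generate_configurations(10, seed = 2),
                                    disc, seed = 3)
  cp2 <- update_parameters(cp, simdb)
  for (v in names(st$nodes)) {
    expect_equal(rowSums(theta_rows(cp, v)), rep(1, nrow(theta_rows(cp, v))),
                 tolerance = 1e-12)
    expect_equal(rowSums(theta_rows(cp2, v)), rep(1, nrow(theta_rows(cp2, v))),
                 tolerance = 1e-12)
  }
})

test_that("relearning from sampled transitions recovers the generating CPTs", {
  set.seed(33)
  st <- dbn_structure(list(
    C = list(states = 2),
    X = list(states = 3, parents_intra = "C", parents_lag = "X")))
  theta_C <- c(0.5, 0.5)
  raw <- matrix(stats::rgamma(6 * 3, 2) + 0.3, nrow = 6)
  theta_X <- array(raw / rowSums(raw), dim = c(3, 2, 3))
  n <- 10000
  xp <- sample.int(3, n, replace = TRUE)
  cc <- sample.int(2, n, replace = TRUE, prob = theta_C)
  x <- vapply(seq_len(n), function(i) {
    sample.int(3, 1, prob = theta_X[xp[i], cc[i], ])
  }, integer(1))
  cp <- learn_parameters(st, data.frame(C = cc, X = x, X.prev = xp))
  expect_lt(max(abs(cpt_theta(cp, "X") - theta_X)), 0.02)
  expect_lt(max(abs(as.vector(cpt_theta(cp, "C")) - theta_C)), 0.02)
})

test_that("the joint probability is the product of local conditionals", {
  st <- dbn_structure(list(A = list(states = 2),
                           B = list(states = 2, parents_intra = "A")))
  cp <- cpt_set_from_theta(st, list(A = c(0.6, 0.4),
                                    B = array(c(0.8, 0.2, 0.2, 0.8), c(2, 2))))
  one <- dbn_structure(list(Z = list(states = 2)))
  cpo <- cpt_set_from_theta(one, list(Z = c(0.7, 0.3)))
  expect_equal(joint_probability(cpo, matrix(1L, 1, 1,
                                             dimnames = list(NULL, "Z"))), 0.7)
  asn <- matrix(c(1L, 2L), 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(joint_probability(cp, asn), 0.6 * 0.2)
  expect_error(joint_probability(cp, matrix(1L, 1, 1,
                                            dimnames = list(NULL, "A"))),
               "named column per node")
  # sums to one over all assignments of a 3-node, 2-slice toy net
  set.seed(34)
  toy <- random_small_dbn(200)
  nm <- names(toy$cpts$structure$nodes)
  r <- vapply(nm, function(v) toy$cpts$structure$nodes[[v]]$states, integer(1))
  grid <- expand.grid(c(lapply(r, seq_len), lapply(r, seq_len)))
  tot <- sum(vapply(seq_len(nrow(grid)), function(i) {
    asn <- matrix(as.integer(grid[i, ]), nrow = 2, byrow = TRUE,
                  dimnames = list(NULL, nm))
    joint_probability(toy$cpts, asn)
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("filtering reproduces hand-computable cases", {
  st <- dbn_structure(list(A = list(states = 2),
                           B = list(states = 2, parents_intra = "A")))
  cp <- cpt_set_from_theta(st, list(A = c(0.6, 0.4),
                                    B = array(c(0.8, 0.2, 0.2, 0.8), c(2, 2))))
  # no evidence, one slice: marginals equal the prior CPT marginals
  bt <- dbn_filter(cp, list(NULL), tau = 1)
  expect_equal(bt$marginals[[1]]$A, c(0.6, 0.4))
  expect_equal(bt$marginals[[1]]$B, c(0.6 * 0.8 + 0.4 * 0.2,
                                      0.6 * 0.2 + 0.4 * 0.8))
  # evidence fully determining the parent pins the child's CPT row
  bt2 <- dbn_filter(cp, list(c(A = 2L)), tau = 1)
  expect_equal(bt2$marginals[[1]]$B, c(0.2, 0.8))
  expect_error(dbn_filter(cp, list(c(Z = 1L)), tau = 1), "unknown node")
  expect_error(dbn_filter(cp, list(c(A = 5L)), tau = 1), "out of range")
})

test_that("filtering equals brute-force enumeration on random networks", {
  set.seed(35)
  for (case in 1:40) {
    net <- random_small_dbn()
    bt <- dbn_filter(net$cpts, net$evidence, net$tau)
    for (t in seq_len(net$tau)) {
      want <- enum_marginals(net$cpts, net$evidence[seq_len(t)], t)
      for (v in names(want)) {
        expect_equal(bt$marginals[[t]][[v]], unname(want[[v]]),
                     tolerance = 1e-9,
                     label = sprintf("case %d, t=%d, node %s", case, t, v))
      }
    }
  }
})

test_that("the transition law is shared by all slices (homogeneity)", {
  set.seed(36)
  st <- dbn_structure(list(X = list(states = 3, parents_lag = "X")))
  raw <- matrix(stats::rgamma(9, 2) + 0.2, nrow = 3)
  theta <- array(raw / rowSums(raw), dim = c(3, 3))
  init <- c(0.2, 0.5, 0.3)
  cp <- cpt_set_from_theta(st, list(X = theta), list(X = init))
  bt <- dbn_filter(cp, vector("list", 5), tau = 5)
  # without evidence the filtered marginal evolves by the SAME matrix at
  # every step, regardless of the absolute week index
  m <- init
  for (t in 2:5) {
    m <- as.vector(m %*% theta)
    expect_equal(bt$marginals[[t]]$X, m, tolerance = 1e-12)
  }
})

test_that("posterior means are midpoint dot products", {
  disc <- discretizer()
  nb <- n_bins(disc)[["S"]]
  degenerate <- rep(0, nb); degenerate[5] <- 1
  expect_equal(posterior_mean(degenerate, disc, "S"),
               undigitize(disc, "S", 5))
  two <- rep(0, nb); two[discretize(disc, "S", 178)] <- 0.5
  two[discretize(disc, "S", 185)] <- 0.5
  expect_equal(posterior_mean(two, disc, "S"), (180 + 188) / 2)
  set.seed(37)
  w <- stats::rgamma(nb, 1); w <- w / sum(w)
  expect_equal(posterior_mean(w, disc, "S"),
               sum(w * bin_midpoints(disc, "S")))
  expect_error(posterior_mean(w * 2, disc, "S"), "normalized")
})

test_that("CPT sets serialize to JSON and back without loss", {
  set.seed(38)
  disc <- discretizer()
  st <- grape_dbn_structure(disc)
  spec <- scenario_spec(n_parcels = 2, vintages = 2007, seed = 9)
  ds <- suppressWarnings(generate_maturation_dataset(spec))
  cp <- learn_parameters(st, suppressWarnings(
    make_transition_records(ds$weekly, disc)),
    suppressWarnings(make_initial_records(ds$weekly, disc)))
  path <- withr::local_tempfile(fileext = ".json")
  write_cpts(cp, path)
  back <- read_cpts(path)
  for (v in names(st$nodes)) {
    expect_equal(cpt_theta(back, v), cpt_theta(cp, v), tolerance = 1e-12)
    expect_equal(back$n_exp[[v]], cp$n_exp[[v]])
  }
  expect_equal(cpt_theta_init(back, "S"), cpt_theta_init(cp, "S"))
})
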
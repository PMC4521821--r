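#' Dynamic Bayesian network structure
#'
#' A first-order homogeneous two-slice template: every node has a state
#' count, intra-slice parents (same week) and lag parents (previous week).
#' The unrolled two-slice graph must be acyclic, which holds iff the
#' intra-slice graph is acyclic.
#'
#' @param nodes Named list; each element a list with fields
#'   `states` (integer `r_i >= 2`), `parents_intra` (character, may be
#'   empty), `parents_lag` (character, may be empty).
#' @return Object of class `dbn_structure` with a topological node order and
#'   the interface set (nodes referenced as lag parents).
#' @export
dbn_structure <- function(nodes) {
  nm <- names(nodes)
  if (is.null(nm) || anyDuplicated(nm)) stop("nodes must be uniquely named",
                                             call. = FALSE)
  for (v in nm) {
    n <- nodes[[v]]
    if (is.null(n$states) || n$states < 2L) {
      stop("node '", v, "' needs at least 2 states", call. = FALSE)
    }
    nodes[[v]]$states <- as.integer(n$states)
    if (is.null(n$parents_intra)) nodes[[v]]$parents_intra <- character(0)
    if (is.null(n$parents_lag)) nodes[[v]]$parents_lag <- character(0)
    bad <- setdiff(c(nodes[[v]]$parents_intra, nodes[[v]]$parents_lag), nm)
    if (length(bad)) stop("node '", v, "' has unknown parent(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  # topological sort of the intra-slice graph
  order <- character(0)
  remaining <- nm
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      all(nodes[[v]]$parents_intra %in% order)
    }, logical(1))]
    if (!length(ready)) stop("intra-slice arcs contain a cycle", call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  interface <- sort(unique(unlist(lapply(nodes, `[[`, "parents_lag"))))
  structure(list(nodes = nodes, order = order, interface = interface),
            class = "dbn_structure")
}

#' @export
print.dbn_structure <- function(x, ...) {
  cat("<dbn_structure> ", length(x$nodes), " nodes; interface: ",
      paste(x$interface, collapse = ", "), "\n", sep = "")
  for (v in x$order) {
    n <- x$nodes[[v]]
    cat("  ", v, " (", n$states, " states)",
        if (length(n$parents_lag)) paste0(" <- lag{",
                                          paste(n$parents_lag, collapse = ","),
                                          "}") else "",
        if (length(n$parents_intra)) paste0(" <- {",
                                            paste(n$parents_intra,
                                                  collapse = ","), "}") else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Default network structure for grape maturation
#'
#' Weekly climate nodes `T`, `RH`, `Ins`, `Pl` are roots; the weekly
#' variations `dS`, `dAc` depend on the four climate nodes of the same week;
#' sugar `S` depends on last week's `S` and this week's `dS`, and likewise
#' acidity `Ac` on last week's `Ac` and `dAc`.
#'
#' @param disc A [discretizer()] providing state counts.
#' @return A [dbn_structure()].
#' @export
grape_dbn_structure <- function(disc = discretizer()) {
  nb <- n_bins(disc)
  climate <- c("T", "RH", "Ins", "Pl")
  nodes <- list()
  for (v in climate) nodes[[v]] <- list(states = nb[[v]])
  nodes$dS <- list(states = nb[["dS"]], parents_intra = climate)
  nodes$dAc <- list(states = nb[["dAc"]], parents_intra = climate)
  nodes$S <- list(states = nb[["S"]], parents_intra = "dS", parents_lag = "S")
  nodes$Ac <- list(states = nb[["Ac"]], parents_intra = "dAc",
                   parents_lag = "Ac")
  dbn_structure(nodes)
}

# lag-parent variable names in the two-slice template (empty-safe paste)
.prev_names <- function(x) if (length(x)) paste0(x, ".prev") else character(0)

# dims of a node's CPT count array: (lag parents, intra parents, self)
.cpt_dims <- function(st, v) {
  n <- st$nodes[[v]]
  pars <- c(n$parents_lag, n$parents_intra)
  c(vapply(pars, function(p) st$nodes[[p]]$states, integer(1)), n$states)
}

#' Initialize an empty conditional-probability-table set
#'
#' Every count is zero and every Dirichlet pseudo-count is `1/r_i`, giving
#' the uniform prior exactly. Experimental and simulated counts are kept in
#' separate ledgers so later enrichment is auditable and reversible.
#'
#' @param st A [dbn_structure()].
#' @return Object of class `cpt_set` with per-node arrays `alpha`, `n_exp`,
#'   `n_sim` (dims: lag parents, intra parents, self) and, for nodes with
#'   lag parents, first-slice marginal ledgers `n_init`/`alpha_init`.
#' @export
init_cpts <- function(st) {
  stopifnot(inherits(st, "dbn_structure"))
  alpha <- n_exp <- n_sim <- list()
  n_init <- alpha_init <- list()
  for (v in names(st$nodes)) {
    d <- .cpt_dims(st, v)
    r <- st$nodes[[v]]$states
    alpha[[v]] <- array(1 / r, dim = d)
    n_exp[[v]] <- array(0, dim = d)
    n_sim[[v]] <- array(0, dim = d)
    if (length(st$nodes[[v]]$parents_lag)) {
      n_init[[v]] <- rep(0, r)
      alpha_init[[v]] <- rep(1 / r, r)
    }
  }
  structure(list(structure = st, alpha = alpha, n_exp = n_exp, n_sim = n_sim,
                 n_init = n_init, alpha_init = alpha_init,
                 theta_fixed = NULL),
            class = "cpt_set")
}

#' Build a CPT set from known probability tables
#'
#' Used for simulation studies and as the starting point of oracle checks:
#' the given tables are taken as-is instead of being derived from counts.
#'
#' @param st A [dbn_structure()].
#' @param theta Named list of probability arrays, dims (lag parents, intra
#'   parents, self), rows normalized over the last dimension.
#' @param theta_init Optional named list of first-slice marginals for nodes
#'   with lag parents (default uniform).
#' @return A `cpt_set`.
#' @export
cpt_set_from_theta <- function(st, theta, theta_init = NULL) {
  cpts <- init_cpts(st)
  for (v in names(st$nodes)) {
    d <- .cpt_dims(st, v)
    if (is.null(theta[[v]])) stop("missing theta for node '", v, "'",
                                  call. = FALSE)
    arr <- array(as.numeric(theta[[v]]), dim = d)
    rows <- matrix(arr, ncol = d[length(d)])
    if (any(abs(rowSums(rows) - 1) > 1e-8) || any(rows < 0)) {
      stop("theta rows for '", v, "' must be a probability table",
           call. = FALSE)
    }
    theta[[v]] <- arr
  }
  cpts$theta_fixed <- theta
  if (!is.null(theta_init)) {
    for (v in names(theta_init)) cpts$theta_init_fixed[[v]] <- theta_init[[v]]
  }
  cpts
}

#' Conditional probability table of a node
#'
#' The expected-a-posteriori estimate under the Dirichlet prior:
#' `theta_ijk = (N_ijk + alpha_ijk) / sum_k (N_ijk + alpha_ijk)`, where the
#' counts are the sum of the experimental and simulated ledgers. With no
#' data this is exactly the uniform prior; as counts grow the prior washes
#' out and `theta` approaches the empirical frequencies.
#'
#' @param cpts A `cpt_set`.
#' @param node Node name.
#' @return Probability array, dims (lag parents, intra parents, self); every
#'   row (last dimension) sums to 1.
#' @export
cpt_theta <- function(cpts, node) {
  if (!is.null(cpts$theta_fixed)) return(cpts$theta_fixed[[node]])
  raw <- cpts$n_exp[[node]] + cpts$n_sim[[node]] + cpts$alpha[[node]]
  d <- dim(raw)
  rows <- matrix(raw, ncol = d[length(d)])
  array(rows / rowSums(rows), dim = d)
}

#' @rdname cpt_theta
#' @return For `cpt_theta_init`, the first-slice marginal of a node with lag
#'   parents.
#' @export
cpt_theta_init <- function(cpts, node) {
  if (!is.null(cpts$theta_init_fixed) &&
      !is.null(cpts$theta_init_fixed[[node]])) {
    return(cpts$theta_init_fixed[[node]])
  }
  raw <- cpts$n_init[[node]] + cpts$alpha_init[[node]]
  raw / sum(raw)
}

# linear row index of parent configuration + self state, vectorized
.count_into <- function(arr, states_matrix) {
  d <- dim(arr)
  strides <- cumprod(c(1L, d[-length(d)]))
  lin <- as.vector((states_matrix - 1L) %*% strides) + 1L
  tab <- tabulate(lin, nbins = length(arr))
  arr + array(tab, dim = d)
}

# columns of `records` corresponding to a node's CPT dims
.record_columns <- function(st, v) {
  n <- st$nodes[[v]]
  c(.prev_names(n$parents_lag), n$parents_intra, v)
}

#' Learn CPT parameters from discretized transition records
#'
#' Counts event occurrences per node and parent configuration into the
#' experimental ledger; probabilities follow from [cpt_theta()] (Dirichlet
#' smoothing with `alpha_ijk = 1/r_i`). An empty record set yields the
#' uniform prior exactly. Counts are retained so parameters can be updated
#' later with simulated records.
#'
#' @param st A [dbn_structure()].
#' @param records Data frame of weekly transitions: one integer state column
#'   per node (its value at week `t`) plus `<name>.prev` columns for lag
#'   parents (their value at week `t - 1`).
#' @param init_records Optional data frame of first-week states (columns =
#'   nodes with lag parents) used to learn the first-slice marginals.
#' @return A `cpt_set`.
#' @export
learn_parameters <- function(st, records, init_records = NULL) {
  cpts <- init_cpts(st)
  if (nrow_or_zero(records) > 0L) {
    for (v in names(st$nodes)) {
      cols <- .record_columns(st, v)
      missing_col <- setdiff(cols, names(records))
      if (length(missing_col)) stop("records lack column(s): ",
                                    paste(missing_col, collapse = ", "),
                                    call. = FALSE)
      m <- as.matrix(records[cols])
      storage.mode(m) <- "integer"
      .check_states(m, .cpt_dims(st, v), v)
      cpts$n_exp[[v]] <- .count_into(cpts$n_exp[[v]], m)
    }
  }
  if (!is.null(init_records) && nrow(init_records) > 0L) {
    for (v in names(cpts$n_init)) {
      if (!v %in% names(init_records)) next
      s <- as.integer(init_records[[v]])
      cpts$n_init[[v]] <- cpts$n_init[[v]] +
        tabulate(s, nbins = st$nodes[[v]]$states)
    }
  }
  cpts
}

nrow_or_zero <- function(x) if (is.null(x)) 0L else nrow(x)

.check_states <- function(m, dims, v) {
  for (j in seq_len(ncol(m))) {
    if (any(m[, j] < 1L | m[, j] > dims[j])) {
      stop("state out of range in records for node '", v, "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Joint probability of a complete assignment
#'
#' Product of the local conditionals over all nodes and slices; the
#' first-slice distribution of a node with lag parents is its marginal
#' prior. Used as the exact-inference oracle on small networks.
#'
#' @param cpts A `cpt_set`.
#' @param assignment Integer matrix, `tau` rows (slices) and one column per
#'   node (named), giving the state of every variable.
#' @return The joint probability (scalar).
#' @export
joint_probability <- function(cpts, assignment) {
  st <- cpts$structure
  nm <- names(st$nodes)
  if (is.null(colnames(assignment)) || !all(nm %in% colnames(assignment))) {
    stop("assignment must have one named column per node", call. = FALSE)
  }
  if (anyNA(assignment[, nm])) stop("assignment must be complete",
                                    call. = FALSE)
  tau <- nrow(assignment)
  p <- 1
  for (t in seq_len(tau)) {
    for (v in nm) {
      n <- st$nodes[[v]]
      if (t == 1L && length(n$parents_lag)) {
        p <- p * cpt_theta_init(cpts, v)[assignment[1, v]]
      } else {
        th <- cpt_theta(cpts, v)
        idx <- c(if (t > 1L) assignment[t - 1L, n$parents_lag],
                 assignment[t, n$parents_intra], assignment[t, v])
        p <- p * th[matrix(as.integer(idx), nrow = 1)]
      }
    }
  }
  p
}

# factor for node v at slice t (slice1 switches lag-parent nodes to priors)
.cpt_factor <- function(cpts, v, slice1) {
  st <- cpts$structure
  n <- st$nodes[[v]]
  if (slice1 && length(n$parents_lag)) {
    return(new_factor(v, st$nodes[[v]]$states, cpt_theta_init(cpts, v)))
  }
  pars_lag <- .prev_names(n$parents_lag)
  vars <- c(pars_lag, n$parents_intra, v)
  card <- c(vapply(n$parents_lag, function(p) st$nodes[[p]]$states, integer(1)),
            vapply(n$parents_intra, function(p) st$nodes[[p]]$states,
                   integer(1)),
            n$states)
  new_factor(vars, card, as.numeric(cpt_theta(cpts, v)))
}

#' Forward filtering over the unrolled network
#'
#' Exact recursive computation of `P(X(t) | O(1..t))` week by week: the
#' belief over the interface nodes is propagated through the two-slice
#' template by variable elimination, conditioning on each week's evidence as
#' it arrives (prediction mode: no look-ahead).
#'
#' @param cpts A `cpt_set`.
#' @param evidence List of length `tau`; element `t` a named integer vector
#'   of observed states at week `t` (may be `NULL`/empty). Names must be
#'   node names.
#' @param tau Number of weeks (`>= 1`).
#' @param query Nodes whose weekly marginals are returned (default: all).
#' @return Object of class `belief_trajectory`: list with `marginals`
#'   (per week, named list of probability vectors) and `evidence`.
#' @export
dbn_filter <- function(cpts, evidence = vector("list", tau), tau,
                       query = NULL) {
  st <- cpts$structure
  nm <- names(st$nodes)
  if (is.null(query)) query <- nm
  if (length(evidence) < tau) evidence <- c(evidence, vector(
    "list", tau - length(evidence)))
  for (t in seq_len(tau)) {
    ev <- evidence[[t]]
    if (length(ev)) {
      bad <- setdiff(names(ev), nm)
      if (length(bad)) stop("evidence names unknown node(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      for (v in names(ev)) {
        if (ev[[v]] < 1L || ev[[v]] > st$nodes[[v]]$states) {
          stop("evidence state out of range for node '", v, "'",
               call. = FALSE)
        }
      }
    }
  }
  marginals <- vector("list", tau)
  belief <- NULL        # factor over unobserved interface nodes at t-1
  prev_obs <- integer(0) # observed interface states at t-1
  for (t in seq_len(tau)) {
    ev <- evidence[[t]]
    if (is.null(ev)) ev <- integer(0)
    factors <- list()
    for (v in nm) {
      f <- .cpt_factor(cpts, v, slice1 = (t == 1L))
      if (t > 1L) {
        for (p in intersect(st$nodes[[v]]$parents_lag, names(prev_obs))) {
          f <- factor_reduce(f, paste0(p, ".prev"), prev_obs[[p]])
        }
      }
      for (w in intersect(f$vars, names(ev))) {
        f <- factor_reduce(f, w, ev[[w]])
      }
      factors[[length(factors) + 1L]] <- f
    }
    if (t > 1L && !is.null(belief) && length(belief$vars)) {
      b <- belief
      b$vars <- paste0(b$vars, ".prev")
      names(b$card) <- b$vars
      factors[[length(factors) + 1L]] <- b
    }
    prev_vars <- unique(unlist(lapply(factors, function(f) {
      grep("\\.prev$", f$vars, value = TRUE)
    })))
    for (pv in prev_vars) factors <- factor_eliminate(factors, pv)
    joint <- Reduce(factor_product, factors)
    z <- sum(joint$val)
    if (!is.finite(z) || z <= 0) stop("evidence has zero probability",
                                      call. = FALSE)
    joint$val <- joint$val / z
    marg <- list()
    for (q in query) {
      if (q %in% names(ev)) {
        m <- rep(0, st$nodes[[q]]$states)
        m[ev[[q]]] <- 1
      } else {
        m <- factor_marginal(joint, q)$val
      }
      marg[[q]] <- m
    }
    marginals[[t]] <- marg
    unobs_int <- setdiff(st$interface, names(ev))
    belief <- if (length(unobs_int)) factor_marginal(joint, unobs_int)
              else NULL
    prev_obs <- ev[intersect(names(ev), st$interface)]
  }
  structure(list(marginals = marginals, evidence = evidence, query = query,
                 tau = tau),
            class = "belief_trajectory")
}

#' Posterior mean in physical units
#'
#' Dot product of a belief's marginal with the bin representatives of the
#' discretizer (the mean-value post-processing of the filtered
#' distribution).
#'
#' @param belief A probability vector or a `belief_trajectory`.
#' @param disc A [discretizer()].
#' @param variable Variable name (for a vector) or variables to extract
#'   (for a trajectory; default the trajectory's query nodes that have
#'   discretizations).
#' @param ... Unused.
#' @return A scalar (vector input) or a data frame `week` x variables.
#' @export
posterior_mean <- function(belief, disc, variable = NULL, ...) {
  UseMethod("posterior_mean")
}

#' @export
posterior_mean.numeric <- function(belief, disc, variable = NULL, ...) {
  if (is.null(variable)) stop("'variable' is required for a bare marginal",
                              call. = FALSE)
  if (abs(sum(belief) - 1) > 1e-6) stop("marginal must be normalized",
                                        call. = FALSE)
  sum(bin_midpoints(disc, variable) * belief)
}

#' @export
posterior_mean.belief_trajectory <- function(belief, disc, variable = NULL,
                                             ...) {
  vars <- variable
  if (is.null(vars)) vars <- intersect(belief$query, names(disc$edges))
  out <- data.frame(week = seq_len(belief$tau))
  for (v in vars) {
    out[[v]] <- vapply(belief$marginals, function(m) {
      posterior_mean(m[[v]], disc, v)
    }, numeric(1))
  }
  out
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat("<belief_trajectory> ", x$tau, " weeks; query: ",
      paste(x$query, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of prior-only CPT rows
#'
#' Counts the parent configurations whose probability row is still exactly
#' the uniform prior, i.e. that received no experimental or simulated
#' counts. These are the "never encountered" climate/state cells the
#' fuzzy-model enrichment is meant to fill.
#'
#' @param cpts A `cpt_set`.
#' @param nodes Nodes to inspect (default: all with at least one parent).
#' @return Named integer vector of untouched row counts per node.
#' @export
prior_only_rows <- function(cpts, nodes = NULL) {
  st <- cpts$structure
  if (is.null(nodes)) {
    nodes <- names(st$nodes)[vapply(names(st$nodes), function(v) {
      n <- st$nodes[[v]]
      length(n$parents_intra) + length(n$parents_lag) > 0
    }, logical(1))]
  }
  vapply(nodes, function(v) {
    d <- .cpt_dims(st, v)
    counts <- matrix(cpts$n_exp[[v]] + cpts$n_sim[[v]], ncol = d[length(d)])
    sum(rowSums(counts) == 0)
  }, integer(1))
}

#' Serialize / load a CPT set
#'
#' JSON layout retaining the structure, the Dirichlet pseudo-counts and both
#' count ledgers (experimental and simulated), so a reloaded set reproduces
#' identical probabilities and can keep being updated.
#'
#' @param cpts A `cpt_set`.
#' @param path File path.
#' @return `read_cpts` returns the `cpt_set`.
#' @export
write_cpts <- function(cpts, path) {
  st <- cpts$structure
  payload <- list(
    nodes = lapply(st$nodes, function(n) {
      list(states = n$states, parents_intra = I(n$parents_intra),
           parents_lag = I(n$parents_lag))
    }),
    alpha = lapply(cpts$alpha, as.vector),
    n_exp = lapply(cpts$n_exp, as.vector),
    n_sim = lapply(cpts$n_sim, as.vector),
    n_init = lapply(cpts$n_init, as.vector),
    alpha_init = lapply(cpts$alpha_init, as.vector)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cpts
#' @export
read_cpts <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- lapply(payload$nodes, function(n) {
    list(states = as.integer(n$states),
         parents_intra = as.character(n$parents_intra),
         parents_lag = as.character(n$parents_lag))
  })
  st <- dbn_structure(nodes)
  cpts <- init_cpts(st)
  for (v in names(st$nodes)) {
    d <- .cpt_dims(st, v)
    cpts$alpha[[v]] <- array(payload$alpha[[v]], dim = d)
    cpts$n_exp[[v]] <- array(payload$n_exp[[v]], dim = d)
    cpts$n_sim[[v]] <- array(payload$n_sim[[v]], dim = d)
  }
  for (v in names(cpts$n_init)) {
    if (!is.null(payload$n_init[[v]])) {
      cpts$n_init[[v]] <- as.numeric(payload$n_init[[v]])
    }
    if (!is.null(payload$alpha_init[[v]])) {
      cpts$alpha_init[[v]] <- as.numeric(payload$alpha_init[[v]])
    }
  }
  cpts
}
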
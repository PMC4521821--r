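# Independent oracles and fixture builders used across the suite.

# Brute-force fuzzy aggregation: recompute the normalized weighted vote
# directly from the rule list, without the package's aggregation code path.
brute_force_aggregate <- function(rules, activations, classes) {
  outputs <- names(rules[[1]]$conclusion)
  out <- list()
  for (o in outputs) {
    num <- stats::setNames(rep(0, length(classes)), classes)
    for (j in seq_along(rules)) {
      cl <- rules[[j]]$conclusion[[o]]
      num[cl] <- num[cl] + activations[j]
    }
    out[[o]] <- num / sum(activations)
  }
  out
}

# Exact posterior marginals at slice t by full enumeration of all
# assignments over slices 1..t (conditioning on evidence up to t only).
# Reimplements the model semantics directly from the theta arrays; shares
# no code with the filter.
enum_marginals <- function(cpts, evidence, t) {
  st <- cpts$structure
  nm <- names(st$nodes)
  cols <- as.vector(t(outer(1:t, nm, function(s, v) paste0(v, "@", s))))
  cards <- unlist(lapply(1:t, function(s) {
    vapply(nm, function(v) st$nodes[[v]]$states, integer(1))
  }))
  grid <- expand.grid(lapply(cards, seq_len), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- cols
  p <- rep(1, nrow(grid))
  for (s in 1:t) {
    for (v in nm) {
      n <- st$nodes[[v]]
      if (s == 1L && length(n$parents_lag)) {
        p <- p * cpt_theta_init(cpts, v)[grid[[paste0(v, "@1")]]]
      } else {
        th <- cpt_theta(cpts, v)
        at <- function(x, s) if (length(x)) paste0(x, "@", s) else character(0)
        idx_cols <- c(if (s > 1L) at(n$parents_lag, s - 1L),
                      at(n$parents_intra, s), paste0(v, "@", s))
        p <- p * th[as.matrix(grid[idx_cols])]
      }
    }
  }
  for (s in 1:t) {
    ev <- evidence[[s]]
    if (is.null(ev)) next
    for (w in names(ev)) p <- p * (grid[[paste0(w, "@", s)]] == ev[[w]])
  }
  z <- sum(p)
  stopifnot(z > 0)
  marg <- list()
  for (v in nm) {
    col <- grid[[paste0(v, "@", t)]]
    marg[[v]] <- vapply(seq_len(st$nodes[[v]]$states),
                        function(k) sum(p[col == k]), numeric(1)) / z
  }
  marg
}

# Random small two-slice network with positive random CPTs and random
# evidence; assignment space capped so enumeration stays cheap.
random_small_dbn <- function(max_assignments = 30000) {
  repeat {
    n <- sample(2:5, 1)
    r <- sample(2:3, n, replace = TRUE)
    tau <- sample(2:3, 1)
    if (prod(r)^tau <= max_assignments) break
  }
  nm <- paste0("N", seq_len(n))
  nodes <- list()
  for (i in seq_len(n)) {
    intra <- if (i > 1) nm[seq_len(i - 1)][stats::runif(i - 1) < 0.5] else character(0)
    if (length(intra) > 2) intra <- intra[1:2]
    lag <- nm[stats::runif(n) < 0.4]
    if (length(lag) > 2) lag <- lag[1:2]
    nodes[[nm[i]]] <- list(states = r[i], parents_intra = intra,
                           parents_lag = lag)
  }
  st <- dbn_structure(nodes)
  theta <- list()
  theta_init <- list()
  for (v in nm) {
    d <- prod(c(vapply(c(st$nodes[[v]]$parents_lag,
                         st$nodes[[v]]$parents_intra),
                       function(p) st$nodes[[p]]$states, integer(1)), 1)) # rows
    rr <- st$nodes[[v]]$states
    raw <- matrix(stats::rgamma(d * rr, shape = 1) + 0.05, nrow = d)
    theta[[v]] <- array(raw / rowSums(raw),
                        dim = c(if (d > 1) .row_dims(st, v), rr))
    if (length(st$nodes[[v]]$parents_lag)) {
      ini <- stats::rgamma(rr, shape = 1) + 0.05
      theta_init[[v]] <- ini / sum(ini)
    }
  }
  ev <- lapply(seq_len(tau), function(s) {
    obs <- nm[stats::runif(n) < 0.4]
    if (!length(obs)) return(NULL)
    stats::setNames(vapply(obs, function(v) {
      sample.int(st$nodes[[v]]$states, 1)
    }, integer(1)), obs)
  })
  list(cpts = cpt_set_from_theta(st, theta, theta_init),
       evidence = ev, tau = tau)
}

.row_dims <- function(st, v) {
  pars <- c(st$nodes[[v]]$parents_lag, st$nodes[[v]]$parents_intra)
  vapply(pars, function(p) st$nodes[[p]]$states, integer(1))
}

# matrix version of theta: rows = parent configurations
theta_rows <- function(cpts, v) {
  th <- cpt_theta(cpts, v)
  d <- dim(th)
  matrix(th, ncol = d[length(d)])
}

# small deterministic GP transition table driven by a smooth response
make_gp_fixture <- function(n = 25, noise = 0, seed = 51) {
  set.seed(seed)
  x <- data.frame(Ac = stats::runif(n, 3, 8), S = stats::runif(n, 110, 230),
                  T = stats::runif(n, 60, 175), Ins = stats::runif(n, 0, 80),
                  RH = stats::runif(n, 50, 100), Pl = stats::runif(n, 0, 100))
  x$m_Ac <- x$Ac + stats::runif(n, -0.3, 0.3)
  x$m_S <- x$S + stats::runif(n, -8, 8)
  x$Ac_next <- x$Ac - 0.5 + 0.3 * sin(x$T / 30) + stats::rnorm(n, 0, noise)
  x$S_next <- x$S + 15 + 5 * cos(x$Pl / 20) + stats::rnorm(n, 0, noise)
  x
}

# seven identical "standard days" (index 2 crisp: +3 sugar, -0.2 acidity)
standard_week <- function() {
  data.frame(Tmeanday = rep(14, 7), Tmaxday = rep(20, 7),
             Insday = rep(6.5, 7), RHday = rep(60, 7), Plday = rep(2, 7))
}
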
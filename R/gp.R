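# Gaussian-process dynamic regression baseline: one squared-exponential
# kernel shared by the two outputs (next week's acidity and sugar), each
# with its own linear mean function, hyperparameters fitted by maximizing
# the summed log marginal likelihood with seeded multi-start optimization.

#' Squared-exponential kernel
#'
#' `k(xi, xj) = theta1 * exp(-theta2 * ||xi - xj||^2)`. `theta1` is the
#' prior variance (value at zero distance); `theta2` the inverse squared
#' length scale of the isotropic decay.
#'
#' @param xi,xj Numeric vectors (or matrices with points in rows).
#' @param theta1,theta2 Positive kernel parameters.
#' @return Covariance value(s); a matrix if `xi`/`xj` are matrices.
#' @export
gp_kernel <- function(xi, xj, theta1, theta2) {
  if (theta1 <= 0 || theta2 <= 0) stop("kernel parameters must be positive",
                                       call. = FALSE)
  if (is.matrix(xi) || is.matrix(xj)) {
    xi <- as.matrix(xi); xj <- as.matrix(xj)
    d2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * tcrossprod(xi, xj)
    d2[d2 < 0] <- 0
    theta1 * exp(-theta2 * d2)
  } else {
    theta1 * exp(-theta2 * sum((xi - xj)^2))
  }
}

# moving average of the previous `window` values of y within one kinetics
.moving_avg <- function(y, window) {
  n <- length(y)
  vapply(seq_len(n), function(t) {
    lo <- max(1L, t - window)
    if (t == 1L) y[1] else mean(y[lo:(t - 1L)])
  }, numeric(1))
}

#' Assemble GP training transitions from weekly measurements
#'
#' One row per weekly transition: the six-dimensional state at week `t`
#' (`Ac`, `S`, `T`, `Ins`, `RH`, `Pl`), per-output moving averages `m_Ac`,
#' `m_S` of the previous weeks, and the targets at week `t + 1`.
#'
#' @param weekly Weekly table with `parcel`, `vintage`, `week`, `T`, `RH`,
#'   `Ins`, `Pl`, `S`, `Ac`.
#' @param window Moving-average window (weeks), default 2.
#' @return Data frame with inputs, `m_Ac`, `m_S`, and targets `Ac_next`,
#'   `S_next`.
#' @export
gp_transitions <- function(weekly, window = 2) {
  unit <- interaction(weekly$parcel, weekly$vintage, drop = TRUE)
  pieces <- lapply(split(weekly, unit), function(g) {
    g <- g[order(g$week), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    i <- seq_len(nrow(g) - 1L)
    data.frame(
      Ac = g$Ac[i], S = g$S[i], T = g$T[i], Ins = g$Ins[i],
      RH = g$RH[i], Pl = g$Pl[i],
      m_Ac = .moving_avg(g$Ac, window)[i],
      m_S = .moving_avg(g$S, window)[i],
      Ac_next = g$Ac[i + 1L], S_next = g$S[i + 1L]
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

.gp_inputs <- c("Ac", "S", "T", "Ins", "RH", "Pl")

.gp_design <- function(transitions, output) {
  mcol <- if (output == "Ac_next") "m_Ac" else "m_S"
  cbind(1, as.matrix(transitions[c(mcol, .gp_inputs)]))
}

# negative log marginal likelihood with beta profiled out by GLS, for both
# outputs sharing the kernel; returns also the profiled quantities
.gp_nll <- function(log_theta, Xs, H1, H2, y1, y2, jitter) {
  theta1 <- exp(log_theta[1]); theta2 <- exp(log_theta[2])
  n <- nrow(Xs)
  K <- gp_kernel(Xs, Xs, theta1, theta2) + diag(jitter, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10))
  logdet <- 2 * sum(log(diag(ch)))
  nll_one <- function(H, y) {
    Ki_H <- backsolve(ch, forwardsolve(t(ch), H))
    Ki_y <- backsolve(ch, forwardsolve(t(ch), y))
    A <- crossprod(H, Ki_H)
    # small ridge keeps the profiled solve defined when mean-function
    # columns are collinear (e.g. moving averages equal to a state column)
    ridge <- 1e-8 * mean(diag(A)) * diag(nrow(A))
    beta <- tryCatch(solve(A + ridge, crossprod(H, Ki_y)),
                     error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    r <- y - H %*% beta
    Ki_r <- backsolve(ch, forwardsolve(t(ch), r))
    list(nll = 0.5 * (logdet + sum(r * Ki_r) + n * log(2 * pi)),
         beta = beta)
  }
  a1 <- nll_one(H1, y1); a2 <- nll_one(H2, y2)
  if (is.null(a1) || is.null(a2)) return(list(value = 1e10))
  list(value = a1$nll + a2$nll, beta1 = a1$beta, beta2 = a2$beta)
}

#' Fit the GP baseline
#'
#' Maximizes the log marginal likelihood of the two outputs (next-week
#' acidity and sugar) jointly over the shared kernel parameters, with the
#' linear mean coefficients profiled out by generalized least squares.
#' Inputs are standardized before entering the isotropic kernel so no
#' variable dominates the distance. The objective is non-convex, so the
#' optimizer is restarted from several seeded starting points; a jitter
#' ladder keeps the kernel matrix factorizable in degenerate cases (e.g.
#' duplicated training points).
#'
#' @param transitions Output of [gp_transitions()] (at least 3 rows).
#' @param restarts Number of seeded optimizer restarts (default 10).
#' @param seed Integer seed for the restarts.
#' @param jitter Initial diagonal jitter; escalated by 100x up to `1e-6`
#'   if factorization fails.
#' @param window Moving-average window recorded for prediction.
#' @return Object of class `gp_model` with kernel parameters `theta1`,
#'   `theta2`, mean coefficients `beta` per output, the standardization and
#'   the training data.
#' @export
gp_fit <- function(transitions, restarts = 10, seed = 1, jitter = 1e-10,
                   window = 2) {
  if (nrow_or_zero(transitions) < 3L) stop("need at least 3 transitions",
                                           call. = FALSE)
  X <- as.matrix(transitions[.gp_inputs])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  H1 <- .gp_design(transitions, "Ac_next")
  H2 <- .gp_design(transitions, "S_next")
  y1 <- transitions$Ac_next
  y2 <- transitions$S_next
  restore <- .local_seed(seed)
  on.exit(if (is.function(restore)) restore())
  starts <- rbind(c(log(stats::var(y2) + 1), log(1 / ncol(Xs))),
                  cbind(stats::runif(restarts - 1, -2, 8),
                        stats::runif(restarts - 1, -6, 2)))
  best <- NULL
  for (j in seq_len(restarts)) {
    jit <- jitter
    repeat {
      fit <- tryCatch(
        stats::optim(starts[j, ], function(p) {
          .gp_nll(p, Xs, H1, H2, y1, y2, jit)$value
        }, method = "L-BFGS-B", lower = c(-10, -12), upper = c(15, 6)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9) break
      jit <- jit * 100
      if (jit > 1e-6) {
        if (is.null(fit)) stop("kernel matrix singular beyond jitter ladder",
                               call. = FALSE)
        break
      }
    }
    if (is.null(best) || (!is.null(fit) && fit$value < best$value)) {
      best <- fit; best$jitter <- jit
    }
  }
  final <- .gp_nll(best$par, Xs, H1, H2, y1, y2, best$jitter)
  structure(list(
    theta1 = exp(best$par[1]), theta2 = exp(best$par[2]),
    beta = list(Ac = drop(final$beta1), S = drop(final$beta2)),
    center = ctr, scale = scl, Xs = Xs, H1 = H1, H2 = H2,
    y1 = y1, y2 = y2, jitter = best$jitter,
    log_marginal_likelihood = -best$value, window = window
  ), class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat("<gp_model> theta1 =", signif(x$theta1, 4),
      " theta2 =", signif(x$theta2, 4),
      " logML =", signif(x$log_marginal_likelihood, 6), "\n")
  invisible(x)
}

#' Predictive distribution at a new state
#'
#' Posterior mean and variance of the two outputs at a new six-dimensional
#' state: `mu(x*) = h(x*)'beta + k*' K^{-1} (y - H beta)` and
#' `sigma^2(x*) = k(x*,x*) - k*' K^{-1} k*` (clipped at zero), per output.
#' The posterior variance never exceeds the prior variance `theta1`.
#'
#' @param model A fitted [gp_fit()] model.
#' @param newdata Data frame with columns `Ac`, `S`, `T`, `Ins`, `RH`, `Pl`,
#'   `m_Ac`, `m_S` (one row per query point).
#' @return Data frame with `Ac_mean`, `Ac_var`, `S_mean`, `S_var`.
#' @export
gp_predict <- function(model, newdata) {
  Xq <- as.matrix(newdata[.gp_inputs])
  Xqs <- scale(Xq, center = model$center, scale = model$scale)
  Kq <- gp_kernel(Xqs, model$Xs, model$theta1, model$theta2)
  n <- nrow(model$Xs)
  K <- gp_kernel(model$Xs, model$Xs, model$theta1, model$theta2) +
    diag(model$jitter, n)
  ch <- chol(K)
  solve_K <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  out <- data.frame(row.names = seq_len(nrow(Xq)))
  for (o in c("Ac", "S")) {
    H <- if (o == "Ac") model$H1 else model$H2
    y <- if (o == "Ac") model$y1 else model$y2
    beta <- model$beta[[o]]
    hq <- cbind(1, as.matrix(newdata[c(paste0("m_", o), .gp_inputs)]))
    resid <- y - H %*% beta
    mu <- drop(hq %*% beta + Kq %*% solve_K(resid))
    v <- model$theta1 - rowSums(Kq * t(solve_K(t(Kq))))
    out[[paste0(o, "_mean")]] <- mu
    out[[paste0(o, "_var")]] <- pmax(v, 0)
  }
  out
}

#' Dynamic trajectory prediction with the GP baseline
#'
#' Iterates one-step predictions from the measured week-1 state, feeding
#' each predicted sugar/acidity back as the next input (the observed weekly
#' climate is used throughout), mirroring the week-by-week protocol of the
#' network model.
#'
#' @param model A [gp_fit()] model.
#' @param initial Named list with measured `S` and `Ac` at week 1.
#' @param weekly Weekly climate data frame (`week`, `T`, `RH`, `Ins`, `Pl`).
#' @return Data frame `week`, `S`, `Ac` of predicted trajectories (week 1 =
#'   the measurements).
#' @export
gp_predict_trajectory <- function(model, initial, weekly) {
  g <- weekly[order(weekly$week), , drop = FALSE]
  n <- nrow(g)
  S <- numeric(n); Ac <- numeric(n)
  S[1] <- initial$S; Ac[1] <- initial$Ac
  if (n > 1) {
    for (t in seq_len(n - 1L)) {
      hist_lo <- max(1L, t - model$window)
      m_S <- if (t == 1L) S[1] else mean(S[hist_lo:(t - 1L)])
      m_Ac <- if (t == 1L) Ac[1] else mean(Ac[hist_lo:(t - 1L)])
      q <- data.frame(Ac = Ac[t], S = S[t], T = g$T[t], Ins = g$Ins[t],
                      RH = g$RH[t], Pl = g$Pl[t], m_Ac = m_Ac, m_S = m_S)
      p <- gp_predict(model, q)
      S[t + 1L] <- p$S_mean; Ac[t + 1L] <- p$Ac_mean
    }
  }
  data.frame(week = g$week, S = S, Ac = Ac)
}
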
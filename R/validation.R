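#' Root mean square error
#'
#' @param predicted,observed Numeric vectors of equal, positive length.
#' @return `sqrt(mean((predicted - observed)^2))`, in the data's units.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted)) {
    stop("'predicted' and 'observed' must have equal positive length",
         call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` with the total sum of squares about the observed mean.
#' Undefined (returned as `NA` with a warning) when the observations have
#' zero variance.
#'
#' @inheritParams rmse
#' @return Dimensionless value `<= 1`.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted)) {
    stop("'predicted' and 'observed' must have equal positive length",
         call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("observed values have zero variance; R^2 undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - sum((predicted - observed)^2) / sst
}

#' Oenological prediction-error thresholds
#'
#' The acceptable sugar error corresponds to half an alcoholic degree
#' (17 g/L of sugar per degree), i.e. 8.5 g/L; the acceptable error on the
#' other outputs is 7.5% of the maximum scale deviation, i.e.
#' `0.075 * (8.4 - 2.9) = 0.4125` g/L for total acidity (reported to 2
#' decimals, compared unrounded).
#'
#' @param bounds Physical bounds (default [maturation_bounds()]).
#' @return Named numeric vector `c(sugar = 8.5, acidity = 0.4125)`.
#' @export
error_thresholds <- function(bounds = maturation_bounds()) {
  c(sugar = 0.5 * 17,
    acidity = 0.075 * (bounds["Ac", "upper"] - bounds["Ac", "lower"]))
}

# deterministic fold assignment of parcel-vintage units, stratified by
# vintage where possible
.assign_folds <- function(units, folds, seed) {
  restore <- .local_seed(seed)
  on.exit(if (is.function(restore)) restore())
  fold <- integer(nrow(units))
  offset <- 0L
  for (v in split(seq_len(nrow(units)), units$vintage)) {
    v <- v[sample.int(length(v))]
    fold[v] <- ((seq_along(v) + offset - 1L) %% folds) + 1L
    offset <- offset + length(v)
  }
  fold
}

#' K-fold cross-validation of a maturation model
#'
#' Partitions the parcel-vintage kinetics (never individual weekly points,
#' which are serially dependent) into folds, stratified by vintage; each
#' fold is held out once while the remaining kinetics train the model, and
#' every held-out kinetics is predicted week by week from its first-week
#' measurement and its weekly climate. Metrics are pooled over all held-out
#' predictions.
#'
#' Models:
#' \describe{
#'   \item{`"dbn"`}{network with parameters learnt from the training
#'     transitions only.}
#'   \item{`"fgrapedbn"`}{same, then enriched with `n_scenarios` simulated
#'     fuzzy-model configurations.}
#'   \item{`"fgrape"`}{the expert model alone (no learning; folds kept for
#'     comparability), driven by the daily weather.}
#'   \item{`"gp"`}{the Gaussian-process baseline fitted on the training
#'     transitions.}
#' }
#'
#' @param dataset List with `weekly` (and `daily` for `"fgrape"`), as
#'   returned by [generate_maturation_dataset()].
#' @param model One of `"dbn"`, `"fgrapedbn"`, `"fgrape"`, `"gp"`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the partition (and scenario generation).
#' @param disc Shared [discretizer()].
#' @param n_scenarios Simulated configurations for `"fgrapedbn"`.
#' @param gp_restarts Optimizer restarts for `"gp"`.
#' @return Object of class `validation_report`: pooled `rmse` and `r2` per
#'   output, per-fold breakdown, exceedance counts against
#'   [error_thresholds()], and the pooled prediction table.
#' @export
kfold_cv <- function(dataset, model = c("dbn", "fgrapedbn", "fgrape", "gp"),
                     folds = 10, seed = 1, disc = discretizer(),
                     n_scenarios = 100, gp_restarts = 5) {
  model <- match.arg(model)
  weekly <- dataset$weekly
  units <- unique(weekly[c("parcel", "vintage")])
  if (nrow(units) < folds) stop("fewer parcel-vintage units (", nrow(units),
                                ") than folds (", folds, ")", call. = FALSE)
  units$fold <- .assign_folds(units, folds, seed)
  weekly <- merge(weekly, units, by = c("parcel", "vintage"))
  weekly <- weekly[order(weekly$vintage, weekly$parcel, weekly$week), ]
  pooled <- list()
  for (f in seq_len(folds)) {
    train <- weekly[weekly$fold != f, ]
    test <- weekly[weekly$fold == f, ]
    if (!nrow(test)) next
    fitted <- switch(model,
      dbn = ,
      fgrapedbn = {
        cpts <- learn_parameters(grape_dbn_structure(disc),
                                 suppressWarnings(
                                   make_transition_records(train, disc)),
                                 suppressWarnings(
                                   make_initial_records(train, disc)))
        if (model == "fgrapedbn") {
          sc <- generate_configurations(n_scenarios, seed = seed + f)
          simdb <- build_simulated_database(sc, disc, seed = seed + f)
          cpts <- update_parameters(cpts, simdb)
        }
        cpts
      },
      gp = gp_fit(gp_transitions(train), restarts = gp_restarts,
                  seed = seed + f),
      fgrape = NULL
    )
    key <- interaction(test$parcel, test$vintage, drop = TRUE)
    for (g in split(test, key)) {
      g <- g[order(g$week), ]
      init <- list(S = g$S[1], Ac = g$Ac[1])
      pred <- switch(model,
        dbn = ,
        fgrapedbn = suppressWarnings(
          fgrapedbn_predict(init, g, fitted, disc)$means),
        gp = gp_predict_trajectory(fitted, init, g),
        fgrape = {
          du <- dataset$daily[dataset$daily$parcel == g$parcel[1] &
                                dataset$daily$vintage == g$vintage[1], ]
          kv <- unname(season_coefficients(g$vintage[1]))
          traj <- suppressWarnings(
            simulate_kinetics(init, split(du, du$week), k = kv))
          traj$week <- sort(unique(c(g$week[1], du$week)))
          traj
        }
      )
      m <- merge(g[c("week", "S", "Ac")], pred, by = "week",
                 suffixes = c("_obs", "_pred"))
      m$parcel <- g$parcel[1]; m$vintage <- g$vintage[1]; m$fold <- f
      pooled[[length(pooled) + 1L]] <- m
    }
  }
  pooled <- do.call(rbind, pooled)
  thr <- error_thresholds()
  per_fold <- do.call(rbind, lapply(split(pooled, pooled$fold), function(p) {
    data.frame(fold = p$fold[1], n = nrow(p),
               rmse_sugar = rmse(p$S_pred, p$S_obs),
               rmse_acidity = rmse(p$Ac_pred, p$Ac_obs))
  }))
  rownames(per_fold) <- NULL
  structure(list(
    model = model, folds = folds, n = nrow(pooled),
    rmse = c(sugar = rmse(pooled$S_pred, pooled$S_obs),
             acidity = rmse(pooled$Ac_pred, pooled$Ac_obs)),
    r2 = c(sugar = r_squared(pooled$S_pred, pooled$S_obs),
           acidity = r_squared(pooled$Ac_pred, pooled$Ac_obs)),
    per_fold = per_fold,
    exceedance = c(
      sugar = mean(abs(pooled$S_pred - pooled$S_obs) > thr[["sugar"]]),
      acidity = mean(abs(pooled$Ac_pred - pooled$Ac_obs) > thr[["acidity"]])),
    thresholds = thr,
    predictions = pooled
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> model =", x$model, " (", x$folds, "folds,",
      x$n, "pooled predictions )\n")
  cat(sprintf("  sugar:   RMSE %.2f g/L  R2 %.3f  |err|>%.2f: %.1f%%\n",
              x$rmse[["sugar"]], x$r2[["sugar"]], x$thresholds[["sugar"]],
              100 * x$exceedance[["sugar"]]))
  cat(sprintf("  acidity: RMSE %.3f g/L  R2 %.3f  |err|>%.2f: %.1f%%\n",
              x$rmse[["acidity"]], x$r2[["acidity"]],
              round(x$thresholds[["acidity"]], 2),
              100 * x$exceedance[["acidity"]]))
  invisible(x)
}

#' Compare a validation report to the acceptance thresholds
#'
#' @param report A [kfold_cv()] report.
#' @param thresholds Error thresholds (default [error_thresholds()];
#'   compared unrounded).
#' @return Named logical vector: pooled RMSE within threshold per output.
#' @export
check_thresholds <- function(report, thresholds = error_thresholds()) {
  c(sugar = unname(report$rmse["sugar"] <= thresholds[["sugar"]]),
    acidity = unname(report$rmse["acidity"] <= thresholds[["acidity"]]))
}
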
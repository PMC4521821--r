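#' Build discretized transition records from weekly measurements
#'
#' Turns a weekly measurement table into the one-row-per-transition format
#' consumed by [learn_parameters()]: for each consecutive pair of weeks
#' within a parcel-vintage kinetics, the climate states of the later week,
#' the sugar/acidity states at both weeks and the discretized weekly
#' variations (`dS`, `dAc`), computed from the consecutive measurements.
#'
#' @param weekly Data frame with columns `parcel`, `vintage`, `week`, the
#'   weekly climate `T`, `RH`, `Ins`, `Pl`, and measurements `S`, `Ac`.
#' @param disc A [discretizer()].
#' @return Data frame of integer state columns `T`, `RH`, `Ins`, `Pl`,
#'   `dS`, `dAc`, `S`, `Ac`, `S.prev`, `Ac.prev` plus the identifying
#'   `parcel`, `vintage`, `week`.
#' @export
make_transition_records <- function(weekly, disc = discretizer()) {
  need <- c("parcel", "vintage", "week", "T", "RH", "Ins", "Pl", "S", "Ac")
  missing_col <- setdiff(need, names(weekly))
  if (length(missing_col)) stop("weekly table lacks column(s): ",
                                paste(missing_col, collapse = ", "),
                                call. = FALSE)
  unit <- interaction(weekly$parcel, weekly$vintage, drop = TRUE)
  pieces <- lapply(split(weekly, unit), function(g) {
    g <- g[order(g$week), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    i <- 2:nrow(g)
    data.frame(
      parcel = g$parcel[i], vintage = g$vintage[i], week = g$week[i],
      T = discretize(disc, "T", g$T[i]),
      RH = discretize(disc, "RH", g$RH[i]),
      Ins = discretize(disc, "Ins", g$Ins[i]),
      Pl = discretize(disc, "Pl", g$Pl[i]),
      dS = discretize(disc, "dS", g$S[i] - g$S[i - 1L]),
      dAc = discretize(disc, "dAc", g$Ac[i] - g$Ac[i - 1L]),
      S = discretize(disc, "S", g$S[i]),
      Ac = discretize(disc, "Ac", g$Ac[i]),
      S.prev = discretize(disc, "S", g$S[i - 1L]),
      Ac.prev = discretize(disc, "Ac", g$Ac[i - 1L])
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' First-week states of each kinetics
#'
#' @inheritParams make_transition_records
#' @return Data frame with columns `S`, `Ac` (integer states), one row per
#'   parcel-vintage unit.
#' @export
make_initial_records <- function(weekly, disc = discretizer()) {
  unit <- interaction(weekly$parcel, weekly$vintage, drop = TRUE)
  pieces <- lapply(split(weekly, unit), function(g) {
    g <- g[order(g$week), , drop = FALSE]
    data.frame(S = discretize(disc, "S", g$S[1]),
               Ac = discretize(disc, "Ac", g$Ac[1]))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Evidence series for one kinetics
#'
#' Discretizes a unit's weekly climate into per-week evidence for the
#' filter; week 1 additionally pins the measured sugar and acidity states.
#'
#' @param unit_weekly Weekly rows of one parcel-vintage, ordered by week,
#'   with columns `T`, `RH`, `Ins`, `Pl` and (week 1) `S`, `Ac`.
#' @param disc A [discretizer()].
#' @param include_initial Pin `S`/`Ac` at week 1 from the measurements.
#' @return List of named integer vectors, one per week.
#' @export
make_evidence <- function(unit_weekly, disc = discretizer(),
                          include_initial = TRUE) {
  g <- unit_weekly[order(unit_weekly$week), , drop = FALSE]
  ev <- lapply(seq_len(nrow(g)), function(i) {
    c(T = discretize(disc, "T", g$T[i]),
      RH = discretize(disc, "RH", g$RH[i]),
      Ins = discretize(disc, "Ins", g$Ins[i]),
      Pl = discretize(disc, "Pl", g$Pl[i]))
  })
  if (include_initial && nrow(g)) {
    ev[[1]] <- c(ev[[1]],
                 S = discretize(disc, "S", g$S[1]),
                 Ac = discretize(disc, "Ac", g$Ac[1]))
  }
  ev
}
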
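#' Physical validity bounds of the maturation variables
#'
#' Lower and upper bounds of the weekly variables: weekly temperature sum
#' `T` (degC), weekly insolation `Ins` (h), weekly mean relative humidity
#' `RH` (%), weekly rainfall `Pl` (mm), sugar `S` (g/L), total acidity `Ac`
#' (g/L eq H2SO4) and their weekly variations `dS`, `dAc`.
#'
#' @return Data frame with rownames = variable, columns `lower`, `upper`.
#' @export
maturation_bounds <- function() {
  data.frame(
    lower = c(T = 60, RH = 50, Ins = 0, Pl = 0,
              S = 106, Ac = 2.9, dS = -14, dAc = -2.2),
    upper = c(T = 175, RH = 100, Ins = 80, Pl = 100,
              S = 237, Ac = 8.4, dS = 36, dAc = 0.4)
  )
}

#' Discretizer for the network variables
#'
#' Maps each continuous variable to ordered bins (half-open `[e_i, e_{i+1})`,
#' last bin closed) with a representative value per bin (the midpoint).
#' Defaults, chosen to keep conditional tables learnable from hundreds of
#' records while matching the 8 g/L sugar resolution used in the study
#' regime:
#' sugar in 8 g/L bins on an edge grid containing 184 and 192; acidity in
#' 0.5 g/L bins over its bounds; weekly variations `dS` in 5 g/L bins and
#' `dAc` in 0.4 g/L bins (its last bin is narrower so the bounds stay
#' covered); climate variables in 3 equal bins (2 for relative humidity).
#'
#' @param edges Named list of strictly increasing numeric edge vectors; the
#'   default covers `T`, `RH`, `Ins`, `Pl`, `S`, `Ac`, `dS`, `dAc`.
#' @return Object of class `discretizer`.
#' @export
discretizer <- function(edges = default_bin_edges()) {
  for (v in names(edges)) {
    e <- edges[[v]]
    if (length(e) < 2L || is.unsorted(e, strictly = TRUE)) {
      stop("edges for '", v, "' must be strictly increasing, length >= 2",
           call. = FALSE)
    }
  }
  structure(list(edges = edges), class = "discretizer")
}

#' @rdname discretizer
#' @export
default_bin_edges <- function() {
  seq_cover <- function(lo, hi, by) unique(c(seq(lo, hi, by = by), hi))
  list(
    T   = seq(60, 175, length.out = 4),
    RH  = seq(50, 100, length.out = 3),
    Ins = seq(0, 80, length.out = 4),
    Pl  = seq(0, 100, length.out = 4),
    S   = seq(104, 240, by = 8),
    Ac  = seq(2.9, 8.4, by = 0.5),
    dS  = seq(-14, 36, by = 5),
    dAc = seq_cover(-2.2, 0.4, by = 0.4)
  )
}

#' @export
print.discretizer <- function(x, ...) {
  cat("<discretizer>\n")
  for (v in names(x$edges)) {
    e <- x$edges[[v]]
    cat("  ", v, ": ", length(e) - 1L, " bins over [", e[1], ", ",
        e[length(e)], "]\n", sep = "")
  }
  invisible(x)
}

#' Number of bins per variable
#' @param disc A [discretizer()].
#' @return Named integer vector.
#' @export
n_bins <- function(disc) {
  vapply(disc$edges, function(e) length(e) - 1L, integer(1))
}

#' Discretize a value to its bin index
#'
#' Half-open bins `[e_i, e_{i+1})`, the last bin closed at the top. Values
#' outside the covered range are clamped to the boundary bin with a warning;
#' non-finite values are an error.
#'
#' @param disc A [discretizer()].
#' @param variable Variable name (must have edges).
#' @param x Numeric vector.
#' @return Integer bin indices in `1..n_bins`.
#' @export
discretize <- function(disc, variable, x) {
  e <- disc$edges[[variable]]
  if (is.null(e)) stop("no discretization defined for '", variable, "'",
                       call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite value for '", variable,
                                           "'", call. = FALSE)
  nb <- length(e) - 1L
  if (any(x < e[1] | x > e[length(e)])) {
    warning("value(s) of '", variable,
            "' outside declared bounds; clamped to boundary bin",
            call. = FALSE)
  }
  idx <- findInterval(x, e, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), nb)
}

#' Representative (midpoint) value of a bin
#'
#' @param disc A [discretizer()].
#' @param variable Variable name.
#' @param state Integer bin indices.
#' @return Numeric midpoints; `undigitize(discretize(x))` lands in the same
#'   bin as `x`.
#' @export
undigitize <- function(disc, variable, state) {
  e <- disc$edges[[variable]]
  if (is.null(e)) stop("no discretization defined for '", variable, "'",
                       call. = FALSE)
  nb <- length(e) - 1L
  if (any(state < 1L | state > nb)) stop("state out of range for '", variable,
                                         "'", call. = FALSE)
  (e[state] + e[state + 1L]) / 2
}

#' @rdname undigitize
#' @return For `bin_midpoints`, the vector of all representatives.
#' @export
bin_midpoints <- function(disc, variable) {
  undigitize(disc, variable, seq_len(n_bins(disc)[[variable]]))
}
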
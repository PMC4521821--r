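#' Membership function of a fuzzy set
#'
#' Piecewise-linear membership functions over a numeric universe. Four shapes
#' are supported:
#' \describe{
#'   \item{`"triangular"`}{breakpoints `(a1, a2, a3)`: 0 outside
#'     `[a1, a3]`, apex 1 at `a2`.}
#'   \item{`"trapezoidal"`}{breakpoints `(a1, a2, a3, a4)`: 0 outside
#'     `[a1, a4]`, plateau 1 on `[a2, a3]`.}
#'   \item{`"left-shoulder"`}{breakpoints `(a1, a2)`: 1 below `a1`, linear
#'     decay to 0 at `a2`, 0 beyond.}
#'   \item{`"right-shoulder"`}{breakpoints `(a1, a2)`: 0 below `a1`, linear
#'     rise to 1 at `a2`, 1 beyond.}
#' }
#' Shoulder shapes evaluate to exactly 1 on their unbounded plateau, so a
#' left/right shoulder pair plus interior trapezoids with shared breakpoints
#' forms a partition whose degrees sum to one everywhere.
#'
#' @param shape One of `"triangular"`, `"trapezoidal"`, `"left-shoulder"`,
#'   `"right-shoulder"`.
#' @param breakpoints Non-decreasing numeric vector; length 3, 4, 2, 2
#'   respectively for the shapes above.
#' @return An object of class `membership_function`.
#' @examples
#' mf <- membership_function("trapezoidal", c(7, 13, 15, 21))
#' evaluate_membership(mf, 10.5) # 0.5833...
#' @export
membership_function <- function(shape = c("triangular", "trapezoidal",
                                          "left-shoulder", "right-shoulder"),
                                breakpoints) {
  shape <- match.arg(shape)
  breakpoints <- as.numeric(breakpoints)
  n_expected <- switch(shape, triangular = 3L, trapezoidal = 4L,
                       `left-shoulder` = 2L, `right-shoulder` = 2L)
  if (length(breakpoints) != n_expected || anyNA(breakpoints)) {
    stop("shape '", shape, "' needs ", n_expected,
         " finite breakpoints, got ", length(breakpoints), call. = FALSE)
  }
  if (is.unsorted(breakpoints)) {
    stop("breakpoints must be non-decreasing", call. = FALSE)
  }
  structure(list(shape = shape, breakpoints = breakpoints),
            class = "membership_function")
}

# linear edges clamped to [0,1]; `a` is the zero end, `b` the unit end,
# guarded against zero-width (step) transitions
.edge_up <- function(x, a, b) {   # 0 at a, rising to 1 at b >= a
  if (b == a) as.numeric(x >= a) else pmin(1, pmax(0, (x - a) / (b - a)))
}
.edge_down <- function(x, a, b) { # 1 at b, falling to 0 at a >= b
  if (b == a) as.numeric(x < a) else pmin(1, pmax(0, (a - x) / (a - b)))
}

#' Evaluate a membership function
#'
#' @param mf A [membership_function()].
#' @param x Numeric vector of input values (in the variable's units).
#' @return Membership degrees in `[0, 1]`, same length as `x`.
#' @export
evaluate_membership <- function(mf, x) {
  if (!inherits(mf, "membership_function")) {
    stop("'mf' must be a membership_function", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("'x' must be finite numeric", call. = FALSE)
  }
  b <- mf$breakpoints
  switch(mf$shape,
    triangular = pmin(.edge_up(x, b[1], b[2]), .edge_down(x, b[3], b[2])),
    trapezoidal = pmin(.edge_up(x, b[1], b[2]), .edge_down(x, b[4], b[3])),
    `left-shoulder` = .edge_down(x, b[2], b[1]),
    `right-shoulder` = .edge_up(x, b[1], b[2])
  )
}

#' @export
print.membership_function <- function(x, ...) {
  cat("<membership_function> ", x$shape, " (",
      paste(x$breakpoints, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Linguistic variable
#'
#' A numeric input partitioned into labelled fuzzy terms, e.g. a mean day
#' temperature described as "low", "middle" or "high".
#'
#' @param name Identifier of the variable.
#' @param unit Unit of the underlying numeric measurement.
#' @param terms Named list of [membership_function()]s, at least two, with
#'   unique labels. Order is kept (conventionally from lowest to highest).
#' @return An object of class `linguistic_variable`.
#' @export
linguistic_variable <- function(name, unit, terms) {
  if (!is.list(terms) || length(terms) < 2L) {
    stop("a linguistic variable needs at least 2 terms", call. = FALSE)
  }
  labels <- names(terms)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("term labels must be unique and non-empty", call. = FALSE)
  }
  ok <- vapply(terms, inherits, logical(1), "membership_function")
  if (!all(ok)) stop("all terms must be membership_function objects", call. = FALSE)
  structure(list(name = name, unit = unit, terms = terms),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat("<linguistic_variable> ", x$name, " [", x$unit, "]: ",
      paste(names(x$terms), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fuzzify a crisp value
#'
#' Maps a numeric observation to its vector of membership grades, one per
#' term of the linguistic variable. Degrees need not sum to one in general
#' (they do for sum-to-one partitions such as the default FGRAPE ones).
#'
#' @param var A [linguistic_variable()].
#' @param x A single finite numeric value.
#' @return Named numeric vector of degrees in `[0, 1]`, one per term.
#' @export
fuzzify <- function(var, x) {
  if (!inherits(var, "linguistic_variable")) {
    stop("'var' must be a linguistic_variable", call. = FALSE)
  }
  if (length(x) != 1L || !is.finite(x)) stop("'x' must be a single finite value",
                                             call. = FALSE)
  vapply(var$terms, evaluate_membership, numeric(1), x = x)
}

#' Fuzzy rule
#'
#' A symbolic rule with conjunctive antecedents over linguistic variables and
#' one concluded class per output. Each antecedent is a set of admissible
#' term labels; disjunction within a variable ("low or middle") is a set with
#' several labels, combined by max before the product conjunction. A set
#' listing all terms of a variable (or an absent variable) acts as a
#' wildcard.
#'
#' @param antecedent Named list; each element a character vector of term
#'   labels for that variable.
#' @param conclusion Named vector/list mapping output name to a class label.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, conclusion) {
  if (!is.list(antecedent) || is.null(names(antecedent)) ||
      any(!nzchar(names(antecedent)))) {
    stop("'antecedent' must be a named list of term-label sets", call. = FALSE)
  }
  if (any(lengths(antecedent) == 0L)) {
    stop("every antecedent term set must be non-empty", call. = FALSE)
  }
  conclusion <- unlist(conclusion)
  if (is.null(names(conclusion)) || any(!nzchar(names(conclusion)))) {
    stop("'conclusion' must be named by output", call. = FALSE)
  }
  structure(list(antecedent = lapply(antecedent, as.character),
                 conclusion = stats::setNames(as.character(conclusion),
                                              names(conclusion))),
            class = "fuzzy_rule")
}

#' Rule base
#'
#' A list of [fuzzy_rule()]s bound to the linguistic variables they quantify
#' over. Construction checks every antecedent variable and term label against
#' the variable definitions.
#'
#' @param rules List of [fuzzy_rule()]s (non-empty).
#' @param variables Named list of [linguistic_variable()]s.
#' @return An object of class `rule_base`.
#' @export
rule_base <- function(rules, variables) {
  if (!length(rules)) stop("empty rule list", call. = FALSE)
  if (is.null(names(variables))) names(variables) <- vapply(variables, `[[`,
                                                            character(1), "name")
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    if (!inherits(r, "fuzzy_rule")) stop("rule ", j, " is not a fuzzy_rule",
                                         call. = FALSE)
    for (v in names(r$antecedent)) {
      if (!v %in% names(variables)) {
        stop("rule ", j, " refers to unknown variable '", v, "'", call. = FALSE)
      }
      bad <- setdiff(r$antecedent[[v]], names(variables[[v]]$terms))
      if (length(bad)) {
        stop("rule ", j, ", variable '", v, "': unknown term label(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(rules = rules, variables = variables), class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat("<rule_base> ", length(x$rules), " rules over ",
      paste(names(x$variables), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.rule_base <- function(x) length(x$rules)

#' Activation grade of a rule
#'
#' Product t-norm over antecedent variables; within each variable the degree
#' is the max over the rule's admissible term labels (disjunction).
#' Variables not constrained by the rule contribute a factor of one.
#'
#' @param rule A [fuzzy_rule()].
#' @param fuzzified Named list: per variable, the named degree vector
#'   returned by [fuzzify()].
#' @return Activation grade alpha in `[0, 1]`.
#' @export
activate_rule <- function(rule, fuzzified) {
  alpha <- 1
  for (v in names(rule$antecedent)) {
    deg <- fuzzified[[v]]
    if (is.null(deg)) stop("variable '", v, "' has not been fuzzified",
                           call. = FALSE)
    labs <- rule$antecedent[[v]]
    if (any(!labs %in% names(deg))) {
      stop("unknown term label for variable '", v, "'", call. = FALSE)
    }
    alpha <- alpha * max(deg[labs])
  }
  alpha
}

#' Aggregate rule conclusions into class weights
#'
#' Normalized weighted vote: for each output, the weight of class `C` is
#' `sum(alpha_j for rules concluding C) / sum(alpha_j)`. If no rule is
#' activated (`sum(alpha) == 0`) the quotient is undefined; the configured
#' fallback class receives weight one and a warning is emitted (the neutral
#' "not favorable" level 1 by default, matching the limiting-conditions
#' semantics of the day-index scale).
#'
#' @param rules List of [fuzzy_rule()]s (or a [rule_base()]).
#' @param activations Numeric vector of activation grades, same length.
#' @param classes Optional character vector (or named list per output) of the
#'   full class label set; weights are returned over this set, zero-filled.
#' @param fallback_class Class label used when no rule fires. Default `"1"`.
#' @return Named list per output: named numeric weight vector summing to 1.
#' @export
aggregate_classes <- function(rules, activations, classes = NULL,
                              fallback_class = "1") {
  if (inherits(rules, "rule_base")) rules <- rules$rules
  if (!length(rules)) stop("empty rule list", call. = FALSE)
  if (length(rules) != length(activations)) {
    stop("'rules' and 'activations' must have the same length", call. = FALSE)
  }
  outputs <- names(rules[[1]]$conclusion)
  concl <- do.call(rbind, lapply(rules, `[[`, "conclusion"))
  total <- sum(activations)
  out <- vector("list", length(outputs))
  names(out) <- outputs
  for (o in outputs) {
    if (is.list(classes)) lev <- classes[[o]] else lev <- classes
    if (is.null(lev)) lev <- sort(unique(concl[, o]))
    if (total > 0) {
      w <- vapply(lev, function(cl) sum(activations[concl[, o] == cl]),
                  numeric(1)) / total
    } else {
      warning("no rule activated; falling back to neutral class '",
              fallback_class, "'", call. = FALSE)
      if (!fallback_class %in% lev) lev <- c(lev, fallback_class)
      w <- stats::setNames(as.numeric(lev == fallback_class), lev)
    }
    names(w) <- lev
    out[[o]] <- w
  }
  out
}

#' Read / write a rule base file
#'
#' Delimited text, one rule per row. Antecedent columns hold `;`-separated
#' term labels (`*` = wildcard over all the variable's terms); the remaining
#' columns hold one concluded class label per output.
#'
#' @param path File path.
#' @param variables Named list of [linguistic_variable()]s (defines which
#'   columns are antecedents).
#' @param outputs Character vector of output column names.
#' @param sep Field separator (default tab).
#' @return A [rule_base()] (for `read_rule_base`).
#' @export
read_rule_base <- function(path, variables,
                           outputs = c("sugar", "acidity"), sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  if (is.null(names(variables))) names(variables) <- vapply(variables, `[[`,
                                                            character(1), "name")
  vars <- intersect(names(variables), names(tab))
  if (!length(vars)) stop("no antecedent columns found in ", path, call. = FALSE)
  missing_out <- setdiff(outputs, names(tab))
  if (length(missing_out)) stop("missing output column(s): ",
                                paste(missing_out, collapse = ", "), call. = FALSE)
  rules <- lapply(seq_len(nrow(tab)), function(i) {
    ant <- lapply(vars, function(v) {
      val <- tab[i, v]
      if (identical(val, "*")) names(variables[[v]]$terms)
      else strsplit(val, ";", fixed = TRUE)[[1]]
    })
    names(ant) <- vars
    fuzzy_rule(ant, stats::setNames(as.character(tab[i, outputs]), outputs))
  })
  rule_base(rules, variables)
}

#' @rdname read_rule_base
#' @param base A [rule_base()] to serialize.
#' @export
write_rule_base <- function(base, path, outputs = NULL, sep = "\t") {
  stopifnot(inherits(base, "rule_base"))
  vars <- names(base$variables)
  if (is.null(outputs)) outputs <- names(base$rules[[1]]$conclusion)
  rows <- lapply(base$rules, function(r) {
    ant <- vapply(vars, function(v) {
      labs <- r$antecedent[[v]]
      if (is.null(labs) || setequal(labs, names(base$variables[[v]]$terms))) "*"
      else paste(labs, collapse = ";")
    }, character(1))
    c(ant, r$conclusion[outputs])
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  names(tab) <- c(vars, outputs)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
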
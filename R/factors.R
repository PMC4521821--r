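# Internal discrete-factor algebra used by the exact DBN inference.
# A factor is a list(vars, card, val): `vars` a character vector of variable
# names, `card` a named integer vector of cardinalities (same order), `val`
# a numeric vector enumerating states with the FIRST variable fastest
# (column-major array order).

new_factor <- function(vars, card, val) {
  card <- stats::setNames(as.integer(card), vars)
  stopifnot(length(val) == prod(card))
  list(vars = vars, card = card, val = as.numeric(val))
}

# align f$val to the enumeration over (vars, card); vars must contain f$vars
factor_gather <- function(f, vars, card) {
  if (!length(f$vars)) return(rep(f$val, prod(card)))
  pos <- match(f$vars, vars)
  n <- prod(card)
  coords <- arrayInd(seq_len(n), .dim = unname(card))
  strides <- cumprod(c(1L, unname(f$card)[-length(f$card)]))
  idx <- as.vector((coords[, pos, drop = FALSE] - 1L) %*% strides) + 1L
  f$val[idx]
}

factor_product <- function(f1, f2) {
  if (!length(f1$vars)) return(new_factor(f2$vars, f2$card, f1$val * f2$val))
  if (!length(f2$vars)) return(new_factor(f1$vars, f1$card, f2$val * f1$val))
  vars <- union(f1$vars, f2$vars)
  card <- c(f1$card, f2$card)[vars]
  new_factor(vars, card,
             factor_gather(f1, vars, card) * factor_gather(f2, vars, card))
}

# sum out every variable not in `keep` (keep order = order given)
factor_marginal <- function(f, keep) {
  keep <- intersect(keep, f$vars)
  drop_vars <- setdiff(f$vars, keep)
  if (!length(drop_vars)) {
    # reorder to `keep`
    return(new_factor(keep, f$card[keep],
                      factor_gather(f, keep, f$card[keep])))
  }
  arr <- array(f$val, dim = unname(f$card))
  perm <- c(match(keep, f$vars), match(drop_vars, f$vars))
  arr <- aperm(arr, perm)
  m <- matrix(arr, nrow = prod(c(1L, f$card[keep])))
  new_factor(keep, f$card[keep], rowSums(m))
}

# fix variable `var` to `state`, dropping the dimension
factor_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  args <- c(list(array(f$val, dim = unname(f$card))),
            lapply(seq_along(f$vars), function(j) {
              if (j == i) as.integer(state) else substitute()
            }),
            list(drop = FALSE))
  sub <- do.call(`[`, args)
  new_factor(f$vars[-i], f$card[-i], as.vector(sub))
}

# multiply all factors mentioning `var`, sum it out, return reduced list
factor_eliminate <- function(factors, var) {
  touches <- vapply(factors, function(f) var %in% f$vars, logical(1))
  if (!any(touches)) return(factors)
  merged <- Reduce(factor_product, factors[touches])
  merged <- factor_marginal(merged, setdiff(merged$vars, var))
  c(factors[!touches], list(merged))
}
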
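#' Fuzzy rule
#'
#' An IF-THEN rule whose antecedent names one term per input variable
#' (conjunction) and whose consequent names one output term.
#'
#' @param antecedent Named character vector, `variable name -> term name`.
#' @param consequent Single output term name.
#' @param weight Rule weight in `(0, 1]`; the activation degree is
#'   multiplied by it.  Defaults to 1.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent, weight = 1) {
  antecedent <- unlist(antecedent)
  stopifnot(is.character(antecedent), !is.null(names(antecedent)),
            all(nzchar(names(antecedent))))
  stopifnot(is.character(consequent), length(consequent) == 1L)
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0 || weight > 1) {
    stop("rule weight must lie in (0, 1]", call. = FALSE)
  }
  structure(list(antecedent = antecedent, consequent = consequent,
                 weight = as.numeric(weight)),
            class = "fuzzy_rule")
}

#' Mamdani fuzzy inference system
#'
#' Bundles input linguistic variables, one output variable, a rule base
#' and the defuzzification resolution into a runnable system.  Inference
#' uses the classical min/max ("maximum and minimum") Mamdani operators:
#' min for antecedent conjunction and implication (clipping), max for
#' rule aggregation, and centroid defuzzification on a uniform grid.
#'
#' @param inputs List of input [linguistic_variable()]s.
#' @param output The output [linguistic_variable()].
#' @param rules List of [fuzzy_rule()]s.  Every variable and term a rule
#'   references must exist.
#' @param defuzz_resolution Number of uniform sample points over the
#'   output domain used by centroid defuzzification (default 1001).
#' @return An object of class `fuzzy_inference_system`.
#' @export
fuzzy_inference_system <- function(inputs, output, rules,
                                   defuzz_resolution = 1001L) {
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  for (v in inputs) stopifnot(inherits(v, "linguistic_variable"))
  stopifnot(inherits(output, "linguistic_variable"))
  stopifnot(is.list(rules), length(rules) >= 1L)
  defuzz_resolution <- as.integer(defuzz_resolution)
  stopifnot(defuzz_resolution >= 2L)
  names(inputs) <- vapply(inputs, `[[`, character(1), "name")
  if (anyDuplicated(names(inputs))) {
    stop("input variable names must be unique", call. = FALSE)
  }
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!inherits(r, "fuzzy_rule")) {
      stop(sprintf("rules[[%d]] is not a fuzzy_rule", i), call. = FALSE)
    }
    for (vn in names(r$antecedent)) {
      if (!vn %in% names(inputs)) {
        stop(sprintf("rule %d references unknown input variable '%s'", i, vn),
             call. = FALSE)
      }
      if (!r$antecedent[[vn]] %in% names(inputs[[vn]]$terms)) {
        stop(sprintf("rule %d references unknown term '%s' of variable '%s'",
                     i, r$antecedent[[vn]], vn), call. = FALSE)
      }
    }
    if (!r$consequent %in% names(output$terms)) {
      stop(sprintf("rule %d references unknown output term '%s'",
                   i, r$consequent), call. = FALSE)
    }
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 defuzz_resolution = defuzz_resolution),
            class = "fuzzy_inference_system")
}

#' @export
print.fuzzy_inference_system <- function(x, ...) {
  cat(sprintf("Mamdani fuzzy inference system: %d inputs (%s) -> '%s', %d rules, centroid grid %d\n",
              length(x$inputs), paste(names(x$inputs), collapse = ", "),
              x$output$name, length(x$rules), x$defuzz_resolution))
  invisible(x)
}

#' Uniform output-domain grid of a system
#' @param fis A [fuzzy_inference_system()].
#' @return Numeric vector of `defuzz_resolution` points spanning the
#'   output domain.
#' @export
output_grid <- function(fis) {
  seq(fis$output$domain[1], fis$output$domain[2],
      length.out = fis$defuzz_resolution)
}

#' Rule activation degree
#'
#' The firing strength of a rule: its weight times the minimum of the
#' fuzzified degrees of its antecedent terms.
#'
#' @param rule A [fuzzy_rule()].
#' @param fuzzified Named list, `variable name -> named degree vector` as
#'   produced by [fuzzify()] per input.
#' @return Degree in `[0, 1]`.
#' @export
activate_rule <- function(rule, fuzzified) {
  degs <- vapply(names(rule$antecedent), function(vn) {
    dv <- fuzzified[[vn]]
    if (is.null(dv)) {
      stop(sprintf("no fuzzified degrees supplied for variable '%s'", vn),
           call. = FALSE)
    }
    term <- rule$antecedent[[vn]]
    if (!term %in% names(dv)) {
      stop(sprintf("term '%s' missing from fuzzified degrees of '%s'",
                   term, vn), call. = FALSE)
    }
    dv[[term]]
  }, numeric(1))
  rule$weight * min(degs)
}

#' Aggregate clipped consequents (Mamdani max step)
#'
#' For each output-grid point, takes the maximum over rules of
#' `min(activation, consequent membership)`.  Rules with zero activation
#' contribute nothing.
#'
#' @param activations Named numeric vector or list of pairs: activation
#'   degree per rule, with the consequent term name as the name.  Pass
#'   the degrees from [activate_rule()].
#' @param output The output [linguistic_variable()].
#' @param grid Uniform sampling of the output domain (>= 2 points).
#' @return Numeric vector of aggregated membership on `grid`, in `[0, 1]`.
#' @export
aggregate_output <- function(activations, output, grid) {
  stopifnot(length(grid) >= 2L)
  activations <- unlist(activations)
  if (length(activations) == 0L || all(activations <= 0)) {
    stop("no rule fired: all activation degrees are zero", call. = FALSE)
  }
  curve <- numeric(length(grid))
  for (i in seq_along(activations)) {
    a <- activations[[i]]
    if (a <= 0) next
    term <- names(activations)[i]
    mu <- evaluate_membership(output$terms[[term]], grid)
    curve <- pmax(curve, pmin(a, mu))
  }
  curve
}

#' Centroid defuzzification
#'
#' Collapses an aggregated membership curve to its centre of mass,
#' `sum(w * x * mu) / sum(w * mu)` over the grid points, with
#' trapezoidal-rule weights (`w = 1/2` at the two domain edges) so that
#' shoulder terms touching a domain edge are not over-weighted.
#'
#' @param curve Aggregated membership values on `grid`.
#' @param grid The matching uniform output-domain grid.
#' @return Crisp value within `[min(grid), max(grid)]`.
#' @export
defuzzify_centroid <- function(curve, grid) {
  stopifnot(length(curve) == length(grid))
  w <- rep(1, length(grid))
  w[c(1L, length(grid))] <- 0.5
  mass <- sum(w * curve)
  if (!is.finite(mass) || mass <= 0) {
    stop("no rule fired: aggregated membership has zero mass", call. = FALSE)
  }
  sum(w * grid * curve) / mass
}

#' Run Mamdani inference for one observation
#'
#' Full pipeline: fuzzify each input, fire all rules (min conjunction),
#' aggregate clipped consequents (max), and defuzzify by centroid.  If no
#' rule fires with positive degree — impossible under the default
#' partition-of-unity terms, but reachable with user-supplied
#' configurations — the domain midpoint is returned with a warning.
#'
#' @param fis A [fuzzy_inference_system()].
#' @param inputs Named numeric vector or list, one finite value per input
#'   variable.
#' @param warn_clamp Warn when an input lies outside its variable domain.
#' @return Crisp output value within the output domain.
#' @export
#' @examples
#' fis <- respiratory_fis()
#' infer(fis, c(pm10 = 24, no2 = 30, temperature = 33, wind = 3.5))
infer <- function(fis, inputs, warn_clamp = TRUE) {
  stopifnot(inherits(fis, "fuzzy_inference_system"))
  inputs <- unlist(inputs)
  missing_vars <- setdiff(names(fis$inputs), names(inputs))
  if (length(missing_vars)) {
    stop(sprintf("no value supplied for input variable(s): %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  }
  fuzzified <- lapply(fis$inputs, function(v) {
    fuzzify(v, inputs[[v$name]], warn = warn_clamp)
  })
  acts <- vapply(fis$rules, activate_rule, numeric(1), fuzzified = fuzzified)
  names(acts) <- vapply(fis$rules, `[[`, character(1), "consequent")
  grid <- output_grid(fis)
  if (all(acts <= 0)) {
    warning("no rule fired; returning the output-domain midpoint",
            call. = FALSE)
    return(mean(fis$output$domain))
  }
  curve <- aggregate_output(acts, fis$output, grid)
  defuzzify_centroid(curve, grid)
}

# Vectorised inference over many observations: same pipeline as infer(),
# restructured around matrices.  Activation matrix A (n x rules) is
# reduced per output term to the max activation M (n x terms); the
# aggregated curve never needs materialising per day because
# sum-over-grid quantities distribute over the term-wise pmin/pmax.
infer_many <- function(fis, X, warn_clamp = TRUE) {
  stopifnot(is.matrix(X) || is.data.frame(X))
  X <- as.data.frame(X)
  vars <- names(fis$inputs)
  stopifnot(all(vars %in% names(X)))
  n <- nrow(X)
  ok <- stats::complete.cases(X[vars])
  out <- rep(NA_real_, n)
  if (!any(ok)) return(out)

  # degree of every (variable, term) for the complete rows
  deg <- lapply(fis$inputs, function(v) {
    x <- clamp_to_domain(v, X[[v$name]][ok], warn = warn_clamp)
    vapply(v$terms, evaluate_membership, numeric(sum(ok)), x = x)
  })
  for (v in vars) if (is.null(dim(deg[[v]]))) {
    deg[[v]] <- matrix(deg[[v]], nrow = 1,
                       dimnames = list(NULL, names(fis$inputs[[v]]$terms)))
  }

  # n_ok x n_rules activation matrix (min over conjuncts, times weight)
  acts <- vapply(fis$rules, function(r) {
    m <- rep(r$weight, sum(ok))
    for (vn in names(r$antecedent)) {
      m <- pmin(m, deg[[vn]][, r$antecedent[[vn]]])
    }
    m
  }, numeric(sum(ok)))
  if (is.null(dim(acts))) acts <- matrix(acts, nrow = 1)

  cons <- vapply(fis$rules, `[[`, character(1), "consequent")
  terms <- names(fis$output$terms)
  # per output term: max activation over the rules that conclude it
  M <- vapply(terms, function(tm) {
    idx <- which(cons == tm)
    if (length(idx) == 0L) return(numeric(nrow(acts)))
    apply(acts[, idx, drop = FALSE], 1, max)
  }, numeric(nrow(acts)))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, terms))

  grid <- output_grid(fis)
  C <- vapply(terms, function(tm) {
    evaluate_membership(fis$output$terms[[tm]], grid)
  }, numeric(length(grid)))

  w <- rep(1, length(grid))
  w[c(1L, length(grid))] <- 0.5
  num <- numeric(nrow(M)); den <- numeric(nrow(M))
  curve_g <- numeric(nrow(M))
  for (g in seq_along(grid)) {
    curve_g[] <- 0
    for (k in seq_along(terms)) {
      curve_g <- pmax(curve_g, pmin(M[, k], C[g, k]))
    }
    num <- num + w[g] * grid[g] * curve_g
    den <- den + w[g] * curve_g
  }
  fired <- den > 0
  if (any(!fired)) {
    warning(sprintf("no rule fired for %d observation(s); using the output-domain midpoint",
                    sum(!fired)), call. = FALSE)
  }
  res <- ifelse(fired, num / den, mean(fis$output$domain))
  out[ok] <- res
  out
}
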
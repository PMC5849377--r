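#' Trapezoidal membership function
#'
#' Constructs a trapezoidal fuzzy membership function with breakpoints
#' `a <= b <= c <= d`: membership is 0 below `a`, rises linearly from `a`
#' to `b`, equals 1 on `[b, c]`, falls linearly from `c` to `d`, and is 0
#' above `d`.  Shoulder functions (flat at a domain edge) are expressed by
#' collapsing the rising or falling flank, e.g. `trapezoid_mf(0, 0, 15, 35)`.
#'
#' @param a,b,c,d Numeric breakpoints in the variable's physical units,
#'   non-decreasing.
#' @return An object of class `membership_function`.
#' @seealso [triangle_mf()], [evaluate_membership()]
#' @export
#' @examples
#' mf <- trapezoid_mf(0, 0, 15, 35)
#' evaluate_membership(mf, 24) # 0.55
trapezoid_mf <- function(a, b, c, d) {
  params <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(params))) {
    stop("membership breakpoints must be finite numbers", call. = FALSE)
  }
  if (is.unsorted(params)) {
    stop(sprintf(
      "membership breakpoints must be non-decreasing, got (%s)",
      paste(format(params), collapse = ", ")
    ), call. = FALSE)
  }
  structure(list(shape = "trapezoid", params = unname(params)),
            class = "membership_function")
}

#' Triangular membership function
#'
#' A triangle with feet at `a` and `c` and apex at `b`; equivalent to the
#' trapezoid `(a, b, b, c)`.
#'
#' @param a,b,c Numeric breakpoints, non-decreasing.
#' @return An object of class `membership_function`.
#' @export
triangle_mf <- function(a, b, c) {
  mf <- trapezoid_mf(a, b, b, c)
  mf$shape <- "triangle"
  mf
}

#' Evaluate a membership function
#'
#' Returns the degree of membership (pertinence) of `x` in the fuzzy set,
#' a value in `[0, 1]`, piecewise linear in `x`.  Vectorised over `x`.
#'
#' @param mf A [trapezoid_mf()] or [triangle_mf()].
#' @param x Numeric vector of crisp values in the variable's units.  Must
#'   be finite; `NA` propagates to `NA`.
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
evaluate_membership <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  if (any(is.infinite(x) | is.nan(x))) {
    stop("membership evaluation requires finite input values", call. = FALSE)
  }
  p <- mf$params
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  down <- if (d > c) (d - x) / (d - c) else as.numeric(x <= c)
  pmax(0, pmin(up, down, 1))
}

#' @export
print.membership_function <- function(x, ...) {
  cat(sprintf("<%s membership function: (%s)>\n", x$shape,
              paste(format(x$params, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Linguistic variable
#'
#' A named variable over a closed physical domain whose values are fuzzy
#' sets (terms), e.g. PM10 over `[0, 150]` ug/m3 with terms `acceptable`
#' and `unacceptable`.
#'
#' @param name Identifier used in rules and data columns.
#' @param domain Length-2 numeric, the closed interval of admissible
#'   crisp values.
#' @param terms Named list of [membership_function]s; names are the term
#'   (linguistic-value) labels and must be unique.
#' @param units Optional unit string, for printing only.
#' @return An object of class `linguistic_variable`.
#' @export
linguistic_variable <- function(name, domain, terms, units = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
  if (length(terms) == 0L || is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("`terms` must be a non-empty named list of membership functions",
         call. = FALSE)
  }
  if (anyDuplicated(names(terms))) {
    stop(sprintf("duplicate term names in variable '%s'", name), call. = FALSE)
  }
  for (tn in names(terms)) {
    mf <- terms[[tn]]
    if (!inherits(mf, "membership_function")) {
      stop(sprintf("term '%s' of variable '%s' is not a membership function",
                   tn, name), call. = FALSE)
    }
  }
  structure(list(name = name, domain = as.numeric(domain),
                 terms = terms, units = units),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat(sprintf("Linguistic variable '%s' on [%s, %s]%s with %d terms: %s\n",
              x$name, format(x$domain[1]), format(x$domain[2]),
              if (is.null(x$units)) "" else paste0(" ", x$units),
              length(x$terms), paste(names(x$terms), collapse = ", ")))
  invisible(x)
}

#' Clamp values to a variable's domain
#'
#' Out-of-domain measurements (sensor series legitimately exceed nominal
#' scales) are pulled to the nearest domain edge with a warning rather
#' than rejected.
#'
#' @param var A [linguistic_variable()].
#' @param x Numeric vector.
#' @param warn Emit a warning when clamping occurs.
#' @return `x` with values outside the domain replaced by the edge.
#' @export
clamp_to_domain <- function(var, x, warn = TRUE) {
  out <- !is.na(x) & (x < var$domain[1] | x > var$domain[2])
  if (any(out) && warn) {
    warning(sprintf("%d value(s) of '%s' outside [%s, %s] clamped to the domain edge",
                    sum(out), var$name,
                    format(var$domain[1]), format(var$domain[2])),
            call. = FALSE)
  }
  pmin(pmax(x, var$domain[1]), var$domain[2])
}

#' Fuzzify a crisp value
#'
#' Maps a crisp measurement to its degree of membership in every term of
#' the variable.  Values outside the domain are clamped to the nearest
#' edge first (see [clamp_to_domain()]).
#'
#' @param var A [linguistic_variable()].
#' @param x A single finite numeric value.
#' @param warn Warn when `x` lies outside the domain.
#' @return Named numeric vector, one degree in `[0, 1]` per term.
#' @export
#' @examples
#' pm10 <- linguistic_variable("pm10", c(0, 150), list(
#'   acceptable = trapezoid_mf(0, 0, 15, 35),
#'   unacceptable = trapezoid_mf(15, 35, 150, 150)
#' ), units = "ug/m3")
#' fuzzify(pm10, 24) # acceptable 0.55, unacceptable 0.45
fuzzify <- function(var, x, warn = TRUE) {
  stopifnot(inherits(var, "linguistic_variable"))
  if (length(x) != 1L || !is.finite(x)) {
    stop(sprintf("fuzzify() needs one finite value for '%s'", var$name),
         call. = FALSE)
  }
  x <- clamp_to_domain(var, x, warn = warn)
  vapply(var$terms, evaluate_membership, numeric(1), x = x)
}
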
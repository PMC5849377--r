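#' Default membership breakpoints of the respiratory model
#'
#' The calibration used by [respiratory_fis()].  Each input has two
#' shoulder trapezoids forming a partition of unity (the two degrees sum
#' to 1 everywhere); the output has five terms — four triangles and an
#' upper-shoulder trapezoid — spanning 0 to 9 daily hospitalizations.
#' The PM10 breakpoints place the acceptable/unacceptable crossover at
#' 25 ug/m3, so a reading of 24 ug/m3 is 0.55 acceptable / 0.45
#' unacceptable.  All breakpoints can be overridden term by term.
#'
#' @return Nested named list: `variable -> term -> numeric breakpoints`
#'   (length 4 for trapezoids, 3 for triangles).
#' @export
respiratory_breakpoints <- function() {
  list(
    pm10 = list(
      acceptable   = c(0, 0, 15, 35),
      unacceptable = c(15, 35, 150, 150)
    ),
    no2 = list(
      acceptable   = c(0, 0, 40, 80),
      unacceptable = c(40, 80, 130, 130)
    ),
    temperature = list(
      low  = c(0, 0, 22, 32),
      high = c(22, 32, 45, 45)
    ),
    wind = list(
      weak   = c(0, 0, 1.8, 2.8),
      strong = c(1.8, 2.8, 5, 5)
    ),
    hospitalizations = list(
      L  = c(0, 0, 1.11),
      ML = c(0.5, 2.25, 4),
      M  = c(2.5, 4.5, 6.5),
      MH = c(5, 6.75, 8.5),
      H  = c(6, 8, 9, 9)
    )
  )
}

# domain and unit metadata for the five model variables
.resp_domains <- list(
  pm10 = list(domain = c(0, 150), units = "ug/m3"),
  no2 = list(domain = c(0, 130), units = "ug/m3"),
  temperature = list(domain = c(0, 45), units = "degC"),
  wind = list(domain = c(0, 5), units = "m/s"),
  hospitalizations = list(domain = c(0, 9), units = "admissions/day")
)

# printable labels for the abbreviated output terms
.resp_output_labels <- c(L = "low", ML = "medium-low", M = "medium",
                         MH = "medium-high", H = "high")

#' The sixteen-rule base of the respiratory model
#'
#' The full 2x2x2x2 factorial over the input terms, in its canonical
#' printed order (PM10 outermost, then NO2, temperature, wind), each
#' combination appearing exactly once with weight 1.  Consequents run
#' from L (all inputs favourable) to H (unacceptable pollutants, low
#' temperature, weak wind), with wind and temperature acting
#' protectively.
#'
#' @return Data frame with columns `rule`, `pm10`, `no2`, `temperature`,
#'   `wind`, `consequent`, `weight`.
#' @export
respiratory_rule_table <- function() {
  grid <- expand.grid(
    wind = c("strong", "weak"),
    temperature = c("high", "low"),
    no2 = c("acceptable", "unacceptable"),
    pm10 = c("acceptable", "unacceptable"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  data.frame(
    rule = seq_len(16),
    pm10 = grid$pm10,
    no2 = grid$no2,
    temperature = grid$temperature,
    wind = grid$wind,
    consequent = c("L", "L", "L", "L",
                   "ML", "M", "M", "M",
                   "ML", "ML", "M", "M",
                   "M", "MH", "MH", "H"),
    weight = 1,
    stringsAsFactors = FALSE
  )
}

#' Build the respiratory-hospitalization fuzzy model
#'
#' Constructs the Mamdani system with four two-term inputs (PM10, NO2,
#' air temperature, wind speed), a five-term hospitalization-count
#' output, and the sixteen expert rules of [respiratory_rule_table()].
#'
#' @param breakpoints Nested list of term breakpoints in the shape of
#'   [respiratory_breakpoints()]; supply a partial list to override
#'   individual terms.  Breakpoints must be non-decreasing.
#' @param defuzz_resolution Centroid grid size (default 1001).
#' @return A [fuzzy_inference_system()].
#' @export
#' @examples
#' fis <- respiratory_fis()
#' length(fis$rules)           # 16
#' length(fis$output$terms)    # 5
respiratory_fis <- function(breakpoints = NULL, defuzz_resolution = 1001L) {
  bp <- respiratory_breakpoints()
  if (!is.null(breakpoints)) {
    for (vn in names(breakpoints)) {
      if (!vn %in% names(bp)) {
        stop(sprintf("unknown variable '%s' in breakpoint overrides", vn),
             call. = FALSE)
      }
      for (tn in names(breakpoints[[vn]])) {
        if (!tn %in% names(bp[[vn]])) {
          stop(sprintf("unknown term '%s' of variable '%s' in breakpoint overrides",
                       tn, vn), call. = FALSE)
        }
        bp[[vn]][[tn]] <- breakpoints[[vn]][[tn]]
      }
    }
  }
  make_mf <- function(p, vn, tn) {
    p <- as.numeric(p)
    if (is.unsorted(p)) {
      stop(sprintf("breakpoints of term '%s' (variable '%s') must be non-decreasing",
                   tn, vn), call. = FALSE)
    }
    if (length(p) == 3L) triangle_mf(p[1], p[2], p[3])
    else if (length(p) == 4L) trapezoid_mf(p[1], p[2], p[3], p[4])
    else stop(sprintf("term '%s' of '%s' needs 3 or 4 breakpoints", tn, vn),
              call. = FALSE)
  }
  build_var <- function(vn) {
    terms <- lapply(stats::setNames(names(bp[[vn]]), names(bp[[vn]])),
                    function(tn) make_mf(bp[[vn]][[tn]], vn, tn))
    linguistic_variable(vn, .resp_domains[[vn]]$domain, terms,
                        units = .resp_domains[[vn]]$units)
  }
  inputs <- lapply(c("pm10", "no2", "temperature", "wind"), build_var)
  output <- build_var("hospitalizations")
  rt <- respiratory_rule_table()
  rules <- lapply(seq_len(nrow(rt)), function(i) {
    fuzzy_rule(c(pm10 = rt$pm10[i], no2 = rt$no2[i],
                 temperature = rt$temperature[i], wind = rt$wind[i]),
               rt$consequent[i], weight = rt$weight[i])
  })
  fuzzy_inference_system(inputs, output, rules,
                         defuzz_resolution = defuzz_resolution)
}

#' Predict daily hospitalization counts for a series
#'
#' Applies the fuzzy model day by day (predictions are stateless: each
#' day depends only on that day's exposures).  Rows with any missing
#' exposure yield `NA` and are counted in a message.
#'
#' @param fis A [fuzzy_inference_system()], typically [respiratory_fis()].
#' @param series Data frame with one row per day and the model's input
#'   columns (`pm10`, `no2`, `temperature`, `wind` for the default model).
#' @param warn_clamp Warn when exposures fall outside variable domains.
#' @return Numeric vector of crisp predictions, one per row, each within
#'   the output domain; `NA` where exposures are missing.
#' @export
predict_series <- function(fis, series, warn_clamp = TRUE) {
  stopifnot(inherits(fis, "fuzzy_inference_system"))
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("`series` must be a data frame with at least one row", call. = FALSE)
  }
  vars <- names(fis$inputs)
  missing_cols <- setdiff(vars, names(series))
  if (length(missing_cols)) {
    stop(sprintf("series lacks required exposure column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- any(vapply(series[vars], function(x) any(is.infinite(x) | is.nan(x)),
                    logical(1)))
  if (bad) stop("exposure columns contain non-finite values", call. = FALSE)
  pred <- infer_many(fis, series[vars], warn_clamp = warn_clamp)
  n_na <- sum(is.na(pred))
  if (n_na > 0) {
    message(sprintf("%d day(s) with missing exposures: prediction set to NA",
                    n_na))
  }
  pred
}
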
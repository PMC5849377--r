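#' Serialize a fuzzy inference system to a list / YAML / JSON
#'
#' The configuration captures every variable (domain, units, term
#' breakpoints), the rule base and the defuzzification resolution, and
#' round-trips losslessly through [fis_from_config()].
#'
#' @param fis A [fuzzy_inference_system()].
#' @return A plain named list suitable for `yaml::write_yaml()` or
#'   `jsonlite::write_json()`.
#' @export
fis_to_config <- function(fis) {
  var_cfg <- function(v) {
    list(
      domain = as.numeric(v$domain),
      units = v$units,
      terms = lapply(v$terms, function(mf) {
        list(shape = mf$shape, params = as.numeric(mf$params))
      })
    )
  }
  list(
    inputs = lapply(fis$inputs, var_cfg),
    output = stats::setNames(list(var_cfg(fis$output)), fis$output$name),
    rules = lapply(fis$rules, function(r) {
      list(antecedent = as.list(r$antecedent),
           consequent = r$consequent,
           weight = r$weight)
    }),
    defuzz_resolution = fis$defuzz_resolution
  )
}

#' Rebuild a fuzzy inference system from a configuration list
#'
#' @param cfg A list with the structure produced by [fis_to_config()]
#'   (e.g. read back from YAML).
#' @return A [fuzzy_inference_system()].
#' @export
fis_from_config <- function(cfg) {
  build_var <- function(name, vc) {
    terms <- lapply(vc$terms, function(tc) {
      p <- as.numeric(tc$params)
      if (identical(tc$shape, "triangle")) {
        triangle_mf(p[1], p[2], p[4])
      } else {
        trapezoid_mf(p[1], p[2], p[3], p[4])
      }
    })
    linguistic_variable(name, as.numeric(vc$domain), terms, units = vc$units)
  }
  inputs <- Map(build_var, names(cfg$inputs), cfg$inputs)
  out_name <- names(cfg$output)[1]
  output <- build_var(out_name, cfg$output[[1]])
  rules <- lapply(cfg$rules, function(rc) {
    fuzzy_rule(unlist(rc$antecedent), rc$consequent,
               weight = if (is.null(rc$weight)) 1 else rc$weight)
  })
  fuzzy_inference_system(inputs, output, rules,
                         defuzz_resolution = cfg$defuzz_resolution)
}

#' Write / read a model configuration as YAML
#'
#' @param fis A [fuzzy_inference_system()].
#' @param path File path for the YAML document.
#' @return `write_fis_yaml()` returns `path` invisibly; `read_fis_yaml()`
#'   returns the rebuilt system.
#' @export
write_fis_yaml <- function(fis, path) {
  yaml::write_yaml(fis_to_config(fis), path)
  invisible(path)
}

#' @rdname write_fis_yaml
#' @export
read_fis_yaml <- function(path) {
  fis_from_config(yaml::read_yaml(path))
}
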
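#' @importFrom rlang %||% .data
#' @importFrom stats optimize setNames lm coef
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# eigenvalue band inside which invasion fitness is treated as neutral
EPS_NEUTRAL <- 1e-6

utils::globalVariables(c(
  "x", "sex", "gamma", "d", "phi", "resident", "mutant", "lambda",
  "sign_lambda", "x_f_star", "x_m_star", "value", "trait", "axis_value",
  "prev_m", "gamma_m", "gamma_f", "status", "female_higher"
))
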
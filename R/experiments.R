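#' Symmetric-sex ESS curves
#'
#' ESS trait and phenotype values along a joint sweep of either the
#' infection rate (`beta_f = beta_m`) or the virulence
#' (`alpha_f = alpha_m`), with all other parameters identical between the
#' sexes — the baseline in which both sexes evolve to the same strategy.
#'
#' @param model A [tradeoff_model()] shared by the two sexes.
#' @param axis `"beta"` or `"alpha"`: the jointly swept parameter.
#' @param values Axis grid.
#' @param params Base [host_params()] (must be sex-symmetric).
#' @param ... Passed to [find_ess()] via [ess_sweep()].
#' @return An `ess_sweep` tibble with an additional `axis` attribute; the
#'   symmetric setting implies `x_f_star == x_m_star` cell by cell.
#' @examples
#' \donttest{
#' ess_curve(tradeoff_model("i"), "beta", c(0.1, 0.2, 0.3))
#' }
#' @export
ess_curve <- function(model, axis = c("beta", "alpha"), values,
                      params = host_params(), ...) {
  axis <- match.arg(axis)
  if (params$beta_f != params$beta_m || params$alpha_f != params$alpha_m) {
    stop("ess_curve: base parameters must be sex-symmetric")
  }
  sw <- list(values); names(sw) <- axis
  ess_sweep(params, model, sweep = sw, ...)
}

#' ESS surface over sex-specific infection rates or virulences
#'
#' Two-dimensional sweep of the joint ESS over female (first axis) and male
#' (second axis) values of the infection rate `beta` or the virulence
#' `alpha`. Each cell records the ESS traits, both sexes' phenotypes,
#' per-sex prevalence at the ecological equilibrium, and a
#' `female_higher` flag marking cells where females evolve higher
#' immunocompetence than males (recovery rate for models i and iii;
#' fecundity during infection for model ii).
#'
#' @param model A [tradeoff_model()] shared by the two sexes.
#' @param axis `"beta"` or `"alpha"`.
#' @param f_values,m_values Grids for the female / male parameter.
#' @inheritParams ess_curve
#' @return An `ess_sweep` tibble with the extra column `female_higher`.
#' @export
ess_surface <- function(model, axis = c("beta", "alpha"),
                        f_values = seq(0.05, 0.4, length.out = 8),
                        m_values = f_values,
                        params = host_params(), ...) {
  axis <- match.arg(axis)
  sw <- stats::setNames(list(f_values, m_values),
                        paste0(axis, c("_f", "_m")))
  out <- ess_sweep(params, model, sweep = sw, ...)
  out$female_higher <- if (model$kind == "ii") {
    out$phi_f > out$phi_m
  } else {
    out$gamma_f > out$gamma_m
  }
  out
}

#' Turning point of the ES male recovery rate along male susceptibility
#'
#' Under trade-off model (i) the evolutionarily stable male recovery rate
#' first rises and then falls as male susceptibility `beta_m` increases:
#' once males spend more than half their time infected, faster recovery
#' merely hastens reinfection and its constitutive survival cost stops
#' paying. This helper sweeps `beta_m` at fixed `beta_f`, locates the sweep
#' cell with maximal ES male recovery, and reports the male prevalence
#' there — the mechanism predicts a prevalence near 50%.
#'
#' @param params Base [host_params()]; `beta_f` fixed at its value there.
#' @param model A [tradeoff_model()] (model "i" is the setting of interest).
#' @param beta_m_values Male-susceptibility grid.
#' @param ... Passed to [ess_sweep()].
#' @return A list: `sweep` (the `ess_sweep` tibble), `beta_m_at_max`,
#'   `gamma_m_max`, and `prevalence_m_at_max`.
#' @export
recovery_turning_point <- function(params = host_params(),
                                   model = tradeoff_model("i"),
                                   beta_m_values = seq(0.05, 0.4,
                                                       length.out = 8),
                                   ...) {
  sw <- ess_sweep(params, model,
                  sweep = list(beta_m = beta_m_values), ...)
  ok <- !is.na(sw$gamma_m) & sw$status %in% c("interior-ESS", "boundary")
  if (!any(ok)) stop("recovery_turning_point: no successful sweep cells")
  i <- which(sw$gamma_m == max(sw$gamma_m[ok]) & ok)[1]
  list(sweep = sw,
       beta_m_at_max = sw$beta_m[i],
       gamma_m_max = sw$gamma_m[i],
       prevalence_m_at_max = sw$prevalence_m[i])
}
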
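#' Time derivatives of the genotype-resolved SIS system
#'
#' For every genotype `i`, four compartments (susceptible/infected x
#' female/male) follow SIS dynamics with density-dependent (mass-action)
#' transmission: newborns enter the susceptible classes at rate `B_i / 2`
#' per sex, infection occurs at rate `beta_sex * S * I_tot` where
#' `I_tot` sums infected hosts of all genotypes and both sexes (infectivity
#' is independent of sex and genotype), recovery returns hosts to the
#' susceptible class of the same genotype and sex (no acquired immunity),
#' and infected hosts suffer the extra death rate `alpha_sex`.
#'
#' @param state Numeric matrix `n x 4`, columns `S_f`, `I_f`, `S_m`, `I_m`.
#' @inheritParams birth_rates
#' @return Matrix `n x 4` of time derivatives.
#' @export
sis_derivatives <- function(state, space, phen, params, delta = NULL) {
  if (any(state < -1e-8)) stop("sis_derivatives: negative densities")
  state[state < 0] <- 0
  B <- birth_rates(state, space, phen, params, delta = delta)
  I_tot <- sum(state[, 2]) + sum(state[, 4])
  Sf <- state[, 1]; If <- state[, 2]; Sm <- state[, 3]; Im <- state[, 4]
  inf_f <- params$beta_f * Sf * I_tot
  inf_m <- params$beta_m * Sm * I_tot
  cbind(
    S_f = B / 2 - phen$f$d * Sf - inf_f + phen$f$gamma * If,
    I_f = inf_f - (phen$f$d + params$alpha_f + phen$f$gamma) * If,
    S_m = B / 2 - phen$m$d * Sm - inf_m + phen$m$gamma * Im,
    I_m = inf_m - (phen$m$d + params$alpha_m + phen$m$gamma) * Im
  )
}

#' Integrate the genotype-resolved population forward in time
#'
#' @inheritParams sis_derivatives
#' @param times Output time points (passed to [deSolve::ode()]).
#' @return A tibble in long-ish wide form: `time` plus one column per
#'   genotype/compartment, named `<compartment>.g<genotype>`.
#' @export
integrate_population <- function(state, space, phen, params,
                                 times = seq(0, 100, by = 1)) {
  delta <- offspring_array(space)
  y0 <- as.vector(state)
  derivs <- function(t, y, p) {
    m <- matrix(pmax(y, 0), ncol = 4)
    list(as.vector(sis_derivatives(m, space, phen, params, delta)))
  }
  out <- deSolve::ode(y0, times, derivs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  nm <- as.vector(outer(seq_len(space$n), c("S_f", "I_f", "S_m", "I_m"),
                        function(g, comp) paste0(comp, ".g", g)))
  colnames(out) <- c("time", nm)
  tibble::as_tibble(as.data.frame(out))
}

#' Integrate the genotype-resolved system to its attractor
#'
#' Runs the dynamics until the maximum absolute derivative falls below
#' `tol`, then classifies the outcome (extinct / disease-free / endemic)
#' and reports per-sex prevalence.
#'
#' @inheritParams sis_derivatives
#' @param tol Residual tolerance on the max-norm of the derivatives.
#' @param t_max Integration horizon cap.
#' @param eps_ext Density below which the population counts as extinct and
#'   infection as cleared.
#' @return A list of class `sis_equilibrium`; see [equilibrium()].
#' @export
integrate_to_equilibrium <- function(state, space, phen, params,
                                     tol = 1e-9, t_max = 2e4,
                                     eps_ext = 1e-8) {
  if (all(state <= 0)) stop("integrate_to_equilibrium: empty initial state")
  delta <- offspring_array(space)
  derivs <- function(t, y, p) {
    m <- matrix(pmax(y, 0), ncol = 4)
    list(as.vector(sis_derivatives(m, space, phen, params, delta)))
  }
  y <- as.vector(state)
  t_done <- 0; chunk <- 500
  repeat {
    out <- deSolve::ode(y, c(0, chunk), derivs, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    y <- pmax(out[nrow(out), -1], 0)
    t_done <- t_done + chunk
    resid <- max(abs(derivs(0, y, NULL)[[1]]))
    if (resid < tol || t_done >= t_max) break
  }
  m <- matrix(y, ncol = 4, dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
  .classify_equilibrium(m, resid = resid, converged = resid < tol,
                        eps_ext = eps_ext)
}

.classify_equilibrium <- function(m, resid, converged, eps_ext = 1e-8) {
  N <- sum(m)
  If <- sum(m[, "I_f"]); Im <- sum(m[, "I_m"])
  Nf <- sum(m[, "S_f"]) + If; Nm <- sum(m[, "S_m"]) + Im
  type <- if (N < eps_ext) "extinct"
          else if (If + Im < eps_ext) "disease-free"
          else "endemic"
  structure(list(
    state = m, type = type, N = N,
    prevalence_f = if (Nf > 0) If / Nf else NA_real_,
    prevalence_m = if (Nm > 0) Im / Nm else NA_real_,
    converged = converged, residual = resid
  ), class = "sis_equilibrium")
}

#' @export
print.sis_equilibrium <- function(x, ...) {
  cat(sprintf("<sis_equilibrium> %s, N = %.4g, prevalence f/m = %.3g/%.3g (residual %.2g)\n",
              x$type, x$N, x$prevalence_f, x$prevalence_m, x$residual))
  invisible(x)
}

# ---- monomorphic fast path ------------------------------------------------

# derivatives of the 4-compartment monomorphic system; pf/pm are scalar
# phenotype lists. In a monomorphic population the male frequency weight is
# one, so births are b (1 - qN) (S_f + phi_f I_f).
.mono_derivs <- function(y, pf, pm, params) {
  y <- pmax(y, 0)
  Sf <- y[1]; If <- y[2]; Sm <- y[3]; Im <- y[4]
  N <- Sf + If + Sm + Im
  B <- params$b * max(0, 1 - params$q * N) * (Sf + pf$phi * If)
  I <- If + Im
  c(B / 2 - pf$d * Sf - params$beta_f * Sf * I + pf$gamma * If,
    params$beta_f * Sf * I - (pf$d + params$alpha_f + pf$gamma) * If,
    B / 2 - pm$d * Sm - params$beta_m * Sm * I + pm$gamma * Im,
    params$beta_m * Sm * I - (pm$d + params$alpha_m + pm$gamma) * Im)
}

.mono_newton <- function(y, pf, pm, params, tol = 1e-12, max_iter = 30) {
  f <- function(z) .mono_derivs(z, pf, pm, params)
  for (i in seq_len(max_iter)) {
    fy <- f(y)
    if (max(abs(fy)) < tol) break
    J <- matrix(0, 4, 4)
    h <- pmax(abs(y), 1) * 1e-7
    for (j in 1:4) {
      yp <- y; yp[j] <- yp[j] + h[j]
      J[, j] <- (f(yp) - fy) / h[j]
    }
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) break
    ynew <- y + step
    if (any(!is.finite(ynew)) || any(ynew < -1e-6)) break
    y <- pmax(ynew, 0)
  }
  y
}

#' Ecological equilibrium of a monomorphic resident population
#'
#' Fast path for a population fixed for one allele at each locus: the
#' genotype-resolved system collapses to four compartments. The attractor is
#' found by integration (robust against transients) and polished by Newton
#' iteration on the derivative map.
#'
#' @param x_f,x_m Resident trait values in (0, 1).
#' @param params A [host_params()].
#' @param model_f,model_m [tradeoff_model()]s per sex.
#' @param seed_infection If `TRUE` (default) a small infected density is
#'   seeded so the endemic attractor is reached whenever the pathogen can
#'   persist; if `FALSE` the disease-free attractor is computed.
#' @param init Optional length-4 starting state `c(S_f, I_f, S_m, I_m)`
#'   (e.g. a warm start from a neighbouring parameter set).
#' @param tol Residual tolerance (max-norm of derivatives).
#' @param t_max Integration cap before declaring non-convergence.
#' @return A list of class `sis_equilibrium` with elements `state` (1 x 4
#'   matrix), `type`, `N`, `prevalence_f`, `prevalence_m`, `converged`,
#'   `residual`, plus the resident traits, phenotypes, models and
#'   parameters (used downstream by the invasion analysis).
#' @examples
#' eq <- equilibrium(0.5, 0.5, host_params(), tradeoff_model("i"))
#' eq$N
#' @export
equilibrium <- function(x_f, x_m, params, model_f, model_m = model_f,
                        seed_infection = TRUE, init = NULL,
                        tol = 1e-9, t_max = 2e4) {
  stopifnot(x_f > 0, x_f < 1, x_m > 0, x_m < 1)
  pf <- .phen(x_f, model_f, params)
  pm <- .phen(x_m, model_m, params)
  K <- carrying_capacity(params, d_f = pf$d)
  if (K <= 0) {
    m <- matrix(0, 1, 4, dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
    eq <- .classify_equilibrium(m, resid = 0, converged = TRUE)
  } else {
    Sf_df <- K / (1 + pf$d / pm$d); Sm_df <- K - Sf_df
    R0 <- Sf_df * params$beta_f / (pf$d + params$alpha_f + pf$gamma) +
      Sm_df * params$beta_m / (pm$d + params$alpha_m + pm$gamma)
    seed <- 0.01 * K
    if (is.null(init)) {
      s0 <- if (seed_infection) seed else 0
      init <- c(Sf_df - s0 / 2, s0 / 2, Sm_df - s0 / 2, s0 / 2)
    } else if (seed_infection && init[2] + init[4] < 1e-6) {
      # a warm start from a disease-free neighbour must not trap the
      # dynamics on the (possibly unstable) infection-free manifold
      init[2] <- init[2] + seed / 2
      init[4] <- init[4] + seed / 2
    }
    solve_from <- function(y) {
      derivs <- function(t, y, p) list(.mono_derivs(y, pf, pm, params))
      y <- pmax(y, 0); t_done <- 0; chunk <- 400
      repeat {
        out <- deSolve::ode(y, c(0, chunk), derivs, parms = NULL,
                            method = "lsoda", rtol = 1e-10, atol = 1e-12)
        y <- pmax(out[nrow(out), -1], 0)
        t_done <- t_done + chunk
        if (max(abs(.mono_derivs(y, pf, pm, params))) < 1e-6 ||
            t_done >= t_max) break
      }
      .mono_newton(unname(y), pf, pm, params)
    }
    y <- solve_from(init)
    # integration can stall near the disease-free saddle when R0 > 1 and
    # the endemic transient is slow; kick it off the manifold and resolve
    if (seed_infection && R0 > 1 + 1e-9 && y[2] + y[4] < 1e-6) {
      y <- solve_from(y + c(0, seed / 2, 0, seed / 2))
    }
    resid <- max(abs(.mono_derivs(y, pf, pm, params)))
    m <- matrix(y, 1, 4, dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
    eq <- .classify_equilibrium(m, resid = resid, converged = resid < tol)
  }
  eq$x_f <- x_f; eq$x_m <- x_m
  eq$phen_f <- pf; eq$phen_m <- pm
  eq$model_f <- model_f; eq$model_m <- model_m
  eq$params <- params
  eq
}

#' Disease-free carrying capacity
#'
#' At the disease-free equilibrium births balance female deaths, giving the
#' total density `K = (1 - 2 d_f / b) / q`; only the female death rate
#' enters because reproduction is limited by females. Returns 0 (with a
#' warning suppressed into the value) when the population is not viable
#' (`b <= 2 d_f`).
#'
#' @param params A [host_params()].
#' @param d_f Female background death rate (defaults to the baseline `d0`).
#' @return Carrying capacity (density units), clamped at 0.
#' @examples
#' carrying_capacity(host_params()) # 50 at the defaults
#' @export
carrying_capacity <- function(params, d_f = params$d0) {
  max(0, (1 - 2 * d_f / params$b) / params$q)
}

#' Basic reproduction number of the pathogen
#'
#' Next-generation value at the disease-free equilibrium. With susceptible
#' densities `S_f`, `S_m` and mass-action transmission the next-generation
#' matrix is rank one, so
#' `R0 = S_f beta_f / (d_f + alpha_f + gamma_f) + S_m beta_m / (d_m + alpha_m + gamma_m)`.
#'
#' @inheritParams equilibrium
#' @return The basic reproduction number (dimensionless); infection invades
#'   the disease-free population iff `R0 > 1`.
#' @examples
#' basic_reproduction_number(0.5, 0.5, host_params(), tradeoff_model("i"))
#' @export
basic_reproduction_number <- function(x_f, x_m, params, model_f,
                                      model_m = model_f) {
  pf <- .phen(x_f, model_f, params)
  pm <- .phen(x_m, model_m, params)
  K <- carrying_capacity(params, d_f = pf$d)
  if (K <= 0) stop("basic_reproduction_number: population not viable (K = 0)")
  Sf <- K / (1 + pf$d / pm$d); Sm <- K - Sf
  Sf * params$beta_f / (pf$d + params$alpha_f + pf$gamma) +
    Sm * params$beta_m / (pm$d + params$alpha_m + pm$gamma)
}
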
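#' Best mutant response at one locus
#'
#' Finds the mutant allele value that maximises invasion fitness against the
#' given resident, by a coarse scan of candidate values followed by local
#' golden-section refinement around the scan optimum. Ties (no mutant beats
#' the neutral band) resolve to the resident value.
#'
#' @inheritParams invasion_fitness
#' @param locus `"f"` or `"m"`.
#' @param candidates Coarse candidate grid; default 21 points spanning
#'   (0.01, 0.99).
#' @param refine Refine around the scan optimum with [stats::optimize()].
#' @return A list: `value` (the best response), `lambda` (its invasion
#'   fitness), `at_edge` (whether the optimum sits on the grid boundary).
#' @export
best_response <- function(x_f, x_m, locus = c("f", "m"), params,
                          model_f, model_m = model_f, res_eq = NULL,
                          candidates = seq(0.01, 0.99, length.out = 21),
                          refine = TRUE, eps_neutral = EPS_NEUTRAL) {
  locus <- match.arg(locus)
  res_eq <- res_eq %||% equilibrium(x_f, x_m, params, model_f, model_m)
  if (!res_eq$converged) stop("best_response: resident equilibrium failed to converge")
  if (res_eq$type == "extinct") stop("best_response: resident population extinct")
  fit <- function(m) .dominant_eigenvalue(invasion_matrix(res_eq, locus, m))
  lam <- vapply(candidates, fit, numeric(1))
  i <- which.max(lam)
  best <- candidates[i]; best_lam <- lam[i]
  if (refine) {
    lo <- if (i > 1) candidates[i - 1] else max(1e-4, candidates[1] / 2)
    hi <- if (i < length(candidates)) candidates[i + 1] else
      1 - (1 - candidates[length(candidates)]) / 2
    opt <- stats::optimize(fit, c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (opt$objective > best_lam) {
      best <- opt$maximum; best_lam <- opt$objective
    }
  }
  resident_value <- if (locus == "f") res_eq$x_f else res_eq$x_m
  if (best_lam <= eps_neutral) { # nothing invades: stay
    best <- resident_value
    best_lam <- 0
  }
  list(value = best, lambda = best_lam,
       at_edge = i == 1L || i == length(candidates))
}

#' Search for the joint evolutionarily stable strategy
#'
#' Alternates best mutant responses at the two sex-specific loci
#' (Gauss--Seidel over loci, each step recomputing the resident ecological
#' equilibrium) until the resident is its own best response at both loci.
#' The reported fixed point is then verified on a fine mutant grid at both
#' loci; the largest mutant eigenvalue found is returned as a
#' non-invasibility certificate. Cycling triggers damped (half-step)
#' updates; persistent cycling yields status `"not-found"`.
#'
#' @inheritParams invasion_fitness
#' @param init Length-2 start `c(x_f, x_m)`; default the centre of the trait
#'   square.
#' @param tol Convergence tolerance on trait values (default 1e-4).
#' @param max_iter Maximum best-response sweeps.
#' @param verify_n Points per locus in the verification grid (default 101).
#' @param edge Margin defining the boundary of the searchable square.
#' @return A list of class `ess_result`: `x_f_star`, `x_m_star`, per-sex
#'   phenotypes, equilibrium diagnostics (`N`, `prevalence_f`,
#'   `prevalence_m`, `type`), `status` (`"interior-ESS"`, `"boundary"`,
#'   `"not-found"`), `certificate` (max mutant eigenvalue on the
#'   verification grid), `convergence_stable`, and `iterations`.
#' @examples
#' \donttest{
#' fit <- find_ess(host_params(), tradeoff_model("i"))
#' tidy(fit)
#' }
#' @export
find_ess <- function(params, model_f, model_m = model_f,
                     init = c(0.5, 0.5), tol = 1e-4, max_iter = 100,
                     verify_n = 101, edge = 0.01,
                     eps_neutral = EPS_NEUTRAL) {
  x <- init
  status <- "not-found"
  eq <- NULL
  # adaptive damping: a full best-response step is taken while the update
  # sequence at a locus is monotone; once it alternates sign (overshoot
  # around the singular point) the step weight is halved, down to 1/8
  w <- c(1, 1)
  last_step <- c(0, 0)
  for (iter in seq_len(max_iter)) {
    x_old <- x
    for (loc in c("f", "m")) {
      eq <- equilibrium(x[1], x[2], params, model_f, model_m,
                        init = if (!is.null(eq)) as.vector(eq$state) else NULL)
      if (eq$type == "extinct" || !eq$converged) {
        return(.ess_result(x, params, model_f, model_m, status = "not-found",
                           certificate = NA_real_, iterations = iter))
      }
      br <- best_response(x[1], x[2], loc, params, model_f, model_m,
                          res_eq = eq, eps_neutral = eps_neutral)
      i <- if (loc == "f") 1L else 2L
      step <- w[i] * (br$value - x[i])
      if (last_step[i] * step < 0) w[i] <- max(w[i] / 2, 1 / 8)
      step <- w[i] * (br$value - x[i])
      last_step[i] <- step
      x[i] <- min(max(x[i] + step, 1e-3), 1 - 1e-3)
    }
    if (max(abs(x - x_old)) < tol) { status <- "converged"; break }
  }
  if (status == "converged" && all(x > 2e-3 & x < 1 - 2e-3)) {
    x <- .polish_ess(x, params, model_f, model_m, edge = edge)
  }
  if (status != "converged") {
    return(.ess_result(x, params, model_f, model_m, status = "not-found",
                       certificate = NA_real_, iterations = iter))
  }
  at_boundary <- any(x < edge | x > 1 - edge)
  # verification: no mutant on a fine grid at either locus may invade
  eq <- equilibrium(x[1], x[2], params, model_f, model_m)
  grid <- seq(edge, 1 - edge, length.out = verify_n)
  cert <- max(vapply(c("f", "m"), function(loc)
    max(vapply(grid, function(m)
      .dominant_eigenvalue(invasion_matrix(eq, loc, m)), numeric(1))),
    numeric(1)))
  status <- if (at_boundary) "boundary"
            else if (cert <= eps_neutral) "interior-ESS"
            else "not-found"
  .ess_result(x, params, model_f, model_m, status = status,
              certificate = cert, iterations = iter, eq = eq)
}

.ess_result <- function(x, params, model_f, model_m, status, certificate,
                        iterations, eq = NULL) {
  if (is.null(eq)) {
    eq <- tryCatch(equilibrium(x[1], x[2], params, model_f, model_m),
                   error = function(e) NULL)
  }
  pf <- .phen(x[1], model_f, params); pm <- .phen(x[2], model_m, params)
  cs <- if (status %in% c("interior-ESS", "boundary") && !is.null(eq)) {
    .convergence_stable(x, params, model_f, model_m)
  } else NA
  structure(list(
    x_f_star = x[1], x_m_star = x[2],
    gamma_f = pf$gamma, d_f = pf$d, phi_f = pf$phi,
    gamma_m = pm$gamma, d_m = pm$d, phi_m = pm$phi,
    N = if (!is.null(eq)) eq$N else NA_real_,
    prevalence_f = if (!is.null(eq)) eq$prevalence_f else NA_real_,
    prevalence_m = if (!is.null(eq)) eq$prevalence_m else NA_real_,
    eq_type = if (!is.null(eq)) eq$type else NA_character_,
    status = status, certificate = certificate,
    convergence_stable = cs, iterations = iterations,
    params = params, model_f = model_f, model_m = model_m
  ), class = "ess_result")
}

# selection gradient at both loci for a given resident: d lambda / d mutant
# evaluated at mutant = resident (central differences, shared equilibrium)
.ess_gradient <- function(x, params, model_f, model_m, h = 1e-4) {
  eq <- equilibrium(x[1], x[2], params, model_f, model_m)
  if (!eq$converged || eq$type == "extinct") return(c(NA_real_, NA_real_))
  g <- function(loc, v) {
    dm <- min(h, v / 2, (1 - v) / 2)
    (.dominant_eigenvalue(invasion_matrix(eq, loc, v + dm)) -
       .dominant_eigenvalue(invasion_matrix(eq, loc, v - dm))) / (2 * dm)
  }
  c(g("f", x[1]), g("m", x[2]))
}

# Newton refinement of the singular point: root of the two-locus selection
# gradient, reached from the best-response fixed point. Falls back to the
# unpolished value if the gradient or Jacobian degenerates.
.polish_ess <- function(x, params, model_f, model_m, edge = 0.01,
                        max_iter = 12) {
  x0 <- x
  G <- .ess_gradient(x, params, model_f, model_m)
  if (any(is.na(G))) return(x0)
  for (it in seq_len(max_iter)) {
    if (max(abs(G)) < 1e-9) break
    h <- 1e-3
    J <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + h
      Gp <- .ess_gradient(xp, params, model_f, model_m)
      J[, j] <- (Gp - G) / h
    }
    if (any(is.na(J))) return(x0)
    step <- tryCatch(solve(J, -G), error = function(e) NULL)
    if (is.null(step)) return(x0)
    step <- pmin(pmax(step, -0.05), 0.05) # trust region
    xn <- pmin(pmax(x + step, edge), 1 - edge)
    Gn <- .ess_gradient(xn, params, model_f, model_m)
    if (any(is.na(Gn))) return(x0)
    if (max(abs(Gn)) > max(abs(G)) && max(abs(step)) < 1e-8) break
    x <- xn; G <- Gn
  }
  if (max(abs(G)) < 1e-6 || max(abs(x - x0)) < 0.02) x else x0
}

# selection gradient points towards the singular point on both sides?
.convergence_stable <- function(x, params, model_f, model_m, h = 0.01) {
  grad <- function(x_f, x_m, loc) {
    eq <- equilibrium(x_f, x_m, params, model_f, model_m)
    v <- if (loc == "f") x_f else x_m
    dm <- min(h / 2, v / 2, (1 - v) / 2)
    (.dominant_eigenvalue(invasion_matrix(eq, loc, v + dm)) -
       .dominant_eigenvalue(invasion_matrix(eq, loc, v - dm))) / (2 * dm)
  }
  ok <- TRUE
  for (loc in c("f", "m")) {
    i <- if (loc == "f") 1L else 2L
    lo <- x; lo[i] <- max(x[i] - h, 1e-3)
    hi <- x; hi[i] <- min(x[i] + h, 1 - 1e-3)
    g_lo <- tryCatch(grad(lo[1], lo[2], loc), error = function(e) NA_real_)
    g_hi <- tryCatch(grad(hi[1], hi[2], loc), error = function(e) NA_real_)
    if (is.na(g_lo) || is.na(g_hi)) return(NA)
    ok <- ok && (g_lo > -1e-6) && (g_hi < 1e-6)
  }
  ok
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf("<ess_result> %s: x_f* = %.4f, x_m* = %.4f (certificate %.2g, %d iterations)\n",
              x$status, x$x_f_star, x$x_m_star, x$certificate, x$iterations))
  cat(sprintf("  female: gamma = %.3g, d = %.3g, phi = %.3g | male: gamma = %.3g, d = %.3g, phi = %.3g\n",
              x$gamma_f, x$d_f, x$phi_f, x$gamma_m, x$d_m, x$phi_m))
  cat(sprintf("  equilibrium: %s, N = %.4g, prevalence f/m = %.3g/%.3g\n",
              x$eq_type, x$N, x$prevalence_f, x$prevalence_m))
  invisible(x)
}

#' @export
tidy.ess_result <- function(x, ...) {
  tibble::tibble(
    term = c("x_f_star", "x_m_star", "gamma_f", "gamma_m", "d_f", "d_m",
             "phi_f", "phi_m"),
    estimate = c(x$x_f_star, x$x_m_star, x$gamma_f, x$gamma_m, x$d_f, x$d_m,
                 x$phi_f, x$phi_m)
  )
}

#' @export
glance.ess_result <- function(x, ...) {
  tibble::tibble(
    status = x$status, certificate = x$certificate,
    convergence_stable = x$convergence_stable,
    N = x$N, prevalence_f = x$prevalence_f, prevalence_m = x$prevalence_m,
    eq_type = x$eq_type, iterations = x$iterations
  )
}

# one flat row per ESS fit, used by the sweep routines
.ess_row <- function(fit) {
  tibble::tibble(
    x_f_star = fit$x_f_star, x_m_star = fit$x_m_star,
    gamma_f = fit$gamma_f, gamma_m = fit$gamma_m,
    d_f = fit$d_f, d_m = fit$d_m, phi_f = fit$phi_f, phi_m = fit$phi_m,
    N = fit$N, prevalence_f = fit$prevalence_f,
    prevalence_m = fit$prevalence_m,
    status = fit$status, certificate = fit$certificate
  )
}

#' Sweep the ESS over ecological parameters
#'
#' Finds the joint ESS at every point of a one- or two-dimensional grid of
#' parameter values, warm-starting each search from the previous cell's
#' solution. The axis names are `host_params` fields, plus the aliases
#' `beta` / `alpha` which set both sexes jointly (the symmetric-sex
#' setting). Cells where the search fails are reported with `NA` traits and
#' their status, never interpolated.
#'
#' @param params Base [host_params()]; swept fields are overridden per cell.
#' @inheritParams find_ess
#' @param sweep Named list of one or two numeric vectors, e.g.
#'   `list(beta_m = seq(0.05, 0.4, length.out = 8))` or
#'   `list(beta_f = ..., beta_m = ...)` (crossed).
#' @param ... Passed on to [find_ess()].
#' @return A tibble of class `ess_sweep`: one row per grid cell with the
#'   axis value(s), ESS traits, per-sex phenotypes, equilibrium diagnostics
#'   and search status.
#' @examples
#' \donttest{
#' ess_sweep(host_params(), tradeoff_model("i"),
#'           sweep = list(beta = c(0.15, 0.25)))
#' }
#' @export
ess_sweep <- function(params, model_f, model_m = model_f, sweep,
                      init = c(0.5, 0.5), ...) {
  stopifnot(is.list(sweep), length(sweep) %in% 1:2, !is.null(names(sweep)))
  grid <- do.call(tidyr::expand_grid, sweep)
  last <- init
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    p <- do.call(update_params, c(list(params), cell))
    fit <- tryCatch(
      find_ess(p, model_f, model_m, init = last, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      row <- .ess_row(.ess_result(init, p, model_f, model_m,
                                  status = "not-found",
                                  certificate = NA_real_, iterations = 0L))
      row[, c("x_f_star", "x_m_star")] <- NA_real_
    } else {
      row <- .ess_row(fit)
      if (fit$status %in% c("interior-ESS", "boundary")) {
        last <- c(fit$x_f_star, fit$x_m_star)
      } else {
        row[setdiff(names(row), c("status", "certificate"))] <- NA_real_
      }
    }
    rows[[i]] <- dplyr::bind_cols(grid[i, , drop = FALSE], row)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ess_sweep", class(out)),
            axes = names(sweep))
}
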
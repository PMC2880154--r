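#' Linearised dynamics of a rare mutant allele
#'
#' Builds the 4 x 4 matrix governing the initial growth of the classes that
#' carry a rare mutant allele introduced at one locus into a resident
#' homozygote population at its ecological equilibrium. At first order in
#' rarity only single-heterozygote carriers matter (mutant homozygotes and
#' double heterozygotes are quadratic in the mutant frequency), so the
#' mutant subsystem has four compartments: susceptible / infected x female /
#' male heterozygotes. The heterozygote expresses the mean of resident and
#' mutant allele values at the mutated locus; at the other locus it is
#' resident-homozygous.
#'
#' Birth inflow is linearised around the resident equilibrium: heterozygote
#' mothers pass the mutant allele to half their offspring, and heterozygote
#' fathers sire a share `M' / M_hat` of the resident females' offspring
#' (their effective weight relative to the resident male pool), again with
#' Mendelian halving.
#'
#' @param res_eq A converged, non-extinct [equilibrium()] of the resident.
#' @param locus `"f"` (female-expressed) or `"m"` (male-expressed) locus.
#' @param mutant Mutant allele trait value in (0, 1).
#' @return A 4 x 4 matrix over (`S_f'`, `I_f'`, `S_m'`, `I_m'`).
#' @export
invasion_matrix <- function(res_eq, locus = c("f", "m"), mutant) {
  locus <- match.arg(locus)
  stopifnot(inherits(res_eq, "sis_equilibrium"))
  if (!res_eq$converged) stop("invasion_matrix: resident equilibrium did not converge")
  if (res_eq$type == "extinct") stop("invasion_matrix: resident population is extinct")
  if (mutant <= 0 || mutant >= 1) stop("invasion_matrix: mutant value outside (0, 1)")
  params <- res_eq$params
  # mutant-class phenotypes: heterozygote at the mutated locus, resident at
  # the other; the silent locus does not alter the other sex's phenotype
  if (locus == "f") {
    pf <- .phen((res_eq$x_f + mutant) / 2, res_eq$model_f, params)
    pm <- res_eq$phen_m
  } else {
    pf <- res_eq$phen_f
    pm <- .phen((res_eq$x_m + mutant) / 2, res_eq$model_m, params)
  }
  st <- res_eq$state
  Itot <- st[, "I_f"] + st[, "I_m"]
  Fhat <- st[, "S_f"] + res_eq$phen_f$phi * st[, "I_f"]
  Mhat <- st[, "S_m"] + res_eq$phen_m$phi * st[, "I_m"]
  r <- params$b * max(0, 1 - params$q * res_eq$N)
  if (Mhat <= 0) stop("invasion_matrix: resident male pool has zero weight")
  # d(B'/2)/d(mutant classes): maternal route r/4 * (1, phi_f', 0, 0),
  # paternal route r F_hat / (4 M_hat) * (0, 0, 1, phi_m')
  bS <- r / 4; bI <- r * pf$phi / 4
  cS <- r * Fhat / (4 * Mhat); cI <- cS * pm$phi
  matrix(c(
    bS - pf$d - params$beta_f * Itot, bI + pf$gamma, cS, cI,
    params$beta_f * Itot, -(pf$d + params$alpha_f + pf$gamma), 0, 0,
    bS, bI, cS - pm$d - params$beta_m * Itot, cI + pm$gamma,
    0, 0, params$beta_m * Itot, -(pm$d + params$alpha_m + pm$gamma)
  ), nrow = 4, byrow = TRUE,
  dimnames = rep(list(c("S_f", "I_f", "S_m", "I_m")), 2))
}

# dominant eigenvalue = largest real part (complex pairs compared by real part)
.dominant_eigenvalue <- function(J) max(Re(eigen(J, only.values = TRUE)$values))

#' Invasion fitness of a rare mutant allele
#'
#' Dominant eigenvalue of the linearised mutant subsystem
#' ([invasion_matrix()]) of a mutant allele introduced at low frequency into
#' the resident homozygote population at equilibrium. A positive dominant
#' eigenvalue means the allele spreads; values within `eps_neutral` of zero
#' are treated as neutral (a resident "invading" itself sits exactly on this
#' band).
#'
#' @param x_f,x_m Resident trait values.
#' @inheritParams invasion_matrix
#' @inheritParams equilibrium
#' @param res_eq Optional precomputed resident [equilibrium()] (cached by
#'   grid routines; must match `x_f`, `x_m`).
#' @param eps_neutral Half-width of the neutral eigenvalue band.
#' @return A list of class `invasion_result`: `x_f`, `x_m`, `locus`,
#'   `mutant`, `lambda` (dominant eigenvalue), `invades`.
#' @examples
#' p <- host_params(); m <- tradeoff_model("i")
#' invasion_fitness(0.5, 0.5, locus = "f", mutant = 0.6, params = p, model_f = m)
#' @export
invasion_fitness <- function(x_f, x_m, locus = c("f", "m"), mutant,
                             params, model_f, model_m = model_f,
                             res_eq = NULL, eps_neutral = EPS_NEUTRAL) {
  locus <- match.arg(locus)
  res_eq <- res_eq %||% equilibrium(x_f, x_m, params, model_f, model_m)
  J <- invasion_matrix(res_eq, locus, mutant)
  lam <- .dominant_eigenvalue(J)
  structure(list(x_f = res_eq$x_f, x_m = res_eq$x_m, locus = locus,
                 mutant = mutant, lambda = lam,
                 invades = lam > eps_neutral),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("<invasion_result> resident (%.4g, %.4g), mutant %s-locus %.4g: lambda = %.4g (%s)\n",
              x$x_f, x$x_m, x$locus, x$mutant, x$lambda,
              if (x$invades) "invades" else "does not invade"))
  invisible(x)
}

#' Pairwise-invasion plot grid
#'
#' Sign map of invasion fitness over a resident x mutant grid at one locus,
#' the other locus held fixed and monomorphic. The resident equilibrium is
#' computed once per grid column. Residents whose equilibrium fails to
#' converge are reported with `NA` fitness, not fabricated.
#'
#' @inheritParams invasion_fitness
#' @param locus Locus under study (`"f"` or `"m"`).
#' @param resident_grid,mutant_grid Trait grids strictly inside (0, 1);
#'   `mutant_grid` defaults to `resident_grid`.
#' @param fixed_other Trait value at the non-focal locus.
#' @return A tibble of class `pip_grid` with columns `resident`, `mutant`,
#'   `lambda` and `sign_lambda` (-1, 0, +1; 0 within the neutral band).
#' @examples
#' pg <- pip_grid("f", host_params(), tradeoff_model("i"),
#'                resident_grid = seq(0.2, 0.8, length.out = 5))
#' @export
pip_grid <- function(locus = c("f", "m"), params, model_f, model_m = model_f,
                     resident_grid, mutant_grid = resident_grid,
                     fixed_other = 0.5, eps_neutral = EPS_NEUTRAL) {
  locus <- match.arg(locus)
  stopifnot(all(resident_grid > 0 & resident_grid < 1),
            all(mutant_grid > 0 & mutant_grid < 1))
  rows <- purrr::map_dfr(resident_grid, function(r) {
    x_f <- if (locus == "f") r else fixed_other
    x_m <- if (locus == "m") r else fixed_other
    eq <- tryCatch(equilibrium(x_f, x_m, params, model_f, model_m),
                   error = function(e) NULL)
    if (is.null(eq) || !eq$converged || eq$type == "extinct") {
      return(tibble::tibble(resident = r, mutant = mutant_grid,
                            lambda = NA_real_))
    }
    lam <- vapply(mutant_grid, function(m)
      .dominant_eigenvalue(invasion_matrix(eq, locus, m)), numeric(1))
    tibble::tibble(resident = r, mutant = mutant_grid, lambda = lam)
  })
  rows$sign_lambda <- ifelse(is.na(rows$lambda), NA_real_,
                             ifelse(rows$lambda > eps_neutral, 1,
                                    ifelse(rows$lambda < -eps_neutral, -1, 0)))
  structure(rows, class = c("pip_grid", class(rows)),
            locus = locus, fixed_other = fixed_other)
}
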
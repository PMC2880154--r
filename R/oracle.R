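#' Nonlinear rare-mutant invasion simulation
#'
#' Brute-force check of the eigenvalue invasion criterion: the full
#' genotype-resolved nonlinear system (resident homozygote, heterozygote and
#' mutant homozygote at the mutated locus; monomorphic at the other; 12
#' equations) is integrated from the resident equilibrium perturbed by
#' mutant heterozygotes at allele frequency `freq0`, and the verdict is read
#' off the slope of the log mutant-allele frequency over the final third of
#' the horizon. Integration stops early once the log frequency has moved by
#' more than 3 (decisive growth or decline).
#'
#' @inheritParams invasion_fitness
#' @param locus Mutated locus, `"f"` or `"m"`.
#' @param mutant Mutant allele value in (0, 1).
#' @param freq0 Initial mutant allele frequency (must be at most 1e-4 so the
#'   linear regime applies). Default 1e-5.
#' @param horizon Simulation horizon in time units. Default 2000.
#' @param slope_neutral Verdict threshold: absolute log-frequency slope per
#'   unit time below this is `"neutral"`.
#' @return A list of class `polymorphic_run`: `verdict` (`"grew"`,
#'   `"declined"`, `"neutral"`, or `"extinct"`), `slope`, and a `trajectory`
#'   tibble (`time`, `freq`, `N`).
#' @examples
#' \donttest{
#' simulate_invasion(0.5, 0.5, locus = "f", mutant = 0.6,
#'                   params = host_params(), model_f = tradeoff_model("i"))
#' }
#' @export
simulate_invasion <- function(x_f, x_m, locus = c("f", "m"), mutant,
                              params, model_f, model_m = model_f,
                              freq0 = 1e-5, horizon = 2000,
                              slope_neutral = 1e-4, res_eq = NULL) {
  locus <- match.arg(locus)
  stopifnot(freq0 > 0, freq0 <= 1e-4)
  res_eq <- res_eq %||% equilibrium(x_f, x_m, params, model_f, model_m)
  if (res_eq$type == "extinct") stop("simulate_invasion: resident extinct")
  space <- if (locus == "f") {
    genotype_space(c(res_eq$x_f, mutant), res_eq$x_m)
  } else {
    genotype_space(res_eq$x_f, c(res_eq$x_m, mutant))
  }
  gt <- space$genotypes
  res_hom <- which(gt$fa == 1 & gt$fb == 1 & gt$ma == 1 & gt$mb == 1)
  if (locus == "f") {
    het <- which(gt$fa == 1 & gt$fb == 2)
    mut_hom <- which(gt$fa == 2 & gt$fb == 2)
    mut_count <- (gt$fa == 2) + (gt$fb == 2)
  } else {
    het <- which(gt$ma == 1 & gt$mb == 2)
    mut_hom <- which(gt$ma == 2 & gt$mb == 2)
    mut_count <- (gt$ma == 2) + (gt$mb == 2)
  }
  phen <- genotype_phenotypes(space, res_eq$model_f, res_eq$model_m, params)
  delta <- offspring_array(space)
  state <- matrix(0, space$n, 4,
                  dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
  # heterozygote frequency ~ 2 freq0 at Hardy-Weinberg rarity
  state[res_hom, ] <- (1 - 2 * freq0) * res_eq$state
  state[het, ] <- 2 * freq0 * res_eq$state
  allele_freq <- function(m) {
    tot <- rowSums(m)
    sum(mut_count * tot) / (2 * sum(tot))
  }
  derivs <- function(t, y, p) {
    m <- matrix(pmax(y, 0), ncol = 4)
    list(as.vector(sis_derivatives(m, space, phen, params, delta)))
  }
  step <- horizon / 60
  times <- c(0)
  freqs <- c(allele_freq(state))
  Ns <- c(sum(state))
  y <- as.vector(state)
  t_now <- 0
  while (t_now < horizon) {
    out <- deSolve::ode(y, c(0, step), derivs, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-14)
    y <- pmax(out[nrow(out), -1], 0)
    t_now <- t_now + step
    m <- matrix(y, ncol = 4)
    times <- c(times, t_now)
    freqs <- c(freqs, allele_freq(m))
    Ns <- c(Ns, sum(m))
    if (Ns[length(Ns)] < 1e-8) break
    if (abs(log(freqs[length(freqs)]) - log(freq0)) > 3) break
  }
  traj <- tibble::tibble(time = times, freq = freqs, N = Ns)
  if (Ns[length(Ns)] < 1e-8) {
    verdict <- "extinct"; slope <- NA_real_
  } else {
    tail_idx <- which(times >= times[length(times)] * 2 / 3)
    if (length(tail_idx) < 2) tail_idx <- utils::tail(seq_along(times), 2)
    fit <- stats::lm(log(freqs[tail_idx]) ~ times[tail_idx])
    slope <- unname(stats::coef(fit)[2])
    verdict <- if (abs(slope) < slope_neutral) "neutral"
               else if (slope > 0) "grew" else "declined"
  }
  structure(list(verdict = verdict, slope = slope, trajectory = traj,
                 locus = locus, mutant = mutant, freq0 = freq0),
            class = "polymorphic_run")
}

#' @export
print.polymorphic_run <- function(x, ...) {
  cat(sprintf("<polymorphic_run> %s-locus mutant %.4g from freq %.1g: %s (slope %.3g)\n",
              x$locus, x$mutant, x$freq0, x$verdict, x$slope))
  invisible(x)
}

#' Agreement between eigenvalue criterion and nonlinear simulation
#'
#' Draws random (resident, mutant, parameters) triples, scores each with
#' both the linearised invasion fitness and the nonlinear rare-mutant
#' simulation, and reports the agreement rate among decisive cases. Triples
#' whose eigenvalue lies inside `neutral_band` are excluded from the rate
#' (both methods then sit in numerical-neutrality territory).
#'
#' @param n Number of random triples.
#' @param params Base parameter set; `beta_f`, `beta_m`, `alpha_f`,
#'   `alpha_m` are redrawn per triple.
#' @param seed RNG seed.
#' @param beta_range,alpha_range Sampling ranges for per-triple epidemiology.
#' @param neutral_band Eigenvalue half-width excluded as neutral; matches
#'   the oracle's slope threshold scale.
#' @return A list of class `oracle_report`: `agreement` (fraction),
#'   `n_decisive`, and a per-triple tibble `cases`.
#' @export
invasion_agreement <- function(n = 200, params = host_params(), seed = 1,
                               beta_range = c(0.05, 0.4),
                               alpha_range = c(0.2, 2),
                               neutral_band = 1e-4) {
  set.seed(seed)
  kinds <- c("i", "ii", "iii")
  cases <- purrr::map_dfr(seq_len(n), function(i) {
    p <- update_params(params,
                       beta_f = stats::runif(1, beta_range[1], beta_range[2]),
                       beta_m = stats::runif(1, beta_range[1], beta_range[2]),
                       alpha_f = stats::runif(1, alpha_range[1], alpha_range[2]),
                       alpha_m = stats::runif(1, alpha_range[1], alpha_range[2]))
    model <- tradeoff_model(sample(kinds, 1))
    x_f <- stats::runif(1, 0.15, 0.85); x_m <- stats::runif(1, 0.15, 0.85)
    locus <- sample(c("f", "m"), 1)
    res_val <- if (locus == "f") x_f else x_m
    mut <- min(0.95, max(0.05, res_val + stats::runif(1, -0.15, 0.15)))
    eq <- tryCatch(equilibrium(x_f, x_m, p, model), error = function(e) NULL)
    if (is.null(eq) || !eq$converged || eq$type == "extinct") {
      return(tibble::tibble(i = i, lambda = NA_real_, verdict = NA_character_,
                            agree = NA))
    }
    lam <- invasion_fitness(x_f, x_m, locus, mut, p, model,
                            res_eq = eq)$lambda
    run <- simulate_invasion(x_f, x_m, locus, mut, p, model, res_eq = eq)
    agree <- if (abs(lam) < neutral_band || run$verdict == "extinct") {
      NA
    } else {
      (lam > 0 && run$verdict == "grew") ||
        (lam < 0 && run$verdict == "declined")
    }
    tibble::tibble(i = i, model = model$kind, locus = locus,
                   x_f = x_f, x_m = x_m, mutant = mut,
                   lambda = lam, verdict = run$verdict, agree = agree)
  })
  decisive <- cases$agree[!is.na(cases$agree)]
  structure(list(agreement = mean(decisive), n_decisive = length(decisive),
                 cases = cases),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("<oracle_report> %.1f%% agreement on %d decisive triples\n",
              100 * x$agreement, x$n_decisive))
  invisible(x)
}
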
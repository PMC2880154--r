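#' Life-history trade-off models
#'
#' A trade-off model maps a sex-specific proxy trait `x` in (0, 1) to the
#' phenotype triple (recovery rate `gamma`, background death rate `d`,
#' relative fecundity during infection `phi`). Three built-in models trade
#' different pairs of traits:
#'
#' * **model (i)** — resistance with a constitutive cost: `gamma` increases
#'   with `x` and so does the background death rate `d`; `phi = 1`.
#' * **model (ii)** — tolerance with a constitutive cost: fecundity during
#'   infection `phi` increases with `x`, and so does `d`; `gamma = gamma0`.
#' * **model (iii)** — resistance with a facultative cost: `gamma` increases
#'   with `x` while `phi` decreases; `d = d0`.
#'
#' Default shapes (all anchored so the baseline values `gamma0`, `d0` are
#' attainable, and chosen so that benefits saturate while costs accelerate,
#' which is what lets interior ESSs exist):
#' `Gamma(x) = 2 gamma0 x / (x + 0.5)` (saturating; equal to `gamma0` at
#' `x = 1/2`, bounded by `2 gamma0` so the pathogen is never driven
#' extinct by host evolution alone),
#' `D(x) = d0 / (1 - x^2)`, `Phi(x) = x`, `Psi(x) = 1 - x`. Alternative
#' families plug in through the `recovery`, `mortality`, `fecundity` and
#' `infected_fecundity` arguments, each a `function(x, gamma0, d0)`;
#' this also supports sex-specific trade-offs (pass different models for
#' the two sexes to the downstream analyses).
#'
#' @param kind One of `"i"`, `"ii"`, `"iii"`.
#' @param recovery Shape of the recovery benefit `Gamma(x)` (models i, iii).
#' @param mortality Shape of the mortality cost `D(x)` (models i, ii).
#' @param fecundity Shape of the tolerance benefit `Phi(x)` (model ii).
#' @param infected_fecundity Shape of the facultative cost `Psi(x)`
#'   (model iii).
#' @return An object of class `tradeoff_model`.
#' @examples
#' tradeoff_model("i")
#' # a steeper mortality cost:
#' tradeoff_model("i", mortality = function(x, gamma0, d0) d0 / (1 - x^2)^2)
#' @export
tradeoff_model <- function(kind = c("i", "ii", "iii"),
                           recovery = NULL, mortality = NULL,
                           fecundity = NULL, infected_fecundity = NULL) {
  kind <- match.arg(kind)
  m <- list(
    kind = kind,
    recovery = recovery %||% function(x, gamma0, d0) 2 * gamma0 * x / (x + 0.5),
    mortality = mortality %||% function(x, gamma0, d0) d0 / (1 - x^2),
    fecundity = fecundity %||% function(x, gamma0, d0) x,
    infected_fecundity = infected_fecundity %||% function(x, gamma0, d0) 1 - x
  )
  structure(m, class = "tradeoff_model")
}

#' @export
print.tradeoff_model <- function(x, ...) {
  pair <- switch(x$kind,
    i = "recovery gamma vs background mortality d (constitutive cost)",
    ii = "infected fecundity phi vs background mortality d (constitutive cost)",
    iii = "recovery gamma vs infected fecundity phi (facultative cost)")
  cat(sprintf("<tradeoff_model %s> %s\n", x$kind, pair))
  invisible(x)
}

# scalar/vector core used on hot paths; returns a plain list of vectors
.phen <- function(x, model, params) {
  g0 <- params$gamma0; d0 <- params$d0
  switch(model$kind,
    i = list(gamma = model$recovery(x, g0, d0),
             d = model$mortality(x, g0, d0),
             phi = rep(1, length(x))),
    ii = list(gamma = rep(g0, length(x)),
              d = model$mortality(x, g0, d0),
              phi = model$fecundity(x, g0, d0)),
    iii = list(gamma = model$recovery(x, g0, d0),
               d = rep(d0, length(x)),
               phi = model$infected_fecundity(x, g0, d0)))
}

#' Phenotype under a trade-off model
#'
#' Evaluates the genotype-to-phenotype map at trait value(s) `x`.
#'
#' @param x Trait value(s), strictly inside (0, 1).
#' @param model A [tradeoff_model()].
#' @param params A [host_params()] supplying the baselines `gamma0`, `d0`.
#' @return A tibble with columns `x`, `gamma`, `d`, `phi`.
#' @examples
#' phenotype_at(c(0.25, 0.5, 0.75), tradeoff_model("iii"), host_params())
#' @export
phenotype_at <- function(x, model, params = host_params()) {
  stopifnot(inherits(model, "tradeoff_model"))
  if (any(!is.finite(x) | x <= 0 | x >= 1)) {
    stop("phenotype_at: trait values must lie strictly in (0, 1)")
  }
  p <- .phen(x, model, params)
  tibble::tibble(x = x, gamma = p$gamma, d = p$d, phi = p$phi)
}

#' Sex-specific phenotypes
#'
#' Applies the female model to `x_f` and the male model to `x_m`. With
#' identical models this is the shared-constraint setting; passing different
#' models gives built-in sex differences in the trade-off itself.
#'
#' @param x_f,x_m Female / male trait values in (0, 1).
#' @param model_f,model_m Trade-off models per sex (male defaults to female).
#' @inheritParams phenotype_at
#' @return A tibble with columns `sex`, `x`, `gamma`, `d`, `phi` (two rows).
#' @export
sex_phenotypes <- function(x_f, x_m, model_f, model_m = model_f,
                           params = host_params()) {
  dplyr::bind_rows(
    dplyr::mutate(phenotype_at(x_f, model_f, params), sex = "female",
                  .before = 1),
    dplyr::mutate(phenotype_at(x_m, model_m, params), sex = "male",
                  .before = 1)
  )
}
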
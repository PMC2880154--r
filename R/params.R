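#' Ecological and epidemiological parameters
#'
#' Constructs the parameter set of the host--pathogen model: density-dependent
#' host demography plus SIS (susceptible-infected-susceptible) transmission
#' with sex-specific infection rates and virulences. Defaults are the
#' reference values used throughout the package (arbitrary time and density
#' units).
#'
#' @param b Maximum fecundity of females (births per female per unit time at
#'   zero density). Default 1.
#' @param q Density-dependent reduction in fecundity; the birth rate is scaled
#'   by `1 - q * N` where `N` is total host density. Default 0.01.
#' @param d0 Baseline natural death rate. Default 0.25.
#' @param gamma0 Baseline recovery rate. Default 2.
#' @param beta_f,beta_m Infection rate of females / males (per infected
#'   contact density per unit time). Default 0.2 each.
#' @param alpha_f,alpha_m Virulence, i.e. disease-induced death rate, in
#'   females / males. Default 0.75 each.
#'
#' @return An object of class `host_params` (a named list).
#' @examples
#' host_params()
#' host_params(beta_m = 0.4) # males twice as exposed as females
#' @export
host_params <- function(b = 1, q = 0.01, d0 = 0.25, gamma0 = 2,
                        beta_f = 0.2, beta_m = 0.2,
                        alpha_f = 0.75, alpha_m = 0.75) {
  p <- list(b = b, q = q, d0 = d0, gamma0 = gamma0,
            beta_f = beta_f, beta_m = beta_m,
            alpha_f = alpha_f, alpha_m = alpha_m)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1 ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("host_params: all parameters must be single non-negative numbers; ",
         "offending: ", paste(names(p)[bad], collapse = ", "))
  }
  if (q <= 0) stop("host_params: q must be positive (density regulation)")
  structure(p, class = "host_params")
}

#' @export
print.host_params <- function(x, ...) {
  cat("<host_params>\n")
  cat(sprintf("  demography:   b = %g, q = %g, d0 = %g\n", x$b, x$q, x$d0))
  cat(sprintf("  epidemiology: beta_f = %g, beta_m = %g, alpha_f = %g, alpha_m = %g\n",
              x$beta_f, x$beta_m, x$alpha_f, x$alpha_m))
  cat(sprintf("  baseline recovery: gamma0 = %g\n", x$gamma0))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced. Convenience
#' aliases `beta` and `alpha` set both sexes at once, which is the symmetric
#' setting used in joint sweeps.
#'
#' @param params A [host_params()] object.
#' @param ... Named scalar replacements, e.g. `beta_m = 0.3` or `alpha = 1`.
#' @return A `host_params` object.
#' @examples
#' update_params(host_params(), beta = 0.3)
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(params)
  if (is.null(names(repl)) || any(names(repl) == "")) {
    stop("update_params: replacements must be named")
  }
  for (nm in names(repl)) {
    v <- repl[[nm]]
    if (nm == "beta") {
      params$beta_f <- v; params$beta_m <- v
    } else if (nm == "alpha") {
      params$alpha_f <- v; params$alpha_m <- v
    } else if (nm %in% names(params)) {
      params[[nm]] <- v
    } else {
      stop("update_params: unknown parameter '", nm, "'")
    }
  }
  do.call(host_params, unclass(params))
}
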
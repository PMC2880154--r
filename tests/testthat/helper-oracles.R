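# Independent oracles used to validate the package implementation. These are
# deliberately written from first principles, not by calling package
# internals.

# Brute-force Mendelian cross: enumerate all 2^4 equally likely
# gamete-pairings of a two-locus diploid cross. Genotypes are given as
# lists of allele-index pairs, e.g. list(f = c(1, 2), m = c(1, 1)).
brute_force_cross <- function(mother, father) {
  out <- list()
  for (mf in mother$f) for (mm in mother$m) {
    for (ff in father$f) for (fm in father$m) {
      key <- paste(sort(c(mf, ff)), collapse = "") # unordered pairs
      key <- paste0(key, "|", paste(sort(c(mm, fm)), collapse = ""))
      out[[key]] <- (out[[key]] %||% 0) + 1 / 16
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent 4-compartment SIS integrator for a monomorphic population:
# females and males with fixed phenotypes (d, gamma, phi per sex), births
# b (1 - qN) (S_f + phi_f I_f) split 1:1, mass-action transmission on the
# total infected density.
sis4_oracle <- function(y0, times, b, q, d_f, d_m, gam_f, gam_m,
                        phi_f, phi_m, beta_f, beta_m, alpha_f, alpha_m) {
  rhs <- function(t, y, parms) {
    Sf <- y[1]; If <- y[2]; Sm <- y[3]; Im <- y[4]
    N <- Sf + If + Sm + Im
    births <- b * max(0, 1 - q * N) * (Sf + phi_f * If)
    I <- If + Im
    list(c(
      births / 2 - d_f * Sf - beta_f * Sf * I + gam_f * If,
      beta_f * Sf * I - (d_f + alpha_f + gam_f) * If,
      births / 2 - d_m * Sm - beta_m * Sm * I + gam_m * Im,
      beta_m * Sm * I - (d_m + alpha_m + gam_m) * Im
    ))
  }
  deSolve::ode(y0, times, rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
}
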
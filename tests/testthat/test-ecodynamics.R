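p <- host_params()
m3 <- tradeoff_model("iii") # background mortality fixed at d0

test_that("carrying capacity follows the birth-death balance", {
  expect_equal(carrying_capacity(p), 50)
  expect_equal(carrying_capacity(host_params(b = 0.5)), 0) # b = 2 d0 threshold
  expect_gt(carrying_capacity(host_params(d0 = 0.125)), 50)
  # disease-free integration lands on the closed form (4 significant figures)
  eq <- equilibrium(0.5, 0.5, p, m3, seed_infection = FALSE)
  expect_equal(eq$type, "disease-free")
  expect_equal(eq$N, 50, tolerance = 1e-4)
  # general mortality: model (i) raises d with x and lowers K accordingly
  m1 <- tradeoff_model("i")
  d_at <- phenotype_at(0.5, m1, p)$d
  eq1 <- equilibrium(0.5, 0.5, p, m1, seed_infection = FALSE)
  expect_equal(eq1$N, (1 - 2 * d_at / p$b) / p$q, tolerance = 1e-6)
})

test_that("the disease-free state annihilates the genotype-resolved derivatives", {
  gs <- genotype_space(0.5, 0.5)
  phen <- genotype_phenotypes(gs, m3, params = p)
  state <- matrix(c(25, 0, 25, 0), 1, 4,
                  dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
  expect_equal(max(abs(sis_derivatives(state, gs, phen, p))), 0,
               tolerance = 1e-12)
  # without infecteds the infection terms vanish for any state
  st2 <- state; st2[1, "S_f"] <- 10
  d2 <- sis_derivatives(st2, gs, phen, p)
  expect_equal(d2[1, "I_f"], 0)
  expect_equal(d2[1, "I_m"], 0)
})

test_that("the basic reproduction number takes its closed form and thresholds", {
  expect_equal(basic_reproduction_number(0.5, 0.5, p, m3), 50 * 0.2 / 3)
  # symmetric sexes collapse the two-term sum to K beta / (d + alpha + gamma)
  ph <- phenotype_at(0.3, m3, p)
  expect_equal(basic_reproduction_number(0.3, 0.3, p, m3),
               50 * p$beta_f / (ph$d + p$alpha_f + ph$gamma))
  expect_equal(basic_reproduction_number(0.5, 0.5, update_params(p, beta = 0), m3), 0)
  # seeded infection persists iff R0 > 1 (beta grid straddling R0 = 1 at 0.06)
  for (beta in c(0.04, 0.055, 0.065, 0.09)) {
    pp <- update_params(p, beta = beta)
    r0 <- basic_reproduction_number(0.5, 0.5, pp, m3)
    eq <- equilibrium(0.5, 0.5, pp, m3)
    expect_equal(eq$type == "endemic", r0 > 1, info = paste("beta =", beta))
  }
})

test_that("the endemic equilibrium is interior and infection-free dynamics stay so", {
  eq <- equilibrium(0.5, 0.5, p, m3)
  expect_true(eq$converged)
  expect_equal(eq$type, "endemic")
  expect_true(eq$prevalence_f > 0 && eq$prevalence_f < 1)
  expect_true(eq$prevalence_m > 0 && eq$prevalence_m < 1)
  expect_lt(eq$residual, 1e-9)
  eq0 <- equilibrium(0.5, 0.5, update_params(p, beta = 0), m3)
  expect_equal(eq0$type, "disease-free")
})

test_that("symmetric sexes give mirror-image trajectories", {
  gs <- genotype_space(0.5, 0.5)
  phen <- genotype_phenotypes(gs, m3, params = p)
  state <- matrix(c(20, 1, 20, 1), 1, 4,
                  dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
  tr <- integrate_population(state, gs, phen, p, times = seq(0, 60, by = 5))
  expect_equal(tr$S_f.g1, tr$S_m.g1, tolerance = 1e-8)
  expect_equal(tr$I_f.g1, tr$I_m.g1, tolerance = 1e-8)
  expect_true(all(as.matrix(tr[, -1]) > -1e-9)) # positivity preserved
})

test_that("the genotype-resolved system reduces to an independent 4-ODE model", {
  gs <- genotype_space(0.35, 0.6)
  m1 <- tradeoff_model("i")
  phen <- genotype_phenotypes(gs, m1, params = p)
  state <- matrix(c(18, 2, 17, 3), 1, 4,
                  dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
  times <- seq(0, 40, by = 4)
  tr <- integrate_population(state, gs, phen, p, times = times)
  pf <- phenotype_at(0.35, m1, p); pm <- phenotype_at(0.6, m1, p)
  ora <- sis4_oracle(c(18, 2, 17, 3), times, b = p$b, q = p$q,
                     d_f = pf$d, d_m = pm$d, gam_f = pf$gamma,
                     gam_m = pm$gamma, phi_f = pf$phi, phi_m = pm$phi,
                     beta_f = p$beta_f, beta_m = p$beta_m,
                     alpha_f = p$alpha_f, alpha_m = p$alpha_m)
  expect_equal(tr$S_f.g1, unname(ora[, 2]), tolerance = 1e-6)
  expect_equal(tr$I_f.g1, unname(ora[, 3]), tolerance = 1e-6)
  expect_equal(tr$S_m.g1, unname(ora[, 4]), tolerance = 1e-6)
  expect_equal(tr$I_m.g1, unname(ora[, 5]), tolerance = 1e-6)
  # and the long-run attractor agrees with integrate_to_equilibrium
  eq_gen <- integrate_to_equilibrium(state, gs, phen, p, tol = 1e-9)
  eq_fast <- equilibrium(0.35, 0.6, p, m1)
  expect_equal(eq_gen$N, eq_fast$N, tolerance = 1e-6)
  expect_equal(eq_gen$prevalence_f, eq_fast$prevalence_f, tolerance = 1e-6)
})
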
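p <- host_params()

test_that("a resident allele is exactly neutral against itself", {
  set.seed(11)
  for (rep in 1:8) {
    pp <- update_params(p,
                        beta_f = runif(1, 0.08, 0.4), beta_m = runif(1, 0.08, 0.4),
                        alpha_f = runif(1, 0.2, 1.5), alpha_m = runif(1, 0.2, 1.5))
    mod <- tradeoff_model(sample(c("i", "ii", "iii"), 1))
    x_f <- runif(1, 0.2, 0.8); x_m <- runif(1, 0.2, 0.8)
    eq <- equilibrium(x_f, x_m, pp, mod)
    if (eq$type == "extinct") next # non-viable trait/parameter draw
    res_f <- invasion_fitness(x_f, x_m, "f", x_f, pp, mod, res_eq = eq)
    res_m <- invasion_fitness(x_f, x_m, "m", x_m, pp, mod, res_eq = eq)
    expect_lt(abs(res_f$lambda), 1e-6)
    expect_lt(abs(res_m$lambda), 1e-6)
    expect_false(res_f$invades)
    # the resident equilibrium itself spans the neutral eigendirection
    J <- invasion_matrix(eq, "f", x_f)
    expect_equal(max(abs(J %*% as.vector(eq$state))), 0, tolerance = 1e-8)
  }
})

test_that("a cost-free recovery gain always invades, a loss never does", {
  free <- tradeoff_model("i", mortality = function(x, g0, d0) rep(d0, length(x)))
  eq <- equilibrium(0.3, 0.3, p, free)
  expect_equal(eq$type, "endemic")
  up <- invasion_fitness(0.3, 0.3, "f", 0.5, p, free, res_eq = eq)
  dn <- invasion_fitness(0.3, 0.3, "f", 0.15, p, free, res_eq = eq)
  expect_true(up$invades)
  expect_lt(dn$lambda, 0)
})

test_that("invasion signs are antisymmetric away from singular strategies", {
  for (case in list(list(m = "i", r = 0.5, mu = 0.55),
                    list(m = "i", r = 0.6, mu = 0.5),
                    list(m = "iii", r = 0.3, mu = 0.36))) {
    mod <- tradeoff_model(case$m)
    ab <- invasion_fitness(case$r, 0.5, "f", case$mu, p, mod)$lambda
    ba <- invasion_fitness(case$mu, 0.5, "f", case$r, p, mod)$lambda
    expect_gt(abs(ab), 1e-5) # away from the singular point
    expect_lt(ab * ba, 0)
  }
})

test_that("invasion fitness needs a converged, living resident", {
  eq <- equilibrium(0.5, 0.5, p, tradeoff_model("i"))
  expect_error(invasion_matrix(eq, "f", 1.2), "outside")
  dead <- equilibrium(0.5, 0.5, host_params(b = 0.4), tradeoff_model("iii"))
  expect_equal(dead$type, "extinct")
  expect_error(invasion_matrix(dead, "f", 0.5), "extinct")
})

test_that("pairwise-invasion grids are neutral on the diagonal and flip at the ESS", {
  m1 <- tradeoff_model("i")
  fit <- find_ess(p, m1)
  xs <- fit$x_f_star
  grid <- seq(0.1, 0.6, length.out = 6)
  pg <- pip_grid("f", p, m1, resident_grid = grid,
                 fixed_other = fit$x_m_star)
  diag_rows <- pg[abs(pg$resident - pg$mutant) < 1e-12, ]
  expect_true(all(diag_rows$sign_lambda == 0))
  # mutants between resident and the singular strategy invade; the sign
  # pattern flips across it (cross-check against the ESS search)
  below <- pg[pg$resident < xs - 0.05 & pg$mutant > pg$resident &
                pg$mutant < xs, ]
  above <- pg[pg$resident > xs + 0.05 & pg$mutant < pg$resident &
                pg$mutant > xs, ]
  expect_true(all(below$sign_lambda == 1))
  expect_true(all(above$sign_lambda == 1))
  far_up <- pg[pg$resident > xs + 0.05 & pg$mutant > pg$resident + 0.05, ]
  expect_true(all(far_up$sign_lambda == -1))
  # degenerate minimal grid still works
  tiny <- pip_grid("m", p, m1, resident_grid = c(0.3, 0.5), fixed_other = 0.3)
  expect_equal(nrow(tiny), 4)
  expect_s3_class(autoplot(tiny), "ggplot")
})
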
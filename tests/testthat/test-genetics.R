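test_that("genotype spaces enumerate unordered allele pairs with additive traits", {
  gs <- genotype_space(c(0.2, 0.6), c(0.3, 0.5, 0.9))
  expect_equal(gs$n, 3 * 6) # n1(n1+1)/2 x n2(n2+1)/2
  expect_equal(anyDuplicated(gs$genotypes$label), 0L)
  het <- which(gs$genotypes$fa == 1 & gs$genotypes$fb == 2 &
                 gs$genotypes$ma == 1 & gs$genotypes$mb == 1)[1]
  expect_equal(genotype_trait(gs, het, "female"), 0.4) # mean of 0.2, 0.6
  expect_equal(genotype_trait(gs, het, "male"), 0.3)   # silent locus carried
  expect_error(genotype_space(c(0, 0.5), 0.4), "strictly in")
})

test_that("a heterozygote x heterozygote cross segregates 1:4, 1:2, 1:4", {
  gs <- genotype_space(c(0.3, 0.5), 0.4)
  gt <- gs$genotypes
  het <- which(gt$fa == 1 & gt$fb == 2)
  off <- mendelian_offspring(gs, het, het)
  expect_identical(off[which(gt$fa == 1 & gt$fb == 1)], 1 / 4)
  expect_identical(off[het], 1 / 2)
  expect_identical(off[which(gt$fa == 2 & gt$fb == 2)], 1 / 4)
})

test_that("monomorphic and fully heterozygous crosses are forced", {
  gs <- genotype_space(c(0.3, 0.5), c(0.2, 0.8))
  gt <- gs$genotypes
  aa <- which(gt$fa == 1 & gt$fb == 1 & gt$ma == 1 & gt$mb == 1)
  bb <- which(gt$fa == 2 & gt$fb == 2 & gt$ma == 2 & gt$mb == 2)
  expect_equal(mendelian_offspring(gs, aa, aa)[aa], 1)
  # AA x BB at both loci: every offspring is a double heterozygote
  off <- mendelian_offspring(gs, aa, bb)
  dh <- which(gt$fa == 1 & gt$fb == 2 & gt$ma == 1 & gt$mb == 2)
  expect_equal(off[dh], 1)
  expect_error(mendelian_offspring(gs, aa, gs$n + 1), "outside")
})

test_that("two-locus segregation factorises over loci and matches brute force", {
  gs <- genotype_space(c(0.3, 0.5), c(0.2, 0.8))
  gt <- gs$genotypes
  dh <- which(gt$fa == 1 & gt$fb == 2 & gt$ma == 1 & gt$mb == 2)
  off <- mendelian_offspring(gs, dh, dh)
  expect_equal(sum(off), 1, tolerance = 1e-12)
  expect_equal(sum(off > 0), 9)
  # free recombination: proportion = product of single-locus ratios
  ratio <- c(`11` = 1 / 4, `12` = 1 / 2, `22` = 1 / 4)
  for (i in seq_len(gs$n)) {
    fk <- paste0(gt$fa[i], gt$fb[i]); mk <- paste0(gt$ma[i], gt$mb[i])
    expect_equal(off[i], ratio[[fk]] * ratio[[mk]])
  }
  # independent enumeration of all 16 gamete pairings
  bf <- brute_force_cross(list(f = c(1, 2), m = c(1, 2)),
                          list(f = c(1, 2), m = c(1, 2)))
  for (i in seq_len(gs$n)) {
    key <- paste0(gt$fa[i], gt$fb[i], "|", gt$ma[i], gt$mb[i])
    expect_equal(off[i], bf[[key]] %||% 0)
  }
})

test_that("offspring proportions sum to one and the cross is parent-symmetric", {
  set.seed(41)
  for (rep in 1:5) {
    gs <- genotype_space(sort(runif(2, 0.1, 0.9)), sort(runif(2, 0.1, 0.9)))
    j <- sample(gs$n, 1); k <- sample(gs$n, 1)
    off_jk <- mendelian_offspring(gs, j, k)
    expect_equal(sum(off_jk), 1, tolerance = 1e-12)
    expect_true(all(off_jk >= 0))
    # swapping which parent carries which genotype leaves the cross invariant
    expect_equal(off_jk, mendelian_offspring(gs, k, j))
  }
})

test_that("births scale with effective females and split over fathers by weight", {
  p <- host_params()
  gs <- genotype_space(0.4, c(0.3, 0.7))
  gt <- gs$genotypes
  phen <- genotype_phenotypes(gs, tradeoff_model("i"), params = p)
  g11 <- which(gt$ma == 1 & gt$mb == 1)
  g12 <- which(gt$ma == 1 & gt$mb == 2)
  g22 <- which(gt$ma == 2 & gt$mb == 2)
  state <- matrix(0, gs$n, 4, dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
  state[g11, "S_f"] <- 10
  state[g11, "S_m"] <- 5; state[g22, "S_m"] <- 5
  B <- birth_rates(state, gs, phen, p)
  # N = 20, r = b(1 - qN) = 0.8; fathers split equally between the two
  # homozygotes, so offspring are half M11 (from g11 sires), half M12
  expect_equal(B[g11], 0.8 * 10 * 0.5)
  expect_equal(B[g12], 0.8 * 10 * 0.5)
  expect_equal(B[g22], 0)
})

test_that("total births depend on females only (Bateman), vanish at carrying limit", {
  p <- host_params()
  gs <- genotype_space(0.4, c(0.3, 0.7))
  gt <- gs$genotypes
  phen <- genotype_phenotypes(gs, tradeoff_model("i"), params = p)
  g11 <- which(gt$ma == 1 & gt$mb == 1)
  base <- matrix(0, gs$n, 4, dimnames = list(NULL, c("S_f", "I_f", "S_m", "I_m")))
  base[g11, "S_f"] <- 12
  totals <- sapply(list(c(8, 0, 0), c(0, 8, 0), c(2, 3, 3)), function(split) {
    st <- base; st[, "S_m"] <- split
    sum(birth_rates(st, gs, phen, p))
  })
  expect_equal(totals, rep(totals[1], 3)) # male composition never changes output
  expect_equal(totals[1], p$b * (1 - p$q * 20) * 12)
  # at or beyond the density ceiling no births occur
  over <- base; over[g11, c("S_f", "S_m")] <- c(60, 60)
  expect_equal(birth_rates(over, gs, phen, p), rep(0, gs$n))
  # infected females with zero relative fecundity contribute nothing
  m2 <- tradeoff_model("ii", fecundity = function(x, g0, d0) rep(0, length(x)))
  phen0 <- genotype_phenotypes(gs, m2, params = p)
  inf <- base; inf[, "S_f"] <- 0; inf[g11, "I_f"] <- 12; inf[g11, "S_m"] <- 5
  expect_equal(birth_rates(inf, gs, phen0, p), rep(0, gs$n))
  # all-male weights zero is a degenerate population
  nomale <- base
  expect_error(birth_rates(nomale, gs, phen, p), "degenerate")
})
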
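#' Diploid two-locus genotype space
#'
#' Enumerates all diploid genotypes over two autosomal loci with sex-limited
#' expression: the first ("female") locus controls the female trait, the
#' second ("male") locus the male trait; both loci are carried by both sexes.
#' Alleles are identified by position in the supplied vectors, so two alleles
#' may share the same trait value (e.g. a selectively neutral mutant).
#'
#' With `n1` alleles at the female locus and `n2` at the male locus the space
#' holds `n1 (n1 + 1) / 2 * n2 (n2 + 1) / 2` genotypes (unordered allele
#' pairs at each locus).
#'
#' @param female_alleles Numeric vector of allele trait contributions at the
#'   female-expressed locus, each strictly in (0, 1).
#' @param male_alleles Same for the male-expressed locus.
#' @return An object of class `genotype_space`: allele vectors, a `genotypes`
#'   tibble (allele indices `fa <= fb`, `ma <= mb`, expressed traits
#'   `trait_f`, `trait_m`, and a `label`), and the genotype count `n`.
#' @examples
#' gs <- genotype_space(c(0.3, 0.5), 0.4)
#' gs$genotypes
#' @export
genotype_space <- function(female_alleles, male_alleles) {
  chk <- function(v, nm) {
    if (length(v) < 1 || any(!is.finite(v) | v <= 0 | v >= 1)) {
      stop("genotype_space: ", nm, " must lie strictly in (0, 1)")
    }
  }
  chk(female_alleles, "female_alleles"); chk(male_alleles, "male_alleles")
  pairs <- function(n) {
    idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    idx[order(idx[, 1], idx[, 2]), , drop = FALSE] # (a, b) with a <= b
  }
  pf <- pairs(length(female_alleles))
  pm <- pairs(length(male_alleles))
  grid <- expand.grid(f = seq_len(nrow(pf)), m = seq_len(nrow(pm)))
  geno <- tibble::tibble(
    g = seq_len(nrow(grid)),
    fa = pf[grid$f, 1], fb = pf[grid$f, 2],
    ma = pm[grid$m, 1], mb = pm[grid$m, 2]
  )
  geno$trait_f <- (female_alleles[geno$fa] + female_alleles[geno$fb]) / 2
  geno$trait_m <- (male_alleles[geno$ma] + male_alleles[geno$mb]) / 2
  geno$label <- sprintf("F%d%d|M%d%d", geno$fa, geno$fb, geno$ma, geno$mb)
  # lookup tables: unordered pair of allele indices -> row in pf/pm
  key <- function(p, n) (pmin(p[, 1], p[, 2]) - 1) * n + pmax(p[, 1], p[, 2])
  nf <- length(female_alleles); nm <- length(male_alleles)
  f_lookup <- integer(nf * nf); f_lookup[key(pf, nf)] <- seq_len(nrow(pf))
  m_lookup <- integer(nm * nm); m_lookup[key(pm, nm)] <- seq_len(nrow(pm))
  structure(list(
    female_alleles = female_alleles, male_alleles = male_alleles,
    genotypes = geno, n = nrow(geno),
    .f_pairs = nrow(pf), .m_pairs = nrow(pm),
    .f_lookup = f_lookup, .m_lookup = m_lookup
  ), class = "genotype_space")
}

#' @export
print.genotype_space <- function(x, ...) {
  cat(sprintf("<genotype_space> %d female x %d male alleles, %d genotypes\n",
              length(x$female_alleles), length(x$male_alleles), x$n))
  invisible(x)
}

# genotype id from allele index pairs (unordered)
.geno_id <- function(space, f1, f2, m1, m2) {
  nf <- length(space$female_alleles); nm <- length(space$male_alleles)
  fi <- space$.f_lookup[(pmin(f1, f2) - 1) * nf + pmax(f1, f2)]
  mi <- space$.m_lookup[(pmin(m1, m2) - 1) * nm + pmax(m1, m2)]
  (mi - 1) * space$.f_pairs + fi
}

#' Expressed trait of a genotype
#'
#' Allelic effects are additive, so the expressed trait is the arithmetic
#' mean of the two allele values at the locus matching the sex; the other
#' locus is carried but silent.
#'
#' @param space A [genotype_space()].
#' @param g Genotype id (row of `space$genotypes`).
#' @param sex `"female"` or `"male"`.
#' @return The expressed trait value in (0, 1).
#' @export
genotype_trait <- function(space, g, sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(g >= 1, g <= space$n)
  if (sex == "female") space$genotypes$trait_f[g] else space$genotypes$trait_m[g]
}

#' Mendelian offspring distribution of a cross
#'
#' Each parent transmits one allele per locus with probability 1/2,
#' independently across the two loci (free recombination, no linkage
#' disequilibrium). Proportions are multiples of 1/16 and sum to one.
#'
#' @param space A [genotype_space()].
#' @param mother,father Genotype ids in `space`.
#' @return Numeric vector of length `space$n`: offspring genotype
#'   proportions.
#' @examples
#' gs <- genotype_space(c(0.3, 0.5), 0.4)
#' het <- which(gs$genotypes$fa == 1 & gs$genotypes$fb == 2)
#' mendelian_offspring(gs, het, het) # 1/4, 1/2, 1/4 at the female locus
#' @export
mendelian_offspring <- function(space, mother, father) {
  stopifnot(inherits(space, "genotype_space"))
  if (any(c(mother, father) < 1) || any(c(mother, father) > space$n)) {
    stop("mendelian_offspring: genotype ids outside this genotype space")
  }
  gm <- space$genotypes[mother, ]; gf <- space$genotypes[father, ]
  out <- numeric(space$n)
  for (mf in c(gm$fa, gm$fb)) for (mm in c(gm$ma, gm$mb)) {
    for (ff in c(gf$fa, gf$fb)) for (fm in c(gf$ma, gf$mb)) {
      id <- .geno_id(space, mf, ff, mm, fm)
      out[id] <- out[id] + 1 / 16
    }
  }
  out
}

#' Offspring proportion array
#'
#' Precomputes `delta[i, j, k]`, the proportion of offspring with genotype
#' `i` from a mother `j` and father `k`, for all crosses in the space.
#'
#' @inheritParams mendelian_offspring
#' @return A numeric array `n x n x n` (offspring, mother, father).
#' @export
offspring_array <- function(space) {
  n <- space$n
  delta <- array(0, c(n, n, n))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    delta[, j, k] <- mendelian_offspring(space, j, k)
  }
  delta
}

#' Per-genotype phenotypes under sex-specific trade-offs
#'
#' @inheritParams mendelian_offspring
#' @param model_f,model_m [tradeoff_model()]s applied to the expressed
#'   female / male trait of each genotype.
#' @param params A [host_params()].
#' @return List with elements `f` and `m`, each a list of per-genotype
#'   vectors `gamma`, `d`, `phi`.
#' @export
genotype_phenotypes <- function(space, model_f, model_m = model_f,
                                params = host_params()) {
  list(f = .phen(space$genotypes$trait_f, model_f, params),
       m = .phen(space$genotypes$trait_m, model_m, params))
}

#' Birth rates per offspring genotype
#'
#' Total reproductive output is set by females (density-dependent factor
#' `1 - qN`, effective fecund female density `F_j = S_f + phi_f I_f`), while
#' males determine only the genetic composition: male genotype `k` sires a
#' share proportional to its effective reproductive weight
#' `M_k = S_m + phi_m I_m` relative to all males. Offspring are distributed
#' over genotypes by the Mendelian proportions of each (mother, father)
#' cross.
#'
#' @param state Numeric matrix `n x 4` with columns `S_f`, `I_f`, `S_m`,
#'   `I_m` (densities per genotype).
#' @inheritParams genotype_phenotypes
#' @param phen Per-genotype phenotypes from [genotype_phenotypes()].
#' @param delta Optional precomputed [offspring_array()].
#' @return Numeric vector `B_i` of birth rates per genotype (both sexes
#'   combined; the 1:1 sex split is applied at the dynamics level).
#' @export
birth_rates <- function(state, space, phen, params, delta = NULL) {
  stopifnot(is.matrix(state), nrow(state) == space$n, ncol(state) == 4)
  if (any(state < 0)) stop("birth_rates: negative densities")
  delta <- delta %||% offspring_array(space)
  N <- sum(state)
  r <- params$b * max(0, 1 - params$q * N)
  Fj <- state[, 1] + phen$f$phi * state[, 2]
  Mk <- state[, 3] + phen$m$phi * state[, 4]
  W <- sum(Mk)
  if (r == 0 || sum(Fj) == 0) return(numeric(space$n))
  if (W <= 0) {
    stop("birth_rates: no males with positive reproductive weight ",
         "(degenerate population, no births possible)")
  }
  cross <- outer(Fj, Mk / W) # (mother j, father k) weights
  B <- vapply(seq_len(space$n),
              function(i) sum(delta[i, , ] * cross), numeric(1))
  r * B
}
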
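higher <- trait_direction("t", "higher_favorable")
lower <- trait_direction("t", "lower_favorable")

test_that("genotype-class effects are arithmetic class means with counts", {
  eff <- estimate_genotype_effects(c(0L, 0L, 1L, 2L, 2L), c(10, 10, 8, 6, 6))
  expect_equal(eff[c("A", "M", "C")], list(A = 10, M = 8, C = 6))
  expect_equal(eff[c("nA", "nM", "nC")], list(nA = 2L, nM = 1L, nC = 2L))

  one_class <- estimate_genotype_effects(rep(0L, 4), rnorm(4))
  expect_true(is.na(one_class$M) && is.na(one_class$C))
  est <- compute_da(one_class, higher)
  expect_true(est$excluded)
  expect_false(est$degree_defined)
})

test_that("d/a arithmetic, sign convention and exclusion rules hold", {
  mk <- function(A, M, C, nA = 10L, nM = 10L, nC = 10L)
    list(A = A, M = M, C = C, nA = nA, nM = nM, nC = nC)

  est <- compute_da(mk(10, 8, 6), higher)
  expect_equal(c(est$a, est$d, est$degree), c(2, 0, 0))

  est <- compute_da(mk(10, 10, 6), higher)
  expect_equal(c(est$a, est$d, est$degree), c(2, 2, 1))

  est <- compute_da(mk(1, 1.12, 0), higher)
  expect_equal(c(est$a, est$d, est$degree), c(0.5, 0.62, 1.24))
  expect_equal(classify_dominance(est$degree), "overdominance")

  # low-favorable trait flips the sign so positive still means favorable
  est <- compute_da(mk(10, 8, 6), lower)
  expect_equal(est$degree, 0)
  est <- compute_da(mk(10, 7, 6), lower)
  expect_equal(est$degree, 0.5)

  # fewer than 5 observations in a homozygous class: flagged excluded
  est <- compute_da(mk(10, 8, 6, nC = 4L), higher)
  expect_true(est$excluded)
  expect_equal(est$degree, 0)  # still computed, just flagged

  # a = 0: degree is NaN, flagged, no exception
  est <- compute_da(mk(5, 7, 5), higher)
  expect_true(is.nan(est$degree))
  expect_false(est$degree_defined)
})

test_that("dominance categories reproduce the published readings", {
  expect_equal(classify_dominance(1.24), "overdominance")
  expect_equal(classify_dominance(-0.14), "negative_dominance")
  expect_equal(classify_dominance(0), "additive")
  expect_equal(classify_dominance(0.4), "partial_dominance")
  expect_equal(classify_dominance(0.15), "partial_dominance")
  expect_equal(classify_dominance(1.0), "complete_dominance")
})

test_that("favorable-allele definitions follow the trait direction rules", {
  mk <- function(A, C) list(A = A, M = (A + C) / 2, C = C,
                            nA = 10L, nM = 10L, nC = 10L)
  expect_equal(define_favorable_allele(mk(12, 9), higher)$favorable, "ref")
  expect_equal(define_favorable_allele(mk(95, 85), lower)$favorable, "alt")
  amylose <- trait_direction("amylose", "window_favorable", 13.0, 22.0)
  expect_equal(define_favorable_allele(mk(25, 16), amylose)$favorable, "alt")
  expect_equal(define_favorable_allele(mk(16, 14), amylose)$favorable, "alt")
  tie <- define_favorable_allele(mk(10, 10), higher)
  expect_false(tie$resolved)
})

test_that("pyramiding counts are bounded dosage sums and monotone", {
  fav <- rep("alt", 100)
  expect_equal(count_favorable_alleles(rep(2L, 100), fav)$count, 200)
  expect_equal(count_favorable_alleles(rep(1L, 100), fav)$count, 100)
  expect_equal(count_favorable_alleles(rep(0L, 100), fav)$count, 0)
  fav_ref <- rep("ref", 100)
  expect_equal(count_favorable_alleles(rep(0L, 100), fav_ref)$count, 200)

  set.seed(1)
  g <- sample(0:2, 50, replace = TRUE)
  fav50 <- sample(c("ref", "alt"), 50, replace = TRUE)
  base <- count_favorable_alleles(g, fav50)$count
  j <- which(ifelse(fav50 == "alt", g, 2L - g) < 2L)[1]
  g2 <- g
  g2[j] <- g2[j] + if (fav50[j] == "alt") 1L else -1L
  expect_equal(count_favorable_alleles(g2, fav50)$count, base + 1)

  withNA <- count_favorable_alleles(c(2L, NA, 2L), rep("alt", 3))
  expect_equal(withNA$count, 4)
  expect_equal(withNA$n_missing, 1L)
})

test_that("top-loci selection ranks by p and clumps within 1 Mb", {
  assoc <- data.frame(chrom = c("c1", "c1", "c2"), pos = c(1e6, 5e6, 1e6),
                      p = c(1e-9, 1e-7, 1e-3))
  expect_equal(select_top_loci(assoc, k = 2)$p, c(1e-9, 1e-7))

  # two SNPs 10 kb apart are one signal: single representative
  assoc2 <- data.frame(chrom = "c1", pos = c(1e6, 1e6 + 1e4, 8e6),
                       p = c(1e-9, 1e-8, 1e-4))
  expect_warning(top <- select_top_loci(assoc2, k = 3), "independent signals")
  expect_equal(suppressWarnings(select_top_loci(assoc2, k = 3))$pos,
               c(1e6, 8e6))
  expect_equal(top$p[1], 1e-9)
})

test_that("frequency trajectories sum to one and recover planted drift", {
  g <- c(rep(1L, 10))
  tr <- genotype_frequency_trajectory(g, rep("Y1", 10), favorable = "alt")
  expect_equal(tr$freq_het, 1)
  expect_equal(tr$freq_favorable, 0.5)
  expect_equal(tr$freq_ref_hom + tr$freq_het + tr$freq_alt_hom, 1)

  # planted favorable-allele drift 0.2 -> 0.8 recovered exactly
  g1 <- c(rep(0L, 6), rep(1L, 4))            # alt freq 0.2
  g2 <- c(rep(2L, 6), rep(1L, 4))            # alt freq 0.8
  tr2 <- genotype_frequency_trajectory(c(g1, g2), rep(c("Y1", "Y3"), each = 10))
  expect_equal(tr2$freq_favorable, c(0.2, 0.8))

  tr3 <- genotype_frequency_trajectory(c(g1, g1), rep(c("a", "b"), each = 10))
  expect_equal(tr3[1, -1], tr3[2, -1], ignore_attr = TRUE)
})

test_that("better-parent heterosis respects the direction rule", {
  b <- compute_bph(12, 10, 9, higher)
  expect_equal(b$bph, 2)
  expect_true(b$positive)
  expect_equal(b$bph_rel, 0.2)
  b2 <- compute_bph(9.5, 10, 9, higher)
  expect_equal(b2$bph, -0.5)
  expect_false(b2$positive)
  b3 <- compute_bph(80, 85, 83, lower)
  expect_equal(b3$better_parent, 83)
  expect_true(b3$positive)
  expect_true(is.na(compute_bph(10, NA, 9, higher)$bph))
})

test_that("transgressive-segregation fractions match direct counting", {
  expect_equal(fraction_exceeding_parents(c(1, 2, 3), 5, 4, higher), 0)
  expect_equal(fraction_exceeding_parents(c(6, 7), 5, 4, higher), 1)
  expect_equal(fraction_exceeding_parents(c(6, 3, 2), 5, 4, lower), 2 / 3)
  expect_warning(out <- fraction_exceeding_parents(numeric(0), 5, 4, higher),
                 "empty")
  expect_true(is.na(out))
})

test_that("degree of dominance is invariant to affine trait rescaling", {
  set.seed(2)
  for (i in 1:10) {
    A <- rnorm(1); C <- rnorm(1); M <- rnorm(1)
    if (abs(A - C) < 1e-6) next
    eff <- list(A = A, M = M, C = C, nA = 9L, nM = 9L, nC = 9L)
    alpha <- runif(1, 0.1, 5); beta <- rnorm(1)
    eff2 <- list(A = alpha * A + beta, M = alpha * M + beta,
                 C = alpha * C + beta, nA = 9L, nM = 9L, nC = 9L)
    expect_equal(compute_da(eff2, higher)$degree,
                 compute_da(eff, higher)$degree, tolerance = 1e-8)
  }
})

test_that("noise-free class means recover planted effects; noisy bias shrinks", {
  fd <- fixture_founders()
  mo <- make_parent(fd$truth, "indica", seed = 5L)
  fa <- make_parent(fd$truth, "japonica", seed = 6L)
  het_sites <- which(mo != fa)
  f2 <- simulate_f2(mo, fa, 3000L, fd$panel$map, seed = 13L)
  qtl <- data.frame(marker = het_sites[10], a = 1, d = 0.5)

  ph0 <- simulate_phenotypes(f2, list(t = qtl), c(t = 1), seed = 1L)
  eff <- estimate_genotype_effects(f2$geno[, qtl$marker], ph0$pheno$t)
  est <- compute_da(eff, higher)
  expect_equal(est$a, 1)
  expect_equal(est$d, 0.5)
  expect_equal(est$degree, 0.5)

  # planted degree 1.24 recovered from a noise-free a = 0.5, d = 0.62 locus
  qtl2 <- data.frame(marker = het_sites[11], a = 0.5, d = 0.62)
  ph2 <- simulate_phenotypes(f2, list(t = qtl2), c(t = 1), seed = 2L)
  est2 <- compute_da(estimate_genotype_effects(f2$geno[, qtl2$marker],
                                               ph2$pheno$t), higher)
  expect_equal(est2$degree, 1.24)

  # with noise, the degree estimate tightens from n = 500 to n = 5000
  err_at_n <- function(n, seed) {
    f2n <- simulate_f2(mo, fa, n, fd$panel$map, seed = seed)
    phn <- simulate_phenotypes(f2n, list(t = qtl), c(t = 0.5), seed = seed)
    estn <- compute_da(estimate_genotype_effects(f2n$geno[, qtl$marker],
                                                 phn$pheno$t), higher)
    abs(estn$degree - 0.5)
  }
  errs_small <- sapply(1:5, function(s) err_at_n(500L, s))
  errs_big <- sapply(1:5, function(s) err_at_n(5000L, s + 100))
  expect_lt(mean(errs_big), mean(errs_small))
})
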
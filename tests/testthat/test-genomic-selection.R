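test_that("relationship matrices match hand values and the double-loop oracle", {
  # one marker at p = 0.5, two inbred lines with opposite homozygotes
  g <- matrix(c(0L, 2L), ncol = 1)
  rel <- build_relationship_matrices(g)
  expect_equal(rel$A, matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)

  set.seed(30)
  g2 <- matrix(rbinom(20 * 100, 2, runif(100, 0.1, 0.9)), 20, byrow = FALSE)
  rel2 <- build_relationship_matrices(g2)
  oracle <- bf_relationship(g2)
  expect_lt(max(abs(rel2$A - oracle$A)), 1e-10)
  expect_lt(max(abs(rel2$D - oracle$D)), 1e-10)

  # duplicated individual: identical rows and columns
  g3 <- rbind(g2, g2[1, ])
  rel3 <- build_relationship_matrices(g3)
  expect_equal(rel3$A[1, ], rel3$A[21, ], ignore_attr = TRUE)
  expect_equal(rel3$D[, 1], rel3$D[, 21], ignore_attr = TRUE)

  expect_error(build_relationship_matrices(matrix(2L, 5, 4)), "monomorphic")
  expect_warning(build_relationship_matrices(cbind(g2, 0L)), "monomorphic")

  # canonical dominance denominator differs from the shared default
  rel_c <- build_relationship_matrices(g2, d_denominator = "canonical")
  expect_equal(rel_c$A, rel2$A)
  expect_false(isTRUE(all.equal(rel_c$D, rel2$D)))
})

test_that("GBLUP recovers planted variance components", {
  set.seed(31)
  n <- 400; m <- 300
  g <- matrix(rbinom(n * m, 2, 0.5), n)
  rel <- build_relationship_matrices(g)
  u <- drop(t(chol(rel$A + diag(1e-6, n))) %*% rnorm(n, sd = sqrt(0.5)))
  y <- 2 + u + rnorm(n, sd = sqrt(0.5))
  fit <- fit_gblup(y, NULL, rel$A)
  expect_lt(abs(fit$h2 - 0.5), 0.2)
  expect_gt(cor(fit$gebv, u), 0.7)

  # null trait: additive variance collapses to the boundary
  y0 <- rnorm(n)
  fit0 <- fit_gblup(y0, NULL, rel$A)
  expect_lt(fit0$h2, 0.1)

  # planted dominance variance: the A+D model finds a non-trivial sigma2_d
  ud <- drop(t(chol(rel$D + diag(1e-6, n))) %*% rnorm(n, sd = sqrt(0.4)))
  yd <- u + ud + rnorm(n, sd = sqrt(0.3))
  fitd <- fit_gblup(yd, NULL, rel$A, rel$D)
  expect_gt(fitd$sigma2[["d"]] / sum(fitd$sigma2), 0.1)
  fita <- fit_gblup(yd, NULL, rel$A)
  expect_lt(fita$sigma2[["a"]] / sum(fita$sigma2), 0.95)
})

test_that("cross-validation is seeded, reproducible and calibrated", {
  set.seed(32)
  n <- 500; m <- 100
  g <- matrix(rbinom(n * m, 2, 0.5), n)
  rel <- build_relationship_matrices(g)
  beta <- rnorm(m, 0, 0.3)
  y <- drop(scale(g, scale = FALSE) %*% beta)  # noise-free additive trait

  cv <- cross_validate(y, rel$A, k = 6, iterations = 1, seed = 7)
  expect_gte(cv$accuracy, 0.95)

  cv_a <- cross_validate(y, rel$A, k = 6, iterations = 2, seed = 9)
  cv_b <- cross_validate(y, rel$A, k = 6, iterations = 2, seed = 9)
  expect_identical(cv_a, cv_b)

  y0 <- rnorm(n)
  cv0 <- cross_validate(y0, rel$A, k = 6, iterations = 1, seed = 7)
  expect_lt(abs(cv0$accuracy), 0.15)
})

test_that("combination enumeration is the product of parent-set sizes", {
  mk_inbred <- function(n, m, seed, prefix) {
    set.seed(seed)
    g <- matrix(2L * rbinom(n * m, 1, 0.5), n, m)
    rownames(g) <- sprintf("%s%03d", prefix, seq_len(n))
    geno_matrix(g, data.frame(chrom = "c1", pos = seq_len(m), ref = "A",
                              alt = "G"))
  }
  f <- mk_inbred(12, 30, 1, "F")
  m <- mk_inbred(7, 30, 2, "M")
  cmb <- enumerate_combinations(f, m)
  expect_equal(cmb$n, 12 * 7)
  expect_equal(nrow(cmb$geno), 12 * 7)
  # F1 semantics: het exactly where parents differ
  i <- 5
  fi <- match(cmb$pairs$female[i], rownames(f$geno))
  mi <- match(cmb$pairs$male[i], rownames(m$geno))
  expect_equal(unname(cmb$geno[i, ]),
               make_f1(f$geno[fi, ], m$geno[mi, ]))

  one <- enumerate_combinations(subset_geno(f, 1), subset_geno(m, 1))
  expect_equal(one$n, 1L)
  expect_error(enumerate_combinations(subset_geno(f, integer(0)), m), "empty")

  het <- f
  het$geno[1, ] <- 1L
  expect_error(enumerate_combinations(het, m), "heterozygosity")
})

test_that("candidate GEBV prediction interpolates training and cross-checks", {
  set.seed(34)
  n <- 150; m <- 200
  g <- matrix(rbinom(n * m, 2, 0.5), n)
  rel <- build_relationship_matrices(g)
  beta <- rnorm(m, 0, 0.3)
  gtrue <- drop(scale(g, scale = FALSE) %*% beta)
  y <- gtrue + rnorm(n, sd = 0.2 * sd(gtrue))
  fit <- fit_gblup(y, NULL, rel$A)

  # candidate identical to a training individual: same GEBV
  pred_same <- predict_gebv(fit, g, g[3, , drop = FALSE])
  expect_lt(abs(pred_same - fit$gebv[3]), 1e-6)

  # fresh candidates: prediction tracks the true genetic value
  gc <- matrix(rbinom(40 * m, 2, 0.5), 40)
  gc_true <- drop(sweep(gc, 2, colMeans(g)) %*% beta)
  pred <- predict_gebv(fit, g, gc)
  expect_gt(cor(pred, gc_true), 0.7)

  # the two prediction mechanisms agree on a full-rank instance
  pred_rel <- predict_gebv(fit, g, gc, method = "relationship")
  pred_mk <- predict_gebv(fit, g, gc, method = "marker")
  expect_lt(max(abs(pred_rel - pred_mk)), 1e-6 * max(1, max(abs(pred_rel))))

  expect_error(predict_gebv(fit, g, gc[, 1:10]), "panels differ")
})

test_that("selection index respects printed scores, bounds and bin occupancy", {
  set.seed(35)
  n <- 200
  gebv <- data.frame(female = sprintf("f%03d", 1:n),
                     yield_per_plant = rnorm(n),
                     seed_setting_rate = rnorm(n),
                     grain_number_per_panicle = rnorm(n),
                     valid_panicle_number = rnorm(n),
                     heading_date = runif(n, 70, 100),
                     plant_height = runif(n, 100, 140),
                     grain_shape = runif(n, 2.5, 3.8))
  idx <- selection_index(gebv)
  expect_true(all(idx$index >= 60 & idx$index <= 280))
  expect_true(all(idx$index %% 10 == 0))

  # exactly 20% (+/- ties) of candidates in each percentile bin
  for (tr in c("yield_per_plant", "seed_setting_rate")) {
    counts <- table(idx[[paste0("score_", tr)]])
    expect_true(all(abs(counts - n / 5) <= 1))
  }

  # a candidate at the top of everything scores the 280 maximum
  best <- gebv[1, ]
  best[2:5] <- apply(gebv[2:5], 2, max) + 1
  best$heading_date <- 85; best$plant_height <- 120; best$grain_shape <- 3.2
  idx2 <- selection_index(rbind(best, gebv[-1, ]))
  expect_equal(idx2$index[1], 280)

  # GEBV exactly at the 80th percentile falls in the 60-80% bin
  x <- 0:100                      # 101 values: the 80th percentile is 80
  gebv3 <- gebv[1:101, ]
  gebv3$yield_per_plant <- x
  stopifnot(unname(quantile(x, 0.8)) == 80)
  idx3 <- selection_index(gebv3)
  at_q80 <- which(gebv3$yield_per_plant == 80)
  expect_equal(idx3$score_yield_per_plant[at_q80], 30)

  gebv_na <- gebv
  gebv_na$grain_shape[3] <- NA
  expect_message(idx4 <- selection_index(gebv_na), "excluded")
  expect_equal(nrow(idx4), n - 1)
})

test_that("sterility screening flags homozygous sterile F1s by system", {
  g <- rbind(AA = c(2L, 0L, 2L), Aa = c(2L, 2L, 0L))  # two females
  gm <- rbind(m1 = c(2L, 0L, NA))                     # one male
  f <- geno_matrix(g, data.frame(chrom = "c1", pos = 1:3, ref = "A", alt = "G"))
  m <- geno_matrix(gm, data.frame(chrom = "c1", pos = 1:3, ref = "A", alt = "G"))
  cmb <- enumerate_combinations(f, m)
  loci <- data.frame(locus = c(1L, 3L), name = c("rf3", "tms5"),
                     sterile_dosage = c(2L, 2L),
                     system = c("WA", "two_line"), stringsAsFactors = FALSE)
  sys <- c(AA = "WA", Aa = "two_line")
  out <- screen_sterility(cmb, loci, sys)
  # female AA (WA): both parents hom sterile at rf3 -> flagged
  expect_true(out$sterile_flag[out$female == "AA"])
  expect_equal(out$sterile_loci[out$female == "AA"], "rf3")
  # female Aa (two_line): tms5 locus missing in the male -> undetermined
  expect_true(is.na(out$sterile_flag[out$female == "Aa"]))

  # heterozygous F1 (one restorer allele) is never flagged
  g2 <- rbind(B = c(0L, 0L, 0L))
  f2 <- geno_matrix(g2, f$map)
  out2 <- screen_sterility(enumerate_combinations(f2, m), loci,
                           c(B = "WA"))
  expect_false(out2$sterile_flag)

  # flagged fraction equals a direct counting oracle on a random cohort
  set.seed(36)
  nf <- 25; nm <- 15
  gf <- matrix(2L * rbinom(nf * 4, 1, 0.5), nf)
  gmm <- matrix(2L * rbinom(nm * 4, 1, 0.5), nm)
  rownames(gf) <- sprintf("F%02d", 1:nf); rownames(gmm) <- sprintf("M%02d", 1:nm)
  map4 <- data.frame(chrom = "c1", pos = 1:4, ref = "A", alt = "G")
  cmb3 <- enumerate_combinations(geno_matrix(gf, map4), geno_matrix(gmm, map4))
  loci3 <- data.frame(locus = 2L, name = "rf4", sterile_dosage = 0L,
                      system = "WA", stringsAsFactors = FALSE)
  sys3 <- setNames(rep("WA", nf), rownames(gf))
  out3 <- screen_sterility(cmb3, loci3, sys3)
  oracle <- outer(gf[, 2] == 0L, gmm[, 2] == 0L, `&`)
  expect_equal(mean(out3$sterile_flag), mean(oracle))
})

test_that("high-index combinations pyramid more favorable alleles", {
  set.seed(37)
  n <- 300; m <- 120
  g <- matrix(rbinom(n * m, 2, 0.5), n)
  rel <- build_relationship_matrices(g)
  beta <- abs(rnorm(m, 0, 0.3))      # alt allele favorable everywhere
  gtrue <- drop(scale(g, scale = FALSE) %*% beta)
  y <- gtrue + rnorm(n, sd = sd(gtrue))
  fit <- fit_gblup(y, NULL, rel$A)
  counts <- vapply(seq_len(n), function(i)
    count_favorable_alleles(g[i, ], rep("alt", m))$count, numeric(1))
  top <- order(fit$gebv, decreasing = TRUE)[1:30]
  rest <- setdiff(seq_len(n), top)
  wt <- wilcox.test(counts[top], counts[rest], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
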
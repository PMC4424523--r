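test_that("equal-variance effects match their closed form and defining identity", {
  expect_equal(abs(effects_var(0.5, seed = 1)), sqrt(2), tolerance = 1e-12)
  expect_equal(abs(effects_var(0.1, seed = 1)), sqrt(1 / 0.18), tolerance = 1e-12)
  p <- runif(50, 0.01, 0.99)
  a <- effects_var(p, var_qtl = 3.5, seed = 2)
  expect_equal(2 * p * (1 - p) * a^2, rep(3.5, 50), tolerance = 1e-12)
  expect_error(effects_var(c(0.2, 0)), "monomorphic")
  expect_error(effects_var(1), "monomorphic")
})

test_that("gamma effects have the documented moments and symmetric signs", {
  a <- effects_random(1e6, seed = 3)
  expect_equal(mean(abs(a)), 0.4 * 1.66, tolerance = 0.01)
  expect_equal(mean(a), 0, tolerance = 0.01)
  expect_equal(var(abs(a)), 0.4 * 1.66^2, tolerance = 0.02)
  expect_equal(mean(a > 0), 0.5, tolerance = 0.01)
  expect_error(effects_random(10, shape = -1), "positive")
})

test_that("QTL are sampled uniformly from segregating loci of the class", {
  panel <- shared_panel()
  eligible <- which(panel$loci$class == "very_low" & !panel$loci$monomorphic)
  all_of_them <- sample_qtl(panel, "very_low", length(eligible), seed = 1)
  expect_setequal(all_of_them, eligible)
  idx <- sample_qtl(panel, "very_low", 20, seed = 2)
  expect_true(all(!panel$loci$monomorphic[idx]))
  expect_error(sample_qtl(panel, "extremely_low", 1e5), "extremely_low")
})

test_that("rare-class QTL are breed-specific at the class's own rate", {
  panel <- shared_panel()
  seg_cols <- paste0("seg_", panel$breeds)
  pool <- which(panel$loci$class == "extremely_low" & !panel$loci$monomorphic)
  spec_rate <- mean(rowSums(as.matrix(panel$loci[pool, seg_cols])) == 1L)
  n_draw <- min(5L, length(pool))
  draws <- vapply(1:200, function(s) {
    idx <- sample_qtl(panel, "extremely_low", n_draw, seed = s)
    mean(rowSums(as.matrix(panel$loci[idx, seg_cols])) == 1L)
  }, numeric(1))
  expect_lt(abs(mean(draws) - spec_rate), 0.05)
})

test_that("true breeding values match a hand computation and are standardized", {
  geno <- rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L), c(2L, 2L))
  panel <- toy_panel(geno, c("HF", "HF", "J", "J"))
  a <- c(1, -0.5)
  raw <- drop(geno %*% a) # -1, 0.5, 2, 1
  trait <- compute_tbv(panel, 1:2, a)
  expect_equal(trait$individuals$tbv, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  expect_equal(mean(trait$individuals$tbv), 0, tolerance = 1e-12)
  expect_equal(var(trait$individuals$tbv), 1, tolerance = 1e-12)
  be <- trait$breed_effect
  expect_equal(be$effect[be$breed == "J"],
               mean(trait$individuals$tbv[3:4]), tolerance = 1e-12)
  # identical genotypes -> identical tbv
  geno2 <- rbind(geno, geno[2, , drop = FALSE])
  panel2 <- toy_panel(geno2, c("HF", "HF", "J", "J", "J"))
  t2 <- compute_tbv(panel2, 1:2, a)
  expect_equal(t2$individuals$tbv[2], t2$individuals$tbv[5])
  expect_error(compute_tbv(panel, 1:2, c(0, 0)), "zero variance")
})

test_that("phenotype simulation realizes the requested heritability", {
  panel <- shared_panel()
  trait <- simulate_trait(panel, "moderately_low", 60, model = "RANDOM",
                          h2 = 1, seed = 5)
  expect_equal(trait$individuals$phenotype, trait$individuals$tbv)
  expect_equal(trait$env_var, 0)

  trait5 <- simulate_phenotypes(trait, h2 = 0.5, seed = 6)
  corrected <- trait5$individuals$tbv -
    trait5$breed_effect$effect[match(trait5$individuals$breed,
                                     trait5$breed_effect$breed)]
  expect_equal(trait5$env_var, var(corrected), tolerance = 1e-12)

  # h2 = 0.8: within-breed regression of y on tbv has slope ~1, R2 ~ 0.8
  trait8 <- simulate_phenotypes(trait, h2 = 0.8, seed = 7)
  ind <- trait8$individuals
  y_c <- ind$phenotype - stats::ave(ind$phenotype, ind$breed)
  g_c <- ind$tbv - stats::ave(ind$tbv, ind$breed)
  fitlm <- stats::lm(y_c ~ g_c)
  expect_equal(unname(stats::coef(fitlm)[2]), 1, tolerance = 0.1)
  expect_equal(summary(fitlm)$r.squared, 0.8, tolerance = 0.08)
  expect_error(simulate_phenotypes(trait, h2 = 0), "\\(0, 1\\]")
})

test_that("VAR model equalizes per-QTL variance contributions, RANDOM does not", {
  panel <- shared_panel()
  tv <- simulate_trait(panel, "moderately_low", 40, model = "VAR", seed = 8)
  contrib_v <- 2 * tv$qtl$p_pooled * (1 - tv$qtl$p_pooled) * tv$qtl$effect^2
  expect_lt(var(contrib_v), 1e-10)
  tr <- simulate_trait(panel, "moderately_low", 40, model = "RANDOM", seed = 8)
  contrib_r <- 2 * tr$qtl$p_pooled * (1 - tr$qtl$p_pooled) * tr$qtl$effect^2
  expect_gt(var(contrib_r), 1e-6)
})

test_that("trait simulation is reproducible from its seed", {
  panel <- shared_panel()
  t1 <- simulate_trait(panel, "very_low", 30, model = "VAR", seed = 9)
  t2 <- simulate_trait(panel, "very_low", 30, model = "VAR", seed = 9)
  expect_identical(t1$individuals, t2$individuals)
  expect_identical(t1$qtl, t2$qtl)
})
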
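test_that("model_spec validates reference and candidate sets", {
  expect_error(model_spec("a"), "at least 2")
  expect_error(model_spec(c("a", "b"), c("b", "c")), "disjoint")
  sp <- model_spec(c("a", "b"), "c", include_gw = FALSE)
  expect_false(sp$include_gw)
})

test_that("single-kernel REML matches a direct-search likelihood maximizer", {
  fix <- shared_greml_fixture()
  trait <- simulate_trait(fix$panel, "moderately_low", 40, model = "RANDOM",
                          h2 = 0.6, seed = 11)
  ref <- fix$ref[seq(1, 160, by = 6)] # n = 27 toy instance
  spec <- model_spec(ref, character(), include_gw = FALSE)
  fit <- fit_greml(trait, fix$rels, spec, ridge = 0)

  idx <- match(ref, fix$rels$ids)
  K_list <- list(fix$rels$G_a[idx, idx], diag(length(idx)))
  X <- matrix(1, length(idx), 1)
  y <- trait$individuals$phenotype[match(ref, trait$individuals$id)]
  best <- -Inf
  for (s in list(c(1, 1), c(0.2, 1.5), c(2, 0.3))) {
    o <- reml_grid_oracle(K_list, X, y, start = s * var(y) / 2)
    best <- max(best, o$loglik)
  }
  expect_equal(fit$loglik, best, tolerance = 1e-4)
})

test_that("two-kernel REML matches the likelihood-maximizer oracle on a toy instance", {
  fix <- shared_greml_fixture()
  trait <- simulate_trait(fix$panel, "very_low", 30, model = "RANDOM",
                          h2 = 0.8, seed = 12)
  ref <- fix$ref[seq(1, 160, by = 6)]
  spec <- model_spec(ref, character(), include_gw = TRUE)
  fit <- fit_greml(trait, fix$rels, spec, ridge = 1e-8)

  idx <- match(ref, fix$rels$ids)
  K_list <- list(fix$rels$G_a[idx, idx],
                 fix$rels$G_w[idx, idx] + diag(1e-8, length(idx)),
                 diag(length(idx)))
  X <- matrix(1, length(idx), 1)
  y <- trait$individuals$phenotype[match(ref, trait$individuals$id)]
  best <- -Inf
  for (s in list(c(1, 1, 1), c(2, 0.2, 1), c(0.2, 2, 0.5))) {
    o <- reml_grid_oracle(K_list, X, y, start = s * var(y) / 3)
    best <- max(best, o$loglik)
  }
  expect_equal(fit$loglik, best, tolerance = 1e-4)
})

test_that("the restricted likelihood never decreases across accepted iterations", {
  fix <- shared_greml_fixture()
  trait <- simulate_trait(fix$panel, "moderately_low", 40, model = "VAR",
                          h2 = 0.8, seed = 13)
  spec <- model_spec(fix$ref, fix$cand)
  fit <- fit_greml(trait, fix$rels, spec)
  expect_true(all(diff(fit$trace$loglik) >= -1e-8))
  expect_true(all(fit$varcomp$variance >= 0))
  expect_true(is.finite(fit$loglik))
})

test_that("noise-free data from the model drives the residual to its boundary", {
  fix <- shared_greml_fixture()
  ids <- fix$rels$ids
  n <- length(ids)
  K <- fix$rels$G_a + diag(1e-6, n)
  set.seed(14)
  y <- drop(crossprod(chol(K), rnorm(n))) # exact draw from N(0, K), no residual
  names(y) <- ids
  spec <- model_spec(ids, character(), include_gw = FALSE)
  fit <- fit_greml(y, fix$rels, spec)
  vc <- stats::setNames(fit$varcomp$variance, fit$varcomp$component)
  expect_lt(vc["e"] / vc["ga"], 0.05)
  expect_gt(estimate_h2(fit), 0.95)
})

test_that("predictions are translation-equivariant up to the intercept", {
  fix <- shared_greml_fixture()
  trait <- simulate_trait(fix$panel, "moderately_low", 40, model = "RANDOM",
                          h2 = 0.8, seed = 15)
  spec <- model_spec(fix$ref, fix$cand)
  f1 <- fit_greml(trait, fix$rels, spec)
  shifted <- trait$individuals
  shifted$phenotype <- shifted$phenotype + 7
  f2 <- fit_greml(shifted, fix$rels, spec)
  expect_equal(f2$beta$estimate[1] - f1$beta$estimate[1], 7, tolerance = 1e-4)
  expect_equal(f2$blup$ga, f1$blup$ga, tolerance = 1e-4)
  expect_equal(f2$blup$gw, f1$blup$gw, tolerance = 1e-4)
})

test_that("total breeding values add the across- and within-breed solutions", {
  fix <- shared_greml_fixture()
  trait <- simulate_trait(fix$panel, "moderately_low", 40, model = "RANDOM",
                          h2 = 0.8, seed = 16)
  spec <- model_spec(fix$ref, fix$cand)
  fit <- fit_greml(trait, fix$rels, spec)
  g <- total_gebv(fit)
  expect_setequal(g$id, fix$cand)
  expect_equal(g$gebv, g$ga + g$gw)
  # without the within-breed effect the total is the across-breed solution
  fit0 <- fit_greml(trait, fix$rels, model_spec(fix$ref, fix$cand,
                                                include_gw = FALSE))
  g0 <- total_gebv(fit0)
  expect_equal(g0$gebv, g0$ga)
  expect_true(all(g0$gw == 0))
  expect_error(total_gebv(fit, "nobody"), "unknown")
})

test_that("genomic heritability combines the variance components", {
  fake <- function(ga, gw, e) {
    structure(list(varcomp = tibble::tibble(
      component = c("ga", "gw", "e"), variance = c(ga, gw, e),
      boundary = FALSE, fixed = FALSE
    )), class = "greml_fit")
  }
  expect_equal(estimate_h2(fake(0.8, 0, 0.2)), 0.8)
  expect_equal(estimate_h2(fake(0.3, 0.3, 0.4)), 0.6)
  expect_error(estimate_h2(fake(0, 0, 0)), "zero")
})

test_that("the mixture chi-square 5% threshold is 2.71", {
  thr <- mixture_chisq_threshold(0.05)
  expect_equal(round(thr, 2), 2.71)
  # defining property: half the chi-square(1) tail mass at the threshold
  expect_equal(0.5 * stats::pchisq(thr, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-12)
})

test_that("the profile LRT is zero at the free split and non-negative elsewhere", {
  fix <- shared_greml_fixture()
  trait <- simulate_trait(fix$panel, "moderately_low", 40, model = "RANDOM",
                          h2 = 0.8, seed = 17)
  spec <- model_spec(fix$ref, fix$cand)
  free_fit <- fit_greml(trait, fix$rels, spec)
  th <- stats::setNames(free_fit$varcomp$variance, free_fit$varcomp$component)
  own_split <- 100 * th["gw"] / (th["ga"] + th["gw"])
  prof <- profile_lrt(trait, fix$rels, spec,
                      fractions = c(1, own_split, 99), free_fit = free_fit)
  expect_true(all(prof$lrt >= -1e-6))
  expect_lt(prof$lrt[2], 1e-3)
  expect_equal(attr(prof, "threshold"), mixture_chisq_threshold())
})

test_that("glance and tidy expose the fit in broom form", {
  fix <- shared_greml_fixture()
  trait <- simulate_trait(fix$panel, "very_low", 30, model = "RANDOM",
                          h2 = 0.8, seed = 18)
  fit <- fit_greml(trait, fix$rels, model_spec(fix$ref, fix$cand))
  gl <- glance(fit)
  expect_named(gl, c("loglik", "converged", "n_iter", "var_ga", "var_gw",
                     "var_e", "h2_hat"))
  expect_equal(nrow(gl), 1L)
  td <- tidy(fit)
  expect_equal(td$component, c("ga", "gw", "e"))
  expect_equal(gl$h2_hat, estimate_h2(fit))
})
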
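test_that("breed inbreeding since divergence matches the printed formula", {
  # undiverged: identical frequencies give zero inbreeding
  f0 <- multibreed:::pooled_freqs(0.5, 0.5)
  expect_equal(unname(f0$F_breed), c(0, 0))
  expect_equal(f0$F, 0)
  expect_equal(f0$p_j, 0.5)

  # one locus, p_HF = 0.5, p_Jer = 0.1:
  # F_Jer = 1 - 2*0.1*0.9 / (0.5*0.9 + 0.1*0.5) = 1 - 0.18/0.50 = 0.64
  f1 <- multibreed:::pooled_freqs(0.5, 0.1)
  expect_equal(unname(f1$F_breed["J"]), 0.64, tolerance = 1e-12)
  expect_equal(unname(f1$F_breed["HF"]), 0, tolerance = 1e-12)
  # alpha = F_Jer / (F_Jer + F_HF) = 1, so p_j = p_HF
  expect_equal(f1$alpha, 1)
  expect_equal(f1$p_j, 0.5)
  expect_equal(f1$F, 0)

  p1 <- c(0.5, 0.3); p2 <- c(0.2, 0.4)
  fr <- multibreed:::pooled_freqs(p1, p2)
  expect_equal(fr$alpha, unname(fr$F_breed[2] / sum(fr$F_breed)))
  expect_equal(fr$p_j, fr$alpha * p1 + (1 - fr$alpha) * p2)
  expect_equal(fr$F, unname(prod(fr$F_breed) / sum(fr$F_breed)))
  expect_lte(fr$F, min(fr$F_breed))

  expect_error(multibreed:::pooled_freqs(c(0, 1), c(0, 1)), "monomorphic")
})

test_that("estimated breed inbreeding increases with the simulated divergence", {
  cls <- variant_class("snp_panel", 600, 0.27, beta_shape = 1.4)
  est <- vapply(c(0.03, 0.12, 0.3), function(fst) {
    pops <- list(breed_population("HF", 80, fst, seed = 21),
                 breed_population("J", 80, fst, seed = 22))
    panel <- simulate_two_breed_panel(cls, pops, seed = 23)
    mean(compute_breed_inbreeding(panel)$F_breed)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("build_G matches a naive per-element double-loop oracle", {
  set.seed(31)
  geno <- matrix(rbinom(20 * 50, 2, runif(50, 0.05, 0.95)),
                 nrow = 20, byrow = TRUE)
  panel <- toy_panel(geno, rep(c("HF", "J"), each = 10))
  freqs <- compute_breed_inbreeding(panel)
  G <- build_G(panel, freqs = freqs)
  p <- freqs$p_j
  denom <- 2 * sum(p * (1 - p))
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (k in 1:20) {
      oracle[i, k] <- sum((geno[i, ] - 2 * p) * (geno[k, ] - 2 * p)) / denom
    }
  }
  expect_equal(unname(G), oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(G), t(unclass(G)), ignore_attr = TRUE)
})

test_that("monomorphic loci contribute nothing to G", {
  geno <- cbind(c(0L, 1L, 2L, 1L), c(2L, 2L, 2L, 2L), c(0L, 0L, 0L, 0L))
  panel <- toy_panel(geno, c("HF", "HF", "J", "J"))
  G_all <- build_G(panel, loci = 1:3)
  G_poly <- build_G(panel, loci = 1L)
  expect_equal(unname(G_all), unname(G_poly), ignore_attr = TRUE)
  expect_error(build_G(panel, loci = 2:3), "monomorphic")
})

test_that("a heterozygote at frequency one half carries zero relationship", {
  geno <- matrix(c(1L, 1L), nrow = 2)
  panel <- toy_panel(geno, c("HF", "J"))
  G <- build_G(panel)
  expect_equal(unname(G), matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("rescaling to the divergence base is the documented affine map", {
  fix <- shared_greml_fixture()
  rels <- fix$rels
  Fc <- rels$freqs$F
  expect_equal(rels$G_star, rels$G * (1 - Fc) + 2 * Fc, ignore_attr = TRUE)
  # A* within-breed blocks: A (1 - (F_b - f_b)) + 2 (F_b - f_b)
  for (b in rels$f$breed) {
    rows <- which(rels$breed_of == b)
    delta <- unname(rels$freqs$F_breed[b]) - rels$f$f[rels$f$breed == b]
    expect_equal(rels$A_star[rows, rows],
                 rels$A[rows, rows] * (1 - delta) + 2 * delta)
    expect_true(all(rels$A_star[rows, -rows] == 0))
  }
  # F = 0.1 on an element of 0.5: 0.5 * 0.9 + 0.2 = 0.65
  pa <- build_pedigree_A(fix$panel)
  fr <- rels$freqs
  fr$F <- 0.1
  star <- rescale_to_base(matrix(0.5, length(pa$ids), length(pa$ids)), pa, fr)
  expect_equal(star$G_star[1, 2], 0.65)
  # F = 0: G* equals G
  fr$F <- 0
  fr$F_breed[] <- pa$f$f[match(names(fr$F_breed), pa$f$breed)]
  star0 <- rescale_to_base(rels$G, pa, fr)
  expect_equal(star0$G_star, rels$G, ignore_attr = TRUE)
  expect_equal(star0$A_star, pa$A, ignore_attr = TRUE)
})

test_that("regression towards A interpolates between G* and A*", {
  fix <- shared_greml_fixture()
  rels <- fix$rels
  pa <- list(A = rels$A, breed_of = rels$breed_of)
  # no variance information: b = 1 everywhere, G_a = G*
  r1 <- regress_G_on_A(rels$G_star, rels$A_star, rels$A, rels$breed_of,
                       var_G_star = NULL)
  expect_equal(r1$G_a, rels$G_star, ignore_attr = TRUE)
  expect_true(all(r1$b_bin$b == 1))
  # overwhelming sampling variance: b = 0 in every occupied bin, G_a = A*
  big <- matrix(1e9, nrow(rels$G), ncol(rels$G))
  r0 <- regress_G_on_A(rels$G_star, rels$A_star, rels$A, rels$breed_of,
                       var_G_star = big)
  occupied <- r0$b_bin$n_elements >= 2
  expect_true(all(r0$b_bin$b[occupied] == 0))
  expect_equal(r0$G_a, rels$A_star, ignore_attr = TRUE)
  # actual coefficients lie in [0, 1] and G_a stays symmetric
  expect_true(all(rels$b_bin$b >= 0 & rels$b_bin$b <= 1.05))
  expect_equal(rels$G_a, t(rels$G_a))
})

test_that("family-bin shrinkage weakens as marker density grows", {
  panel <- shared_panel()
  get_b <- function(n_snps) {
    snps <- ascertain_snp_panel(panel, n_snps, min_maf = 0.05, seed = 77)
    b <- build_relationships(panel, snps)$b_bin
    fam <- b$bin %in% c("[0.25,0.50)", "[0.50,Inf)") & b$n_elements >= 2
    stats::weighted.mean(b$b[fam], b$n_elements[fam])
  }
  b_sparse <- get_b(150)
  b_dense <- get_b(1000)
  expect_gt(b_dense, b_sparse)
  expect_gt(b_dense, 0.3)
})

test_that("masking zeroes exactly the across-breed block", {
  G <- matrix(1:16, 4, 4)
  G <- G + t(G)
  breed_of <- c("HF", "HF", "J", "J")
  Gw <- mask_within(G, breed_of)
  expect_equal(Gw[1:2, 1:2], G[1:2, 1:2])
  expect_equal(Gw[3:4, 3:4], G[3:4, 3:4])
  expect_true(all(Gw[1:2, 3:4] == 0) && all(Gw[3:4, 1:2] == 0))
  expect_equal(mask_within(G, rep("HF", 4)), G)
  # complement check: G - Gw vanishes on within-breed blocks
  D <- G - Gw
  expect_true(all(D[1:2, 1:2] == 0) && all(D[3:4, 3:4] == 0))
})

test_that("within-breed blocks of the relationship set stay positive semidefinite", {
  rels <- shared_greml_fixture()$rels
  for (b in unique(rels$breed_of)) {
    rows <- which(rels$breed_of == b)
    ev <- eigen(rels$G_w[rows, rows], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  expect_equal(rels$G_w, mask_within(rels$G_a, rels$breed_of))
})

test_that("marker subsets run through one code path with stable locus indices", {
  panel <- shared_panel()
  snps <- ascertain_snp_panel(panel, 300, seed = 5)
  qtl <- sample_qtl(panel, "moderately_low", 20, seed = 6)
  G_sub <- build_G(panel, snps)
  G_plus <- build_G(panel, sort(union(snps, qtl)))
  expect_false(isTRUE(all.equal(G_sub, G_plus, check.attributes = FALSE)))
  expect_identical(dim(G_sub), dim(G_plus))
  expect_error(build_G(panel, integer(0)), "no markers")
  expect_error(build_G(panel, 1e7), "outside")
})
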
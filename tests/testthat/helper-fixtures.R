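# shared fixtures, built once per test run

# hand-made panel: direct construction from a genotype matrix, for unit
# tests that need exact control over genotypes and frequencies
toy_panel <- function(geno, breeds_of, class_label = "snp_panel") {
  breeds <- unique(breeds_of)
  stopifnot(length(breeds) <= 2L)
  if (length(breeds) == 1L) breeds <- c(breeds, ".absent")
  ids <- sprintf("I%02d", seq_len(nrow(geno)))
  rownames(geno) <- ids
  colnames(geno) <- sprintf("L%05d", seq_len(ncol(geno)))
  obs <- lapply(breeds, function(b) {
    if (any(breeds_of == b)) {
      colMeans(geno[breeds_of == b, , drop = FALSE]) / 2
    } else {
      rep(0, ncol(geno))
    }
  })
  nb <- vapply(breeds, function(b) sum(breeds_of == b), integer(1))
  p_pool <- colMeans(geno) / 2
  loci <- tibble::tibble(
    locus = colnames(geno), class = class_label,
    chrom = 1L, pos = seq_len(ncol(geno)) / ncol(geno),
    p_anc = NA_real_, p_pooled = p_pool,
    maf_pooled = pmin(p_pool, 1 - p_pool),
    monomorphic = p_pool <= 0 | p_pool >= 1
  )
  for (k in 1:2) {
    loci[[paste0("p_", breeds[k])]] <- obs[[k]]
    loci[[paste0("seg_", breeds[k])]] <- obs[[k]] > 0 & obs[[k]] < 1
  }
  structure(
    list(
      geno = geno,
      indiv = tibble::tibble(id = ids, breed = breeds_of,
                             sire = NA_character_, dam = NA_character_,
                             sex = NA_character_, generation = 0L),
      loci = loci, breeds = breeds,
      classes = tibble::tibble(class = class_label, n_loci = ncol(geno),
                               target_maf = 0.25, beta_shape = 1)
    ),
    class = "genotype_panel"
  )
}

# one simulated mid-size two-breed panel shared across test files
shared_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) {
      pops <- list(breed_population("HF", 120, 0.10, seed = 101),
                   breed_population("J", 120, 0.14, seed = 102))
      cls <- default_variant_classes(c(500L, 500L, 400L), 1200L)
      panel <<- simulate_two_breed_panel(cls, pops, seed = 4242)
    }
    panel
  }
})

# independent recursive tabular-method oracle for pedigree relationships
relationship_oracle <- function(ped) {
  pos <- stats::setNames(seq_len(nrow(ped)), ped$id)
  memo <- new.env()
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- if (is.na(ped$sire[j])) 0L else pos[[ped$sire[j]]]
    d <- if (is.na(ped$dam[j])) 0L else pos[[ped$dam[j]]]
    val <- if (i == j) 1 + 0.5 * a(s, d) else 0.5 * (a(i, s) + a(i, d))
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  outer(seq_len(n), seq_len(n), Vectorize(a))
}

# independent dense REML log-likelihood (textbook formula, base solve())
# for oracle maximization; deliberately a different code path than the
# package's Cholesky-based evaluator
reml_loglik_oracle <- function(theta, K_list, X, y) {
  V <- Reduce(`+`, Map(`*`, theta, K_list))
  detV <- determinant(V, logarithm = TRUE)
  if (detV$sign <= 0) return(-Inf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  detX <- determinant(XtViX, logarithm = TRUE)
  if (detX$sign <= 0) return(-Inf)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (as.numeric(detV$modulus) + as.numeric(detX$modulus) +
            drop(t(y) %*% P %*% y))
}

# direct-search maximizer of the oracle likelihood over log-variances
reml_grid_oracle <- function(K_list, X, y, start = NULL) {
  if (is.null(start)) start <- rep(stats::var(y) / length(K_list), length(K_list))
  obj <- function(lt) -reml_loglik_oracle(exp(lt), K_list, X, y)
  opt <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(theta = exp(opt$par), loglik = -opt$value)
}

# small end-to-end fixture for GREML tests: panel, relationships, split
shared_greml_fixture <- local({
  fix <- NULL
  function() {
    if (is.null(fix)) {
      panel <- shared_panel()
      snps <- ascertain_snp_panel(panel, 700, min_maf = 0.05, seed = 7)
      rels <- build_relationships(panel, snps)
      ids <- panel$indiv$id
      set.seed(99)
      cand <- c(sample(ids[1:120], 40), sample(ids[121:240], 40))
      ref <- setdiff(ids, cand)
      fix <<- list(panel = panel, rels = rels, ref = ref, cand = cand)
    }
    fix
  }
})
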
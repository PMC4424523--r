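#' Sample QTL positions from a variant class
#'
#' Draws a uniform sample, without replacement, from the loci of one
#' variant class that segregate in the pooled sample (monomorphic loci are
#' never eligible as QTL).
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param class_label class to sample from.
#' @param n_qtl number of QTL (commonly 100 or 1000).
#' @param seed integer seed.
#' @return An integer vector of locus (column) indices.
#' @export
sample_qtl <- function(panel, class_label, n_qtl, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  eligible <- which(panel$loci$class == class_label & !panel$loci$monomorphic)
  n_qtl <- as.integer(n_qtl)
  if (n_qtl > length(eligible)) {
    abort(sprintf(
      "class '%s' has only %d loci segregating in the pooled sample; %d QTL requested.",
      class_label, length(eligible), n_qtl
    ))
  }
  with_seed_if(seed, sort(sample(eligible, n_qtl)))
}

#' Allele substitution effects under the pseudo-infinitesimal (RANDOM) model
#'
#' Effect magnitudes are drawn i.i.d. from a gamma distribution with shape
#' 0.4 and scale 1.66 (mean effect 0.664), independently of allele
#' frequency; each effect then receives a positive or negative sign with
#' equal probability.
#'
#' @param n_qtl number of effects.
#' @param shape,scale gamma parameters (scale, not rate).
#' @param seed integer seed.
#' @return A numeric vector of signed effects.
#' @export
#' @examples
#' mean(abs(effects_random(1e4, seed = 1))) # ~ 0.4 * 1.66
effects_random <- function(n_qtl, shape = 0.4, scale = 1.66, seed = NULL) {
  stopifnot(n_qtl >= 1L)
  if (shape <= 0 || scale <= 0) abort("gamma `shape` and `scale` must be positive.")
  with_seed_if(seed, {
    mag <- rgamma(n_qtl, shape = shape, scale = scale)
    sgn <- sample(c(-1, 1), n_qtl, replace = TRUE)
    mag * sgn
  })
}

#' Allele substitution effects under the equal-variance (VAR) model
#'
#' The "rare allele, large effect" model: each QTL explains the same amount
#' of genetic variance, so the magnitude at pooled allele frequency `p` is
#' `a = sqrt(var_qtl / (2 p (1 - p)))`; under Hardy-Weinberg at `p` the
#' variance contributed, `2 p (1 - p) a^2`, equals `var_qtl` for every QTL.
#' Signs are assigned by a fair coin.
#'
#' @param p_pooled per-QTL allele frequency across all individuals of both
#'   breeds (the plain unweighted pooled frequency, not the alpha-weighted
#'   one used in the G matrix).
#' @param var_qtl variance explained per QTL.
#' @param seed integer seed.
#' @return A numeric vector of signed effects aligned with `p_pooled`.
#' @export
#' @examples
#' abs(effects_var(0.5, seed = 1)) # sqrt(2)
effects_var <- function(p_pooled, var_qtl = 1, seed = NULL) {
  if (any(p_pooled <= 0 | p_pooled >= 1)) {
    abort("monomorphic QTL: every pooled frequency must lie strictly in (0, 1).")
  }
  stopifnot(var_qtl > 0)
  mag <- sqrt(var_qtl / (2 * p_pooled * (1 - p_pooled)))
  with_seed_if(seed, mag * sample(c(-1, 1), length(mag), replace = TRUE))
}

#' True breeding values from QTL genotypes and effects
#'
#' Multiplies allele substitution effects by the genotype codes (0, 1, 2)
#' and sums over QTL, then rescales the result over all individuals and
#' across the breeds to mean 0 and variance 1. Per-breed means of the
#' rescaled values are the breed effects.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param qtl_loci locus indices of the QTL.
#' @param effects signed allele substitution effects aligned with
#'   `qtl_loci`.
#' @param model label recording the effect model used.
#' @return A list of class `trait_data`: `individuals` (tibble `id`,
#'   `breed`, `tbv`), `qtl` (tibble `locus`, `class`, `p_pooled`,
#'   `effect`), `breed_effect` (tibble `breed`, `effect`), `model`;
#'   phenotype fields are added by [simulate_phenotypes()].
#' @export
compute_tbv <- function(panel, qtl_loci, effects, model = "custom") {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- resolve_loci(panel, qtl_loci)
  if (length(effects) != length(idx)) {
    abort("`effects` must align one-to-one with `qtl_loci`.")
  }
  raw <- unname(drop(panel$geno[, idx, drop = FALSE] %*% effects))
  s <- sd(raw)
  if (!is.finite(s) || s <= 0) {
    abort("true breeding values have zero variance; check the QTL effects.")
  }
  tbv <- (raw - mean(raw)) / s
  individuals <- tibble(id = panel$indiv$id, breed = panel$indiv$breed, tbv = tbv)
  breed_effect <- individuals %>%
    group_by(.data$breed) %>%
    summarise(effect = mean(.data$tbv), .groups = "drop")
  structure(
    list(
      individuals = individuals,
      qtl = tibble(locus = panel$loci$locus[idx],
                   class = panel$loci$class[idx],
                   p_pooled = panel$loci$p_pooled[idx],
                   effect = effects),
      breed_effect = breed_effect,
      model = model, h2 = NA_real_, env_var = NA_real_
    ),
    class = "trait_data"
  )
}

#' Simulate phenotypes at a fixed heritability
#'
#' Breed effects are first subtracted from the true breeding values so they
#' do not inflate the simulated heritability; the environmental variance is
#' then `(1 / h2 - 1)` times the variance of the breed-corrected TBV, and
#' each phenotype is the sum of the individual's TBV (breed effect
#' included) and a normal environmental deviate.
#'
#' @param trait a [compute_tbv()] result.
#' @param h2 narrow-sense heritability in (0, 1]; with `h2 = 1` phenotypes
#'   equal the TBV exactly.
#' @param seed integer seed.
#' @return The `trait_data` object with `phenotype` added to
#'   `$individuals` and `h2`, `env_var` filled in.
#' @export
simulate_phenotypes <- function(trait, h2 = 0.8, seed = NULL) {
  stopifnot(inherits(trait, "trait_data"))
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1) {
    abort("`h2` must lie in (0, 1].")
  }
  ind <- trait$individuals
  corrected <- ind$tbv -
    trait$breed_effect$effect[match(ind$breed, trait$breed_effect$breed)]
  env_var <- (1 / h2 - 1) * var(corrected)
  ind$phenotype <- with_seed_if(seed, {
    ind$tbv + if (env_var > 0) rnorm(nrow(ind), 0, sqrt(env_var)) else 0
  })
  trait$individuals <- ind
  trait$h2 <- h2
  trait$env_var <- env_var
  trait
}

#' Simulate a complete trait for a panel
#'
#' One-call wrapper: sample QTL from a class, draw allele substitution
#' effects under the RANDOM (gamma) or VAR (equal-variance) model, compute
#' rescaled true breeding values and simulate phenotypes.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param class_label variant class to draw QTL from.
#' @param n_qtl number of QTL.
#' @param model `"RANDOM"` or `"VAR"`.
#' @param h2 heritability.
#' @param var_qtl per-QTL variance for the VAR model.
#' @param shape,scale gamma parameters for the RANDOM model.
#' @param seed integer seed covering QTL sampling, effects and phenotypes.
#' @return A `trait_data` object, see [compute_tbv()].
#' @export
#' @examples
#' pops <- list(breed_population("HF", 40, 0.10, seed = 1),
#'              breed_population("J", 40, 0.14, seed = 2))
#' panel <- simulate_two_breed_panel(default_variant_classes(c(80, 80, 40), 100),
#'                                   pops, seed = 3)
#' trait <- simulate_trait(panel, "moderately_low", n_qtl = 20,
#'                         model = "RANDOM", seed = 4)
#' trait
simulate_trait <- function(panel, class_label, n_qtl, model = c("RANDOM", "VAR"),
                           h2 = 0.8, var_qtl = 1, shape = 0.4, scale = 1.66,
                           seed = NULL) {
  model <- match.arg(model)
  with_seed_if(seed, {
    qtl <- sample_qtl(panel, class_label, n_qtl)
    effects <- switch(
      model,
      RANDOM = effects_random(n_qtl, shape = shape, scale = scale),
      VAR = effects_var(panel$loci$p_pooled[qtl], var_qtl = var_qtl)
    )
    trait <- compute_tbv(panel, qtl, effects, model = model)
    simulate_phenotypes(trait, h2 = h2)
  })
}

#' @export
print.trait_data <- function(x, ...) {
  cat(sprintf("<trait_data> %d individuals, %d QTL (%s model), h2 = %s\n",
              nrow(x$individuals), nrow(x$qtl), x$model,
              ifelse(is.na(x$h2), "unset", format(x$h2))))
  print(x$breed_effect)
  invisible(x)
}

#' @describeIn compute_tbv tidy accessor: the per-individual tibble
#'   (`id`, `breed`, `tbv`, `phenotype` when simulated).
#' @param x a `trait_data` object.
#' @param ... unused.
#' @export
tidy.trait_data <- function(x, ...) x$individuals
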
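#' Define a variant class by its ancestral allele-frequency spectrum
#'
#' A variant class groups loci that share an ancestral allele-frequency
#' distribution and a target pooled minor allele frequency (MAF). Three QTL
#' classes with decreasing average MAF (moderately low ~0.122, very low
#' ~0.077, extremely low ~0.016) emulate annotated sequence-variant classes
#' ranging from effectively neutral to strongly selected, and a `snp_panel`
#' class with a much higher average MAF (~0.27) emulates an ascertained
#' SNP chip.
#'
#' Ancestral frequencies are drawn from a one-parameter Beta family indexed
#' by a shape `t`: for `t >= 1` the symmetric Beta(t, t) (uniform at
#' `t = 1`, concentrating on 0.5 as `t` grows), and for `t < 1` the skewed
#' Beta(1, 1/t), which piles mass on rare derived alleles the smaller `t`
#' gets. When `beta_shape` is `NULL` it is tuned by
#' [tune_ancestral_shape()] so that the realized pooled average MAF of
#' segregating loci matches `target_maf`.
#'
#' @param label one of `"moderately_low"`, `"very_low"`, `"extremely_low"`,
#'   `"snp_panel"`, or any other single string naming the class.
#' @param n_loci number of loci to simulate for this class.
#' @param target_maf target pooled average MAF of segregating loci, in
#'   (0, 0.5].
#' @param beta_shape optional shape of the ancestral Beta family; tuned
#'   from `target_maf` at panel-build time when `NULL`.
#' @return A one-row tibble with columns `class`, `n_loci`, `target_maf`,
#'   `beta_shape`.
#' @export
#' @examples
#' variant_class("extremely_low", n_loci = 1000, target_maf = 0.016)
variant_class <- function(label, n_loci, target_maf, beta_shape = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort("`label` must be a single non-empty string.")
  }
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) {
    abort(sprintf("class '%s' is degenerate: `n_loci` must be >= 1.", label))
  }
  if (!is.numeric(target_maf) || target_maf <= 0 || target_maf > 0.5) {
    abort(sprintf("class '%s': `target_maf` must lie in (0, 0.5].", label))
  }
  tibble(
    class = label,
    n_loci = n_loci,
    target_maf = target_maf,
    beta_shape = if (is.null(beta_shape)) NA_real_ else as.numeric(beta_shape)
  )
}

#' Default variant classes at desk scale
#'
#' Three QTL classes with pooled-MAF targets 0.122, 0.077 and 0.016 and an
#' ascertainment-biased SNP-panel class with target 0.27, sized for a
#' desk-scale run (4000/4000/6000 QTL-class loci, 5000 panel loci). The
#' extremely-low class is deliberately larger than its share of the trait
#' architecture: at its target MAF under two-breed drift only a few
#' percent of its loci stay polymorphic in a desk-scale sample, and the
#' class must still supply at least 100 segregating potential QTL.
#'
#' @param n_qtl_loci lengths of the three QTL classes
#'   (moderately low, very low, extremely low).
#' @param n_panel_loci number of SNP-panel loci.
#' @return A tibble with one row per class, see [variant_class()].
#' @export
default_variant_classes <- function(n_qtl_loci = c(4000L, 4000L, 6000L),
                                    n_panel_loci = 5000L) {
  stopifnot(length(n_qtl_loci) == 3L)
  bind_rows(
    variant_class("moderately_low", n_qtl_loci[1], 0.122),
    variant_class("very_low", n_qtl_loci[2], 0.077),
    variant_class("extremely_low", n_qtl_loci[3], 0.016),
    variant_class("snp_panel", n_panel_loci, 0.27)
  )
}

#' Tune the ancestral Beta shape for a target pooled MAF
#'
#' One-dimensional search for the shape `t` of the ancestral Beta family
#' (Beta(1, 1/t) for `t < 1`, Beta(t, t) for `t >= 1`; see
#' [variant_class()]) such that, after Balding-Nichols drift in the two
#' breeds and binomial genotype sampling, the average pooled MAF of loci
#' segregating in the pooled sample matches `target_maf`. Conditioning on
#' segregation matters: for low targets most loci end up monomorphic in a
#' finite sample, and the folded spectrum of the survivors is what the
#' target describes. The objective is evaluated on a fixed set of uniform
#' draws (common random numbers), so the search is deterministic and
#' smooth in the shape.
#'
#' @param target_maf target pooled average MAF of segregating loci.
#' @param fst length-2 divergence (Fst) parameters of the two breeds.
#' @param n_per_breed diploid individuals per breed used for the sampling
#'   layer of the surrogate (ignored when `gen_structure` is given).
#' @param gen_structure optional list of two per-breed lists, each with
#'   `census` (individuals per discrete generation, founders first) and
#'   `ne` (effective number of parents behind each offspring generation,
#'   `4 Nm Nf / (Nm + Nf)`). When supplied, the surrogate layers
#'   per-generation drift at `F = 1/(2 Ne)` between the binomial sampling
#'   steps, capturing the strong drift of popular-sire pedigrees where a
#'   handful of sires dominates the offspring gene pool.
#' @param n_mc number of Monte Carlo loci in the surrogate.
#' @param seed integer seed for the surrogate draws.
#' @return The tuned shape (a single positive number).
#' @export
tune_ancestral_shape <- function(target_maf, fst = c(0.10, 0.14),
                                 n_per_breed = c(200L, 200L),
                                 gen_structure = NULL,
                                 n_mc = 8000L, seed = 1L) {
  stopifnot(target_maf > 0, target_maf <= 0.5, length(fst) == 2L)
  if (is.null(gen_structure)) {
    gen_structure <- lapply(1:2, function(k) {
      list(census = as.integer(n_per_breed[k]), ne = numeric(0))
    })
  }
  n_gen <- vapply(gen_structure, function(s) length(s$census), integer(1))
  n_u <- 1L + sum(1L + n_gen + pmax(n_gen - 1L, 0L))
  u <- with_seed_if(seed, matrix(runif(n_u * n_mc), ncol = n_u))
  total_alleles <- sum(vapply(gen_structure, function(s) 2L * sum(s$census),
                              integer(1)))
  realized <- function(log_shape) {
    s <- exp(log_shape)
    p_anc <- ancestral_freq_q(u[, 1L], s)
    col <- 1L
    x <- 0
    for (k in 1:2) {
      st <- gen_structure[[k]]
      col <- col + 1L
      q <- drift_freq_q(u[, col], p_anc, fst[k])
      for (g in seq_along(st$census)) {
        if (g > 1L) {
          # family drift between generations: BN step at F = 1/(2 Ne)
          col <- col + 1L
          q <- drift_freq_q(u[, col], q, min(0.5, 1 / (2 * st$ne[g - 1L])))
        }
        col <- col + 1L
        xg <- stats::qbinom(u[, col], 2L * st$census[g], q)
        if (g < length(st$census)) {
          # later generations inherit from this one's realized pool
          q <- xg / (2L * st$census[g])
        }
        x <- x + xg
      }
    }
    p_pool <- x / total_alleles
    seg <- p_pool > 0 & p_pool < 1
    if (!any(seg)) return(0)
    mean(pmin(p_pool[seg], 1 - p_pool[seg]))
  }
  obj <- function(log_shape) (realized(log_shape) - target_maf)^2
  opt <- optimize(obj, interval = log(c(1e-4, 1e3)), tol = 1e-3)
  exp(opt$minimum)
}

# per-generation census and effective parent numbers of one pedigree
pedigree_gen_structure <- function(ped) {
  gens <- sort(unique(ped$generation))
  census <- vapply(gens, function(g) sum(ped$generation == g), integer(1))
  ne <- vapply(gens[-1], function(g) {
    off <- ped[ped$generation == g, ]
    nm <- length(unique(off$sire))
    nf <- length(unique(off$dam))
    4 * nm * nf / (nm + nf)
  }, numeric(1))
  list(census = census, ne = ne)
}

# quantile function of the one-parameter ancestral Beta family
ancestral_freq_q <- function(u, shape) {
  if (shape >= 1) stats::qbeta(u, shape, shape) else stats::qbeta(u, 1, 1 / shape)
}

ancestral_freq_r <- function(n, shape) {
  if (shape >= 1) rbeta(n, shape, shape) else rbeta(n, 1, 1 / shape)
}

# Balding-Nichols quantile transform: per-breed frequency given ancestral p
# and divergence F, via Beta(p(1-F)/F, (1-p)(1-F)/F). F below ~1e-10 is
# treated as no drift. Degenerate ancestral p (0 or 1) maps to itself.
drift_freq_q <- function(u, p_anc, fst) {
  if (fst < 1e-10) return(p_anc)
  c0 <- (1 - fst) / fst
  # qbeta warns about reduced precision for near-degenerate shapes; those
  # quantiles are 0/1 to machine precision, which is exactly what we want
  out <- suppressWarnings(
    stats::qbeta(u, pmax(p_anc * c0, 1e-12), pmax((1 - p_anc) * c0, 1e-12))
  )
  out[p_anc <= 0] <- 0
  out[p_anc >= 1] <- 1
  out
}

#' Define a breed population with a shallow within-breed pedigree
#'
#' Builds the pedigree scaffold for one breed: `n_generations` discrete,
#' non-overlapping generations of within-breed matings with a dairy-like
#' family structure. Founders are unrelated and non-inbred. In each later
#' generation a small fraction of individuals (`prop_male`) are male;
#' every dam is assigned a single random sire from the previous
#' generation and offspring are allocated to dams evenly, so the pedigree
#' carries full-sib families nested in large paternal half-sib families -
#' the relationship structure genomic prediction feeds on. Matings never
#' cross breeds.
#'
#' @param breed_label breed name, conventionally `"HF"` or `"J"`.
#' @param n_individuals total individuals in the breed (all generations).
#' @param fst divergence of the breed from the common ancestral population,
#'   in (0, 1).
#' @param founder_frac fraction of individuals that are founders.
#' @param n_generations number of discrete generations (>= 1); with 2 the
#'   pedigree holds founders plus one offspring generation.
#' @param prop_male fraction of males per generation (popular-sire
#'   breeding uses few males).
#' @param seed integer seed for the random matings.
#' @return A list of class `breed_population` with elements `breed`, `fst`
#'   and `pedigree` (tibble: `id`, `sire`, `dam`, `sex`, `generation`;
#'   unknown parents are `NA`).
#' @export
#' @examples
#' hf <- breed_population("HF", 60, fst = 0.10, seed = 1)
#' dplyr::count(hf$pedigree, generation)
breed_population <- function(breed_label, n_individuals, fst,
                             founder_frac = 1 / 3, n_generations = 2L,
                             prop_male = 0.1, seed = NULL) {
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1) {
    abort("`fst` must lie strictly inside (0, 1).")
  }
  n_individuals <- as.integer(n_individuals)
  stopifnot(n_individuals >= 1L, n_generations >= 1L,
            founder_frac > 0, founder_frac <= 1)
  ped <- with_seed_if(seed, {
    n_found <- if (n_generations == 1L) n_individuals else
      max(2L, ceiling(n_individuals * founder_frac))
    n_found <- min(n_found, n_individuals)
    sizes <- c(n_found, rep(0L, n_generations - 1L))
    if (n_generations > 1L) {
      remaining <- n_individuals - n_found
      per_gen <- floor(remaining / (n_generations - 1L))
      sizes[-1L] <- per_gen
      sizes[n_generations] <- remaining - per_gen * (n_generations - 2L)
    }
    ids <- sprintf("%s_%04d", breed_label, seq_len(n_individuals))
    gen <- rep(seq_len(n_generations) - 1L, times = sizes)
    sex <- character(n_individuals)
    sire <- dam <- rep(NA_character_, n_individuals)
    for (g in seq_len(n_generations) - 1L) {
      idx <- which(gen == g)
      n_m <- max(2L, round(prop_male * length(idx)))
      sex[idx] <- sample(rep_len(c(rep("M", n_m), rep("F", length(idx))),
                                 length(idx)))
      if (g > 0L) {
        prev <- which(gen == g - 1L)
        males <- ids[prev][sex[prev] == "M"]
        females <- ids[prev][sex[prev] == "F"]
        # one sire per dam, offspring spread evenly over dams: full-sib
        # families nested in paternal half-sib families
        sire_of_dam <- setNames(sample(males, length(females), replace = TRUE),
                                females)
        dam[idx] <- rep_len(sample(females), length(idx))
        sire[idx] <- sire_of_dam[dam[idx]]
      }
    }
    tibble(id = ids, sire = sire, dam = dam, sex = sex, generation = gen)
  })
  structure(
    list(breed = breed_label, fst = fst, pedigree = ped),
    class = "breed_population"
  )
}

#' @export
print.breed_population <- function(x, ...) {
  cat(sprintf("<breed_population> %s: %d individuals, Fst = %.3f, %d generation(s)\n",
              x$breed, nrow(x$pedigree), x$fst, max(x$pedigree$generation) + 1L))
  invisible(x)
}

#' Simulate a two-breed genotype panel
#'
#' For each locus an ancestral allele frequency is drawn from its class
#' distribution, per-breed frequencies are derived by a Balding-Nichols
#' drift model with each breed's Fst, founder haplotypes are drawn
#' independently per locus at the breed frequencies (complete linkage
#' equilibrium, Hardy-Weinberg within breed), and pedigree offspring
#' receive genotypes by gene-dropping: each locus is placed uniformly on a
#' genetic map of `n_chromosomes` chromosomes of `map_length` Morgan, and
#' each parent transmits one recombinant haplotype per meiosis (Haldane
#' model). Linked transmission gives realized relationships genuine
#' Mendelian-sampling variation around the pedigree expectation - the
#' signal the genomic relationship matrix exists to capture - while the
#' founder population carries no linkage disequilibrium at all. Loci
#' monomorphic in the pooled sample are flagged, not removed, so locus
#' indices stay stable across marker subsets.
#'
#' @param classes tibble of variant classes, see [variant_class()]. Classes
#'   with missing `beta_shape` are tuned first via [tune_ancestral_shape()].
#' @param pops list of two [breed_population()] objects with distinct labels.
#' @param seed integer seed; the same seed yields a bit-identical panel.
#' @param n_chromosomes,map_length genetic map used for gene-dropping:
#'   number of chromosomes and length of each in Morgan.
#' @return A list of class `genotype_panel` with elements
#'   \describe{
#'     \item{geno}{integer matrix, individuals x loci, entries 0/1/2
#'       counting copies of the allele coded 2.}
#'     \item{indiv}{tibble `id`, `breed`, `sire`, `dam`, `sex`, `generation`.}
#'     \item{loci}{tibble per locus: `locus`, `class`, `p_anc`, observed
#'       per-breed frequencies `p_1`/`p_2` named by breed, pooled frequency
#'       `p_pooled`, `maf_pooled`, segregation flags and `monomorphic`.}
#'     \item{breeds}{the two breed labels in panel order.}
#'     \item{classes}{the class tibble with tuned `beta_shape` filled in.}
#'   }
#' @export
#' @examples
#' pops <- list(breed_population("HF", 40, 0.10, seed = 1),
#'              breed_population("J", 40, 0.14, seed = 2))
#' cls <- default_variant_classes(c(200, 200, 100), 300)
#' panel <- simulate_two_breed_panel(cls, pops, seed = 42)
#' maf_summary(panel)
simulate_two_breed_panel <- function(classes, pops, seed,
                                     n_chromosomes = 30L, map_length = 1) {
  stopifnot(is.data.frame(classes), nrow(classes) >= 1L)
  if (length(pops) != 2L ||
      !all(vapply(pops, inherits, logical(1), "breed_population"))) {
    abort("`pops` must be a list of two breed_population objects.")
  }
  breeds <- vapply(pops, `[[`, character(1), "breed")
  if (breeds[1] == breeds[2]) abort("the two populations must have distinct breed labels.")
  if (any(classes$n_loci < 1L)) abort("every class must have n_loci >= 1.")
  validate_pedigree(pops[[1]]$pedigree)
  validate_pedigree(pops[[2]]$pedigree)

  with_seed_if(seed, {
    # tune missing shapes against this panel's own drift and size settings
    n_per_breed <- vapply(pops, function(p) nrow(p$pedigree), integer(1))
    fst <- vapply(pops, `[[`, numeric(1), "fst")
    gen_structure <- lapply(pops, function(p) pedigree_gen_structure(p$pedigree))

    draw_class_geno <- function(cls_tbl) {
      m <- sum(cls_tbl$n_loci)
      p_anc <- unlist(lapply(seq_len(nrow(cls_tbl)), function(i) {
        ancestral_freq_r(cls_tbl$n_loci[i], cls_tbl$beta_shape[i])
      }), use.names = FALSE)
      p_breed <- lapply(1:2, function(k) drift_freq_q(runif(m), p_anc, fst[k]))
      chrom <- sample.int(n_chromosomes, m, replace = TRUE)
      pos <- runif(m) * map_length
      gmap <- genome_order(chrom, pos)
      geno_list <- lapply(1:2, function(k) {
        gene_drop(pops[[k]]$pedigree, p_breed[[k]], gmap)
      })
      list(p_anc = p_anc, chrom = chrom, pos = pos, geno_list = geno_list,
           class_of = rep(cls_tbl$class, times = cls_tbl$n_loci))
    }

    untuned <- is.na(classes$beta_shape)
    if (any(untuned)) {
      classes$beta_shape[untuned] <- vapply(
        classes$target_maf[untuned], function(t) {
          tune_ancestral_shape(t, fst = fst, n_per_breed = n_per_breed,
                               gen_structure = gen_structure,
                               seed = sample.int(.Machine$integer.max, 1L))
        }, numeric(1)
      )
    }

    drawn <- draw_class_geno(classes)
    p_anc <- drawn$p_anc
    chrom <- drawn$chrom
    pos <- drawn$pos
    class_of <- drawn$class_of
    geno_list <- drawn$geno_list
    m <- sum(classes$n_loci)
    geno <- rbind(geno_list[[1]], geno_list[[2]])
    colnames(geno) <- sprintf("L%05d", seq_len(m))

    indiv <- bind_rows(
      mutate(pops[[1]]$pedigree, breed = breeds[1]),
      mutate(pops[[2]]$pedigree, breed = breeds[2])
    ) %>% select("id", "breed", "sire", "dam", "sex", "generation")

    obs1 <- colMeans(geno_list[[1]]) / 2
    obs2 <- colMeans(geno_list[[2]]) / 2
    n1 <- nrow(geno_list[[1]]); n2 <- nrow(geno_list[[2]])
    p_pool <- (n1 * obs1 + n2 * obs2) / (n1 + n2)
    loci <- tibble(
      locus = colnames(geno),
      class = class_of,
      chrom = chrom,
      pos = pos,
      p_anc = p_anc,
      p_pooled = p_pool,
      maf_pooled = pmin(p_pool, 1 - p_pool),
      monomorphic = p_pool <= 0 | p_pool >= 1
    )
    loci[[paste0("p_", breeds[1])]] <- obs1
    loci[[paste0("p_", breeds[2])]] <- obs2
    loci[[paste0("seg_", breeds[1])]] <- obs1 > 0 & obs1 < 1
    loci[[paste0("seg_", breeds[2])]] <- obs2 > 0 & obs2 < 1

    structure(
      list(geno = geno, indiv = indiv, loci = loci, breeds = breeds,
           classes = classes),
      class = "genotype_panel"
    )
  })
}

# genome ordering and per-interval recombination probabilities (Haldane);
# the first locus of every chromosome segregates freely (prob 1/2)
genome_order <- function(chrom, pos) {
  ord <- order(chrom, pos)
  d <- c(Inf, diff(pos[ord]))
  d[c(TRUE, diff(chrom[ord]) != 0L)] <- Inf
  list(ord = ord, inv = order(ord), rp = 0.5 * (1 - exp(-2 * d)))
}

# drop haplotypes down one breed's pedigree: founder haplotypes are
# independent Bernoulli(p) per locus (linkage equilibrium), offspring get
# one recombinant haplotype per parent along the genetic map
gene_drop <- function(ped, p, gmap) {
  n <- nrow(ped)
  m <- length(p)
  pg <- p[gmap$ord] # work in genome order
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  row_of <- setNames(seq_len(n), ped$id)
  transmit <- function(parent_row) {
    h <- cumsum(as.integer(runif(m) < gmap$rp)) %% 2L
    ifelse(h == 0L, H1[parent_row, ], H2[parent_row, ])
  }
  for (i in seq_len(n)) {
    if (is.na(ped$sire[i]) && is.na(ped$dam[i])) {
      H1[i, ] <- rbinom(m, 1L, pg)
      H2[i, ] <- rbinom(m, 1L, pg)
    } else {
      H1[i, ] <- transmit(row_of[[ped$sire[i]]])
      H2[i, ] <- transmit(row_of[[ped$dam[i]]])
    }
  }
  geno <- H1 + H2
  geno <- geno[, gmap$inv, drop = FALSE] # back to original column order
  rownames(geno) <- ped$id
  geno
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) abort("pedigree ids must be unique.")
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- !is.na(par)
    if (any(known & !(par %in% ped$id))) {
      abort(sprintf("pedigree refers to unknown %s(s).", col))
    }
    if (any(pos[par[known]] >= which(known))) {
      abort("pedigree is not sorted: every parent must precede its offspring.")
    }
  }
  invisible(ped)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals (%s) x %d loci in %d class(es)\n",
              nrow(x$geno), paste(table(x$indiv$breed)[x$breeds], x$breeds,
                                  collapse = " + "),
              ncol(x$geno), nrow(x$classes)))
  print(maf_summary(x))
  invisible(x)
}

#' Per-class MAF and breed-specificity summary of a panel
#'
#' Summarises each variant class over its loci segregating in the pooled
#' sample: counts of segregating and breed-specific loci (segregating in
#' exactly one breed) and the pooled average MAF.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @return A tibble with one row per class: `class`, `n_loci`,
#'   `n_segregating`, `n_breed_specific`, `pct_breed_specific`, `mean_maf`.
#' @export
maf_summary <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  seg_cols <- paste0("seg_", panel$breeds)
  panel$loci %>%
    mutate(
      seg_pool = !.data$monomorphic,
      specific = .data$seg_pool &
        (.data[[seg_cols[1]]] + .data[[seg_cols[2]]] == 1L)
    ) %>%
    group_by(class = factor(.data$class, levels = panel$classes$class)) %>%
    summarise(
      n_loci = n(),
      n_segregating = sum(.data$seg_pool),
      n_breed_specific = sum(.data$specific),
      pct_breed_specific = 100 * sum(.data$specific) / max(1L, sum(.data$seg_pool)),
      mean_maf = mean(.data$maf_pooled[.data$seg_pool]),
      .groups = "drop"
    )
}

#' Ascertain a SNP panel by minor allele frequency
#'
#' Mimics the ascertainment bias of commercial SNP chips: draws a random
#' subset of `snp_panel`-class loci whose pooled MAF is at least `min_maf`
#' and (by default) that segregate in both breeds, giving the panel a much
#' higher average MAF than the variant classes QTL are drawn from.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param n_snps number of SNPs to return.
#' @param min_maf minimum pooled MAF for eligibility.
#' @param both_breeds require segregation in both breeds.
#' @param class_label class to draw from, default `"snp_panel"`.
#' @param seed integer seed.
#' @return An integer vector of locus (column) indices into `panel$geno`.
#' @export
ascertain_snp_panel <- function(panel, n_snps, min_maf = 0.05,
                                both_breeds = TRUE,
                                class_label = "snp_panel", seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  seg_cols <- paste0("seg_", panel$breeds)
  eligible <- which(
    panel$loci$class == class_label &
      panel$loci$maf_pooled >= min_maf &
      (!both_breeds | (panel$loci[[seg_cols[1]]] & panel$loci[[seg_cols[2]]]))
  )
  n_snps <- as.integer(n_snps)
  if (n_snps > length(eligible)) {
    abort(sprintf(
      "requested %d SNPs but only %d loci of class '%s' pass MAF >= %g.",
      n_snps, length(eligible), class_label, min_maf
    ))
  }
  with_seed_if(seed, sort(sample(eligible, n_snps)))
}
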
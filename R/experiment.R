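#' Assemble and validate an experiment configuration
#'
#' Collects every knob of a multi-breed prediction experiment in one
#' validated object: the two-breed population (sizes, divergence,
#' pedigree depth), the variant classes, the SNP-panel ascertainment, the
#' reference-population designs, the trait settings (QTL class, effect
#' model, number of QTL, heritability), the marker-panel variants, the
#' model variants and the replicate count. Defaults are the desk-scale
#' study conditions: 750 individuals per breed (500 reference + 250
#' candidates), Fst 0.10/0.14, 5000 ascertained panel SNPs,
#' 4000/4000/1000 loci in the three QTL classes, heritability 0.8, 100
#' QTL, 10 replicates.
#'
#' @param n_per_breed individuals simulated per breed.
#' @param breeds the two breed labels.
#' @param fst length-2 divergence parameters, each in (0, 1).
#' @param founder_frac,n_generations pedigree shape, see
#'   [breed_population()].
#' @param classes variant-class tibble, see [default_variant_classes()].
#' @param n_cand_per_breed fixed selection candidates per breed.
#' @param scenarios reference designs, see [scenario_table()].
#' @param qtl_classes,effect_models,n_qtl trait settings; all combinations
#'   are run.
#' @param marker_panels subset of `"full"`, `"sub10"`, `"full+qtl"`,
#'   `"sub10+qtl"`; `sub10` is a random 10\% of the full panel, `+qtl`
#'   appends the genotypes of every locus of the QTL variant classes
#'   (all classes except `snp_panel`) to the marker subset, so the causal
#'   variants are guaranteed to be in the marker set.
#' @param n_snps,min_maf SNP-panel ascertainment, see
#'   [ascertain_snp_panel()].
#' @param h2 simulated heritability.
#' @param model_variants subset of `"base"` (across- plus within-breed
#'   random effects), `"no_gw"`, `"base_breed"` (base plus fixed breed
#'   effect).
#' @param n_replicates replicates per cell.
#' @param n_jackknife_blocks marker blocks for the G regression, see
#'   [build_relationships()].
#' @param seed master seed; every random stage of [run_experiment()] draws
#'   from the stream it starts.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_per_breed = 750L,
                              breeds = c("HF", "J"),
                              fst = c(0.10, 0.14),
                              founder_frac = 1 / 3,
                              n_generations = 2L,
                              classes = default_variant_classes(),
                              n_cand_per_breed = 250L,
                              scenarios = scenario_table(0.25),
                              qtl_classes = "moderately_low",
                              effect_models = "RANDOM",
                              n_qtl = 100L,
                              marker_panels = "full",
                              n_snps = 5000L,
                              min_maf = 0.05,
                              h2 = 0.8,
                              model_variants = "base",
                              n_replicates = 10L,
                              n_jackknife_blocks = 10L,
                              seed = 1L) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (length(breeds) != 2L || anyDuplicated(breeds)) {
    note("`breeds` must be two distinct labels.")
  }
  if (length(fst) != 2L || any(fst <= 0) || any(fst >= 1)) {
    note("`fst` must be two values strictly inside (0, 1).")
  }
  if (!is.data.frame(classes) ||
      !all(c("class", "n_loci", "target_maf", "beta_shape") %in% names(classes))) {
    note("`classes` must be a variant-class tibble (see variant_class()).")
  }
  if (!is.data.frame(scenarios) ||
      !all(c("scenario", "n_ref_1", "n_ref_2") %in% names(scenarios))) {
    note("`scenarios` must have columns scenario, n_ref_1, n_ref_2.")
  } else {
    max_ref <- n_per_breed - n_cand_per_breed
    if (any(scenarios$n_ref_1 > max_ref) || any(scenarios$n_ref_2 > max_ref)) {
      note(sprintf(
        "largest reference design exceeds the %d animals per breed left after reserving candidates.",
        max_ref
      ))
    }
  }
  if (is.data.frame(classes)) {
    bad <- setdiff(qtl_classes, classes$class)
    if (length(bad) > 0L) note(sprintf("unknown QTL class(es): %s.", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(effect_models, c("RANDOM", "VAR"))
  if (length(bad) > 0L) note(sprintf("unknown effect model(s): %s.", paste(bad, collapse = ", ")))
  bad <- setdiff(marker_panels, c("full", "sub10", "full+qtl", "sub10+qtl"))
  if (length(bad) > 0L) note(sprintf("unknown marker panel(s): %s.", paste(bad, collapse = ", ")))
  bad <- setdiff(model_variants, c("base", "no_gw", "base_breed"))
  if (length(bad) > 0L) note(sprintf("unknown model variant(s): %s.", paste(bad, collapse = ", ")))
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1) note("`h2` must lie in (0, 1].")
  if (any(n_qtl < 1)) note("`n_qtl` must be positive.")
  if (n_replicates < 1) note("`n_replicates` must be at least 1.")
  if (is.null(seed) || !is.finite(seed)) note("a master `seed` is required (no silent nondeterminism).")

  if (length(problems) > 0L) {
    abort(paste0("invalid experiment configuration:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  structure(
    list(
      n_per_breed = as.integer(n_per_breed), breeds = breeds, fst = fst,
      founder_frac = founder_frac, n_generations = as.integer(n_generations),
      classes = classes, n_cand_per_breed = as.integer(n_cand_per_breed),
      scenarios = as_tibble(scenarios), qtl_classes = qtl_classes,
      effect_models = effect_models, n_qtl = as.integer(n_qtl),
      marker_panels = marker_panels, n_snps = as.integer(n_snps),
      min_maf = min_maf, h2 = h2, model_variants = model_variants,
      n_replicates = as.integer(n_replicates),
      n_jackknife_blocks = as.integer(n_jackknife_blocks),
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %d/breed (%s), %d candidates/breed, %d scenario(s), %d replicate(s), seed %d\n",
    x$n_per_breed, paste(x$breeds, collapse = "+"), x$n_cand_per_breed,
    nrow(x$scenarios), x$n_replicates, x$seed
  ))
  cat(sprintf("  traits: class {%s} x model {%s} x n_qtl {%s}, h2 = %g\n",
              paste(x$qtl_classes, collapse = ","),
              paste(x$effect_models, collapse = ","),
              paste(x$n_qtl, collapse = ","), x$h2))
  cat(sprintf("  marker panels: %s; model variants: %s\n",
              paste(x$marker_panels, collapse = ","),
              paste(x$model_variants, collapse = ",")))
  invisible(x)
}

#' Run a replicated multi-breed prediction experiment
#'
#' Simulates one two-breed genotype panel, fixes the selection candidates
#' and a nested ordering of the per-breed reference pools, then for each
#' replicate simulates a trait for every QTL-class x effect-model x n-QTL
#' combination and, for every marker panel, reference design and model
#' variant, fits the GREML model and records per-breed prediction accuracy
#' and variance components. The panel and candidate sets are shared by all
#' scenarios, smaller reference populations are random subsets of larger
#' ones, and the whole run is reproducible from the master seed.
#'
#' @param config an [experiment_config()].
#' @param seed optional override of `config$seed`.
#' @param keep_panel attach the simulated panel as attribute `"panel"`.
#' @return A tibble of class `experiment_result`, one row per replicate x
#'   trait combination x marker panel x scenario x model variant x breed:
#'   accuracy `r`, `n_candidates`, `h2_hat`, variance components,
#'   `loglik`, `converged`, and an `error` column (NA on success; failures
#'   are recorded per cell, not fatal).
#' @export
run_experiment <- function(config, seed = NULL, keep_panel = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  master_seed <- if (is.null(seed)) cfg$seed else as.integer(seed)

  with_seed_if(master_seed, {
    pops <- list(
      breed_population(cfg$breeds[1], cfg$n_per_breed, cfg$fst[1],
                       founder_frac = cfg$founder_frac,
                       n_generations = cfg$n_generations),
      breed_population(cfg$breeds[2], cfg$n_per_breed, cfg$fst[2],
                       founder_frac = cfg$founder_frac,
                       n_generations = cfg$n_generations)
    )
    panel <- simulate_two_breed_panel(cfg$classes, pops, seed = NULL)
    ped_A <- build_pedigree_A(panel)

    full_loci <- ascertain_snp_panel(panel, cfg$n_snps, min_maf = cfg$min_maf)
    sub10_loci <- sort(sample(full_loci, max(2L, round(0.1 * length(full_loci)))))

    # fixed candidates; the remainder is the reference pool, permuted once
    # so that smaller reference designs are nested subsets of larger ones
    cand_ids <- ref_pool <- list()
    for (b in cfg$breeds) {
      ids_b <- panel$indiv$id[panel$indiv$breed == b]
      cand_ids[[b]] <- sample(ids_b, cfg$n_cand_per_breed)
      ref_pool[[b]] <- sample(setdiff(ids_b, cand_ids[[b]]))
    }
    candidates <- unlist(cand_ids, use.names = FALSE)

    qtl_class_loci <- which(panel$loci$class != "snp_panel")
    rels_cache <- list()
    get_rels <- function(panel_label) {
      if (is.null(rels_cache[[panel_label]])) {
        loci <- if (startsWith(panel_label, "full")) full_loci else sub10_loci
        if (endsWith(panel_label, "+qtl")) {
          loci <- sort(union(loci, qtl_class_loci))
        }
        rels_cache[[panel_label]] <<- build_relationships(
          panel, loci, ped_A,
          n_jackknife_blocks = cfg$n_jackknife_blocks
        )
      }
      rels_cache[[panel_label]]
    }

    traits_grid <- tidyr::expand_grid(
      qtl_class = cfg$qtl_classes, effect_model = cfg$effect_models,
      n_qtl = cfg$n_qtl
    )

    rows <- list()
    for (rep_i in seq_len(cfg$n_replicates)) {
      for (tg in seq_len(nrow(traits_grid))) {
        trait <- simulate_trait(
          panel, traits_grid$qtl_class[tg], traits_grid$n_qtl[tg],
          model = traits_grid$effect_model[tg], h2 = cfg$h2
        )
        for (mp in cfg$marker_panels) {
          rels <- get_rels(mp)
          for (sc in seq_len(nrow(cfg$scenarios))) {
            n_ref <- c(cfg$scenarios$n_ref_1[sc], cfg$scenarios$n_ref_2[sc])
            ref_ids <- c(head(ref_pool[[cfg$breeds[1]]], n_ref[1]),
                         head(ref_pool[[cfg$breeds[2]]], n_ref[2]))
            for (mv in cfg$model_variants) {
              cell <- tryCatch({
                spec <- model_spec(ref_ids, candidates,
                                   include_gw = mv != "no_gw",
                                   include_breed_fixed = mv == "base_breed")
                fit <- fit_greml(trait, rels, spec)
                acc <- accuracy(total_gebv(fit), trait)
                gl <- glance(fit)
                mutate(acc,
                       h2_hat = gl$h2_hat, var_ga = gl$var_ga,
                       var_gw = gl$var_gw, var_e = gl$var_e,
                       loglik = gl$loglik, converged = gl$converged,
                       error = NA_character_)
              }, error = function(e) {
                tibble(breed = cfg$breeds, r = NA_real_, n = NA_integer_,
                       h2_hat = NA_real_, var_ga = NA_real_,
                       var_gw = NA_real_, var_e = NA_real_,
                       loglik = NA_real_, converged = NA,
                       error = conditionMessage(e))
              })
              rows[[length(rows) + 1L]] <- mutate(
                cell,
                replicate = rep_i,
                qtl_class = traits_grid$qtl_class[tg],
                effect_model = traits_grid$effect_model[tg],
                n_qtl = traits_grid$n_qtl[tg],
                marker_panel = mp,
                scenario = cfg$scenarios$scenario[sc],
                n_ref_1 = n_ref[1], n_ref_2 = n_ref[2],
                model_variant = mv
              )
            }
          }
        }
      }
    }
    res <- bind_rows(rows) %>%
      select("replicate", "qtl_class", "effect_model", "n_qtl",
             "marker_panel", "scenario", "n_ref_1", "n_ref_2",
             "model_variant", "breed", "r", n_candidates = "n",
             "h2_hat", "var_ga", "var_gw", "var_e", "loglik",
             "converged", "error")
    class(res) <- c("experiment_result", class(res))
    attr(res, "breeds") <- cfg$breeds
    if (keep_panel) attr(res, "panel") <- panel
    res
  })
}

#' Aggregate an experiment over replicates
#'
#' Per-cell mean and standard error (sample SD over sqrt of replicate
#' count) of the prediction accuracy and the estimated heritability.
#'
#' @param results an [run_experiment()] result.
#' @return A tibble with one row per cell x breed.
#' @export
summarise_experiment <- function(results) {
  stopifnot(is.data.frame(results))
  results %>%
    filter(is.na(.data$error)) %>%
    group_by(.data$qtl_class, .data$effect_model, .data$n_qtl,
             .data$marker_panel, .data$scenario, .data$n_ref_1,
             .data$n_ref_2, .data$model_variant, .data$breed) %>%
    summarise(
      n_reps = n(),
      mean_r = mean(.data$r),
      se_r = sd(.data$r) / sqrt(n()),
      mean_h2_hat = mean(.data$h2_hat),
      se_h2_hat = sd(.data$h2_hat) / sqrt(n()),
      .groups = "drop"
    )
}
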
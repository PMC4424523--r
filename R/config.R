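#' Parse and validate a YAML experiment configuration
#'
#' Reads a structured YAML configuration (file path or literal text),
#' rejects unknown keys, coerces the `classes` and `scenarios` blocks to
#' their tibble forms, and hands everything to [experiment_config()],
#' which itemizes any remaining violations. A master `seed` is mandatory.
#'
#' Recognized top-level keys are exactly the arguments of
#' [experiment_config()]; `classes` is a list of maps with `label`,
#' `n_loci`, `target_maf` and optional `beta_shape`, and `scenarios` is a
#' list of maps with `n_ref_1`, `n_ref_2`.
#'
#' @param x path to a YAML file, or a string of YAML text.
#' @return A validated [experiment_config()].
#' @export
#' @examples
#' cfg <- validate_config("
#' n_per_breed: 60
#' n_cand_per_breed: 20
#' classes:
#'   - {label: moderately_low, n_loci: 100, target_maf: 0.122}
#'   - {label: snp_panel, n_loci: 200, target_maf: 0.27}
#' scenarios:
#'   - {n_ref_1: 40, n_ref_2: 40}
#' n_snps: 100
#' n_replicates: 2
#' seed: 7
#' ")
validate_config <- function(x) {
  raw <- if (length(x) == 1L && file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    yaml::yaml.load(paste(x, collapse = "\n"))
  }
  if (!is.list(raw)) abort("configuration must be a YAML mapping.")
  allowed <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), allowed)
  problems <- character()
  if (length(unknown) > 0L) {
    problems <- c(problems, sprintf("unknown key(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$seed)) {
    problems <- c(problems, "`seed` is required: every run must be reproducible.")
  }
  if (length(problems) > 0L) {
    abort(paste0("invalid experiment configuration:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  if (!is.null(raw$classes)) {
    raw$classes <- bind_rows(lapply(raw$classes, function(cl) {
      variant_class(cl$label, cl$n_loci, cl$target_maf,
                    beta_shape = cl$beta_shape)
    }))
  }
  if (!is.null(raw$scenarios)) {
    sc <- bind_rows(lapply(raw$scenarios, as_tibble))
    sc$scenario <- seq_len(nrow(sc))
    raw$scenarios <- sc[, c("scenario", "n_ref_1", "n_ref_2")]
  }
  do.call(experiment_config, raw)
}

#' Write an experiment configuration back to YAML
#'
#' Inverse of [validate_config()]: a written configuration re-reads to an
#' identical resolved configuration.
#'
#' @param config an [experiment_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  out <- unclass(config)
  out$classes <- lapply(seq_len(nrow(config$classes)), function(i) {
    row <- config$classes[i, ]
    cl <- list(label = row$class, n_loci = row$n_loci,
               target_maf = row$target_maf)
    if (!is.na(row$beta_shape)) cl$beta_shape <- row$beta_shape
    cl
  })
  out$scenarios <- lapply(seq_len(nrow(config$scenarios)), function(i) {
    list(n_ref_1 = config$scenarios$n_ref_1[i],
         n_ref_2 = config$scenarios$n_ref_2[i])
  })
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
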
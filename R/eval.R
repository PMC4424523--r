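#' Per-breed accuracy of genomic prediction
#'
#' Pearson correlation, per breed, between total genomic breeding values
#' and simulated true breeding values over selection candidates only.
#'
#' @param gebv a [total_gebv()] tibble (columns `id`, `breed`, `gebv`), or
#'   a numeric vector aligned with `tbv`.
#' @param tbv a `trait_data` object, a tibble with `id` and `tbv`, or a
#'   numeric vector.
#' @param breed_of breed labels, only needed when `gebv` and `tbv` are bare
#'   vectors.
#' @return A tibble with columns \code{breed}, \code{r} (the accuracy) and
#'   \code{n}. Breeds with fewer than 3 candidates or zero variance in
#'   either vector get a missing accuracy.
#' @export
accuracy <- function(gebv, tbv, breed_of = NULL) {
  if (is.data.frame(gebv)) {
    if (inherits(tbv, "trait_data")) tbv <- tbv$individuals
    stopifnot(is.data.frame(tbv), all(c("id", "tbv") %in% names(tbv)))
    d <- left_join(gebv, select(tbv, "id", "tbv"), by = "id")
    if (anyNA(d$tbv)) abort("some candidates have no true breeding value.")
  } else {
    stopifnot(length(gebv) == length(tbv), length(breed_of) == length(gebv))
    d <- tibble(breed = breed_of, gebv = gebv, tbv = tbv)
  }
  d %>%
    group_by(.data$breed) %>%
    summarise(
      r = if (n() < 3L || sd(.data$gebv) == 0 || sd(.data$tbv) == 0)
        NA_real_ else cor(.data$gebv, .data$tbv),
      n = n(),
      .groups = "drop"
    )
}

#' Number of replicates needed to estimate squared accuracy
#'
#' Uses the sampling variance of a squared correlation,
#' `Var(r^2) = (1 - r^2)^2 / (N - 1)`, and returns the replicate count
#' `n = z^2 Var(r^2) / delta^2` required to estimate the mean squared
#' accuracy within `delta` at the confidence level implied by `z`
#' (unrounded).
#'
#' @param r assumed accuracy (correlation), in `[-1, 1]`; vectorized.
#' @param N number of selection candidates per replicate.
#' @param delta maximum allowable difference between estimated and true
#'   mean.
#' @param z standard-normal quantile for the confidence level.
#' @return Required number of replicates.
#' @export
#' @examples
#' required_replicates(0, 1000)     # 9.61...
#' required_replicates(0.99, 1000)  # ~0.004
required_replicates <- function(r, N, delta = 0.02, z = 1.96) {
  if (any(abs(r) > 1)) abort("`r` must lie in [-1, 1].")
  if (any(N < 2)) abort("`N` must be at least 2.")
  var_r2 <- (1 - r^2)^2 / (N - 1)
  z^2 * var_r2 / delta^2
}

#' Equivalent reference-size fold change between heritabilities
#'
#' Under the deterministic accuracy formula of Daetwyler and colleagues,
#' expected accuracy depends on the product of reference size and
#' heritability, so a trait with heritability `h2_a` matches a trait with
#' heritability `h2_b` analysed with `h2_a / h2_b` times more reference
#' animals.
#'
#' @param h2_a,h2_b heritabilities in (0, 1].
#' @return The fold change in reference population size.
#' @export
#' @examples
#' daetwyler_equivalent_n(0.8, 0.25) # 3.2
daetwyler_equivalent_n <- function(h2_a, h2_b) {
  if (any(h2_a <= 0 | h2_a > 1) || any(h2_b <= 0 | h2_b > 1)) {
    abort("heritabilities must lie in (0, 1].")
  }
  h2_a / h2_b
}

#' The seven reference-population designs
#'
#' Reference sizes per breed for the seven designs, from a single-breed
#' reference to an equal-size multi-breed reference, scaled from the
#' full-size design (2000/2000 down to 0/2000) by `scale`. Smaller
#' reference populations are drawn as nested subsets of the larger ones by
#' [run_experiment()].
#'
#' @param scale common scaling factor applied to the full-size counts.
#' @return A tibble `scenario`, `n_ref_1`, `n_ref_2` (columns 1 and 2
#'   follow the panel's breed order).
#' @export
#' @examples
#' scenario_table(0.25)
scenario_table <- function(scale = 0.25) {
  full <- rbind(
    c(2000, 2000), c(2000, 500), c(2000, 100), c(2000, 0),
    c(500, 2000), c(100, 2000), c(0, 2000)
  )
  tibble(
    scenario = seq_len(nrow(full)),
    n_ref_1 = as.integer(round(full[, 1] * scale)),
    n_ref_2 = as.integer(round(full[, 2] * scale))
  )
}
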
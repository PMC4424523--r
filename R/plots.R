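#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot prediction accuracies across reference designs
#'
#' Bar chart of replicate-mean accuracy (with standard-error bars) per
#' reference-population scenario and breed, faceted by QTL class and
#' effect model when several are present.
#'
#' @param object an [run_experiment()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object, ...) {
  s <- summarise_experiment(object)
  design <- paste0(s$n_ref_1, "/", s$n_ref_2)
  s$design <- factor(design, levels = unique(design[order(s$scenario)]))
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$design, y = .data$mean_r,
                                       fill = .data$breed)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r - .data$se_r,
                   ymax = .data$mean_r + .data$se_r),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(x = "reference design (breed 1 / breed 2)",
                  y = "accuracy (cor(GEBV, TBV) in candidates)",
                  fill = "candidates") +
    ggplot2::theme_minimal()
  facets <- c(
    if (length(unique(s$qtl_class)) > 1) "qtl_class",
    if (length(unique(s$effect_model)) > 1) "effect_model",
    if (length(unique(s$marker_panel)) > 1) "marker_panel"
  )
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_wrap(facets, labeller = ggplot2::label_both)
  }
  p
}

#' Plot a profile likelihood-ratio curve
#'
#' Twice the log-likelihood difference between the free fit and fits with
#' the within-breed variance fraction fixed, against that fraction, with
#' the 5\% mixture chi-square threshold as a dashed line.
#'
#' @param object a [profile_lrt()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.profile_lrt <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction_pct, y = .data$lrt)) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "within-breed fraction of total genetic variance (%)",
                  y = expression(2 %*% Delta * logL)) +
    ggplot2::theme_minimal()
}

#' Plot the pooled MAF spectrum of a genotype panel
#'
#' Histogram of pooled minor allele frequencies of segregating loci,
#' faceted by variant class.
#'
#' @param object a [simulate_two_breed_panel()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_panel <- function(object, ...) {
  d <- filter(object$loci, !.data$monomorphic)
  d$class <- factor(d$class, levels = object$classes$class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$maf_pooled)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "pooled minor allele frequency", y = "loci") +
    ggplot2::theme_minimal()
}
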
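#' Breed inbreeding since divergence and pooled allele frequencies
#'
#' Computes, over a marker subset, the inbreeding coefficients of the two
#' breeds relative to the common population immediately before they
#' diverged, the ancestral haplotype proportion `alpha`, the combined
#' inbreeding `F` relative to an F1 base, and the alpha-weighted pooled
#' allele frequencies used to standardize the genomic relationship matrix.
#'
#' For breeds 1 and 2 with per-locus frequencies p1, p2 the inbreeding of
#' breed 2 is `F_2 = 1 - sum(2 p2 (1-p2)) / sum(p1 (1-p2) + p2 (1-p1))`
#' (heterozygosity within the breed relative to the across-breed expected
#' heterozygosity), and symmetrically for breed 1. Then
#' `alpha = F_2 / (F_1 + F_2)` is the proportion of breed-1 haplotypes in
#' the ancestral population, `p_j = alpha p1 + (1 - alpha) p2`, and
#' `F = F_1 F_2 / (F_1 + F_2)`.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param loci marker subset: integer/character column indices into
#'   `panel$geno`, or `NULL` for all loci.
#' @return A list of class `pooled_freqs`: `loci` (column names used),
#'   `p_by_breed` (matrix, loci x 2, columns named by breed), `p_j`,
#'   `F_breed` (named length-2), `alpha`, `F`.
#' @export
compute_breed_inbreeding <- function(panel, loci = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- resolve_loci(panel, loci)
  p1 <- panel$loci[[paste0("p_", panel$breeds[1])]][idx]
  p2 <- panel$loci[[paste0("p_", panel$breeds[2])]][idx]
  pooled_freqs(p1, p2, panel$breeds, panel$loci$locus[idx])
}

# core of compute_breed_inbreeding, usable on bare frequency vectors
pooled_freqs <- function(p1, p2, breeds = c("HF", "J"), loci = NULL) {
  stopifnot(length(p1) == length(p2), length(p1) >= 1L)
  het_across <- sum(p1 * (1 - p2) + p2 * (1 - p1))
  if (het_across <= 0) {
    abort("all supplied loci are monomorphic in both breeds; inbreeding undefined.")
  }
  f1 <- 1 - sum(2 * p1 * (1 - p1)) / het_across
  f2 <- 1 - sum(2 * p2 * (1 - p2)) / het_across
  if (f1 + f2 > 0) {
    alpha <- f2 / (f1 + f2)
    f_comb <- f1 * f2 / (f1 + f2)
  } else {
    # undiverged limit: no information to weight the breeds, use 0.5
    alpha <- 0.5
    f_comb <- 0
  }
  p_j <- alpha * p1 + (1 - alpha) * p2
  structure(
    list(
      loci = loci,
      p_by_breed = matrix(c(p1, p2), ncol = 2, dimnames = list(loci, breeds)),
      p_j = p_j,
      F_breed = setNames(c(f1, f2), breeds),
      alpha = alpha,
      F = f_comb
    ),
    class = "pooled_freqs"
  )
}

#' @export
print.pooled_freqs <- function(x, ...) {
  cat(sprintf(
    "<pooled_freqs> %d loci; F_%s = %.4f, F_%s = %.4f, alpha = %.3f, F = %.4f\n",
    length(x$p_j), names(x$F_breed)[1], x$F_breed[1],
    names(x$F_breed)[2], x$F_breed[2], x$alpha, x$F
  ))
  invisible(x)
}

resolve_loci <- function(panel, loci) {
  if (is.null(loci)) return(seq_len(ncol(panel$geno)))
  if (is.character(loci)) loci <- match(loci, colnames(panel$geno))
  loci <- as.integer(loci)
  if (length(loci) == 0L) abort("`loci` selects no markers.")
  if (anyNA(loci) || any(loci < 1L) || any(loci > ncol(panel$geno))) {
    abort("`loci` contains indices outside the panel.")
  }
  loci
}

#' Genomic relationship matrix from a marker subset
#'
#' VanRaden-style genomic relationship matrix
#' `G = W W' / (2 sum p_j (1 - p_j))` with `w_ij = g_ij - 2 p_j`, using the
#' alpha-weighted pooled frequencies of [compute_breed_inbreeding()] so the
#' standardization refers to the population at breed divergence. Loci with
#' `p_j` of 0 or 1 contribute zero to both numerator and denominator, so
#' monomorphic loci may be left in the subset without effect.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param loci marker subset (see [compute_breed_inbreeding()]); all marker
#'   panel variants (full, random subset, subset plus QTL columns) are
#'   expressed through this one argument.
#' @param freqs optional `pooled_freqs` for the same subset; computed when
#'   `NULL`.
#' @param n_jackknife_blocks if > 1, also estimate the marker-sampling
#'   variance of each element of G by a delete-one-block jackknife over
#'   `n_jackknife_blocks` contiguous marker blocks; returned as attribute
#'   `"var_jack"`.
#' @return A symmetric matrix with individual ids as dimnames; attributes
#'   `"freqs"` (the `pooled_freqs` used) and optionally `"var_jack"`.
#' @export
build_G <- function(panel, loci = NULL, freqs = NULL,
                    n_jackknife_blocks = 0L) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- resolve_loci(panel, loci)
  if (is.null(freqs)) freqs <- compute_breed_inbreeding(panel, idx)
  p_j <- freqs$p_j
  stopifnot(length(p_j) == length(idx))
  denom <- 2 * sum(p_j * (1 - p_j))
  if (denom <= 0) abort("all selected loci are monomorphic; G undefined.")
  W <- sweep(panel$geno[, idx, drop = FALSE], 2L, 2 * p_j)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(panel$geno), rownames(panel$geno))
  attr(G, "freqs") <- freqs
  B <- as.integer(n_jackknife_blocks)
  if (B > 1L) {
    m <- length(idx)
    blk <- sort(rep_len(seq_len(B), m))
    Ntot <- G * denom
    s1 <- s2 <- matrix(0, nrow(G), ncol(G))
    for (b in seq_len(B)) {
      cols <- which(blk == b)
      Wb <- W[, cols, drop = FALSE]
      db <- 2 * sum(p_j[cols] * (1 - p_j[cols]))
      if (denom - db <= 0) next
      Gb <- (Ntot - tcrossprod(Wb)) / (denom - db)
      s1 <- s1 + Gb
      s2 <- s2 + Gb^2
    }
    attr(G, "var_jack") <- (B - 1) * (s2 / B - (s1 / B)^2)
  }
  G
}

#' Rescale relationship matrices to the breed-divergence base
#'
#' Re-expresses relationships relative to the population immediately before
#' the breeds diverged: `G* = G (1 - F) + 2 F` element-wise (diagonals
#' included), and, per within-breed block of the pedigree matrix,
#' `A* = A [1 - (F_b - f_b)] + 2 (F_b - f_b)` with `F_b` the breed's
#' inbreeding since divergence and `f_b` its mean pedigree inbreeding; the
#' across-breed block of `A*` is set to 0.
#'
#' @param G genomic relationship matrix from [build_G()].
#' @param ped_A a [build_pedigree_A()] result over the same individuals in
#'   the same order.
#' @param freqs `pooled_freqs` carrying `F` and per-breed `F_breed`.
#' @return A list with `G_star` and `A_star`.
#' @export
rescale_to_base <- function(G, ped_A, freqs) {
  stopifnot(inherits(ped_A, "pedigree_A"), inherits(freqs, "pooled_freqs"))
  stopifnot(identical(dim(G), dim(ped_A$A)))
  G_star <- G * (1 - freqs$F) + 2 * freqs$F
  attr(G_star, "freqs") <- NULL
  attr(G_star, "var_jack") <- NULL
  A_star <- matrix(0, nrow(ped_A$A), ncol(ped_A$A), dimnames = dimnames(ped_A$A))
  for (b in ped_A$f$breed) {
    rows <- which(ped_A$breed_of == b)
    delta <- unname(freqs$F_breed[b]) - ped_A$f$f[ped_A$f$breed == b]
    if (delta < 0) {
      warn(sprintf(
        "breed %s: pedigree inbreeding (%.4f) exceeds inbreeding since divergence (%.4f).",
        b, ped_A$f$f[ped_A$f$breed == b], unname(freqs$F_breed[b])
      ))
    }
    A_star[rows, rows] <- ped_A$A[rows, rows] * (1 - delta) + 2 * delta
  }
  list(G_star = G_star, A_star = A_star)
}

#' Regress the rescaled G back to the rescaled A per relationship bin
#'
#' Shrinks each element of `G*` towards the corresponding element of `A*`
#' to remove marker-sampling noise:
#' `G_a = A* + b (G* - A*)`, with the shrinkage coefficient estimated per
#' bin of pedigree relationship as
#' `b = max(0, 1 - v / Var(G* - A*))`, where `v` is the average
#' marker-sampling variance of the bin's `G*` elements (block-jackknife
#' estimate) and the variance in the denominator is taken across the bin's
#' elements. The regression is done separately across and within breed:
#' across-breed pairs form one class, within-breed off-diagonal pairs are
#' binned by their pedigree relationship (`[0, 0.10)`, `[0.10, 0.25)`,
#' `[0.25, 0.50)`, `[0.50, Inf)` - the sampling error of `G*` depends on
#' the level of family relationship), and diagonal elements form their own
#' class. With dense marker panels the coefficients of the family bins
#' approach 1; bins whose pairs carry no relationship variation beyond
#' marker noise (unrelated founders, across-breed pairs in a
#' linkage-equilibrium base) shrink towards `A*`.
#'
#' @param G_star,A_star rescaled matrices from [rescale_to_base()].
#' @param A raw pedigree relationship matrix used for binning.
#' @param breed_of named character vector mapping each individual (row
#'   order) to its breed.
#' @param var_G_star matrix of element-wise marker-sampling variances of
#'   `G*` (the jackknife variance of G scaled by `(1 - F)^2`); when `NULL`
#'   no shrinkage information is available and all coefficients are 1.
#' @param bins lower edges of the within-breed relationship bins.
#' @return A list: `G_a` (shrunk matrix) and `b_bin` (tibble `bin`, `b`,
#'   `n_elements`, `v_hat`, `var_diff`).
#' @export
regress_G_on_A <- function(G_star, A_star, A, breed_of, var_G_star = NULL,
                           bins = c(0, 0.10, 0.25, 0.50)) {
  stopifnot(identical(dim(G_star), dim(A_star)), identical(dim(G_star), dim(A)))
  n <- nrow(G_star)
  edges <- c(bins, Inf)
  bin_id <- matrix(findInterval(A, edges), n, n) + 1L
  bin_id[bin_id < 2L] <- 2L
  same <- outer(breed_of, breed_of, `==`)
  bin_id[!same] <- 1L # across-breed pairs: own class
  diag(bin_id) <- length(bins) + 2L # diagonals: own class
  labels <- c("across_breed",
              sprintf("[%.2f,%.2f)", edges[-length(edges)], edges[-1]),
              "diagonal")
  diff <- G_star - A_star
  b <- rep(1, length(labels))
  v_hat <- var_diff <- rep(NA_real_, length(labels))
  n_el <- integer(length(labels))
  for (k in seq_along(labels)) {
    el <- bin_id == k
    n_el[k] <- sum(el)
    if (n_el[k] < 2L) {
      if (n_el[k] > 0L) warn(sprintf("relationship bin %s has < 2 elements; b = 1.", labels[k]))
      next
    }
    var_diff[k] <- var(diff[el])
    if (is.null(var_G_star)) next
    v_hat[k] <- mean(var_G_star[el])
    if (var_diff[k] <= 0) {
      b[k] <- 0
    } else {
      b[k] <- min(1, max(0, 1 - v_hat[k] / var_diff[k]))
    }
  }
  G_a <- A_star + matrix(b[bin_id], n, n) * diff
  dimnames(G_a) <- dimnames(G_star)
  list(
    G_a = G_a,
    b_bin = tibble(bin = labels, b = b, n_elements = n_el,
                   v_hat = v_hat, var_diff = var_diff)
  )
}

#' Zero the across-breed block of a relationship matrix
#'
#' Forms the within-breed relationship matrix `G_w` from `G_a` by setting
#' elements between individuals of different breeds to zero; within-breed
#' elements are unchanged.
#'
#' @param G_a relationship matrix.
#' @param breed_of character vector of breed labels in row order.
#' @return The masked matrix.
#' @export
mask_within <- function(G_a, breed_of) {
  stopifnot(length(breed_of) == nrow(G_a))
  same <- outer(breed_of, breed_of, `==`)
  G_w <- G_a * same
  dimnames(G_w) <- dimnames(G_a)
  G_w
}

#' Build the full set of relationship matrices for one marker subset
#'
#' Convenience pipeline: pedigree A with per-breed inbreeding, pooled
#' frequencies and breed inbreeding since divergence over the marker
#' subset, genomic G with a block-jackknife element-variance estimate,
#' rescaling of both matrices to the breed-divergence base, per-bin
#' regression of `G*` back to `A*`, and the within-breed mask.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param loci marker subset (indices or names); `NULL` for all loci.
#' @param ped_A optional precomputed [build_pedigree_A()] result.
#' @param n_jackknife_blocks contiguous marker blocks for the jackknife.
#' @param bins relationship-bin edges, see [regress_G_on_A()].
#' @return A list of class `relationship_set`: matrices `A`, `A_star`, `G`,
#'   `G_star`, `G_a`, `G_w` over one individual ordering `ids`;
#'   `breed_of`; `freqs` (`pooled_freqs`); `f` (pedigree inbreeding
#'   tibble); `b_bin` (regression coefficients).
#' @export
#' @examples
#' pops <- list(breed_population("HF", 30, 0.10, seed = 1),
#'              breed_population("J", 30, 0.14, seed = 2))
#' panel <- simulate_two_breed_panel(default_variant_classes(c(50, 50, 20), 400),
#'                                   pops, seed = 7)
#' snps <- ascertain_snp_panel(panel, 300, min_maf = 0, both_breeds = FALSE,
#'                             seed = 1)
#' rels <- build_relationships(panel, loci = snps)
#' rels$b_bin
build_relationships <- function(panel, loci = NULL, ped_A = NULL,
                                n_jackknife_blocks = 10L,
                                bins = c(0, 0.10, 0.25, 0.50)) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(ped_A)) ped_A <- build_pedigree_A(panel)
  stopifnot(identical(ped_A$ids, panel$indiv$id))
  freqs <- compute_breed_inbreeding(panel, loci)
  G <- build_G(panel, loci, freqs, n_jackknife_blocks = n_jackknife_blocks)
  var_jack <- attr(G, "var_jack")
  star <- rescale_to_base(G, ped_A, freqs)
  var_G_star <- if (is.null(var_jack)) NULL else var_jack * (1 - freqs$F)^2
  reg <- regress_G_on_A(star$G_star, star$A_star, ped_A$A, ped_A$breed_of,
                        var_G_star = var_G_star, bins = bins)
  attr(G, "freqs") <- NULL
  attr(G, "var_jack") <- NULL
  structure(
    list(
      ids = ped_A$ids, breed_of = ped_A$breed_of,
      A = ped_A$A, A_star = star$A_star,
      G = G, G_star = star$G_star,
      G_a = reg$G_a, G_w = mask_within(reg$G_a, ped_A$breed_of),
      freqs = freqs, f = ped_A$f, b_bin = reg$b_bin
    ),
    class = "relationship_set"
  )
}

#' @export
print.relationship_set <- function(x, ...) {
  cat(sprintf("<relationship_set> %d individuals, %d loci; F = %.4f, alpha = %.3f\n",
              length(x$ids), length(x$freqs$p_j), x$freqs$F, x$freqs$alpha))
  print(x$b_bin)
  invisible(x)
}
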
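#' Specify which individuals and effects enter a GREML fit
#'
#' @param reference_ids ids of phenotyped reference individuals.
#' @param candidate_ids ids of selection candidates; they enter the fit
#'   through the relationship matrices only and never through phenotypes.
#' @param include_gw include the random within-breed animal effect `g_w`.
#' @param include_breed_fixed include breed as a fixed effect.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(reference_ids, candidate_ids = character(),
                       include_gw = TRUE, include_breed_fixed = FALSE) {
  reference_ids <- as.character(reference_ids)
  candidate_ids <- as.character(candidate_ids)
  if (length(reference_ids) < 2L) abort("need at least 2 reference individuals.")
  if (length(intersect(reference_ids, candidate_ids)) > 0L) {
    abort("reference and candidate sets must be disjoint.")
  }
  structure(
    list(reference_ids = reference_ids, candidate_ids = candidate_ids,
         include_gw = isTRUE(include_gw),
         include_breed_fixed = isTRUE(include_breed_fixed)),
    class = "model_spec"
  )
}

extract_phenotypes <- function(data, ids) {
  if (inherits(data, "trait_data")) data <- data$individuals
  if (is.data.frame(data)) {
    stopifnot(all(c("id", "phenotype") %in% names(data)))
    y <- setNames(data$phenotype, data$id)
  } else if (is.numeric(data) && !is.null(names(data))) {
    y <- data
  } else {
    abort("`data` must be a trait_data object, a tibble with id/phenotype, or a named numeric vector.")
  }
  missing <- setdiff(ids, names(y))
  if (length(missing) > 0L) {
    abort(sprintf("no phenotype for %d reference individual(s), e.g. %s.",
                  length(missing), missing[1]))
  }
  y[ids]
}

# restricted log-likelihood and the quantities AI-REML needs, at one theta.
# Returns -Inf loglik when V is not positive definite.
reml_eval <- function(theta, K, X, y, want_P = FALSE) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(K)) V <- V + theta[i] * K[[i]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Cx)) return(list(loglik = -Inf))
  XtViX_inv <- chol2inv(Cx)
  beta <- XtViX_inv %*% crossprod(ViX, y)
  Viy <- Vi %*% y
  Py <- Viy - ViX %*% (XtViX_inv %*% crossprod(X, Viy))
  loglik <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Cx))) +
                      sum(y * Py))
  out <- list(loglik = loglik, beta = drop(beta), Py = drop(Py))
  if (want_P) out$P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
  out
}

#' Fit the two-component GREML model
#'
#' Fits `y = X b + Z g_a + Z g_w + e` by restricted maximum likelihood,
#' with `g_a ~ N(0, G_a s2_ga)` the across-breed animal effect,
#' `g_w ~ N(0, G_w s2_gw)` the within-breed animal effect (its cross-breed
#' relationship block is zero) and `e ~ N(0, I s2_e)`. One `s2_ga` and one
#' `s2_gw` are estimated across both breeds; they refer to the base
#' population at breed divergence through the rescaling built into `G_a`.
#' Estimation uses average-information (AI) iterations with
#' expectation-maximization fallback steps whenever an AI proposal leaves
#' the parameter space or decreases the restricted likelihood, so the
#' log-likelihood never decreases over accepted iterations. Components are
#' bounded below at `boundary_eps * var(y)`; estimates resting there at
#' convergence are flagged as boundary solutions. BLUP solutions are
#' computed for every individual in the relationship set, so selection
#' candidates without phenotypes are predicted through their genomic
#' relationships with the reference animals.
#'
#' @param data phenotypes: a [simulate_trait()] result, a tibble with `id`
#'   and `phenotype`, or a named numeric vector. Only reference
#'   individuals' phenotypes are used.
#' @param rels a [build_relationships()] result.
#' @param spec a [model_spec()].
#' @param fixed optional named numeric, e.g. `c(ga = 0.3, gw = 0.1)`,
#'   fixing those variance components; the rest are estimated.
#' @param tol convergence tolerance on the log-likelihood change and the
#'   relative component change.
#' @param max_iter maximum REML iterations.
#' @param ridge added to the diagonal of the reference block of `G_a` (and
#'   `G_w`) if its Cholesky fails.
#' @param boundary_eps lower bound for variance components as a fraction of
#'   `var(y)`.
#' @return A list of class `greml_fit`: `varcomp` (tibble `component`,
#'   `variance`, `boundary`, `fixed`), `beta` (tibble `term`, `estimate`),
#'   `loglik`, `converged`, `n_iter`, `blup` (tibble `id`, `breed`, `ga`,
#'   `gw`, `is_candidate`), `spec`, `trace`.
#' @export
fit_greml <- function(data, rels, spec, fixed = NULL,
                      tol = 1e-6, max_iter = 200L, ridge = 1e-6,
                      boundary_eps = 1e-8) {
  stopifnot(inherits(rels, "relationship_set"), inherits(spec, "model_spec"))
  ids <- rels$ids
  unknown <- setdiff(c(spec$reference_ids, spec$candidate_ids), ids)
  if (length(unknown) > 0L) {
    abort(sprintf("id(s) not in the relationship set: %s ...", unknown[1]))
  }
  ref <- match(spec$reference_ids, ids)
  y <- unname(extract_phenotypes(data, spec$reference_ids))
  n <- length(y)
  vy <- var(y)
  lower <- boundary_eps * vy

  Ka <- rels$G_a[ref, ref]
  if (is.null(tryCatch(chol(Ka), error = function(e) NULL))) {
    message(sprintf("reference block of G_a is not positive definite; adding ridge %g.", ridge))
    Ka <- Ka + diag(ridge, n)
  }
  K <- list(ga = Ka)
  if (spec$include_gw) K$gw <- rels$G_w[ref, ref] + diag(ridge, n)
  K$e <- diag(1, n)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$include_breed_fixed) {
    br <- rels$breed_of[ref]
    lev <- unique(rels$breed_of[ids])
    for (b in lev[-1]) X <- cbind(X, as.numeric(br == b))
    colnames(X) <- c("(Intercept)", paste0("breed", lev[-1]))
  }

  comp <- names(K)
  theta <- setNames(rep(vy / length(K), length(K)), comp)
  free <- rep(TRUE, length(K))
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), comp)
    if (length(bad) > 0L) abort(sprintf("unknown fixed component '%s'.", bad[1]))
    theta[names(fixed)] <- pmax(unname(fixed), 0)
    free[match(names(fixed), comp)] <- FALSE
  }
  if (!any(free)) abort("at least one variance component must be free.")
  theta[free] <- pmax(theta[free], lower)

  ev <- reml_eval(theta, K, X, y, want_P = TRUE)
  if (!is.finite(ev$loglik)) abort("restricted likelihood undefined at the starting values; try a larger ridge.")
  trace <- list()
  converged <- FALSE
  plateau <- 0L
  crawl <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    P <- ev$P
    Py <- ev$Py
    KPy <- lapply(K, function(k) k %*% Py)
    trPK <- vapply(K, function(k) sum(P * k), numeric(1))
    yPKPy <- vapply(KPy, function(v) sum(Py * v), numeric(1))
    score <- -0.5 * (trPK - yPKPy)
    nf <- sum(free)
    AI <- matrix(0, nf, nf)
    fidx <- which(free)
    for (a in seq_len(nf)) {
      PKa <- P %*% KPy[[fidx[a]]]
      for (b in a:nf) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(KPy[[fidx[b]]] * PKa)
      }
    }
    step <- tryCatch(solve(AI, score[fidx]), error = function(e) NULL)

    proposal <- function(new_free) {
      th <- theta
      th[fidx] <- pmax(new_free, lower)
      th
    }
    accepted <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      damp <- 1
      for (h in 1:6) { # step-halving against out-of-bounds / decreasing steps
        th_new <- proposal(theta[fidx] + damp * step)
        ev_new <- reml_eval(th_new, K, X, y, want_P = TRUE)
        if (is.finite(ev_new$loglik) && ev_new$loglik >= ev$loglik - 1e-10) {
          accepted <- TRUE
          break
        }
        damp <- damp / 2
      }
    }
    if (!accepted) {
      # EM-REML fallback: guaranteed uphill, slow but safe near boundaries
      em <- theta[fidx] + theta[fidx]^2 * (yPKPy[fidx] - trPK[fidx]) / n
      th_new <- proposal(em)
      ev_new <- reml_eval(th_new, K, X, y, want_P = TRUE)
      if (!is.finite(ev_new$loglik) || ev_new$loglik < ev$loglik - 1e-8) {
        # no admissible uphill step: stop at the current iterate
        converged <- max(abs(score[fidx])) < 1e-3
        break
      }
    }
    d_ll <- ev_new$loglik - ev$loglik
    active <- free & th_new > 2 * lower # boundary components don't block convergence
    rel_change <- if (any(active)) {
      max(abs(th_new - theta)[active] / pmax(abs(theta[active]), lower))
    } else 0
    trace[[it]] <- c(iter = it, loglik = ev_new$loglik, th_new)
    theta <- th_new
    ev <- ev_new
    plateau <- if (abs(d_ll) < tol) plateau + 1L else 0L
    if (abs(d_ll) < tol && rel_change < sqrt(tol)) {
      converged <- TRUE
      break
    }
    # a flat likelihood ridge (e.g. nearly collinear kernels) can shuffle
    # variance between components indefinitely at constant loglik; treat a
    # sustained plateau as converged, only the component sum is identified
    if (plateau >= 3L) {
      converged <- TRUE
      break
    }
    # sustained slow crawl: EM gains of < 1e-4 per iteration for 10
    # iterations running; the remaining ascent is along the unidentified
    # ridge direction and does not change predictions
    crawl <- if (abs(d_ll) < 1e-4) crawl + 1L else 0L
    if (crawl >= 10L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    # AI/EM can crawl on a flat ridge (nearly collinear kernels) or near a
    # boundary; polish by direct search over the free log-variances
    fidx <- which(free)
    obj <- function(lt) {
      th <- theta
      th[fidx] <- pmax(exp(lt), lower)
      ll <- reml_eval(th, K, X, y)$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
    opt <- tryCatch(
      stats::optim(log(pmax(theta[fidx], lower)), obj,
                   method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(opt) && -opt$value >= ev$loglik) {
      theta[fidx] <- pmax(exp(opt$par), lower)
      ev <- reml_eval(theta, K, X, y, want_P = TRUE)
      converged <- opt$convergence == 0
    }
    if (!converged) {
      warn(sprintf("GREML did not converge in %d iterations; returning best iterate.", max_iter))
    }
  }

  at_bound <- free & theta <= lower * (1 + 1e-6)
  blup <- tibble(
    id = ids,
    breed = unname(rels$breed_of[ids]),
    ga = drop(theta["ga"] * (rels$G_a[, ref] %*% ev$Py)),
    gw = if (spec$include_gw) drop(theta["gw"] * (rels$G_w[, ref] %*% ev$Py)) else 0,
    is_candidate = ids %in% spec$candidate_ids
  )
  structure(
    list(
      varcomp = tibble(component = comp, variance = unname(theta),
                       boundary = unname(at_bound), fixed = !free),
      beta = tibble(term = colnames(X), estimate = ev$beta),
      loglik = ev$loglik, converged = converged, n_iter = it,
      blup = blup, spec = spec,
      trace = if (length(trace) > 0)
        as_tibble(do.call(rbind, trace)) else tibble()
    ),
    class = "greml_fit"
  )
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("<greml_fit> logLik = %.4f, %s in %d iteration(s)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$varcomp)
  invisible(x)
}

#' @describeIn fit_greml variance components as a tibble (broom
#'   convention).
#' @param x a `greml_fit`.
#' @param ... unused.
#' @export
tidy.greml_fit <- function(x, ...) x$varcomp

#' @describeIn fit_greml one-row model summary: `loglik`, `converged`,
#'   `n_iter`, variance components and the genomic heritability.
#' @export
glance.greml_fit <- function(x, ...) {
  th <- setNames(x$varcomp$variance, x$varcomp$component)
  tibble(
    loglik = x$loglik, converged = x$converged, n_iter = x$n_iter,
    var_ga = unname(th["ga"]),
    var_gw = if ("gw" %in% names(th)) unname(th["gw"]) else 0,
    var_e = unname(th["e"]),
    h2_hat = estimate_h2(x)
  )
}

#' Total genomic breeding values
#'
#' Sums the across-breed and within-breed BLUP solutions per individual
#' (the within-breed part is zero for fits without `g_w`).
#'
#' @param fit a [fit_greml()] result.
#' @param ids individuals to return; defaults to the fit's selection
#'   candidates, or everyone when the fit has none.
#' @return A tibble `id`, `breed`, `ga`, `gw`, `gebv`.
#' @export
total_gebv <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "greml_fit"))
  if (is.null(ids)) {
    ids <- if (length(fit$spec$candidate_ids) > 0) fit$spec$candidate_ids else fit$blup$id
  }
  unknown <- setdiff(ids, fit$blup$id)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown id(s): %s ...", unknown[1]))
  }
  fit$blup %>%
    filter(.data$id %in% ids) %>%
    mutate(gebv = .data$ga + .data$gw) %>%
    select("id", "breed", "ga", "gw", "gebv")
}

#' Genomic heritability from a GREML fit
#'
#' `(s2_ga + s2_gw) / (s2_ga + s2_gw + s2_e)`.
#'
#' @param fit a [fit_greml()] result.
#' @return A single number.
#' @export
estimate_h2 <- function(fit) {
  stopifnot(inherits(fit, "greml_fit"))
  th <- setNames(fit$varcomp$variance, fit$varcomp$component)
  g <- unname(th["ga"]) + if ("gw" %in% names(th)) unname(th["gw"]) else 0
  tot <- g + unname(th["e"])
  if (tot <= 0) abort("all variance components are zero; heritability undefined.")
  g / tot
}

#' 5\% critical value of the 50:50 mixture of chi-square(0) and chi-square(1)
#'
#' Null distribution of a likelihood-ratio statistic when a single variance
#' component is tested on the boundary of its parameter space: half the
#' mass at 0 and half chi-square with 1 df, giving
#' `P(chi2_1 > c) = 2 alpha`, i.e. 2.71 at the 5\% level.
#'
#' @param alpha significance level.
#' @return The critical value.
#' @export
#' @examples
#' mixture_chisq_threshold() # 2.71
mixture_chisq_threshold <- function(alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 0.5)
  qchisq(1 - 2 * alpha, df = 1)
}

#' Profile likelihood-ratio curve over fixed within-breed variance fractions
#'
#' Measures the power to separate the across- and within-breed animal
#' effects: after an unconstrained fit defines the total genetic variance,
#' the model is refit with the within-breed variance fixed at each given
#' percentage of that total (the across-breed variance taking the
#' remainder), re-estimating the residual variance and fixed effects. Twice
#' the log-likelihood difference to the free fit is compared with the 5\%
#' threshold (2.71) from the 50:50 mixture of chi-square(0) and
#' chi-square(1).
#'
#' @param data,rels,spec as in [fit_greml()]; `spec` must include `g_w`.
#' @param fractions percentages of the total genetic variance assigned to
#'   the within-breed component.
#' @param free_fit optional precomputed unconstrained [fit_greml()] result.
#' @param ... passed on to [fit_greml()].
#' @return A tibble of class `profile_lrt`: `fraction_pct`,
#'   `loglik_fixed`, `lrt` (= 2 * (free - fixed) log-likelihood), with
#'   attributes `loglik_free`, `threshold` and the free fit's genetic
#'   split.
#' @export
profile_lrt <- function(data, rels, spec,
                        fractions = c(1, seq(10, 90, 10), 99),
                        free_fit = NULL, ...) {
  stopifnot(inherits(spec, "model_spec"))
  if (!spec$include_gw) abort("profile_lrt needs a model specification with the within-breed effect.")
  if (is.null(free_fit)) free_fit <- fit_greml(data, rels, spec, ...)
  if (!free_fit$converged) abort("the unconstrained fit did not converge; cannot profile.")
  th <- setNames(free_fit$varcomp$variance, free_fit$varcomp$component)
  g_tot <- unname(th["ga"] + th["gw"])
  rows <- purrr::map_dfr(fractions, function(f) {
    fixed <- c(gw = g_tot * f / 100, ga = g_tot * (1 - f / 100))
    fit_f <- fit_greml(data, rels, spec, fixed = fixed, ...)
    tibble(fraction_pct = f, loglik_fixed = fit_f$loglik)
  })
  # the constrained fits profile the same likelihood, so their envelope
  # cannot exceed the free maximum; if a constrained fit lands above the
  # free log-likelihood the free fit stopped marginally short on a flat
  # ridge, and the envelope is the better estimate of the maximum
  ll_free <- max(free_fit$loglik, rows$loglik_fixed)
  rows$lrt <- 2 * (ll_free - rows$loglik_fixed)
  structure(
    rows,
    loglik_free = ll_free,
    threshold = mixture_chisq_threshold(0.05),
    free_split_pct = 100 * unname(th["gw"]) / g_tot,
    class = c("profile_lrt", class(rows))
  )
}
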
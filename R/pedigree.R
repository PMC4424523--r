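#' Pedigree numerator relationship matrix for a two-breed panel
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method, per breed, over one fixed individual ordering. Breeds share no
#' pedigree, so across-breed entries are exactly zero. Also returns the
#' per-breed mean pedigree inbreeding since the base of the pedigree
#' (`f`), needed to rescale A to the breed-divergence base population.
#'
#' The tabular recurrences are the standard ones: for individual `i` with
#' parents `s` and `d` (unknown parents contribute 0),
#' `A[i, j] = (A[j, s] + A[j, d]) / 2` for earlier `j`, and
#' `A[i, i] = 1 + A[s, d] / 2`.
#'
#' @param x a `genotype_panel`, a list of [breed_population()] objects, or a
#'   pedigree tibble with columns `id`, `sire`, `dam`, `breed` (parents must
#'   precede offspring).
#' @return A list of class `pedigree_A`: `A` (named matrix), `f` (tibble
#'   `breed`, `f` with mean pedigree inbreeding), `ids`, `breed_of`.
#' @export
#' @examples
#' hf <- breed_population("HF", 30, 0.1, seed = 1)
#' j <- breed_population("J", 30, 0.14, seed = 2)
#' pa <- build_pedigree_A(list(hf, j))
#' range(diag(pa$A))
build_pedigree_A <- function(x) {
  ped <- pedigree_table(x)
  validate_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  if (any(ped$breed[si[si > 0]] != ped$breed[si > 0]) ||
      any(ped$breed[di[di > 0]] != ped$breed[di > 0])) {
    abort("cross-breed matings are not allowed in the pedigree.")
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (s > 0L) rel <- rel + A[j, s]
      if (d > 0L) rel <- rel + A[j, d]
      A[j, i] <- A[i, j] <- rel / 2
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) A[s, d] / 2 else 0)
  }
  # across-breed entries are structurally zero: parents never cross breeds
  f <- tibble(breed = ped$breed, fi = diag(A) - 1) %>%
    group_by(.data$breed) %>%
    summarise(f = mean(.data$fi), .groups = "drop")
  structure(
    list(A = A, f = f, ids = ped$id, breed_of = setNames(ped$breed, ped$id)),
    class = "pedigree_A"
  )
}

pedigree_table <- function(x) {
  if (inherits(x, "genotype_panel")) {
    return(select(x$indiv, "id", "sire", "dam", "breed"))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "breed_population"))) {
    return(bind_rows(lapply(x, function(p) {
      mutate(p$pedigree, breed = p$breed)
    })) %>% select("id", "sire", "dam", "breed"))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sire", "dam", "breed") %in% names(x)))
    return(as_tibble(x)[, c("id", "sire", "dam", "breed")])
  }
  abort("cannot extract a pedigree from this object.")
}

#' @export
print.pedigree_A <- function(x, ...) {
  cat(sprintf("<pedigree_A> %d individuals; mean inbreeding: %s\n",
              nrow(x$A),
              paste(sprintf("%s %.4f", x$f$breed, x$f$f), collapse = ", ")))
  invisible(x)
}
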
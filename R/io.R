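#' Write and read a genotype panel as plain text
#'
#' The panel is stored in a directory of whitespace-delimited text files:
#' `genotypes.txt` holds a two-line header (individual ids, then breed
#' labels, both in row order) followed by the individuals x loci 0/1/2
#' matrix, one individual per row; `pedigree.txt` holds three columns
#' `id sire dam` with `0` for unknown parents; `loci.txt` holds the locus
#' table, including the two-column locus/class assignment.
#'
#' @param panel a [simulate_two_breed_panel()] result.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_genotype_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "genotype_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "genotypes.txt"), "w")
  on.exit(close(con))
  writeLines(paste(panel$indiv$id, collapse = " "), con)
  writeLines(paste(panel$indiv$breed, collapse = " "), con)
  utils::write.table(panel$geno, con, row.names = FALSE, col.names = FALSE)
  ped <- panel$indiv %>%
    mutate(sire = ifelse(is.na(.data$sire), "0", .data$sire),
           dam = ifelse(is.na(.data$dam), "0", .data$dam))
  utils::write.table(ped[, c("id", "sire", "dam")],
                     file.path(dir, "pedigree.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(panel$loci, file.path(dir, "loci.txt"),
                     row.names = FALSE, quote = FALSE)
  utils::write.table(panel$classes, file.path(dir, "classes.txt"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_genotype_panel
#' @export
read_genotype_panel <- function(dir) {
  lines <- readLines(file.path(dir, "genotypes.txt"))
  ids <- strsplit(lines[1], "\\s+")[[1]]
  breeds_of <- strsplit(lines[2], "\\s+")[[1]]
  geno <- as.matrix(utils::read.table(text = lines[-(1:2)]))
  storage.mode(geno) <- "integer"
  rownames(geno) <- ids
  loci <- as_tibble(utils::read.table(file.path(dir, "loci.txt"), header = TRUE))
  colnames(geno) <- loci$locus
  classes <- as_tibble(utils::read.table(file.path(dir, "classes.txt"), header = TRUE))
  ped <- utils::read.table(file.path(dir, "pedigree.txt"),
                           col.names = c("id", "sire", "dam"),
                           colClasses = "character")
  ped$sire[ped$sire == "0"] <- NA_character_
  ped$dam[ped$dam == "0"] <- NA_character_
  indiv <- tibble(id = ids, breed = breeds_of) %>%
    left_join(as_tibble(ped), by = "id") %>%
    mutate(sex = NA_character_,
           generation = ifelse(is.na(.data$sire) & is.na(.data$dam), 0L, 1L))
  breeds <- unique(breeds_of)
  structure(
    list(geno = geno, indiv = indiv, loci = loci, breeds = breeds,
         classes = classes),
    class = "genotype_panel"
  )
}

#' Write and read a relationship matrix as dense whitespace text
#'
#' First line: individual ids; following lines: the dense matrix rows.
#'
#' @param M square matrix with id dimnames.
#' @param path output file.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_txt <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(M), collapse = " "), con)
  utils::write.table(M, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\\s+")[[1]]
  M <- as.matrix(utils::read.table(text = lines[-1]))
  dimnames(M) <- list(ids, ids)
  M
}

#' Export a panel to VCF or import biallelic VCF genotypes
#'
#' `write_panel_vcf()` writes the panel's 0/1/2 genotypes as unphased
#' diploid GT fields over synthetic biallelic sites (the allele counted by
#' code 2 is the ALT allele). `read_panel_vcf()` imports biallelic sites of
#' a VCF into a `genotype_panel`, counting ALT copies; breed labels must be
#' supplied since VCF carries none, and the pedigree is founders-only.
#'
#' @param panel a `genotype_panel`.
#' @param path VCF file path (plain text `.vcf`).
#' @param breed_of named character vector: breed label per sample id.
#' @return `path`, or the imported `genotype_panel`.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  gt_code <- c("0/0", "0/1", "1/1")
  m <- ncol(panel$geno)
  body <- matrix(gt_code[t(panel$geno) + 1L], nrow = m)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=multibreed",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$indiv$id), collapse = "\t"),
    paste(
      "1", seq_len(m), panel$loci$locus, "A", "C", ".", "PASS", ".", "GT",
      apply(body, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_panel_vcf
#' @export
read_panel_vcf <- function(path, breed_of) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  gt <- vcfR::extract.gt(v, element = "GT")[bi, , drop = FALSE]
  counts <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  counts[] <- vapply(strsplit(gsub("\\|", "/", gt), "/"), function(al) {
    sum(al != "0" & al != ".")
  }, integer(1))
  geno <- t(counts)
  ids <- rownames(geno)
  missing <- setdiff(ids, names(breed_of))
  if (length(missing) > 0L) {
    abort(sprintf("no breed label for sample(s) %s ...", missing[1]))
  }
  breeds_of <- unname(breed_of[ids])
  breeds <- unique(breeds_of)
  obs <- lapply(breeds, function(b) {
    unname(colMeans(geno[breeds_of == b, , drop = FALSE]) / 2)
  })
  nb <- vapply(breeds, function(b) sum(breeds_of == b), integer(1))
  p_pool <- Reduce(`+`, Map(`*`, obs, nb)) / sum(nb)
  loci <- tibble(
    locus = colnames(geno), class = "imported", p_anc = NA_real_,
    p_pooled = p_pool, maf_pooled = pmin(p_pool, 1 - p_pool),
    monomorphic = p_pool <= 0 | p_pool >= 1
  )
  for (k in seq_along(breeds)) {
    loci[[paste0("p_", breeds[k])]] <- obs[[k]]
    loci[[paste0("seg_", breeds[k])]] <- obs[[k]] > 0 & obs[[k]] < 1
  }
  indiv <- tibble(id = ids, breed = breeds_of, sire = NA_character_,
                  dam = NA_character_, sex = NA_character_, generation = 0L)
  structure(
    list(geno = geno, indiv = indiv, loci = loci, breeds = breeds,
         classes = tibble(class = "imported", n_loci = ncol(geno),
                          target_maf = NA_real_, beta_shape = NA_real_)),
    class = "genotype_panel"
  )
}
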
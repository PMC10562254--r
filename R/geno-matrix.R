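#' Genotype matrix with marker map
#'
#' Light container for an individuals x markers dosage matrix together with
#' its marker map. Genotypes are coded as counts of the alternate allele
#' (0 = hom reference, 1 = het, 2 = hom alternate, NA = missing). The map
#' carries chromosome, 1-based physical position and the two alleles.
#'
#' @param geno integer matrix, individuals in rows (rownames = ids), markers
#'   in columns; entries in \{0, 1, 2, NA\}.
#' @param map data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   one row per marker, sorted by chromosome then position.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(map), nrow(map) == ncol(geno),
            all(c("chrom", "pos", "ref", "alt") %in% names(map)))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype dosages must lie in {0, 1, 2} or be NA")
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
  }
  rownames(map) <- NULL
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%03d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0(map$chrom, "_", map$pos)
  structure(list(geno = geno, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing: %.2f%%  het: %.2f%%\n", 100 * miss,
              100 * mean(x$geno == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a geno_matrix by individuals and/or markers
#'
#' @param x geno_matrix.
#' @param individuals row index (integer, logical or character).
#' @param markers column index (integer or logical).
#' @return geno_matrix.
#' @export
subset_geno <- function(x, individuals = NULL, markers = NULL) {
  g <- x$geno
  m <- x$map
  if (!is.null(individuals)) g <- g[individuals, , drop = FALSE]
  if (!is.null(markers)) {
    g <- g[, markers, drop = FALSE]
    m <- m[markers, , drop = FALSE]
  }
  geno_matrix(g, m)
}

#' Bind two geno_matrix cohorts sharing a marker map
#'
#' @param x,y geno_matrix objects on the identical marker panel.
#' @return geno_matrix with the rows of both.
#' @export
rbind_geno <- function(x, y) {
  if (!isTRUE(all.equal(x$map[c("chrom", "pos")], y$map[c("chrom", "pos")])))
    stop("marker maps differ; cohorts cannot be combined")
  geno_matrix(rbind(x$geno, y$geno), x$map)
}
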
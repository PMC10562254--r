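#' Read genotypes from VCF or matrix TSV
#'
#' VCF input is restricted to biallelic SNP records carrying a GT field;
#' multiallelic and indel records are skipped and the skip count logged.
#' Phased (`0|1`) and unphased (`0/1`) separators are treated identically.
#' Matrix TSV input is the format written by [write_genotypes()]: four map
#' columns (chrom, pos, ref, alt) followed by one dosage column per
#' individual, `NA` for missing.
#'
#' @param path input file path.
#' @param format `"vcf"` or `"matrix-tsv"`.
#' @return [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  if (!any(snp)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt == "1/1"] <- 2L
  map <- data.frame(chrom = fix[snp, "CHROM"],
                    pos = as.integer(fix[snp, "POS"]),
                    ref = ref[snp], alt = alt[snp],
                    stringsAsFactors = FALSE)
  geno_matrix(t(dos), map)
}

read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(d))) stop("matrix TSV must start with columns ", paste(need, collapse = ", "))
  map_cols <- intersect(c(need, "cM"), names(d))
  map <- d[map_cols]
  g <- t(as.matrix(d[setdiff(names(d), map_cols)]))
  storage.mode(g) <- "integer"
  geno_matrix(g, map)
}

#' Write genotypes as minimal VCF v4.2 or matrix TSV
#'
#' The VCF carries GT only, unphased separators, `./.` for missing and
#' 1-based positions.
#'
#' @param x geno_matrix.
#' @param path output file path.
#' @param format `"vcf"` or `"matrix-tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path, format = c("vcf", "matrix-tsv")) {
  format <- match.arg(format)
  if (format == "matrix-tsv") {
    d <- cbind(x$map, as.data.frame(t(x$geno)))
    write_tsv(d, path)
    return(invisible(path))
  }
  gt <- matrix("./.", nrow = ncol(x$geno), ncol = nrow(x$geno))
  g <- t(x$geno)
  gt[g == 0L] <- "0/0"
  gt[g == 1L] <- "0/1"
  gt[g == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(x$geno)), collapse = "\t"))
  body <- paste(x$map$chrom, x$map$pos, colnames(x$geno), x$map$ref, x$map$alt,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# Deterministic TSV writer used for every table the pipeline emits.
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a phenotype table (individual id + one column per trait)
#' @param pheno data.frame with an `id` column and numeric trait columns.
#' @param path output TSV path.
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot("id" %in% names(pheno))
  write_tsv(pheno, path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
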
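#' Trait direction rule for breeding-favorable genotypes
#'
#' Encodes, per trait, whether higher values, lower values, or values inside
#' a window (e.g. amylose content within 13.0-22.0) are favored by breeding
#' practice.
#'
#' @param trait trait name.
#' @param rule `"higher_favorable"`, `"lower_favorable"` or
#'   `"window_favorable"`.
#' @param lo,hi window bounds (required for `window_favorable`; `lo < hi`).
#' @return list of class `trait_direction`.
#' @export
trait_direction <- function(trait, rule = c("higher_favorable",
                                            "lower_favorable",
                                            "window_favorable"),
                            lo = NA_real_, hi = NA_real_) {
  rule <- match.arg(rule)
  if (rule == "window_favorable") {
    if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
      stop("window_favorable needs finite lo < hi")
  }
  structure(list(trait = trait, rule = rule, lo = lo, hi = hi),
            class = "trait_direction")
}

#' Genotype-class effects at one locus
#'
#' Class means of the phenotype over the three genotype classes: A = hom
#' reference (dosage 0), M = heterozygote, C = hom alternate (dosage 2).
#' Pairs with missing genotype or phenotype are dropped; a class with zero
#' observations has an undefined (NA) effect.
#'
#' @param geno integer dosage vector at the locus.
#' @param pheno numeric phenotype vector, same length.
#' @return list: `A`, `M`, `C` (class means) and `nA`, `nM`, `nC` (counts).
#' @export
estimate_genotype_effects <- function(geno, pheno) {
  stopifnot(length(geno) == length(pheno))
  ok <- !is.na(geno) & !is.na(pheno)
  g <- geno[ok]; y <- pheno[ok]
  cls_mean <- function(d) if (any(g == d)) mean(y[g == d]) else NA_real_
  list(A = cls_mean(0L), M = cls_mean(1L), C = cls_mean(2L),
       nA = sum(g == 0L), nM = sum(g == 1L), nC = sum(g == 2L))
}

#' Degree of dominance d/a from genotype-class effects
#'
#' Additive effect a = |A - C| / 2 and dominance effect d = M - (A + C) / 2.
#' The degree of dominance is d/a for traits where higher values are favored
#' and -d/a where lower values are favored, so a positive degree always
#' means the heterozygote deviates toward the favorable direction. Loci
#' where either homozygous class has fewer than `min_hom` observations are
#' flagged excluded (class means driven by so few plants are outlier-prone);
#' a = 0 yields an NaN degree with a flag rather than an error.
#'
#' @param eff list from [estimate_genotype_effects()].
#' @param direction [trait_direction()]. Window-favorable traits use the
#'   unflipped d/a (the sign convention targets monotone-preference traits).
#' @param min_hom minimum per-homozygote-class count (default 5).
#' @return list of class `dominance_estimate`: `A`, `M`, `C`, counts, `a`,
#'   `d`, `degree`, `excluded` (logical), `degree_defined` (logical).
#' @export
compute_da <- function(eff, direction, min_hom = 5L) {
  stopifnot(inherits(direction, "trait_direction"))
  A <- eff$A; M <- eff$M; C <- eff$C
  if (is.na(A) || is.na(C) || is.na(M))
    return(structure(c(eff, list(a = NA_real_, d = NA_real_,
                                 degree = NA_real_, excluded = TRUE,
                                 degree_defined = FALSE)),
                     class = "dominance_estimate"))
  a <- abs(A - C) / 2
  d <- M - (A + C) / 2
  degree <- if (a == 0) NaN else d / a
  if (direction$rule == "lower_favorable" && is.finite(degree))
    degree <- -degree
  structure(c(eff, list(a = a, d = d, degree = degree,
                        excluded = min(eff$nA, eff$nC) < min_hom,
                        degree_defined = is.finite(degree))),
            class = "dominance_estimate")
}

#' Classify a degree of dominance
#'
#' Default category bounds: degree < -0.1 negative dominance; |degree| <=
#' 0.1 additive; up to 0.9 partial dominance; 0.9-1.1 complete dominance;
#' above 1.1 overdominance.
#'
#' @param degree finite degree of dominance.
#' @param bounds numeric `c(additive_halfwidth, complete_lo, complete_hi)`.
#' @return character category.
#' @export
classify_dominance <- function(degree, bounds = c(0.1, 0.9, 1.1)) {
  stopifnot(is.finite(degree))
  if (degree < -bounds[1]) "negative_dominance"
  else if (degree <= bounds[1]) "additive"
  else if (degree < bounds[2]) "partial_dominance"
  else if (degree <= bounds[3]) "complete_dominance"
  else "overdominance"
}

#' Identify the breeding-favorable allele at a locus
#'
#' The favorable allele is the one whose homozygote mean is favored by the
#' trait's direction rule; for a window rule, the homozygote inside the
#' window wins, and when both (or neither) are inside, the one closer to
#' the window midpoint / boundary. A tie in class means is flagged
#' unresolved.
#'
#' @param eff list from [estimate_genotype_effects()] (`A` and `C` must be
#'   defined).
#' @param direction [trait_direction()].
#' @return list: `favorable` (`"ref"` for the dosage-0 homozygote, `"alt"`
#'   for dosage-2, or NA), `resolved` logical.
#' @export
define_favorable_allele <- function(eff, direction) {
  A <- eff$A; C <- eff$C
  if (is.na(A) || is.na(C)) stop("both homozygous class means must be defined")
  if (A == C) return(list(favorable = NA_character_, resolved = FALSE))
  fav <- switch(direction$rule,
    higher_favorable = if (A > C) "ref" else "alt",
    lower_favorable = if (A < C) "ref" else "alt",
    window_favorable = {
      dist <- function(x) {
        if (x >= direction$lo && x <= direction$hi) 0 else
          min(abs(x - direction$lo), abs(x - direction$hi))
      }
      dA <- dist(A); dC <- dist(C)
      if (dA < dC) "ref"
      else if (dC < dA) "alt"
      else if (A < C) "ref" else "alt"  # both in window: lower value wins
    })
  list(favorable = fav, resolved = TRUE)
}

#' Count breeding-favorable alleles pyramided in one individual
#'
#' Each locus contributes its favorable-allele dosage (0, 1 or 2), so K
#' loci cap the count at 2K. Missing genotypes contribute 0 and are counted
#' separately.
#'
#' @param geno integer dosage vector for the individual over the panel loci
#'   (in panel order).
#' @param favorable character vector, `"ref"` or `"alt"` per locus.
#' @return list: `count`, `n_missing`.
#' @export
count_favorable_alleles <- function(geno, favorable) {
  stopifnot(length(geno) == length(favorable))
  dos <- ifelse(favorable == "alt", geno, 2L - geno)
  list(count = sum(dos, na.rm = TRUE), n_missing = sum(is.na(geno)))
}

#' Select top associated loci with distance clumping
#'
#' Ranks loci by ascending p-value and greedily keeps one representative
#' per signal: any locus within `radius_bp` of an already kept locus on the
#' same chromosome is absorbed into that signal.
#'
#' @param assoc data.frame: `chrom`, `pos`, `p` (finite p-values); extra
#'   columns are carried through.
#' @param k number of loci to return (default 100).
#' @param radius_bp clumping exclusion radius (default 1 Mb, matching the
#'   1 Mb candidate-region convention).
#' @return data.frame of up to `k` loci, best first.
#' @export
select_top_loci <- function(assoc, k = 100L, radius_bp = 1e6) {
  stopifnot(all(c("chrom", "pos", "p") %in% names(assoc)),
            all(is.finite(assoc$p)))
  assoc <- assoc[order(assoc$p), , drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(assoc))) {
    if (length(kept) >= k) break
    near <- kept[assoc$chrom[kept] == assoc$chrom[i] &
                   abs(assoc$pos[kept] - assoc$pos[i]) <= radius_bp]
    if (length(near) == 0L) kept <- c(kept, i)
  }
  if (length(kept) < k)
    warning("only ", length(kept), " independent signals available (asked ", k, ")")
  out <- assoc[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype and favorable-allele frequency trajectories across groups
#'
#' @param geno integer dosage vector at one locus.
#' @param groups factor-like group label per individual (e.g. breeding
#'   periods Y1/Y2/Y3).
#' @param favorable `"ref"` or `"alt"`.
#' @return data.frame, one row per group: genotype-class frequencies
#'   (`freq_ref_hom`, `freq_het`, `freq_alt_hom`, summing to 1 over
#'   non-missing) and `freq_favorable` allele frequency.
#' @export
genotype_frequency_trajectory <- function(geno, groups, favorable = "alt") {
  stopifnot(length(geno) == length(groups))
  groups <- factor(groups, levels = unique(groups))
  out <- do.call(rbind, lapply(levels(groups), function(gr) {
    g <- geno[groups == gr]
    g <- g[!is.na(g)]
    if (length(g) == 0L)
      return(data.frame(group = gr, n = 0L, freq_ref_hom = NA_real_,
                        freq_het = NA_real_, freq_alt_hom = NA_real_,
                        freq_favorable = NA_real_, stringsAsFactors = FALSE))
    f <- c(mean(g == 0L), mean(g == 1L), mean(g == 2L))
    alt_f <- mean(g) / 2
    data.frame(group = gr, n = length(g), freq_ref_hom = f[1], freq_het = f[2],
               freq_alt_hom = f[3],
               freq_favorable = if (favorable == "alt") alt_f else 1 - alt_f,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Better-parent heterosis of a parent-hybrid trio
#'
#' BPH is the amount by which the F1 exceeds its better-performing parent
#' under the trait's direction rule, reported on the absolute scale and as
#' a fraction of the better parent; the indicator uses the absolute form.
#'
#' @param f1,mother,father phenotype values.
#' @param direction [trait_direction()] (`higher_favorable` or
#'   `lower_favorable`).
#' @return list: `bph` (absolute), `bph_rel`, `positive` (logical),
#'   `better_parent` value.
#' @export
compute_bph <- function(f1, mother, father, direction) {
  if (is.na(f1) || is.na(mother) || is.na(father))
    return(list(bph = NA_real_, bph_rel = NA_real_, positive = NA,
                better_parent = NA_real_))
  higher <- direction$rule == "higher_favorable"
  best <- if (higher) max(mother, father) else min(mother, father)
  bph <- if (higher) f1 - best else best - f1
  list(bph = bph, bph_rel = bph / abs(best), positive = bph > 0,
       better_parent = best)
}

#' Fraction of F2 individuals transgressing both parents
#'
#' @param f2 numeric F2 phenotypes (already filtered to the genotype class
#'   of interest, e.g. individuals heterozygous at all complementary loci).
#' @param mother,father parental phenotype values.
#' @param direction [trait_direction()].
#' @return fraction of F2s strictly better than both parents; NA (with a
#'   warning) when the subset is empty.
#' @export
fraction_exceeding_parents <- function(f2, mother, father, direction) {
  f2 <- f2[!is.na(f2)]
  if (length(f2) == 0L) {
    warning("empty F2 subset; fraction undefined")
    return(NA_real_)
  }
  if (direction$rule == "higher_favorable")
    mean(f2 > max(mother, father))
  else
    mean(f2 < min(mother, father))
}
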
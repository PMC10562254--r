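#' Simulation configuration for synthetic hybrid cohorts
#'
#' Defines the study conditions every synthetic cohort is generated under:
#' a genome of evenly spaced biallelic SNPs, two differentiated founder
#' subpopulations (indica-like and japonica-like reference panels), and
#' per-trait QTL architectures with additive effect `a` and dominance
#' effect `d` per locus.
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers per chromosome, evenly spaced.
#' @param chrom_length_cM genetic length of each chromosome (centimorgan).
#' @param chrom_length_bp physical length of each chromosome (bp); defaults
#'   to 25 Mb, a typical rice chromosome.
#' @param diff_fraction fraction of markers fixed or nearly fixed for
#'   alternate alleles between the two founder subpopulations, in [0, 1].
#' @param purity within-subpopulation major-allele frequency at
#'   differentiated markers; 1 means fully fixed. Default 0.95 so the
#'   panel majority rules are exercised non-trivially.
#' @param panel_sizes integer vector `c(indica, japonica)`; defaults 19 and
#'   23, the reference-panel sizes used for differentiated-SNP calling.
#' @param qtl_spec named list (one element per trait) of data.frames with
#'   columns `marker` (column index), `a` (additive effect) and `d`
#'   (dominance effect).
#' @param heritability named numeric vector in [0, 1], names matching
#'   `qtl_spec`.
#' @param seed master seed; per-stage child seeds are derived from it
#'   deterministically so stages are independently reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       markers_per_chromosome = 500L,
                       chrom_length_cM = 150,
                       chrom_length_bp = 25e6,
                       diff_fraction = 0.5,
                       purity = 0.95,
                       panel_sizes = c(indica = 19L, japonica = 23L),
                       qtl_spec = list(),
                       heritability = numeric(),
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1,
            chrom_length_cM >= 0, chrom_length_bp > 0)
  if (diff_fraction < 0 || diff_fraction > 1)
    stop("diff_fraction must lie in [0, 1]")
  if (purity < 0.5 || purity > 1)
    stop("purity must lie in [0.5, 1]")
  if (length(heritability) && (any(heritability < 0) || any(heritability > 1)))
    stop("heritability must lie in [0, 1]")
  m_total <- n_chromosomes * markers_per_chromosome
  for (tr in names(qtl_spec)) {
    q <- qtl_spec[[tr]]
    stopifnot(all(c("marker", "a", "d") %in% names(q)))
    if (any(q$marker < 1) || any(q$marker > m_total))
      stop("QTL marker index out of range for trait ", tr)
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 markers_per_chromosome = as.integer(markers_per_chromosome),
                 chrom_length_cM = chrom_length_cM,
                 chrom_length_bp = chrom_length_bp,
                 diff_fraction = diff_fraction,
                 purity = purity,
                 panel_sizes = panel_sizes,
                 qtl_spec = qtl_spec,
                 heritability = heritability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-stage child seeds from one master seed, so each pipeline
# stage can be re-run in isolation with identical randomness.
child_seed <- function(master, stage) {
  stages <- c("founders", "parents", "f1", "f2", "phenotypes", "cv",
              "pipeline", "misc")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, length(stages))[i]
}

#' Simulate the two differentiated founder subpopulations
#'
#' Draws fully homozygous inbred founders for an indica-like and a
#' japonica-like panel. A `diff_fraction` share of markers is truly
#' differentiated: each subpopulation carries its own major allele with
#' within-panel frequency `purity` (homozygous either way). The remaining
#' markers share one alternate-allele frequency across both panels. The
#' per-marker truth (differentiated or not; which dosage is the indica and
#' japonica major) is returned for oracle tests.
#'
#' @param config [sim_config()].
#' @return list with `panel` (geno_matrix; indica rows first), `roles`
#'   (character vector `panel_ind` / `panel_jap`) and `truth` (list with
#'   `is_diff`, `indica_dosage`, `jap_dosage`, `base_freq`).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_chromosomes * config$markers_per_chromosome
  if (m == 0L) stop("zero markers requested")
  set.seed(child_seed(config$seed, "founders"))
  n_ind <- config$panel_sizes[[1]]
  n_jap <- config$panel_sizes[[2]]

  is_diff <- stats::runif(m) < config$diff_fraction
  # at differentiated markers, randomize which allele is the indica major
  indica_dosage <- ifelse(is_diff, sample(c(0L, 2L), m, replace = TRUE), NA_integer_)
  jap_dosage <- ifelse(is_diff, 2L - indica_dosage, NA_integer_)
  base_freq <- ifelse(is_diff, NA_real_, stats::runif(m, 0.1, 0.9))

  draw_panel <- function(n, major_dosage) {
    g <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      if (is_diff[j]) {
        keep <- stats::runif(n) < config$purity
        g[, j] <- ifelse(keep, major_dosage[j], 2L - major_dosage[j])
      } else {
        g[, j] <- 2L * (stats::runif(n) < base_freq[j])
      }
    }
    g
  }
  geno <- rbind(draw_panel(n_ind, indica_dosage),
                draw_panel(n_jap, jap_dosage))
  rownames(geno) <- c(sprintf("ind_panel%02d", seq_len(n_ind)),
                      sprintf("jap_panel%02d", seq_len(n_jap)))
  map <- founder_map(config)
  list(panel = geno_matrix(geno, map),
       roles = rep(c("panel_ind", "panel_jap"), c(n_ind, n_jap)),
       truth = list(is_diff = is_diff, indica_dosage = indica_dosage,
                    jap_dosage = jap_dosage, base_freq = base_freq))
}

founder_map <- function(config) {
  k <- config$markers_per_chromosome
  pos <- round(seq(1, config$chrom_length_bp, length.out = k))
  cm <- seq(0, config$chrom_length_cM, length.out = k)
  data.frame(chrom = rep(sprintf("chr%02d", seq_len(config$n_chromosomes)), each = k),
             pos = rep(pos, config$n_chromosomes),
             ref = "A", alt = "G",
             cM = rep(cm, config$n_chromosomes),
             stringsAsFactors = FALSE)
}

#' Draw one inbred parent line from the founder truth
#'
#' A fully homozygous line of the requested subspecies origin: at
#' differentiated markers it carries that subspecies' major allele with
#' probability `purity`; at undifferentiated markers it draws from the
#' shared base frequency.
#'
#' @param truth `truth` list from [simulate_founders()].
#' @param origin `"indica"` or `"japonica"`.
#' @param purity carry probability for the subspecies major allele
#'   (1 = a pure representative line).
#' @param seed integer seed.
#' @return integer dosage vector.
#' @export
make_parent <- function(truth, origin = c("indica", "japonica"), purity = 1,
                        seed = 1L) {
  origin <- match.arg(origin)
  set.seed(seed)
  m <- length(truth$is_diff)
  major <- if (origin == "indica") truth$indica_dosage else truth$jap_dosage
  g <- integer(m)
  d <- truth$is_diff
  keep <- stats::runif(m) < purity
  g[d] <- ifelse(keep[d], major[d], 2L - major[d])
  g[!d] <- 2L * (stats::runif(sum(!d)) < truth$base_freq[!d])
  g
}

#' Cross two inbred lines into an F1
#'
#' The F1 is heterozygous exactly where the parents carry different alleles,
#' homozygous for the shared parental allele elsewhere, and missing where
#' either parent is missing.
#'
#' @param mother,father integer dosage vectors; every non-missing entry must
#'   be homozygous (0 or 2) — heterozygous parents are rejected because the
#'   cross semantics assume inbred lines.
#' @return integer dosage vector for the F1.
#' @export
make_f1 <- function(mother, father) {
  stopifnot(length(mother) == length(father))
  if (any(mother == 1L, na.rm = TRUE) || any(father == 1L, na.rm = TRUE))
    stop("parents must be inbred (no heterozygous sites)")
  f1 <- (mother + father) %/% 2L
  f1[is.na(mother) | is.na(father)] <- NA_integer_
  as.integer(f1)
}

#' Simulate an F2 population by selfing the F1 of two inbred lines
#'
#' Each F2 individual is the sum of two independent gametes of the F1.
#' Gametes are mosaics of the two parental haplotypes with crossovers
#' following a Haldane (Poisson, no interference) process along the genetic
#' map: the recombination fraction between adjacent markers d cM apart is
#' (1 - exp(-2d/100)) / 2.
#'
#' @param mother,father inbred parental dosage vectors (the F1 is formed
#'   internally with [make_f1()]).
#' @param n number of F2 individuals (>= 1).
#' @param map data.frame with columns `chrom` and `cM` (one row per marker,
#'   positions non-decreasing within chromosome).
#' @param seed integer seed.
#' @return geno_matrix of the F2 cohort (map columns `pos`, `ref`, `alt`
#'   taken from `map` when present, else filled with placeholders).
#' @export
simulate_f2 <- function(mother, father, n, map, seed = 1L) {
  stopifnot(n >= 1, nrow(map) == length(mother),
            all(c("chrom", "cM") %in% names(map)))
  if (any(diff(map$cM) < 0 & map$chrom[-1] == map$chrom[-nrow(map)]))
    stop("cM positions must be non-decreasing within chromosome")
  make_f1(mother, father)  # validates inbredness
  set.seed(seed)
  hapA <- mother %/% 2L    # allele carried by the maternal haplotype
  hapB <- father %/% 2L
  geno <- gamete_states(n, map) + gamete_states(n, map)
  # states count how many of the two gametes carry the paternal haplotype:
  # dosage = (2 - s) * hapA + s * hapB per locus
  g <- sweep(2L - geno, 2L, hapA, `*`) + sweep(geno, 2L, hapB, `*`)
  g[, is.na(hapA) | is.na(hapB)] <- NA_integer_
  out <- geno_matrix(g, data.frame(chrom = map$chrom,
                                   pos = if ("pos" %in% names(map)) map$pos else seq_len(nrow(map)),
                                   ref = if ("ref" %in% names(map)) map$ref else "A",
                                   alt = if ("alt" %in% names(map)) map$alt else "G",
                                   cM = map$cM,
                                   stringsAsFactors = FALSE))
  rownames(out$geno) <- sprintf("F2_%04d", seq_len(n))
  out
}

# n gametes over the whole map; returns an n x m 0/1 matrix of which parental
# haplotype each locus comes from (Markov chain per chromosome, Haldane
# switch probabilities).
gamete_states <- function(n, map) {
  out <- matrix(0L, n, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    k <- length(idx)
    r <- 0.5 * (1 - exp(-2 * diff(map$cM[idx]) / 100))
    s <- matrix(0L, n, k)
    s[, 1] <- stats::rbinom(n, 1L, 0.5)
    if (k > 1) {
      flips <- matrix(stats::rbinom(n * (k - 1), 1L, rep(r, each = n)), n, k - 1)
      cum <- flips
      if (k > 2) cum <- t(apply(flips, 1, cumsum))
      s <- (s[, 1] + cbind(0L, cum)) %% 2L
    }
    out[, idx] <- s
  }
  out
}

#' Simulate phenotypes from a QTL architecture at a target heritability
#'
#' The genetic value of individual i is
#' g_i = sum_j a_j x_ij + d_j z_ij, with x the additive coding (dosage - 1,
#' in \{-1, 0, 1\}) and z the heterozygosity indicator. Gaussian residual
#' variance is calibrated empirically on the simulated cohort so that
#' Var(g) / Var(y) equals the target heritability.
#'
#' @param gm geno_matrix of the cohort.
#' @param qtl_spec named list per trait of data.frames (`marker`, `a`, `d`).
#' @param heritability named numeric in [0, 1].
#' @param seed integer seed.
#' @return list with `pheno` (data.frame: id + one column per trait) and
#'   `genetic_values` (same shape; the true g_i for recovery tests).
#' @export
simulate_phenotypes <- function(gm, qtl_spec, heritability, seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!all(names(qtl_spec) %in% names(heritability)))
    stop("every trait in qtl_spec needs a heritability entry")
  set.seed(seed)
  n <- nrow(gm$geno)
  pheno <- data.frame(id = rownames(gm$geno), stringsAsFactors = FALSE)
  gvals <- pheno
  for (tr in names(qtl_spec)) {
    q <- qtl_spec[[tr]]
    h2 <- heritability[[tr]]
    x <- gm$geno[, q$marker, drop = FALSE] - 1L
    z <- (gm$geno[, q$marker, drop = FALSE] == 1L) * 1L
    x[is.na(x)] <- 0; z[is.na(z)] <- 0
    g <- as.numeric(x %*% q$a + z %*% q$d)
    vg <- stats::var(g)
    if (h2 == 0) {
      if (vg > 1e-12)
        stop("heritability 0 with non-zero genetic variance for trait ", tr)
      y <- stats::rnorm(n)
    } else if (h2 == 1) {
      if (vg < 1e-12)
        stop("heritability 1 requested with zero genetic variance for trait ", tr)
      y <- g
    } else {
      if (vg < 1e-12 && h2 > 0)
        stop("no genetic variance but positive heritability for trait ", tr)
      y <- g + stats::rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
    }
    pheno[[tr]] <- y
    gvals[[tr]] <- g
  }
  list(pheno = pheno, genetic_values = gvals)
}
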
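#' Run configuration for the end-to-end pipeline
#'
#' Collects the simulation conditions and stage parameters for one
#' deterministic pipeline run. Window sizes and thresholds default to the
#' field-standard values the rest of the package uses (199-SNP window,
#' >=120 hits, >=17/>=21 panel majorities, top-100 loci, sixfold CV x 3).
#'
#' @param sim [sim_config()] for the synthetic cohorts.
#' @param out_dir output directory (created if absent).
#' @param n_f2 F2 population size.
#' @param window,min_hits introgression-scan parameters.
#' @param min_indica,min_japonica differentiated-SNP panel thresholds.
#' @param top_k favorable-loci panel size.
#' @param k_folds,cv_iterations cross-validation design.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("hybridsel_run_"),
                       n_f2 = 300L, window = 199L, min_hits = 120L,
                       min_indica = 17L, min_japonica = 21L,
                       top_k = 100L, k_folds = 6L, cv_iterations = 3L) {
  structure(list(sim = sim, out_dir = out_dir, n_f2 = as.integer(n_f2),
                 window = as.integer(window), min_hits = as.integer(min_hits),
                 min_indica = as.integer(min_indica),
                 min_japonica = as.integer(min_japonica),
                 top_k = as.integer(top_k), k_folds = as.integer(k_folds),
                 cv_iterations = as.integer(cv_iterations)),
            class = "run_config")
}

# content hash of the configuration (excluding the output path), recorded
# in every output's metadata
config_hash <- function(config) {
  config$out_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline on one synthetic study
#'
#' Chains the stages: simulate founders and F2 cohort; call differentiated
#' SNPs and scan a pure-japonica line, the F1 and the F2s for introgression;
#' estimate per-QTL dominance (d/a) and favorable alleles; partition
#' variance around the strongest QTL; fit GBLUP with cross-validation.
#' Every table is written under `config$out_dir` and the run metadata
#' (seeds, config hash, per-stage record counts) as JSON; outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param config [run_config()].
#' @return list with the in-memory stage results (`founders`, `panel`,
#'   `f2`, `pheno`, `da_table`, `pve`, `gblup`, `cv`, `metadata`),
#'   invisibly writing all tables to `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  counts <- list()
  cfg_hash <- config_hash(config)
  sim <- config$sim

  # stage 1: founders + parents -------------------------------------------
  founders <- simulate_founders(sim)
  write_genotypes(founders$panel, out("panel.vcf"), "vcf")
  jsonlite::write_json(founders$truth, out("truth_markers.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  counts$panel_accessions <- nrow(founders$panel$geno)

  seed_par <- child_seed(sim$seed, "parents")
  mother <- make_parent(founders$truth, "indica", purity = 1, seed = seed_par)
  father <- make_parent(founders$truth, "japonica", purity = 1, seed = seed_par + 1L)

  # stage 2: F1 + F2 cohort ------------------------------------------------
  f1 <- make_f1(mother, father)
  f2 <- simulate_f2(mother, father, config$n_f2, founders$panel$map,
                    seed = child_seed(sim$seed, "f2"))
  write_genotypes(f2, out("f2_genotypes.tsv"), "matrix-tsv")
  counts$f2_individuals <- nrow(f2$geno)

  # stage 3: phenotypes ----------------------------------------------------
  ph <- simulate_phenotypes(f2, sim$qtl_spec, sim$heritability,
                            seed = child_seed(sim$seed, "phenotypes"))
  write_phenotypes(ph$pheno, out("phenotypes.tsv"))

  # stage 4: ancestry scan -------------------------------------------------
  ip <- subset_geno(founders$panel, founders$roles == "panel_ind")
  jp <- subset_geno(founders$panel, founders$roles == "panel_jap")
  panel <- call_differentiated_snps(ip, jp, config$min_indica, config$min_japonica)
  write_tsv(panel, out("differentiated_snps.tsv"))
  counts$differentiated_snps <- nrow(panel)

  tracks <- c(list(indica_parent = classify_sites(mother, panel),
                   japonica_parent = classify_sites(father, panel),
                   F1 = classify_sites(f1, panel)),
              stats::setNames(lapply(seq_len(min(20L, nrow(f2$geno))), function(i)
                classify_sites(f2$geno[i, ], panel)),
                rownames(f2$geno)[seq_len(min(20L, nrow(f2$geno)))]))
  segs <- lapply(tracks, scan_introgression, window = config$window,
                 min_hits = config$min_hits)
  write_segments_bed(segs, out("introgression_segments.bed.tsv"))
  comp <- t(vapply(tracks, genome_composition, numeric(4)))
  write_tsv(data.frame(individual = rownames(comp), comp, row.names = NULL),
            out("genome_composition.tsv"))
  counts$segments <- sum(vapply(segs, nrow, integer(1)))

  # stage 5: dominance effects at the planted QTLs -------------------------
  da_rows <- list()
  for (tr in names(sim$qtl_spec)) {
    dir_tr <- trait_direction(tr, "higher_favorable")
    q <- sim$qtl_spec[[tr]]
    for (r in seq_len(nrow(q))) {
      eff <- estimate_genotype_effects(f2$geno[, q$marker[r]], ph$pheno[[tr]])
      est <- compute_da(eff, dir_tr)
      fav <- if (!is.na(eff$A) && !is.na(eff$C) && eff$A != eff$C)
        define_favorable_allele(eff, dir_tr)$favorable else NA_character_
      da_rows[[length(da_rows) + 1L]] <- data.frame(
        trait = tr, marker = q$marker[r], a_true = q$a[r], d_true = q$d[r],
        a_hat = est$a, d_hat = est$d, degree = est$degree,
        category = if (isTRUE(est$degree_defined)) classify_dominance(est$degree) else NA_character_,
        excluded = est$excluded, favorable = fav, stringsAsFactors = FALSE)
    }
  }
  da_table <- do.call(rbind, da_rows)
  if (!is.null(da_table)) write_tsv(da_table, out("dominance_estimates.tsv"))

  # stage 6: variance partition around the strongest QTL -------------------
  pve <- NULL
  first_trait <- names(sim$qtl_spec)[1]
  if (!is.null(first_trait)) {
    q <- sim$qtl_spec[[first_trait]]
    peak <- q$marker[which.max(abs(q$a))]
    reg <- split_region(f2$map, f2$map$chrom[peak], f2$map$pos[peak])
    A_in <- build_relationship_matrices(f2$geno[, reg$in_region, drop = FALSE])
    A_out <- build_relationship_matrices(f2$geno[, reg$out_region, drop = FALSE])
    rvm <- fit_region_model(ph$pheno[[first_trait]], NULL,
                            A_in$A, A_in$D, A_out$A, A_out$D)
    pve <- compute_pve(rvm)
    write_tsv(data.frame(trait = first_trait, peak_marker = peak,
                         genetic_proportion = pve$genetic_proportion,
                         pve = pve$pve, converged = rvm$converged),
              out("region_pve.tsv"))
  }

  # stage 7: genomic selection ---------------------------------------------
  gb <- cv <- NULL
  if (!is.null(first_trait)) {
    rel <- build_relationship_matrices(f2)
    gb <- fit_gblup(ph$pheno[[first_trait]], NULL, rel$A)
    cv <- cross_validate(ph$pheno[[first_trait]], rel$A, k = config$k_folds,
                         iterations = config$cv_iterations,
                         seed = child_seed(sim$seed, "cv"))
    write_tsv(data.frame(id = rownames(f2$geno), gebv = gb$gebv),
              out("gebv.tsv"))
    jsonlite::write_json(list(trait = first_trait, h2 = gb$h2,
                              accuracy = cv$accuracy),
                         out("cv_report.json"), auto_unbox = TRUE, digits = NA)
  }

  metadata <- list(package = "hybridsel",
                   version = as.character(utils::packageVersion("hybridsel")),
                   config_hash = cfg_hash, master_seed = sim$seed,
                   counts = counts)
  jsonlite::write_json(metadata, out("run_metadata.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(founders = founders, panel = panel, f1 = f1, f2 = f2,
                 pheno = ph, tracks = tracks, segments = segs,
                 da_table = da_table, pve = pve, gblup = gb, cv = cv,
                 metadata = metadata))
}

#' Demo configuration used by the bundled analysis scripts
#'
#' Desk-scale study conditions: 2 chromosomes x 500 markers, 80% of them
#' subspecies-differentiated at 0.95 panel purity (so each chromosome's
#' called panel comfortably exceeds the 199-SNP scan window), a
#' 300-individual F2 cohort and one yield-like trait with five QTLs (mixed
#' additive and dominant) at heritability 0.5.
#'
#' @param seed master seed.
#' @return [run_config()].
#' @export
demo_config <- function(seed = 1L) {
  qtl <- data.frame(marker = c(60L, 180L, 320L, 480L, 700L),
                    a = c(1, 0.8, 0.6, 0.5, 0.4),
                    d = c(0.5, 0, 0.6, -0.2, 0.4))
  run_config(sim = sim_config(n_chromosomes = 2L, markers_per_chromosome = 500L,
                              chrom_length_cM = 150, diff_fraction = 0.8,
                              qtl_spec = list(yield_per_plant = qtl),
                              heritability = c(yield_per_plant = 0.5),
                              seed = seed),
             n_f2 = 300L)
}
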
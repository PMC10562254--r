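#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohorts with known ground truth.
#
# Two differentiated founder panels (19 indica-like + 23 japonica-like
# accessions), one pure inbred parent per subspecies, their F1, and a
# 500-individual F2 population with one yield-like trait controlled by five
# QTLs (mixed additive/dominant effects) at heritability 0.5. QTLs are
# placed at parent-discordant markers so all three genotype classes
# segregate in the F2.

library(hybridsel)

out <- "results/cohorts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026L

cfg <- sim_config(n_chromosomes = 2L, markers_per_chromosome = 500L,
                  chrom_length_cM = 150, diff_fraction = 0.8, seed = seed)

founders <- simulate_founders(cfg)
write_genotypes(founders$panel, file.path(out, "panel.vcf"), "vcf")
jsonlite::write_json(founders$truth, file.path(out, "truth_markers.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")

mother <- make_parent(founders$truth, "indica", purity = 1, seed = seed + 1L)
father <- make_parent(founders$truth, "japonica", purity = 1, seed = seed + 2L)
f1 <- make_f1(mother, father)
parents <- geno_matrix(rbind(indica_parent = mother, japonica_parent = father,
                             F1 = f1), founders$panel$map)
write_genotypes(parents, file.path(out, "parents_f1.tsv"), "matrix-tsv")

f2 <- simulate_f2(mother, father, 500L, founders$panel$map, seed = seed + 3L)
write_genotypes(f2, file.path(out, "f2_genotypes.tsv"), "matrix-tsv")

# five QTLs at evenly spaced parent-discordant markers, with favorable
# alleles alternating between the two parents (genetic complementation:
# neither inbred carries them all, the F1 is heterozygous at every QTL)
het_sites <- which(mother != father)
markers <- het_sites[round(seq(40, length(het_sites) - 40, length.out = 5))]
x_mother <- mother[markers] - 1L            # +1 or -1
sign <- ifelse(seq_along(markers) %% 2L == 1L, x_mother, -x_mother)
qtl <- data.frame(marker = markers,
                  a = c(1, 0.8, 0.6, 0.5, 0.4) * sign,
                  d = c(0.5, 0, 0.6, -0.2, 0.4))
utils::write.table(qtl, file.path(out, "qtl_spec.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

ph <- simulate_phenotypes(f2, list(yield_per_plant = qtl),
                          c(yield_per_plant = 0.5), seed = seed + 4L)
write_phenotypes(ph$pheno, file.path(out, "f2_phenotypes.tsv"))
write_phenotypes(ph$genetic_values, file.path(out, "f2_true_genetic_values.tsv"))

cat(sprintf("panel: %d accessions x %d markers (%.0f%% differentiated in truth)\n",
            nrow(founders$panel$geno), ncol(founders$panel$geno),
            100 * mean(founders$truth$is_diff)))
cat(sprintf("F1 heterozygosity: %.3f (parents discordant at %d sites)\n",
            mean(f1 == 1L), length(het_sites)))
cat(sprintf("QTL markers: %s\n", paste(qtl$marker, collapse = ", ")))
cat(sprintf("F2: %d individuals; realized h2 of yield_per_plant: %.3f\n",
            nrow(f2$geno),
            var(ph$genetic_values$yield_per_plant) / var(ph$pheno$yield_per_plant)))
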
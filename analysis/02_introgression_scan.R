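#!/usr/bin/env Rscript
# Stage 2: call subspecies-differentiated SNPs from the two reference
# panels and scan parents, F1 and F2 individuals for japonica introgression
# with the 199-SNP / >=120-hit sliding-window rule.

library(hybridsel)

inp <- "results/cohorts"
out <- "results/introgression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel_geno <- read_genotypes(file.path(inp, "panel.vcf"), "vcf")
roles <- rep(c("panel_ind", "panel_jap"), c(19, 23))
parents <- read_genotypes(file.path(inp, "parents_f1.tsv"), "matrix-tsv")
f2 <- read_genotypes(file.path(inp, "f2_genotypes.tsv"), "matrix-tsv")

pan <- call_differentiated_snps(subset_geno(panel_geno, roles == "panel_ind"),
                                subset_geno(panel_geno, roles == "panel_jap"))
write_tsv <- function(d, f) utils::write.table(d, f, sep = "\t", quote = FALSE,
                                               row.names = FALSE)
write_tsv(pan, file.path(out, "differentiated_snps.tsv"))
cat(sprintf("differentiated SNPs called: %d of %d markers\n",
            nrow(pan), ncol(panel_geno$geno)))

samples <- rbind(parents$geno, f2$geno[1:30, ])
tracks <- lapply(seq_len(nrow(samples)), function(i)
  classify_sites(samples[i, ], pan))
names(tracks) <- rownames(samples)
segs <- lapply(tracks, scan_introgression)
write_segments_bed(segs, file.path(out, "introgression_segments.bed.tsv"))

comp <- t(vapply(tracks, genome_composition, numeric(4)))
utils::write.table(data.frame(individual = rownames(comp), round(comp, 4)),
                   file.path(out, "genome_composition.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("\ngenome composition (II / IJ / JJ fractions of classified sequence):\n")
for (id in c("indica_parent", "japonica_parent", "F1"))
  cat(sprintf("  %-16s II=%.3f IJ=%.3f JJ=%.3f\n", id,
              comp[id, "II"], comp[id, "IJ"], comp[id, "JJ"]))

# per-bin fraction of F2s carrying each introgression state (5 Mb bins)
map <- pan
edges <- seq(0, max(map$pos) + 5e6, by = 5e6)
bins <- do.call(rbind, lapply(unique(map$chrom), function(ch)
  data.frame(chrom = ch, start_bp = head(edges, -1), end_bp = edges[-1])))
f2_segs <- segs[grep("^F2", names(segs))]
sm <- summarize_introgression(f2_segs, bins)
utils::write.table(sm, file.path(out, "f2_bin_summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
occupied <- sm$frac_het[sm$frac_het > 0]
cat(sprintf("\nF2 het-japonica bin fractions (occupied bins): mean %.2f\n",
            if (length(occupied)) mean(occupied) else 0))
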
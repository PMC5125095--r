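#!/usr/bin/env Rscript
# Generate the synthetic study population: an LD-block-structured SNP
# panel with planted causal signals, a quantitative trait (average
# daily gain, kg/day) with mean 0.98, SD 0.16 and h2 = 0.48, repeated
# weight records, and a matching gene annotation. Writes PLINK/VCF
# genotypes, the phenotype TSV and the annotation BED under results/.

library(multigwas)

dir.create("results", showWarnings = FALSE)

# 2,000-SNP panel: big enough that no single block dominates the
# genomic relationship (mirrors a genome-wide kinship)
cfg <- sim_config(n_samples = 1000, n_blocks = 400, snps_per_block = 5,
                  founder_haplotypes_per_block = 4, seed = 2024L)
d <- simulate_dataset(cfg)

# derive the trait the way it is measured in practice: the slope of
# body weight on age over the fattening period
rec <- simulate_weights(setNames(d$pheno$adg, d$pheno$sample_id),
                        ages = c(0, 210, 365, 545, 720),
                        noise_sd = 3, seed = 2024L)
adg_hat <- adg_from_weights(rec, window = c(210, 720))
message(sprintf(
  "trait: mean %.3f kg/day, SD %.3f; slope-recovered ADG r = %.3f",
  mean(d$pheno$adg), sd(d$pheno$adg),
  cor(adg_hat[d$pheno$sample_id], d$pheno$adg)))

write_genotypes(d$G, "results/sim_geno", format = "plink")
write_genotypes(d$G, "results/sim_geno.vcf", format = "vcf")
write_phenotype(d$pheno, "results/sim_pheno.tsv")
write_annotation_bed(d$annotation, "results/sim_genes.bed")
saveRDS(d$truth, "results/sim_truth.rds")  # local scratch for later steps

causal <- vapply(d$truth$causal, function(x) x$type, character(1))
message("planted: ", paste(causal, collapse = ", "),
        " | ", ncol(d$G$dosage), " SNPs, ", nrow(d$G$dosage), " samples")
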
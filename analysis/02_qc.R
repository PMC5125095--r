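#!/usr/bin/env Rscript
# Marker and sample quality control on the simulated panel: call rate
# >= 95%, MAF >= 0.05, Hardy-Weinberg exact P >= 1e-5, sample
# missingness <= 10%; then frequency-based imputation of the survivors.

library(multigwas)

G <- read_plink("results/sim_geno")
t <- qc_thresholds()          # the pipeline's default thresholds

snp <- snp_qc_filter(G, t)
print(snp$report)
smp <- sample_qc_filter(snp$G, t)
print(smp$report)

Gi <- impute_missing(smp$G, seed = 11L)
write_genotypes(Gi, "results/qc_geno", format = "plink")

report <- rbind(
  data.frame(scope = "snp", rule = names(snp$report$counts),
             removed = as.integer(snp$report$counts)),
  data.frame(scope = "sample", rule = names(smp$report$counts),
             removed = as.integer(smp$report$counts)))
write.table(report, "results/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("kept %d/%d SNPs and %d/%d samples",
                snp$report$n_kept, snp$report$n_input,
                smp$report$n_kept, smp$report$n_input))
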
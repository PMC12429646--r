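#!/usr/bin/env Rscript
# Simulate the study design: three groups (C, A20, AD) of six replicates,
# 500 genes with planted trajectory classes, and one A20-specific
# co-expression cluster. Writes the expression table, group map, truth
# labels and the simulation config under results/simulated/.

library(trajdeg)

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- simulation_spec(
  class_counts = default_class_counts(500),
  coordination = list(list(group = "A20", size = 10, lambda = 1)),
  seed = 20260929)
write_simulation_spec(spec, file.path(out, "sim_spec.yaml"))

sim <- generate_dataset(spec)
write_expression_table(sim$expression, file.path(out, "expression.tsv"),
                       file.path(out, "groups.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", n_genes(sim$expression), "genes x",
    n_samples(sim$expression), "samples\n")
print(table(sim$truth$class))
cat("cluster members:",
    paste(sim$truth$gene[!is.na(sim$truth$cluster)], collapse = ", "), "\n")
cat("outputs in", out, "\n")
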
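#!/usr/bin/env Rscript
# Trajectory classification of the bundled nucleus-accumbens call fixture:
# per-system trajectory categories, DEG sets and pathology-associated gene
# lists under each of the three persistence rules.

library(trajdeg)

out <- "results/fixture"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calls <- nacc_call_fixture()
panels <- load_default_panels()

traj <- classify_trajectories(calls)
write.table(traj, file.path(out, "trajectories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

summaries <- summarize_panels(calls, panels)
write.table(panel_summary_table(summaries),
            file.path(out, "panel_summaries.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (s in summaries) {
  cat(sprintf("%-28s members %2d  tested %2d  DEGs %2d  pathology %2d: %s\n",
              s$system, s$n_members, length(s$tested), length(s$deg_set),
              length(s$pathology_set),
              paste(s$pathology_set, collapse = ", ")))
}

cat("\npathology-set sizes per rule:\n")
for (rule in c("cvsad_or_a20vsad", "cvsad_only", "non_normalized")) {
  sizes <- vapply(summarize_panels(calls, panels, rule),
                  function(s) length(s$pathology_set), integer(1))
  cat(sprintf("  %-18s %s  total %d\n", rule,
              paste(sprintf("%s=%d", substr(names(sizes), 1, 4), sizes),
                    collapse = " "), sum(sizes)))
}
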
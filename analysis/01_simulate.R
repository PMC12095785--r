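#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic multisession study.
#
# Emulates the study's inputs at the node level: a 200-node left-hemisphere
# parcellation with a seven-network partition, 2,000 spatially
# autocorrelated gene-expression maps (50 planted drivers), depth-wise MT
# profiles and resting time series for 20 subjects across
# baseline/pre/post sessions, and three training sessions of behavioral
# accuracy following a logarithmic learning curve. Everything is written as
# labeled TSV plus a JSON manifest under results/data/.

library(gradlink)

cfg <- default_run_config(seed = 1)
sc <- cfg$synth

geom <- gen_geometry(sc)
effects <- gradlink:::draw_subject_effects(sc$n_subjects, sc$seed)
phenotype <- planted_change_pattern(sc, geom)
expression <- gen_expression(sc, geom, phenotype)
profiles <- gen_profiles(sc, geom, effects)
timeseries <- gen_timeseries(sc, geom, effects)
behavior <- gen_behavior(sc, effects)

dir <- "results/data"
write_synth_inputs(sc, geom, expression, profiles, timeseries, behavior, dir)
writeLines(as.character(phenotype), file.path(dir, "phenotype_map.txt"))

cat("wrote synthetic study to", dir, "\n")
cat(sprintf("  %d nodes, %d genes (%d planted), %d subjects, %d sessions\n",
            sc$n_nodes, sc$n_genes, length(sc$planted_genes),
            sc$n_subjects, sc$n_sessions))
cat("  network sizes:\n")
print(table(geom$network_labels))
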
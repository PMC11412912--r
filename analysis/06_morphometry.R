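#!/usr/bin/env Rscript
# Rule-based morphometry: dendritic-spine classification of simulated
# geometry measurements and the immuno-EM particle localization proportions.

library(synaptoform)

out <- "results/morphometry"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(9)

# synthetic spine geometries: a mushroom-rich mixture with stubby and thin
# protrusions, in um
n <- 300
kind <- sample(c("m", "s", "t"), n, TRUE, prob = c(0.5, 0.2, 0.3))
spines <- data.frame(
  length = ifelse(kind == "s", runif(n, 0.2, 0.5), runif(n, 0.6, 2.5)),
  head_width = ifelse(kind == "m", runif(n, 0.55, 1.2),
                      ifelse(kind == "t", runif(n, 0.1, 0.45), NA)),
  neck_width = ifelse(kind == "m", runif(n, 0.1, 0.3), NA))
spines$head_width[kind == "s"] <- NA
spines <- classify_spines(spines)
write.table(spines, file.path(out, "spines_classified.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
tab <- table(spines$class)
cat("spine classes:",
    paste(sprintf("%s %.0f%%", names(tab), 100 * tab / n), collapse = ", "),
    "\n")

p <- particle_proportions(cleft = 23, intra_spine = 20)
cat(sprintf("immuno-EM particles: %d%% in the synaptic cleft, %d%% intra-spine (n = 43)\n",
            p$pct_cleft, p$pct_intra))
write.table(data.frame(compartment = c("cleft", "intra_spine"),
                       count = c(23, 20),
                       percent = c(p$pct_cleft, p$pct_intra)),
            file.path(out, "particle_proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
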
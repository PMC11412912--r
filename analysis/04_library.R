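#!/usr/bin/env Rscript
# Supervised postsynaptic proteome library: three simulated 3-plex probe
# experiments, random-forest classification with out-of-bag scoring, ROC
# evaluation, the two-experiment inclusion rule and class-specific FDRs.

library(synaptoform)

out <- "results/library"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# annotation universe built from the simulated truth of experiment 1
sim1 <- simulate_classifier_proteome(150, separation = 2.5, seed = 101)
truth <- sim1$truth
ann <- annotation_sets(
  # the broad set is deep but contaminated with some presynaptic genes
  broad_postsynaptic = c(names(truth)[truth == "postsynaptic"],
                         head(names(truth)[truth == "presynaptic"], 20)),
  curated_presynaptic = head(names(truth)[truth == "presynaptic"], 60),
  curated_postsynaptic = head(names(truth)[truth == "postsynaptic"], 60),
  nonsynaptic_membrane = names(truth)[truth == "nonsynaptic_membrane"],
  cytosolic_er = names(truth)[truth == "cytosolic_er"])
training <- build_training_set(ann)
lab <- setNames(training$label, training$gene)
lab[lab != "postsynaptic"] <- "negative"
cat(sprintf("training set: %d positives, %d negatives\n",
            sum(lab == "postsynaptic"), sum(lab == "negative")))

scores <- lapply(1:3, function(i) {
  sim <- simulate_classifier_proteome(150, separation = 2.5, seed = 100 + i)
  train_and_classify(sim$features, lab, ntree = 500, seed = i)
})

roc <- roc_curve(scores[[1]],
                 ifelse(truth[names(scores[[1]])] == "postsynaptic",
                        "postsynaptic", "negative"))
cat(sprintf("experiment 1 AUROC (out-of-bag on labelled genes): %.3f\n",
            roc$auc))
write.table(data.frame(fpr = roc$fpr, tpr = roc$tpr),
            file.path(out, "roc_experiment1.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

lib <- assemble_library(scores, threshold = 0.5)
fdr <- estimate_library_fdr(lib, ann)
write.table(lib, file.path(out, "library.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("library: %d of %d genes included (positive in >= 2 of 3 experiments)\n",
            sum(lib$included), nrow(lib)))
cat(sprintf("library FDR: %.1f%% non-synaptic membrane, %.1f%% presynaptic\n",
            100 * fdr$fdr_nonsynaptic_membrane, 100 * fdr$fdr_presynaptic))
tp <- mean(truth[lib$gene[lib$included]] == "postsynaptic")
cat(sprintf("ground truth: %.1f%% of included genes are truly postsynaptic\n",
            100 * tp))
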
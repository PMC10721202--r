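#!/usr/bin/env Rscript
# Step 3 — fit the model battery.
#
# Reads the sparsity tables produced by steps 1-2 and fits the five
# model families (per-layer univariate sparsity, all-layer ridge on
# sparsity, per-layer ridge on retained PCs, global ridge on leading
# PCs, combined) with repeated 10-fold cross-validation. PC features
# are refitted here from the fixture activations; the synthetic studies
# are sparsity-only by construction, so their battery covers families
# 1-2. Results go to results/fits/.

suppressMessages(library(sparsebeauty))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2L && args[1L] == "--seed") {
  as.integer(args[2L])
} else 1L

dir.create("results/fits", recursive = TRUE, showWarnings = FALSE)
cvc <- cv_config(folds = 10L, repeats = 5L, seed = seed + 4L)

fit_synthetic <- function(label) {
  base <- file.path("results/synthetic", label)
  prof <- read_sparsity_table(file.path(base, "sparsity_gini.csv"))
  y <- read.csv(file.path(base, "scores.csv"))$score
  bat <- run_model_battery(prof, features = NULL, y, cvc)
  out <- file.path("results/fits", label)
  write_results(list(battery = bat$battery, per_layer = bat$per_layer,
                     metadata = list(seed = seed, folds = cvc$folds,
                                     repeats = cvc$repeats, study = label)),
                out)
  cat(sprintf("%s: all-layer sparsity CV R2 = %.3f\n", label,
              bat$battery$r2[bat$battery$family == "sparsity_all"]))
  bat
}

for (label in c("recovery_r2_025", "recovery_r2_050", "null")) {
  fit_synthetic(label)
}

# fixture study: recompute activations for the PCA feature families
st_manifest <- load_manifest("results/fixture/manifest.csv")
backend <- fixture_backend(seed + 9L)
acts <- lapply(st_manifest$records$image_path, function(p) {
  extract_layer_activations(preprocess_image(p, backend), backend)
})
names(acts) <- basename(st_manifest$records$image_path)
prof <- read_sparsity_table("results/fixture/sparsity_gini.csv")
feats <- lapply(colnames(prof), function(l) {
  A <- t(vapply(acts, function(a) a[[l]], numeric(length(acts[[1L]][[l]]))))
  pca_retain(A, 0.80, layer_id = l)
})
names(feats) <- colnames(prof)
bat <- run_model_battery(prof, feats, st_manifest$records$score_05, cvc,
                         permutations = 199L)
write_results(list(battery = bat$battery, per_layer = bat$per_layer,
                   metadata = list(seed = seed, folds = cvc$folds,
                                   repeats = cvc$repeats,
                                   permutations = 199L,
                                   study = "fixture")),
              "results/fits/fixture")
cat("fixture battery:\n")
print(bat$battery, digits = 3)
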
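#!/usr/bin/env Rscript
# Step 2 — encode images and measure sparsity.
#
# Generates the two-class fixture image study (sparse dots vs dense
# noise, 200 images), runs every image through the seeded fixture
# encoder, and writes the per-image per-layer Gini sparsity table plus
# the scored manifest to results/fixture/. With a user-supplied VGG16
# weight file and image manifest the same calls run the full-scale
# analysis: swap fixture_backend() for vgg16_backend(weights) and
# load_manifest() for simulate_fixture_study().

suppressMessages(library(sparsebeauty))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2L && args[1L] == "--seed") {
  as.integer(args[2L])
} else 1L

out <- "results/fixture"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

st <- simulate_fixture_study(n = 200L, seed = seed + 8L,
                             dir = file.path(out, "images"))
# manifest paths are stored relative to the manifest's own directory
rel_paths <- file.path("images", st$class, basename(st$paths))
write_manifest(rel_paths, st$scores, file.path(out, "manifest.csv"),
               dataset_name = "fixture_study", scale_min = 0, scale_max = 5)

backend <- fixture_backend(seed + 9L)
acts <- lapply(st$paths, function(p) {
  extract_layer_activations(preprocess_image(p, backend), backend)
})
names(acts) <- basename(st$paths)
prof <- sparsity_profile(acts, "gini")
prof_tr <- sparsity_profile(acts, "treves_rolls")

write_results(list(sparsity = prof,
                   metadata = list(seed = seed, backend = backend$name,
                                   backend_seed = backend$seed,
                                   resampling = "bilinear",
                                   n_images = length(st$paths))), out)
write_results(list(sparsity = prof_tr), out)

for (l in colnames(prof)) {
  cat(sprintf("%-6s median Gini: sparse_dots %.3f  dense_noise %.3f\n", l,
              median(prof[st$class == "sparse_dots", l]),
              median(prof[st$class == "dense_noise", l])))
}
cat("sparsity tables written to", out, "\n")
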
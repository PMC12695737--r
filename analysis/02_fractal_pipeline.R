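#!/usr/bin/env Rscript
# Step 2: run the segmentation -> edge -> box-counting pipeline on the
# stacks written by step 1, producing per-slice fractal dimensions and the
# five regional summaries per stack, plus an amplitude sweep demonstrating
# that estimated FD tracks the generated trabecular complexity.

suppressMessages(library(trabfd))
cfg <- run_config(seed = 42L)

for (name in c("smooth", "trabeculated")) {
  stack <- read_stack_png(file.path("results/stacks", name))
  res <- run_subject(stack, cfg)
  write.csv(slice_fd_table(res),
            sprintf("results/slice_fd_%s.csv", name), row.names = FALSE)
  cat("\n--", name, "stack:", res$manifest$status, "--\n")
  if (!is.null(res$summary)) print(res$summary)
}

# amplitude sweep: 5 seeds x 3 amplitudes, single mid-ventricular slices
sweep <- expand.grid(seed = 1:5, amplitude = c(0.02, 0.06, 0.10))
sweep$fd <- mapply(function(s, a) {
  ph <- generate_slice_phantom(
    slice_phantom_spec(trabecular_amplitude = a, papillary_count = 0,
                       seed = s))
  process_slice(ph$image, cfg, 1L)$slice_fd$fd
}, sweep$seed, sweep$amplitude)
write.csv(sweep, "results/fd_by_amplitude.csv", row.names = FALSE)
rho <- cor(sweep$amplitude, sweep$fd, method = "spearman")
cat(sprintf("\nAmplitude sweep: estimated FD rises with trabecular amplitude (Spearman rho = %.3f over %d runs).\n",
            rho, nrow(sweep)))
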
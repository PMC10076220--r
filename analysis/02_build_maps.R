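#!/usr/bin/env Rscript

# Stage 2: build each participant's cognitive maps.
#
# Spatial map: Euclidean distances between path-integrated stimulus
# locations, Gaussian kernel. Predictive map: TD-learned successor matrix
# from the visit sequence, inverted to a symmetric transition matrix
# (T = (M^-1 - I)/(-gamma)), diffusion kernel exp(-lambda L). Writes the
# kernel matrices for the first participant as a worked example and
# summarises kernel similarity across the cohort.

suppressPackageStartupMessages(library(rewardmaps))

seed <- 2026
out <- "results/maps"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ch <- generate_cohort(n_participants = 24, agent = "compositional",
                      seed = seed)

cors <- sapply(names(ch$participants), function(id) {
  p <- ch$participants[[id]]
  K_sp <- gaussian_kernel(p$distances, lambda = 4)
  M <- learn_successor(p$visits, ch$n_stimuli, gamma = 0.9, eta = 0.1)
  K_pr <- diffusion_kernel(successor_to_transition(M, gamma = 0.9), 1)
  if (id == "1") {
    tr <- successor_to_transition(M, gamma = 0.9)
    write_matrix_csv(unclass(M), file.path(out, "p1_successor.csv"))
    write_matrix_csv(tr$T, file.path(out, "p1_transition.csv"))
    write_matrix_csv(unclass(K_sp), file.path(out, "p1_spatial_kernel.csv"))
    write_matrix_csv(unclass(K_pr), file.path(out, "p1_predictive_kernel.csv"))
    write_matrix_csv(unclass(compose_kernels(K_sp, K_pr)),
                     file.path(out, "p1_compositional_kernel.csv"))
    jsonlite::write_json(list(gamma = 0.9, eta = 0.1, lambda_spatial = 4,
                              lambda_diffusion = 1,
                              n_clipped = tr$n_clipped,
                              symmetrized = tr$symmetrized),
                         file.path(out, "p1_maps_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  off <- lower.tri(unclass(K_sp))
  cor(unclass(K_sp)[off], unclass(K_pr)[off])
})

cat(sprintf("Spatial-predictive kernel correlation across %d participants: mean r = %.2f (range %.2f to %.2f).\n",
            length(cors), mean(cors), min(cors), max(cors)))
cat("The two kernels stay substantially correlated even with randomized\n")
cat("exploration tours (both are smooth similarity structures over the same\n")
cat("stimuli); the choice-level decomposition therefore uses the two\n")
cat("reparameterized competition models rather than raw per-kernel fits.\n")
cat("Example kernels for participant 1 written under", out, "\n")
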
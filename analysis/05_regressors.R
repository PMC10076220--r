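#!/usr/bin/env Rscript

# Stage 5: model-derived parametric regressors for neuroimaging GLMs.
#
# Builds, per participant: adaptation (repetition) distance regressors for
# a picture-viewing sequence (spatial and predictive distance to the
# preceding stimulus, z-scored per block, repeats and post-choice events
# excluded); chosen/unchosen value and compositional reward-prediction-
# error modulators for the choice task; the spatial-weight update signal;
# and the relative map accuracy (difference of unsigned prediction errors
# under the two maps). No GLM is estimated here — these tables are the
# package's hand-off to the neuroimaging stack.

suppressPackageStartupMessages(library(rewardmaps))

seed <- 2026
out <- "results/regressors"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ch <- generate_cohort(n_participants = 24, agent = "compositional",
                      seed = seed)
co <- cohort_predictions(ch, "compositional", lambda = 4, eta = 0.1)
sp <- cohort_predictions(ch, "spatial", lambda = 4)
pr <- cohort_predictions(ch, "predictive", eta = 0.1)
wt <- trialwise_weights(sp$pred_diff, pr$pred_diff, sp$choice,
                        sp$participant, sp$trial)

# a pseudorandom picture-viewing sequence (each stimulus six times per
# block, no immediate information about values)
set.seed(seed)
viewing <- do.call(rbind, lapply(1:3, function(b) {
  stim <- sample(rep(1:12, 6))
  data.frame(onset = seq(0, by = 5, length.out = length(stim)), block = b,
             stimulus = stim)
}))

p1 <- ch$participants[[1]]
D_sp <- euclidean_distances(p1$layout_hat)
M <- learn_successor(p1$visits, 12, gamma = 0.9, eta = 0.1)
D_pr <- kernel_distance(diffusion_kernel(successor_to_transition(M, 0.9), 1))
adapt <- adaptation_regressors(viewing, D_sp, D_pr)
utils::write.csv(adapt, file.path(out, "p1_adaptation_events.csv"),
                 row.names = FALSE)
cat(sprintf("Adaptation regressors: %d of %d events included; z-scored columns have mean %.1e / sd %.3f.\n",
            sum(adapt$included), nrow(adapt),
            mean(adapt$spatial_distance[adapt$included]),
            sd(adapt$spatial_distance[adapt$included])))

r1 <- co$participant == "1"
rpe <- compositional_rpe(co[r1, ])
rma <- relative_map_accuracy(sp$reward[r1] - sp$pred_chosen[r1],
                             pr$reward[r1] - pr$pred_chosen[r1])
vals <- choice_value_regressors(co[r1, ])
upd <- weight_update_regressor(wt$w[wt$participant == "1"],
                               wt$trial[wt$participant == "1"])
events <- data.frame(onset = (seq_len(sum(r1)) - 1) * 8, duration = 2,
                     trial_type = "feedback",
                     chosen_value = vals$chosen_value,
                     unchosen_value = vals$unchosen_value,
                     compositional_rpe = rpe$rpe_demeaned,
                     relative_map_accuracy = rma$value_demeaned,
                     weight_update = c(NA, upd$update_demeaned))
utils::write.table(events, file.path(out, "p1_choice_events.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(transforms = list(
  chosen_value = "demeaned", unchosen_value = "demeaned",
  compositional_rpe = "demeaned", relative_map_accuracy = "demeaned",
  weight_update = "demeaned; first trial undefined",
  sign_convention = attr(rma, "sign_convention"))),
  file.path(out, "p1_choice_events.json"), auto_unbox = TRUE)

cat(sprintf("Choice-task regressors (participant 1): RPE sd %.2f points, |r(RMA, RPE)| = %.3f.\n",
            sd(rpe$rpe), abs(cor(rma$value, rpe$rpe))))
cat("BIDS-style events tables written under", out, "\n")
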
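# Self-contained desk-scale experiments on synthetic cohorts: learnability
# of stage signatures by the reduced model, and the effect of adversarial
# subject-invariant training on the discriminator. Both are pure functions
# of their seeds and drive the acceptance checks and examples.

#' Learnability of synthetic stage signatures
#'
#' Generates a two-subject cohort (200 epochs each), trains the reduced
#' model on one subject and evaluates on the held-out subject. With the
#' default stage signatures the signal is learnable; with `flat = TRUE`
#' every stage shares one spectral profile and no event structure, so
#' held-out accuracy collapses to chance.
#'
#' @param seed integer seed controlling cohort, initialisation and training.
#' @param epochs_per_subject epochs simulated per subject.
#' @param passes training epochs of the fit.
#' @param flat remove all stage-dependent structure from the generator.
#' @param lr0 learning rate of the short training run.
#' @return list with `train_acc`, `heldout_acc`, `model`, `report`
#'   (held-out [metrics_report()]).
#' @export
learnability_experiment <- function(seed = 1L, epochs_per_subject = 200L,
                                    passes = 10L, flat = FALSE, lr0 = 2e-3) {
  args <- list(n_subjects = 2L, epochs_per_subject = epochs_per_subject,
               stage_transition = stationary_transition(rep(0.2, 5)),
               seed = seed)
  if (flat) {
    bp <- default_band_power()
    bp[] <- rep(bp["W", ], each = 5L)
    args$stage_band_power <- bp
    args$event_rates <- default_event_rates() * 0
    args$shared_gain <- stats::setNames(rep(0.5, 5), sleep_stages())
  }
  ds <- as_dataset(generate_cohort(do.call(cohort_spec, args)))
  tr <- dataset_subset(ds, which(ds$subject_id == "S01"))
  te <- dataset_subset(ds, which(ds$subject_id == "S02"))
  cfg <- sleepgcn_config_reduced()
  model <- sleepgcn_model(cfg, n_domains = 1L, seed = seed)
  tc <- train_config(epochs = passes, batch_size = 32L, lr0 = lr0,
                     lambda_grl = 0, dropout = 0.2, seed = seed)
  fit <- fit_sleepgcn(model, tr, tc)
  pr_tr <- predict(fit, tr)
  pr_te <- predict(fit, te)
  rep <- metrics_report(te$labels, pr_te$label)
  list(train_acc = mean(pr_tr$label == tr$labels),
       heldout_acc = mean(pr_te$label == te$labels),
       model = fit, report = rep)
}

#' Adversarial effect on the subject discriminator
#'
#' For each seed, trains the reduced model twice on a two-subject cohort
#' with subject-level baseline shifts: once with the gradient-reversal
#' strength at 0 (the discriminator learns freely) and once at
#' `lambda`. Reports the final discriminator accuracy of both runs;
#' adversarial training should push it toward chance (0.5).
#'
#' @param seeds integer seeds, one pair of runs each.
#' @param lambda adversarial strength of the active arm.
#' @param epochs_per_subject cohort size per subject.
#' @param passes training epochs per run.
#' @return data frame with one row per seed: discriminator accuracy under
#'   lambda = 0 and under `lambda`, and stage accuracy of the active arm.
#' @export
adversarial_experiment <- function(seeds = 1:5, lambda = 0.4,
                                   epochs_per_subject = 30L, passes = 6L) {
  rows <- lapply(seeds, function(sd) {
    spec <- cohort_spec(n_subjects = 2L,
                        epochs_per_subject = epochs_per_subject,
                        subject_shift_sd = 0.4, seed = 1000L + sd)
    ds <- as_dataset(generate_cohort(spec))
    cfg <- sleepgcn_config_reduced()
    one <- function(lam) {
      tc <- train_config(epochs = passes, batch_size = 20L, lr0 = 2e-3,
                         lambda_grl = lam, dropout = 0.2, seed = sd)
      fit_sleepgcn(sleepgcn_model(cfg, n_domains = 2L, seed = sd), ds, tc)
    }
    m0 <- one(0)
    m1 <- one(lambda)
    data.frame(seed = sd,
               disc_acc_lambda0 = discriminator_accuracy(m0, ds),
               disc_acc_adv = discriminator_accuracy(m1, ds),
               stage_acc_adv = mean(predict(m1, ds)$label == ds$labels))
  })
  do.call(rbind, rows)
}
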
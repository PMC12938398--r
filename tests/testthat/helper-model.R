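# Helpers for exercising the assembled model on tiny geometries.

ns_ <- asNamespace("sleepgcn")

# A miniature architecture: short epochs, few filters, tiny widths.
tiny_cfg <- function(...) {
  sleepgcn_config(epoch_len_s = 6, widths = c(20L, 50L, 100L),
                  branch_filters = 4L, gru_hidden = 8L, expert_width = 12L,
                  att_latent = 3L, n_frames = 3L, conv_stride = "half",
                  window_decim = 8L, disc_hidden = 6L, ...)
}

tiny_cohort_dataset <- function(n_subjects = 2, epochs_each = 3, seed = 7) {
  spec <- cohort_spec(n_subjects = n_subjects,
                      epochs_per_subject = epochs_each,
                      epoch_len_s = 6, seed = seed)
  zscore_normalize(as_dataset(generate_cohort(spec)))
}

prep_sample <- function(ds, cfg, e = 1L) {
  smp <- precompute_inputs(dataset_subset(ds, e), cfg)[[1]]
  smp$im2col <- ns_$sample_im2col(ds$signals[, , e], cfg)
  smp
}

# Loss value of one sample under plain parameters (no tape).
sample_loss_value <- function(P, smp, cfg, part = c("class", "domain"),
                              y = 2L, d = 1L) {
  part <- match.arg(part)
  fw <- ns_$forward_sample(NULL, P, smp, cfg, lambda = 0,
                          with_domain = TRUE)
  if (part == "class") ns_$ce_loss(ns_$ad_value(fw$logits), y)
  else ns_$ce_loss(ns_$ad_value(fw$dlogits), d)
}

# Autodiff gradients of one sample's loss (through the GRL for the domain
# part) for every parameter.
sample_loss_grads <- function(P, smp, cfg, lambda,
                              part = c("class", "domain"), y = 2L, d = 1L) {
  part <- match.arg(part)
  tp <- ns_$ad_tape()
  pn <- lapply(P, function(p) ns_$ad_param(tp, p))
  fw <- ns_$forward_sample(tp, pn, smp, cfg, lambda = lambda,
                          with_domain = TRUE)
  l <- if (part == "class") ns_$ad_crossent(tp, fw$logits, y)
       else ns_$ad_crossent(tp, fw$dlogits, d)
  ns_$ad_backward(tp, l)
  lapply(pn, function(nd) nd$g)
}

fd_gradient <- function(P, smp, cfg, part, nm, i, eps = 1e-5, y = 2L,
                        d = 1L) {
  P[[nm]][i] <- P[[nm]][i] + eps
  up <- sample_loss_value(P, smp, cfg, part, y, d)
  P[[nm]][i] <- P[[nm]][i] - 2 * eps
  dn <- sample_loss_value(P, smp, cfg, part, y, d)
  (up - dn) / (2 * eps)
}

rel_err <- function(a, b) abs(a - b) / max(1e-9, abs(a) + abs(b))
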
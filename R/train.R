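# Adversarial subject-invariant training: cross-entropy losses, the minimax
# objective realised through the gradient-reversal layer, Adam with a halving
# learning-rate schedule, and the mini-batch fit loop.

# Mean cross-entropy of softmax(logits) against integer labels (1-based).
ce_loss <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (any(labels < 1L | labels > ncol(logits)))
    stop("label out of range 1..", ncol(logits))
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), labels)])
}

#' Adversarial classification objective
#'
#' Evaluates the minimax objective
#' L = Lclass(stage predictions, y) - Ldomain(subject predictions, d),
#' both terms mean cross-entropies. During optimisation the domain term
#' reaches the feature extractor through the gradient-reversal layer with
#' strength `lambda`; the returned `total` is the objective value itself.
#'
#' @param stage_logits epochs x 5 stage logits (or one logit vector).
#' @param y stage labels, integers 1..5.
#' @param domain_logits epochs x n_subjects discriminator logits.
#' @param d subject labels, integers 1..n_subjects.
#' @param lambda adversarial strength (recorded; the reversal itself lives
#'   in the backward pass).
#' @return list with `total`, `Lclass`, `Ldomain`, `lambda`.
#' @export
adversarial_loss <- function(stage_logits, y, domain_logits = NULL, d = NULL,
                             lambda = 0.4) {
  Lclass <- ce_loss(stage_logits, y)
  Ldomain <- if (is.null(domain_logits)) 0 else ce_loss(domain_logits, d)
  list(total = Lclass - Ldomain, Lclass = Lclass, Ldomain = Ldomain,
       lambda = lambda)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, 100 epochs, initial
#' learning rate 3e-4 halved every 10 epochs, dropout 0.5, adversarial
#' strength 0.4, Glorot-uniform initial weights (set at model creation).
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size (256 for large cohorts, 128 for small).
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param lambda_grl adversarial strength lambda (0 disables reversal).
#' @param lambda_ramp optionally ramp lambda from 0 to `lambda_grl` over
#'   training (off by default; a fixed lambda is the reference setting).
#' @param dropout dropout rate before the classifier.
#' @param stratify stratify mini-batches by stage to soften class imbalance
#'   (off by default).
#' @param seed integer seed covering shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L, lr0 = 3e-4,
                         lr_decay = 0.5, lr_decay_every = 10L,
                         lambda_grl = 0.4, lambda_ramp = FALSE,
                         dropout = 0.5, stratify = FALSE, seed = 1L,
                         verbose = FALSE) {
  stopifnot(lr0 > 0, dropout >= 0, dropout < 1, lambda_grl >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 lambda_grl = lambda_grl, lambda_ramp = lambda_ramp,
                 dropout = dropout, stratify = stratify,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Learning rate at a given epoch under the halving schedule
#' @param config a [train_config()].
#' @param epoch 1-based epoch index.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr0 * config$lr_decay^floor((epoch - 1) / config$lr_decay_every)
}

adam_step <- function(state, grads, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    p <- state$params[[nm]]
    g <- if (is.null(dim(p))) as.numeric(g) else array(g, dim(p))
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- p * 0
      state$v[[nm]] <- p * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    state$params[[nm]] <- p - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train a model on a labelled dataset
#'
#' Mini-batch Adam on the joint loss Lclass + Ldomain, the domain term fed
#' through the gradient-reversal layer so the feature extractor is pushed
#' away from subject-identifiable representations while the discriminator
#' itself improves. Subject identities of the training set are the domain
#' classes. Fully seeded and reproducible on CPU.
#'
#' @param model a [sleepgcn_model()]; its discriminator is (re)built to
#'   match the training subjects.
#' @param dataset training `psg_dataset` (z-scored internally).
#' @param config a [train_config()].
#' @param val optional validation `psg_dataset` (subject-disjoint); when
#'   given, the returned model carries the parameters of the epoch with the
#'   best validation macro F1.
#' @return the trained model, with `history` (per-epoch data frame) and
#'   `domain_levels` attached.
#' @export
fit_sleepgcn <- function(model, dataset, config = train_config(),
                         val = NULL) {
  if (n_epochs(dataset) == 0L) stop("empty training dataset")
  cfg <- model$config
  dataset <- zscore_normalize(dataset)
  domain_levels <- sort(unique(dataset$subject_id))
  if (model$n_domains != length(domain_levels)) {
    fresh <- sleepgcn_model(cfg, n_domains = length(domain_levels),
                            seed = config$seed)
    for (nm in setdiff(names(fresh$params), names(model$params)))
      model$params[[nm]] <- fresh$params[[nm]]
    model$n_domains <- length(domain_levels)
  }
  inputs <- precompute_inputs(dataset, cfg)
  domains <- match(dataset$subject_id, domain_levels)
  labels <- as.integer(dataset$labels)
  n <- length(inputs)
  use_domain <- model$n_domains > 1L
  state <- list(params = model$params, m = list(), v = list(), t = 0L)
  hist <- vector("list", config$epochs)
  best <- list(f1 = -Inf, params = NULL)
  val_inputs <- NULL
  if (!is.null(val)) val <- zscore_normalize(val)
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, ep)
    lam <- config$lambda_grl
    if (config$lambda_ramp && config$epochs > 1L) {
      pfrac <- (ep - 1) / (config$epochs - 1)
      lam <- config$lambda_grl * (2 / (1 + exp(-10 * pfrac)) - 1)
    }
    ord <- if (config$stratify) stratified_order(labels) else sample.int(n)
    lc_sum <- 0; ld_sum <- 0; nb <- 0L
    for (b0 in seq.int(1L, n, by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      tp <- ad_tape()
      pn <- lapply(state$params, function(p) ad_param(tp, p))
      loss <- NULL
      for (s in bidx) {
        if (is.null(inputs[[s]]$im2col))
          inputs[[s]]$im2col <- sample_im2col(dataset$signals[, , s], cfg)
        smp <- inputs[[s]]
        dm <- NULL
        if (config$dropout > 0) {
          keep <- stats::rbinom(cfg$expert_width, 1L, 1 - config$dropout)
          dm <- keep / (1 - config$dropout)
        }
        fw <- forward_sample(tp, pn, smp, cfg, lambda = lam,
                             drop_mask = dm, with_domain = use_domain)
        ls <- ad_crossent(tp, fw$logits, labels[s])
        lc_sum <- lc_sum + ad_value(ls)
        if (use_domain) {
          ld <- ad_crossent(tp, fw$dlogits, domains[s])
          ld_sum <- ld_sum + ad_value(ld)
          ls <- ad_add(tp, ls, ld)
        }
        loss <- if (is.null(loss)) ls else ad_add(tp, loss, ls)
      }
      loss <- ad_mul(tp, loss, 1 / length(bidx))
      ad_backward(tp, loss)
      grads <- lapply(pn, function(nd) nd$g)
      state <- adam_step(state, grads, lr)
      nb <- nb + 1L
    }
    model$params <- state$params
    row <- data.frame(epoch = ep, lr = lr, lambda = lam,
                      Lclass = lc_sum / n,
                      Ldomain = if (use_domain) ld_sum / n else NA_real_,
                      val_accuracy = NA_real_, val_macro_f1 = NA_real_,
                      val_kappa = NA_real_)
    if (!is.null(val)) {
      pr <- predict(model, val, normalize = FALSE)
      rep <- metrics_report(val$labels, pr$label)
      row$val_accuracy <- rep$accuracy
      row$val_macro_f1 <- rep$macro_f1
      row$val_kappa <- rep$kappa
      if (rep$macro_f1 > best$f1)
        best <- list(f1 = rep$macro_f1, params = model$params)
    }
    hist[[ep]] <- row
    if (config$verbose)
      message(sprintf("epoch %3d  lr %.2e  Lclass %.4f  Ldomain %s%s",
                      ep, lr, row$Lclass,
                      ifelse(use_domain, sprintf("%.4f", row$Ldomain), "-"),
                      ifelse(is.null(val), "",
                             sprintf("  valF1 %.3f", row$val_macro_f1))))
  }
  if (!is.null(best$params)) model$params <- best$params
  model$history <- do.call(rbind, hist)
  model$domain_levels <- domain_levels
  model
}

stratified_order <- function(labels) {
  perm <- sample(seq_along(labels))
  by_class <- split(perm, labels[perm])
  # interleave classes so every batch sees the minority stages
  mx <- max(vapply(by_class, length, 0L))
  out <- integer(0)
  for (i in seq_len(mx))
    for (cl in by_class) if (i <= length(cl)) out <- c(out, cl[i])
  out
}

#' Subject-discriminator accuracy on a dataset
#'
#' Fraction of epochs whose subject the adversarial head identifies
#' correctly; chance level is 1 / n_subjects. Used to quantify how much
#' subject information survives in the final embedding.
#'
#' @param model a trained `sleepgcn_model` (with `domain_levels`).
#' @param dataset a `psg_dataset` whose subjects are the training subjects.
#' @export
discriminator_accuracy <- function(model, dataset) {
  if (model$n_domains < 2L) stop("model has no discriminator")
  cfg <- model$config
  dataset <- zscore_normalize(dataset)
  inputs <- precompute_inputs(dataset, cfg)
  truth <- match(dataset$subject_id, model$domain_levels)
  hit <- 0L
  for (e in seq_along(inputs)) {
    smp <- inputs[[e]]
    smp$im2col <- sample_im2col(dataset$signals[, , e], cfg)
    fw <- forward_sample(NULL, model$params, smp, cfg, lambda = 0,
                         with_domain = TRUE)
    hit <- hit + (which.max(ad_value(fw$dlogits)) == truth[e])
  }
  hit / length(inputs)
}
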
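#' Reward configuration
#'
#' Per-inquiry rewards. The *priori* reward uses the training-set
#' disease-symptom co-occurrence matrix: asking a symptom that co-occurs
#' with the episode's gold disease earns `priori_hit`, otherwise
#' `priori_miss` — it steers the agent away from unrelated symptoms. The
#' *ground* reward checks the record itself: a queried symptom that is
#' truly among the implicit symptoms earns `ground_hit`, otherwise
#' `ground_miss` — it drives symptom recall. Each action's reward is the
#' sum of the two.
#'
#' @param priori_hit,priori_miss,ground_hit,ground_miss Reward values
#'   (defaults +1, -1, +2.5, -0.5).
#' @return An object of class `reward_config`.
#' @export
reward_config <- function(priori_hit = 1, priori_miss = -1,
                          ground_hit = 2.5, ground_miss = -0.5) {
  vals <- c(priori_hit = priori_hit, priori_miss = priori_miss,
            ground_hit = ground_hit, ground_miss = ground_miss)
  if (any(!is.finite(vals))) stop("reward values must be finite")
  structure(as.list(vals), class = "reward_config")
}

#' Priori reward for one inquiry
#'
#' @param cooc A `cooccur_matrices` object built from the training split.
#' @param d Gold disease id of the episode (training-time only — the label
#'   is unavailable at inference).
#' @param s Queried symptom id.
#' @param cfg A [reward_config()].
#' @param min_count Co-occurrence count needed for a hit (default 1, i.e.
#'   any co-occurrence "exceeding zero").
#' @return `priori_hit` or `priori_miss`.
#' @export
priori_reward <- function(cooc, d, s, cfg = reward_config(),
                          min_count = 1L) {
  if (cooc$ds[d + 1L, s - N_SPECIAL + 1L] >= min_count) cfg$priori_hit
  else cfg$priori_miss
}

#' Ground reward for one inquiry
#'
#' @param rec The episode's [mcr_record()].
#' @param s Queried symptom id.
#' @param cfg A [reward_config()].
#' @return `ground_hit` if `s` is among the record's implicit symptoms,
#'   else `ground_miss`.
#' @export
ground_reward <- function(rec, s, cfg = reward_config()) {
  if (s %in% rec$implicit$symptom) cfg$ground_hit else cfg$ground_miss
}

#' Per-step rewards of a trajectory
#'
#' @param traj A `trajectory` from [decode_rollout()].
#' @param rec The episode's record.
#' @param cooc Training-set `cooccur_matrices`.
#' @param cfg A [reward_config()].
#' @param min_count Passed to [priori_reward()].
#' @return Data frame with columns `symptom`, `priori`, `ground`, `total`;
#'   attribute `"R"` holds the episode return (the sum of `total`).
#' @export
trajectory_rewards <- function(traj, rec, cooc, cfg = reward_config(),
                               min_count = 1L) {
  pr <- vapply(traj$asked, function(s)
    priori_reward(cooc, rec$disease, s, cfg, min_count), 0)
  gr <- vapply(traj$asked, function(s) ground_reward(rec, s, cfg), 0)
  out <- data.frame(symptom = traj$asked, priori = pr, ground = gr,
                    total = pr + gr)
  attr(out, "R") <- sum(out$total)
  out
}

# Shared core: teacher-forced cross-entropy over chosen positions of a
# decoder sequence, each step weighted, with per-step action masks.
# Returns the summed weighted NLL and accumulates gradients into `g`
# (if non-NULL).
dec_weighted_nll <- function(model, ids, attrs, pred_pos, targets, masks,
                             weights, g = NULL, dropout = 0) {
  fwd <- dec_forward(model, ids, attrs, dropout = dropout)
  loss <- 0
  dLogits <- if (!is.null(g)) matrix(0, length(ids), model$cfg$n_sym)
  for (t in seq_along(pred_pos)) {
    p <- masked_softmax(fwd$logits[pred_pos[t], ], masks[[t]])
    a <- targets[t] - N_SPECIAL + 1L
    loss <- loss + weights[t] * -log(p[a])
    if (!is.null(g)) {
      drow <- weights[t] * p
      drow[a] <- drow[a] - weights[t]
      dLogits[pred_pos[t], ] <- dLogits[pred_pos[t], ] + drow
    }
  }
  if (!is.null(g)) dec_backward(model, fwd, dLogits, g)
  loss
}

#' Maximum-likelihood pre-training loss for one record
#'
#' Teacher-forced negative log-likelihood of the record's implicit symptom
#' sequence (in recorded order) given BOS + the explicit prefix, under the
#' same action mask used at decoding time (no symptom can repeat), with
#' ground-truth attributes fed at the next input step. The loss is the sum
#' over implicit targets, so it is sensitive to target order.
#'
#' @param model A [dx_model()].
#' @param rec An [mcr_record()] with at least one implicit symptom.
#' @return Scalar NLL.
#' @export
mle_pretrain_loss <- function(model, rec) {
  parts <- mle_parts(rec)
  if (is.null(parts)) stop("record has no implicit symptoms; skip it")
  dec_weighted_nll(model, parts$ids, parts$attrs, parts$pred_pos,
                   parts$targets, parts$masks,
                   rep(1, length(parts$targets)))
}

mle_parts <- function(rec, shuffle_targets = FALSE) {
  m <- nrow(rec$implicit)
  if (m == 0L) return(NULL)
  imp <- rec$implicit
  if (shuffle_targets) imp <- imp[sample.int(m), , drop = FALSE]
  ids <- c(SYM_BOS, rec$explicit$symptom, imp$symptom)
  attrs <- c(ATTR[["PAD"]], rec$explicit$attribute, imp$attribute)
  k <- nrow(rec$explicit)
  pred_pos <- k + seq_len(m)          # prefix lengths before each target
  targets <- imp$symptom
  masks <- lapply(seq_len(m), function(t)
    c(rec$explicit$symptom, imp$symptom[seq_len(t - 1L)]))
  list(ids = ids, attrs = attrs, pred_pos = pred_pos, targets = targets,
       masks = masks)
}

#' REINFORCE surrogate loss and gradients for one sampled trajectory
#'
#' Single-sample score-function estimator: each action's log-probability
#' is weighted by the episode return `R` (no baseline, no discounting),
#' so the surrogate's gradient is `-R * sum_t grad log p(a_t | history)`
#' — an unbiased estimate of the gradient of the negative expected
#' return. Rewards are constants with respect to the parameters.
#' `per_step = "reward_to_go"` instead weights step `t` by the return
#' from `t` onward.
#'
#' @param model A [dx_model()].
#' @param traj A *sampling-mode* `trajectory` (a greedy trajectory is
#'   refused: its actions are not draws from the policy, so the estimator
#'   would be biased).
#' @param rewards Output of [trajectory_rewards()] for `traj`.
#' @param g Optional gradient accumulator (see [new_grads()]); when
#'   supplied, gradients are added into it.
#' @param per_step Credit assignment: full-episode return (default) or
#'   reward-to-go.
#' @return The scalar surrogate loss.
#' @export
reinforce_loss <- function(model, traj, rewards, g = NULL,
                           per_step = c("episode", "reward_to_go")) {
  per_step <- match.arg(per_step)
  if (traj$mode != "sampling")
    stop("REINFORCE requires a sampled trajectory")
  if (length(traj$asked) == 0L) return(0)
  w <- if (per_step == "episode") rep(attr(rewards, "R"),
                                      length(traj$asked))
    else rev(cumsum(rev(rewards$total)))
  dec_weighted_nll(model, traj$seq_ids, traj$seq_attrs, traj$pred_pos,
                   traj$asked, traj$masks, w, g = g)
}

#' Gradient accumulator
#'
#' Fresh container that [reinforce_loss()], and the training loops,
#' accumulate parameter gradients into (an environment keyed like the
#' model's parameter store).
#'
#' @return An empty gradient environment.
#' @export
new_grads_env <- function() new_grads()

#' Maximum-likelihood pre-training loop
#'
#' Adam on the mean [mle_pretrain_loss()] over minibatches; records with
#' zero implicit symptoms are skipped (their loss is undefined).
#'
#' @param model A [dx_model()] (updated in place — its parameter store is
#'   an environment).
#' @param ds Training [mcr_dataset()].
#' @param epochs Passes over the data.
#' @param lr Learning rate (default 3e-4).
#' @param batch_size Records per optimizer step.
#' @param dropout Dropout probability (defaults to the model's).
#' @param shuffle_targets Re-shuffle implicit target order each epoch.
#' @param seed Seed for batch order/dropout/shuffling.
#' @param verbose Print per-epoch mean loss.
#' @return Invisibly, numeric vector of per-epoch mean NLL per record.
#' @export
pretrain <- function(model, ds, epochs = 3L, lr = 3e-4, batch_size = 32L,
                     dropout = model$cfg$dropout, shuffle_targets = FALSE,
                     seed = 1L, verbose = FALSE) {
  usable <- Filter(function(r) nrow(r$implicit) > 0L, ds$records)
  if (length(usable) == 0L) stop("no records with implicit symptoms")
  history <- numeric(epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(usable))
      total <- 0
      for (start in seq(1L, length(usable), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(usable))]
        g <- new_grads()
        for (i in idx) {
          parts <- mle_parts(usable[[i]], shuffle_targets)
          total <- total +
            dec_weighted_nll(model, parts$ids, parts$attrs,
                             parts$pred_pos, parts$targets, parts$masks,
                             rep(1, length(parts$targets)), g = g,
                             dropout = dropout)
        }
        scale_grads(g, 1 / length(idx))
        adam_step(model, g, lr)
      }
      history[ep] <- total / length(usable)
      if (verbose)
        message(sprintf("pretrain epoch %d: mean NLL %.4f", ep,
                        history[ep]))
    }
  })
  invisible(history)
}

#' One joint policy-gradient + cross-entropy training step
#'
#' For each record in the batch: (i) roll out a *sampled* trajectory of up
#' to `t_train` inquiries and accumulate the REINFORCE gradient of its
#' priori+ground return; (ii) roll out a *greedy* trajectory against the
#' same simulator and feed explicit + greedily collected POS/NEG pairs to
#' the encoder, accumulating the cross-entropy gradient against the gold
#' disease. One Adam step is taken on the summed loss, which updates both
#' submodels and the shared embedding tables.
#'
#' @param model A [dx_model()].
#' @param records List of [mcr_record()]s (the batch).
#' @param cooc Training-set `cooccur_matrices` (priori reward oracle).
#' @param lr Learning rate (default 1e-4).
#' @param t_train Rollout turn budget (default 40).
#' @param rcfg A [reward_config()].
#' @param per_step Credit assignment, see [reinforce_loss()].
#' @return List with `mean_return`, `mean_rl_loss`, `mean_ce` for the
#'   batch.
#' @export
joint_train_step <- function(model, records, cooc, lr = 1e-4,
                             t_train = 40L, rcfg = reward_config(),
                             per_step = "episode") {
  g <- new_grads()
  tot_R <- 0; tot_rl <- 0; tot_ce <- 0
  for (rec in records) {
    traj <- decode_rollout(model, rec, t_train, mode = "sampling")
    rew <- trajectory_rewards(traj, rec, cooc, rcfg)
    tot_R <- tot_R + attr(rew, "R")
    tot_rl <- tot_rl + reinforce_loss(model, traj, rew, g = g,
                                      per_step = per_step)
    gre <- decode_rollout(model, rec, t_train, mode = "greedy")
    keep <- gre$responses != ATTR[["UNK"]]
    known <- rbind(rec$explicit,
                   pair_frame(gre$asked[keep], gre$responses[keep]))
    ord <- order(known$symptom, known$attribute)
    fwd <- enc_forward(model, known$symptom[ord], known$attribute[ord])
    p <- softmax_vec(fwd$logits)
    tot_ce <- tot_ce - log(p[rec$disease + 1L])
    dLog <- p
    dLog[rec$disease + 1L] <- dLog[rec$disease + 1L] - 1
    enc_backward(model, fwd, dLog, g)
  }
  n <- length(records)
  scale_grads(g, 1 / n)
  adam_step(model, g, lr)
  list(mean_return = tot_R / n, mean_rl_loss = tot_rl / n,
       mean_ce = tot_ce / n)
}

#' Joint training loop
#'
#' Runs [joint_train_step()] for `steps` minibatches sampled from the
#' training split, optionally tracking dev-split diagnostic accuracy for
#' early stopping.
#'
#' @param model A [dx_model()].
#' @param ds Training [mcr_dataset()].
#' @param cooc Training-set `cooccur_matrices`.
#' @param steps Number of optimizer steps.
#' @param batch_size Records per step (default 32).
#' @param lr Learning rate (default 1e-4).
#' @param t_train Rollout budget per episode (default 40).
#' @param rcfg A [reward_config()].
#' @param dev Optional dev [mcr_dataset()] for early stopping.
#' @param crit [stopping_criterion()] used for dev evaluation.
#' @param eval_every Steps between dev evaluations.
#' @param patience Dev evaluations without improvement before stopping.
#' @param seed Seed controlling batch sampling and rollouts.
#' @param verbose Print progress.
#' @return Invisibly, data frame of per-step batch metrics.
#' @export
train_joint <- function(model, ds, cooc, steps = 200L, batch_size = 32L,
                        lr = 1e-4, t_train = 40L, rcfg = reward_config(),
                        dev = NULL, crit = stopping_criterion(),
                        eval_every = 50L, patience = 3L, seed = 1L,
                        verbose = FALSE) {
  hist <- vector("list", steps)
  best_acc <- -Inf; bad <- 0L
  withr::with_seed(seed, {
    for (st in seq_len(steps)) {
      idx <- sample.int(length(ds$records), batch_size, replace = TRUE)
      m <- joint_train_step(model, ds$records[idx], cooc, lr = lr,
                            t_train = t_train, rcfg = rcfg)
      hist[[st]] <- data.frame(step = st, mean_return = m$mean_return,
                               mean_rl_loss = m$mean_rl_loss,
                               mean_ce = m$mean_ce)
      if (verbose && st %% 10L == 0L)
        message(sprintf("step %d: return %.2f, CE %.3f", st,
                        m$mean_return, m$mean_ce))
      if (!is.null(dev) && st %% eval_every == 0L) {
        acc <- run_inference(model, dev, crit)$metrics$dx_acc
        if (acc > best_acc) { best_acc <- acc; bad <- 0L }
        else bad <- bad + 1L
        if (verbose) message(sprintf("  dev DX-Acc %.3f", acc))
        if (bad >= patience) break
      }
    }
  })
  invisible(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
}
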
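#' Construct a decoupled inquiry/diagnosis model
#'
#' One object holds both submodels and their *shared* symptom and
#' attribute embedding tables (stored in a single mutable parameter
#' environment, so a gradient step on either submodel is visible to the
#' other):
#'
#' * the **inquiry decoder** — a unidirectional (causally masked)
#'   multi-head self-attention stack over the symptom/attribute history
#'   with sinusoidal position encodings, producing a next-symptom
#'   distribution;
#' * the **diagnosis encoder** — a shallower bidirectional stack without
#'   position encodings, mean-pooled and linearly mapped to a disease
#'   distribution, hence exactly order-invariant in its input pairs.
#'
#' @param sym_vocab A [symptom_vocabulary()].
#' @param dis_vocab A [disease_vocabulary()].
#' @param hidden Embedding/hidden width (default 128; must be divisible by
#'   `heads` and even).
#' @param ff Position-wise feed-forward width (default `2 * hidden`).
#' @param dec_layers Decoder depth (default 4).
#' @param enc_layers Encoder depth (default 1; must be `< dec_layers`).
#' @param heads Attention heads (default 8).
#' @param dropout Dropout probability used during training passes.
#' @param seed Seed for parameter initialization.
#' @return An object of class `dx_model`.
#' @export
dx_model <- function(sym_vocab, dis_vocab, hidden = 128L,
                     ff = 2L * hidden, dec_layers = 4L, enc_layers = 1L,
                     heads = 8L, dropout = 0.1, seed = 1L) {
  if (hidden %% heads != 0L) stop("hidden must be divisible by heads")
  if (hidden %% 2L != 0L) stop("hidden must be even")
  if (enc_layers >= dec_layers)
    stop("the encoder must be shallower than the decoder")
  n_sym <- vocab_size(sym_vocab)
  n_dis <- vocab_size(dis_vocab)
  pe <- new.env(parent = emptyenv())
  withr::with_seed(seed, {
    pe$E_sym <- rnorm_mat(n_sym + N_SPECIAL, hidden)
    pe$E_attr <- rnorm_mat(length(ATTR), hidden)
    for (l in seq_len(dec_layers))
      init_block_params(pe, paste0("dec", l), hidden, ff)
    for (l in seq_len(enc_layers))
      init_block_params(pe, paste0("enc", l), hidden, ff)
    pe$out.W <- rnorm_mat(hidden, n_sym)
    pe$out.b <- numeric(n_sym)
    pe$dis.W <- rnorm_mat(hidden, n_dis)
    pe$dis.b <- numeric(n_dis)
  })
  structure(
    list(cfg = list(hidden = as.integer(hidden), ff = as.integer(ff),
                    dec_layers = as.integer(dec_layers),
                    enc_layers = as.integer(enc_layers),
                    heads = as.integer(heads), dropout = dropout,
                    n_sym = n_sym, n_dis = n_dis, seed = as.integer(seed)),
         params = pe, opt = new.env(parent = emptyenv()),
         sym_vocab = sym_vocab, dis_vocab = dis_vocab),
    class = "dx_model")
}

#' @export
print.dx_model <- function(x, ...) {
  n_par <- sum(vapply(ls(x$params), function(nm) length(x$params[[nm]]), 0))
  cat(sprintf(
    paste0("dx_model: %d-layer decoder / %d-layer encoder, hidden %d,",
           " %d heads\n  %d symptoms, %d diseases, %s parameters",
           " (embedding tables shared)\n"),
    x$cfg$dec_layers, x$cfg$enc_layers, x$cfg$hidden, x$cfg$heads,
    x$cfg$n_sym, x$cfg$n_dis, format(n_par, big.mark = ",")))
  invisible(x)
}

check_ids <- function(model, ids, attrs) {
  if (length(ids) != length(attrs)) stop("ids/attrs length mismatch")
  if (any(ids < 0L | ids >= model$cfg$n_sym + N_SPECIAL))
    stop("symptom id out of range")
  if (any(!attrs %in% ATTR)) stop("attribute code out of range")
}

#' Dense input representation of a symptom/attribute sequence
#'
#' Each element is the sum of its symptom embedding, attribute embedding
#' and (for the decoder) the fixed sinusoidal position encoding at its
#' position. The embedding tables are the ones shared with the encoder.
#'
#' @param model A [dx_model()].
#' @param ids Integer symptom-token ids (BOS-prefixed for the decoder).
#' @param attrs Parallel integer attribute codes.
#' @param positions Add sinusoidal position encodings (decoder: `TRUE`;
#'   encoder: `FALSE`).
#' @return `length(ids) x hidden` matrix.
#' @export
embed_input <- function(model, ids, attrs, positions = TRUE) {
  check_ids(model, ids, attrs)
  pe <- model$params
  X <- pe$E_sym[ids + 1L, , drop = FALSE] +
    pe$E_attr[attrs + 1L, , drop = FALSE]
  if (positions) X <- X + sinusoidal_encoding(length(ids), model$cfg$hidden)
  X
}

dec_forward <- function(model, ids, attrs, dropout = 0) {
  X <- embed_input(model, ids, attrs, positions = TRUE)
  caches <- vector("list", model$cfg$dec_layers)
  for (l in seq_len(model$cfg$dec_layers)) {
    caches[[l]] <- block_forward(model$params, paste0("dec", l), X,
                                 causal = TRUE, nh = model$cfg$heads,
                                 dropout = dropout)
    X <- caches[[l]]$Y
  }
  logits <- add_bias(X %*% model$params$out.W, model$params$out.b)
  list(logits = logits, H = X, caches = caches, ids = ids, attrs = attrs)
}

dec_backward <- function(model, fwd, dLogits, g) {
  pe <- model$params
  acc(g, "out.W", t(fwd$H) %*% dLogits)
  acc(g, "out.b", colSums(dLogits))
  dX <- dLogits %*% t(pe$out.W)
  for (l in rev(seq_len(model$cfg$dec_layers)))
    dX <- block_backward(pe, paste0("dec", l), fwd$caches[[l]], dX,
                         causal = TRUE, nh = model$cfg$heads, g)
  embed_backward(model, fwd$ids, fwd$attrs, dX, g)
}

enc_forward <- function(model, ids, attrs, dropout = 0) {
  X <- embed_input(model, ids, attrs, positions = FALSE)
  caches <- vector("list", model$cfg$enc_layers)
  for (l in seq_len(model$cfg$enc_layers)) {
    caches[[l]] <- block_forward(model$params, paste0("enc", l), X,
                                 causal = FALSE, nh = model$cfg$heads,
                                 dropout = dropout)
    X <- caches[[l]]$Y
  }
  pooled <- colMeans(X)
  logits <- as.numeric(pooled %*% model$params$dis.W) + model$params$dis.b
  list(logits = logits, pooled = pooled, H = X, caches = caches,
       ids = ids, attrs = attrs)
}

enc_backward <- function(model, fwd, dLogits, g) {
  pe <- model$params
  acc(g, "dis.W", outer(fwd$pooled, dLogits))
  acc(g, "dis.b", dLogits)
  dPooled <- as.numeric(pe$dis.W %*% dLogits)
  L <- nrow(fwd$H)
  dX <- matrix(dPooled / L, L, model$cfg$hidden, byrow = TRUE)
  for (l in rev(seq_len(model$cfg$enc_layers)))
    dX <- block_backward(pe, paste0("enc", l), fwd$caches[[l]], dX,
                         causal = FALSE, nh = model$cfg$heads, g)
  embed_backward(model, fwd$ids, fwd$attrs, dX, g)
}

embed_backward <- function(model, ids, attrs, dX, g) {
  dEs <- matrix(0, model$cfg$n_sym + N_SPECIAL, model$cfg$hidden)
  dEa <- matrix(0, length(ATTR), model$cfg$hidden)
  for (i in seq_along(ids)) {
    dEs[ids[i] + 1L, ] <- dEs[ids[i] + 1L, ] + dX[i, ]
    dEa[attrs[i] + 1L, ] <- dEa[attrs[i] + 1L, ] + dX[i, ]
  }
  acc(g, "E_sym", dEs)
  acc(g, "E_attr", dEa)
  invisible(g)
}

masked_softmax <- function(logits_row, mask_ids) {
  z <- logits_row
  if (length(mask_ids))
    z[mask_ids - N_SPECIAL + 1L] <- -Inf
  if (all(is.infinite(z))) stop("all symptoms masked")
  p <- softmax_vec(z)
  p[is.nan(p)] <- 0
  p
}

#' Next-symptom distribution of the inquiry decoder
#'
#' Probability vector over the real symptom vocabulary given the
#' BOS-prefixed symptom/attribute history, with the action mask applied:
#' masked symptoms (anything already asked or known) get probability
#' exactly 0 and the rest renormalize. Causality guarantees the result
#' depends only on the history supplied.
#'
#' @param model A [dx_model()].
#' @param ids,attrs The history (see [embed_input()]).
#' @param mask_ids Integer symptom ids forbidden as next actions; must
#'   cover every real symptom already in `ids`.
#' @return Numeric vector of length `n_symptoms`, named by symptom, summing
#'   to 1.
#' @export
next_symptom_distribution <- function(model, ids, attrs,
                                      mask_ids = integer()) {
  real <- ids[ids >= N_SPECIAL]
  if (!all(real %in% mask_ids))
    stop("mask must include every symptom already in the sequence")
  fwd <- dec_forward(model, ids, attrs)
  p <- masked_softmax(fwd$logits[length(ids), ], mask_ids)
  stats::setNames(p, model$sym_vocab$symptoms)
}

#' Roll out the inquiry policy against a patient simulator
#'
#' Starting from BOS + the record's explicit pairs, repeatedly pick the
#' next symptom (argmax for `"greedy"`, a draw from the masked
#' distribution for `"sampling"`), query the simulator, and append the
#' answered pair to the conditioning history (UNK answers included by
#' default, since failed queries are information the policy may use;
#' `include_unk = FALSE` ablates this). Stops after `t` turns or when
#' every symptom has been asked.
#'
#' @param model A [dx_model()].
#' @param rec An [mcr_record()].
#' @param t Turn budget (number of inquiries).
#' @param mode `"greedy"` (deterministic) or `"sampling"`.
#' @param seed Optional seed making sampling reproducible.
#' @param include_unk Append UNK-answered pairs to the history.
#' @return An object of class `trajectory`: asked symptoms, responses,
#'   per-step log-probabilities, and the bookkeeping needed to recompute
#'   the policy gradient (final sequence, per-step prediction positions
#'   and masks).
#' @export
decode_rollout <- function(model, rec, t, mode = c("greedy", "sampling"),
                           seed = NULL, include_unk = TRUE) {
  mode <- match.arg(mode)
  if (t < 0L) stop("turn budget must be >= 0")
  run <- function() {
    sim <- patient_simulator(rec)
    ids <- c(SYM_BOS, rec$explicit$symptom)
    attrs <- c(ATTR[["PAD"]], rec$explicit$attribute)
    asked <- integer(); responses <- integer(); logp <- numeric()
    pred_pos <- integer(); masks <- list()
    for (turn in seq_len(t)) {
      mask <- unique(c(ids[ids >= N_SPECIAL], asked))
      if (length(mask) >= model$cfg$n_sym) break
      fwd <- dec_forward(model, ids, attrs)
      p <- masked_softmax(fwd$logits[length(ids), ], mask)
      a_idx <- if (mode == "greedy") which.max(p)
        else sample.int(length(p), 1L, prob = p)
      s <- a_idx + N_SPECIAL - 1L
      resp <- sim_respond(sim, s)
      asked <- c(asked, s); responses <- c(responses, resp)
      logp <- c(logp, log(p[a_idx]))
      pred_pos <- c(pred_pos, length(ids)); masks <- c(masks, list(mask))
      if (include_unk || resp != ATTR[["UNK"]]) {
        ids <- c(ids, s); attrs <- c(attrs, resp)
      }
    }
    structure(
      list(record_id = rec$id, asked = asked, responses = responses,
           logp = logp, seq_ids = ids, seq_attrs = attrs,
           pred_pos = pred_pos, masks = masks, mode = mode),
      class = "trajectory")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory (%s): %d inquiries, %d POS/NEG answers\n",
              x$mode, length(x$asked),
              sum(x$responses != ATTR[["UNK"]])))
  invisible(x)
}

#' Classify the collected symptoms into a disease distribution
#'
#' Filters the supplied pairs to POS/NEG (UNK answers carry no attribute
#' evidence and are dropped), canonicalizes their order (the encoder is
#' order-invariant by construction — no position encodings, mean pooling —
#' and sorting by symptom id makes the invariance hold bitwise), and runs
#' the bidirectional encoder.
#'
#' @param model A [dx_model()].
#' @param known Data frame of (symptom, attribute) pairs.
#' @return Object of class `disease_distribution` with fields `probs`
#'   (named, sums to 1), `predicted` (disease id of the argmax) and
#'   `confidence` (the max probability).
#' @export
diagnose <- function(model, known) {
  keep <- known$attribute %in% c(ATTR[["POS"]], ATTR[["NEG"]])
  known <- known[keep, , drop = FALSE]
  if (nrow(known) == 0L)
    stop("no POS/NEG symptom evidence to diagnose from")
  ord <- order(known$symptom, known$attribute)
  fwd <- enc_forward(model, known$symptom[ord], known$attribute[ord])
  p <- softmax_vec(fwd$logits)
  structure(
    list(probs = stats::setNames(p, model$dis_vocab$diseases),
         predicted = which.max(p) - 1L,
         confidence = max(p)),
    class = "disease_distribution")
}

#' @export
print.disease_distribution <- function(x, ...) {
  cat(sprintf("disease_distribution: predicted id %d (confidence %.3f)\n",
              x$predicted, x$confidence))
  invisible(x)
}

#' Confidence/turn-cap stopping criterion
#'
#' Inquiry stops once the classifier's top-disease probability reaches
#' `epsilon` (inclusive, so `epsilon = 0` means diagnose immediately and
#' `epsilon = 1` requires exact certainty) or `t_max` inquiries have been
#' made.
#'
#' @param epsilon Confidence threshold in `[0, 1]` (default 0.99).
#' @param t_max Turn cap (default 10).
#' @return An object of class `stopping_criterion`.
#' @export
stopping_criterion <- function(epsilon = 0.99, t_max = 10L) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (t_max < 0L) stop("t_max must be >= 0")
  structure(list(epsilon = epsilon, t_max = as.integer(t_max)),
            class = "stopping_criterion")
}

#' Should inquiry stop?
#'
#' @param dist A `disease_distribution`.
#' @param crit A [stopping_criterion()].
#' @param turn Inquiries made so far.
#' @return `TRUE` iff `confidence >= epsilon` or `turn >= t_max`.
#' @export
check_stop <- function(dist, crit, turn) {
  dist$confidence >= crit$epsilon || turn >= crit$t_max
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles both submodels (one file — the embedding tables
#' are shared) plus the vocabularies; loading refuses a checkpoint whose
#' vocabularies disagree with the file's own record of them.
#'
#' @param model A [dx_model()].
#' @param path File path.
#' @return `path` invisibly (`save_model`); a `dx_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  params <- mget(ls(model$params), envir = model$params)
  saveRDS(list(cfg = model$cfg, params = params,
               symptoms = model$sym_vocab$symptoms,
               diseases = model$dis_vocab$diseases),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  model <- dx_model(symptom_vocabulary(x$symptoms),
                    disease_vocabulary(x$diseases),
                    hidden = x$cfg$hidden, ff = x$cfg$ff,
                    dec_layers = x$cfg$dec_layers,
                    enc_layers = x$cfg$enc_layers, heads = x$cfg$heads,
                    dropout = x$cfg$dropout, seed = x$cfg$seed)
  for (nm in names(x$params)) model$params[[nm]] <- x$params[[nm]]
  model
}
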
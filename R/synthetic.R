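#' Configuration of the synthetic consultation-record generator
#'
#' The generator emulates the structure of real structured-consultation
#' corpora: each disease owns a small set of characteristic symptoms that
#' patients report frequently; a large pool of background symptoms appears
#' rarely and independently of the disease; and some characteristic
#' symptoms the patient does *not* have are recorded as negative answers
#' (real dialogues contain NEG answers to plausibly related questions,
#' which carry diagnostic signal). The first `k` mentioned symptoms (in
#' randomized order, `k` truncated-geometric) form the explicit
#' self-report; the rest are implicit.
#'
#' The defaults reproduce the scale of a large real corpus: 10 diseases,
#' 331 symptoms, about 1.7 explicit and 6.6 implicit symptoms per record
#' on average (see [synthetic_expectations()]).
#'
#' @param n_diseases Number of diseases.
#' @param n_symptoms Number of symptoms (must be at least
#'   `n_diseases * char_per_disease`).
#' @param char_per_disease Characteristic symptoms per disease.
#' @param char_overlap Characteristic symptoms shared between adjacent
#'   diseases (0 = disjoint sets). Related diseases in real corpora share
#'   symptoms, which is what makes the explicit-only accuracy bound fall
#'   below the full-evidence bound.
#' @param p_char Probability that a characteristic symptom of the true
#'   disease is present (POS).
#' @param p_background Probability that any non-characteristic symptom is
#'   present (POS); must be below `p_char`.
#' @param p_neg_mention Probability that an absent characteristic symptom
#'   of the true disease is recorded as NEG.
#' @param mean_explicit Target mean of the explicit count `k`;
#'   `k` is geometric with success probability `1 / mean_explicit`,
#'   truncated to `[1, n mentioned]`.
#' @param n_train,n_dev,n_test Records per split.
#' @param seed Integer seed; generation is deterministic given the config.
#' @param max_retries Resampling cap for records with zero mentions.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_diseases = 10L, n_symptoms = 331L,
                             char_per_disease = 12L, char_overlap = 4L,
                             p_char = 0.55, p_background = 0.002,
                             p_neg_mention = 0.2,
                             mean_explicit = 1.7,
                             n_train = 2000L, n_dev = 400L, n_test = 600L,
                             seed = 1L, max_retries = 100L) {
  cfg <- list(n_diseases = as.integer(n_diseases),
              n_symptoms = as.integer(n_symptoms),
              char_per_disease = as.integer(char_per_disease),
              char_overlap = as.integer(char_overlap),
              p_char = p_char, p_background = p_background,
              p_neg_mention = p_neg_mention,
              mean_explicit = mean_explicit,
              n_train = as.integer(n_train), n_dev = as.integer(n_dev),
              n_test = as.integer(n_test),
              seed = as.integer(seed), max_retries = as.integer(max_retries))
  probs <- c(p_char = p_char, p_background = p_background,
             p_neg_mention = p_neg_mention)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_char <= p_background)
    stop("p_char must exceed p_background (diseases must be informative)")
  if (cfg$n_diseases < 1L || cfg$n_symptoms < 1L ||
      cfg$char_per_disease < 1L)
    stop("counts must be positive")
  if (cfg$char_overlap < 0L || cfg$char_overlap >= cfg$char_per_disease)
    stop("char_overlap must lie in [0, char_per_disease)")
  stride <- cfg$char_per_disease - cfg$char_overlap
  if ((cfg$n_diseases - 1L) * stride + cfg$char_per_disease >
      cfg$n_symptoms)
    stop("characteristic sets exceed the symptom vocabulary")
  if (mean_explicit < 1) stop("mean_explicit must be >= 1")
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    paste0("synthetic_config: %d diseases x %d symptoms, %d characteristic",
           " each\n  p_char=%.3g p_background=%.3g p_neg_mention=%.3g",
           " mean_explicit=%.2f seed=%d\n"),
    x$n_diseases, x$n_symptoms, x$char_per_disease, x$p_char,
    x$p_background, x$p_neg_mention, x$mean_explicit, x$seed))
  invisible(x)
}

#' Characteristic symptom sets implied by a config
#'
#' Disease `d` (0-based id) owns a window of `char_per_disease` symptom
#' ids starting at `d * (char_per_disease - char_overlap)`, so adjacent
#' diseases share `char_overlap` symptoms (none when the overlap is 0).
#' Pure function of the config, so the Bayes oracle and ground-truth
#' checks need no side channel.
#'
#' @param cfg A [synthetic_config()].
#' @return List (one per disease) of integer symptom ids.
#' @export
characteristic_sets <- function(cfg) {
  stride <- cfg$char_per_disease - cfg$char_overlap
  lapply(seq_len(cfg$n_diseases), function(d)
    ((d - 1L) * stride + seq_len(cfg$char_per_disease)) +
      N_SPECIAL - 1L)
}

synthetic_vocabs <- function(cfg) {
  list(sym = symptom_vocabulary(sprintf("symptom_%03d",
                                        seq_len(cfg$n_symptoms))),
       dis = disease_vocabulary(sprintf("disease_%02d",
                                        seq_len(cfg$n_diseases))))
}

# Geometric on 1,2,... with success prob p, truncated to [1, m].
rtruncgeom <- function(p, m) {
  if (m == 1L) return(1L)
  w <- (1 - p)^(0:(m - 1L))
  sample.int(m, 1L, prob = w)
}

sample_record <- function(cfg, char_sets, rid) {
  all_syms <- seq_len(cfg$n_symptoms) + N_SPECIAL - 1L
  for (try in seq_len(cfg$max_retries)) {
    d <- sample.int(cfg$n_diseases, 1L) - 1L
    chars <- char_sets[[d + 1L]]
    bg <- setdiff(all_syms, chars)
    pos_char <- chars[stats::runif(length(chars)) < cfg$p_char]
    pos_bg <- bg[stats::runif(length(bg)) < cfg$p_background]
    absent_char <- setdiff(chars, pos_char)
    neg_char <- absent_char[stats::runif(length(absent_char)) <
                              cfg$p_neg_mention]
    syms <- c(pos_char, pos_bg, neg_char)
    if (length(syms) == 0L) next
    attrs <- c(rep(ATTR[["POS"]], length(pos_char) + length(pos_bg)),
               rep(ATTR[["NEG"]], length(neg_char)))
    ord <- sample.int(length(syms))  # order carries no disease signal
    syms <- syms[ord]; attrs <- attrs[ord]
    k <- rtruncgeom(1 / cfg$mean_explicit, length(syms))
    return(mcr_record(rid,
                      pair_frame(syms[seq_len(k)], attrs[seq_len(k)]),
                      if (length(syms) > k)
                        pair_frame(syms[-seq_len(k)], attrs[-seq_len(k)])
                      else pair_frame(),
                      d))
  }
  stop("failed to sample a record with at least one mention; ",
       "raise the presence probabilities or max_retries")
}

#' Generate a synthetic dataset triple
#'
#' Samples train/dev/test splits under the generative model described in
#' [synthetic_config()]. Deterministic given the config (the config's
#' `seed` is used internally and the caller's RNG state is untouched).
#'
#' @param cfg A [synthetic_config()].
#' @return List with elements `train`, `dev`, `test`
#'   (each an [mcr_dataset()]) and `cfg`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  vocabs <- synthetic_vocabs(cfg)
  char_sets <- characteristic_sets(cfg)
  withr::with_seed(cfg$seed, {
    make_split <- function(split, n) {
      recs <- lapply(seq_len(n), function(i)
        sample_record(cfg, char_sets, sprintf("%s-%05d", split, i)))
      mcr_dataset(recs, vocabs$sym, vocabs$dis, split)
    }
    out <- list(train = make_split("train", cfg$n_train),
                dev = make_split("dev", cfg$n_dev),
                test = make_split("test", cfg$n_test),
                cfg = cfg)
  })
  out
}

#' Exact moments of the generator
#'
#' Computes, by exact convolution of the mention-count distribution and
#' enumeration of the truncated-geometric explicit count, the expected
#' numbers of mentioned, explicit and implicit symptoms per record
#' (conditioned on at least one mention, as generated records are). Serves
#' as the closed-form oracle for the generator's empirical means.
#'
#' @param cfg A [synthetic_config()].
#' @return Named numeric vector `mean_mentioned`, `mean_explicit`,
#'   `mean_implicit`.
#' @export
synthetic_expectations <- function(cfg) {
  c <- cfg$char_per_disease
  nb <- cfg$n_symptoms - c
  # P(characteristic mentions = j): POS chars Bin(c, p_char), then NEG
  # mentions Bin(c - pos, p_neg_mention).
  p_mc <- numeric(2L * c + 1L)  # support 0..2c is overgenerous but safe
  for (pos in 0:c) {
    pp <- stats::dbinom(pos, c, cfg$p_char)
    for (neg in 0:(c - pos)) {
      j <- pos + neg
      p_mc[j + 1L] <- p_mc[j + 1L] +
        pp * stats::dbinom(neg, c - pos, cfg$p_neg_mention)
    }
  }
  p_bg <- stats::dbinom(0:nb, nb, cfg$p_background)
  p_m <- rep(0, length(p_mc) + nb)
  for (j in seq_along(p_mc)) {
    if (p_mc[j] == 0) next
    idx <- j + 0:nb
    p_m[idx] <- p_m[idx] + p_mc[j] * p_bg
  }
  # condition on at least one mention (zero-mention records are resampled)
  p_m[1L] <- 0
  p_m <- p_m / sum(p_m)
  m_vals <- seq_along(p_m) - 1L
  pgeom1 <- 1 / cfg$mean_explicit
  e_k_given_m <- vapply(m_vals, function(m) {
    if (m < 1L) return(0)
    w <- (1 - pgeom1)^(0:(m - 1L))
    sum((1:m) * w) / sum(w)
  }, 0)
  mean_m <- sum(m_vals * p_m)
  mean_k <- sum(e_k_given_m * p_m)
  c(mean_mentioned = mean_m, mean_explicit = mean_k,
    mean_implicit = mean_m - mean_k)
}

#' Accuracy of the exact Bayes classifier on a generated dataset
#'
#' Scores each record's full evidence (POS symptoms, NEG mentions and
#' unmentioned symptoms) under the known generative model for every
#' disease and takes the posterior argmax. Because it uses the true
#' generative parameters, its accuracy upper-bounds the expected accuracy
#' of any learned classifier on data from the same config.
#'
#' @param cfg The [synthetic_config()] that generated `ds`.
#' @param ds An [mcr_dataset()] drawn from `cfg`.
#' @return Fraction of records whose posterior argmax equals the label.
#' @export
oracle_bayes_accuracy <- function(cfg, ds) {
  if (vocab_size(ds$sym_vocab) != cfg$n_symptoms ||
      vocab_size(ds$dis_vocab) != cfg$n_diseases)
    stop("config/dataset vocabulary size mismatch")
  char_sets <- characteristic_sets(cfg)
  all_syms <- seq_len(cfg$n_symptoms) + N_SPECIAL - 1L
  # n * log(p), with the 0 * log(0) = 0 convention for impossible-but-absent
  nlp <- function(n, p) if (n == 0L) 0 else n * (if (p > 0) log(p) else -Inf)
  correct <- 0L
  for (rec in ds$records) {
    syms <- record_symptoms(rec)
    attrs <- c(rec$explicit$attribute, rec$implicit$attribute)
    pos <- syms[attrs == ATTR[["POS"]]]
    neg <- syms[attrs == ATTR[["NEG"]]]
    scores <- vapply(seq_len(cfg$n_diseases), function(di) {
      chars <- char_sets[[di]]
      n_pos_char <- sum(pos %in% chars)
      n_pos_bg <- length(pos) - n_pos_char
      n_neg_char <- sum(neg %in% chars)
      n_neg_bg <- length(neg) - n_neg_char
      n_unmen_char <- length(chars) - n_pos_char - n_neg_char
      n_unmen_bg <- (cfg$n_symptoms - length(chars)) -
        n_pos_bg - n_neg_bg
      s <- nlp(n_pos_char, cfg$p_char) +
        nlp(n_neg_char, (1 - cfg$p_char) * cfg$p_neg_mention) +
        nlp(n_unmen_char, (1 - cfg$p_char) * (1 - cfg$p_neg_mention)) +
        nlp(n_pos_bg, cfg$p_background) +
        nlp(n_unmen_bg, 1 - cfg$p_background)
      if (n_neg_bg > 0L) s <- -Inf  # NEG mentions only occur on chars
      s
    }, 0)
    if (which.max(scores) - 1L == rec$disease) correct <- correct + 1L
  }
  correct / length(ds$records)
}
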
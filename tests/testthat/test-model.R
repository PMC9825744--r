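test_that("sinusoidal encoding matches the scalar closed form", {
  h <- 12L
  P <- sinusoidal_encoding(7L, h)
  for (t in 0:6) {
    for (i in 0:(h / 2L - 1L)) {
      expect_equal(P[t + 1L, 2L * i + 1L], sin(t / 10000^(2 * i / h)))
      expect_equal(P[t + 1L, 2L * i + 2L], cos(t / 10000^(2 * i / h)))
    }
  }
})

test_that("input representation is the sum of symptom, attribute and position terms", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  ids <- c(1L, 3L, 5L)
  attrs <- c(ATTR[["PAD"]], ATTR[["POS"]], ATTR[["NEG"]])
  # zeroed tables leave only the position encodings
  m$params$E_sym[] <- 0
  m$params$E_attr[] <- 0
  expect_equal(embed_input(m, ids, attrs),
               sinusoidal_encoding(3L, m$cfg$hidden))
  # restore random tables; swapping two attribute codes changes only
  # those positions' vectors
  m2 <- tiny_model(v)
  X1 <- embed_input(m2, ids, attrs)
  X2 <- embed_input(m2, ids, c(ATTR[["PAD"]], ATTR[["NEG"]],
                               ATTR[["POS"]]))
  expect_identical(X1[1L, ], X2[1L, ])
  expect_false(isTRUE(all.equal(X1[2L, ], X2[2L, ])))
  expect_false(isTRUE(all.equal(X1[3L, ], X2[3L, ])))
  expect_error(embed_input(m2, c(1L, 99L), c(0L, 1L)), "out of range")
})

test_that("next-symptom distribution normalizes over the unmasked set", {
  v <- tiny_vocabs(3L, 2L)
  m <- tiny_model(v)
  ids <- c(1L, 2L); attrs <- c(ATTR[["PAD"]], ATTR[["POS"]])
  p <- next_symptom_distribution(m, ids, attrs, mask_ids = c(2L, 3L))
  expect_equal(sum(p), 1.0)
  expect_equal(unname(p[c("s1", "s2")]), c(0, 0))
  expect_equal(unname(p["s3"]), 1.0)  # point mass
  expect_error(next_symptom_distribution(m, ids, attrs,
                                         mask_ids = 2:4),
               "all symptoms masked")
  expect_error(next_symptom_distribution(m, ids, attrs,
                                         mask_ids = integer()),
               "mask must include")
})

test_that("the decoder is causal: appending future tokens leaves earlier steps unchanged", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  ids <- c(1L, 2L, 4L); attrs <- c(0L, 1L, 2L)
  p_prefix <- next_symptom_distribution(m, ids, attrs,
                                        mask_ids = c(2L, 4L))
  for (extra in list(c(6L, 1L), c(9L, 3L))) {
    ids2 <- c(ids, extra[1L]); attrs2 <- c(attrs, extra[2L])
    fwd <- dxagent:::dec_forward(m, ids2, attrs2)
    p_same <- dxagent:::masked_softmax(fwd$logits[3L, ], c(2L, 4L))
    expect_equal(unname(p_prefix), p_same, tolerance = 1e-12)
  }
})

test_that("greedy decoding is deterministic and sampling reproduces bitwise under a seed", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  rec <- tiny_record(v)
  expect_identical(decode_rollout(m, rec, 0L, "greedy")$asked, integer())
  g1 <- decode_rollout(m, rec, 4L, "greedy")
  g2 <- decode_rollout(m, rec, 4L, "greedy")
  expect_identical(g1$asked, g2$asked)
  s1 <- decode_rollout(m, rec, 4L, "sampling", seed = 11L)
  s2 <- decode_rollout(m, rec, 4L, "sampling", seed = 11L)
  expect_identical(s1$asked, s2$asked)
  expect_identical(s1$logp, s2$logp)
})

test_that("rollouts never repeat a symptom and stop when the vocabulary is exhausted", {
  v <- tiny_vocabs(6L, 2L)
  m <- tiny_model(v)
  rec <- mcr_record("r", pairs_of(2L, ATTR[["POS"]]),
                    pairs_of(4L, ATTR[["POS"]]), 0L)
  tr <- decode_rollout(m, rec, 50L, "sampling", seed = 3L)
  expect_identical(length(tr$asked), 5L)  # 6 symptoms - 1 explicit
  expect_false(anyDuplicated(c(rec$explicit$symptom, tr$asked)) > 0L)
})

test_that("diagnosis is bitwise invariant to input permutation and drops UNK", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  known <- pairs_of(c(2L, 5L, 7L, 3L, 9L),
                    c(ATTR[["POS"]], ATTR[["NEG"]], ATTR[["POS"]],
                      ATTR[["NEG"]], ATTR[["POS"]]))
  d0 <- diagnose(m, known)
  withr::with_seed(4L, {
    for (k in 1:10) {
      dp <- diagnose(m, known[sample.int(nrow(known)), , drop = FALSE])
      expect_identical(dp$probs, d0$probs)
    }
  })
  with_unk <- rbind(known, pairs_of(8L, ATTR[["UNK"]]))
  expect_identical(diagnose(m, with_unk)$probs, d0$probs)
  expect_error(diagnose(m, pairs_of(8L, ATTR[["UNK"]])), "no POS/NEG")
  expect_equal(sum(d0$probs), 1.0)
})

test_that("an untrained zeroed head yields the uniform disease distribution", {
  v <- tiny_vocabs(8L, 4L)
  m <- tiny_model(v)
  m$params$dis.W[] <- 0
  m$params$dis.b[] <- 0
  d <- diagnose(m, pairs_of(c(2L, 3L), rep(ATTR[["POS"]], 2L)))
  expect_equal(unname(d$probs), rep(0.25, 4L))
  expect_equal(d$confidence, 0.25)
})

test_that("stopping criterion fires on confidence or the turn cap", {
  mk <- function(conf) structure(list(confidence = conf),
                                 class = "disease_distribution")
  crit <- stopping_criterion(0.99, 10L)
  expect_true(check_stop(mk(0.995), crit, 3L))
  expect_false(check_stop(mk(0.5), crit, 3L))
  expect_true(check_stop(mk(0.5), crit, 10L))
  expect_true(check_stop(mk(0.1), stopping_criterion(0, 10L), 0L))
  expect_error(stopping_criterion(1.2), "epsilon")
})

test_that("hand-derived gradients match finite differences", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  ids <- c(1L, 3L, 5L, 7L); attrs <- c(0L, 1L, 2L, 1L)
  pred_pos <- c(2L, 4L); targets <- c(5L, 8L)
  masks <- list(3L, c(3L, 5L, 7L))
  w <- c(1, 2.5)
  dec_loss <- function()
    dxagent:::dec_weighted_nll(m, ids, attrs, pred_pos, targets, masks, w)
  g <- dxagent:::new_grads()
  dxagent:::dec_weighted_nll(m, ids, attrs, pred_pos, targets, masks, w,
                             g = g)
  eps <- 1e-5
  withr::with_seed(7L, {
    for (nm in ls(g)) {
      for (rep in 1:2) {
        i <- sample(length(m$params[[nm]]), 1L)
        old <- m$params[[nm]][i]
        m$params[[nm]][i] <- old + eps; lp <- dec_loss()
        m$params[[nm]][i] <- old - eps; lm <- dec_loss()
        m$params[[nm]][i] <- old
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-3)
      }
    }
  })
  # encoder path
  kids <- c(3L, 5L, 8L); kattrs <- c(1L, 2L, 1L)
  enc_loss <- function() {
    fwd <- dxagent:::enc_forward(m, kids, kattrs)
    -log(dxagent:::softmax_vec(fwd$logits)[2L])
  }
  g2 <- dxagent:::new_grads()
  fwd <- dxagent:::enc_forward(m, kids, kattrs)
  p <- dxagent:::softmax_vec(fwd$logits)
  dL <- p; dL[2L] <- dL[2L] - 1
  dxagent:::enc_backward(m, fwd, dL, g2)
  withr::with_seed(8L, {
    for (nm in ls(g2)) {
      i <- sample(length(m$params[[nm]]), 1L)
      old <- m$params[[nm]][i]
      m$params[[nm]][i] <- old + eps; lp <- enc_loss()
      m$params[[nm]][i] <- old - eps; lm <- enc_loss()
      m$params[[nm]][i] <- old
      expect_equal(g2[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-3)
    }
  })
})

test_that("checkpoints round-trip and refuse mismatched vocabularies", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  rec <- tiny_record(v)
  expect_identical(decode_rollout(m, rec, 3L, "greedy")$asked,
                   decode_rollout(m2, rec, 3L, "greedy")$asked)
  expect_identical(m2$params$E_sym, m$params$E_sym)
  other <- generate_dataset(small_config(n_train = 5L, n_dev = 5L,
                                         n_test = 5L))$train
  expect_error(run_inference(m2, other), "vocabulary mismatch")
})
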
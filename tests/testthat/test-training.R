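test_that("priori and ground rewards follow the co-occurrence and implicit rules", {
  fx <- make_reward_fixture()
  rc <- reward_config()
  # counts[d1, s1] = 1 > 0 -> hit; counts[d1, s2] = 0 -> miss
  expect_equal(priori_reward(fx$cooc, 0L, 2L, rc), 1)
  expect_equal(priori_reward(fx$cooc, 0L, 3L, rc), -1)
  expect_equal(priori_reward(fx$cooc, 0L, 2L,
                             reward_config(priori_hit = 2)), 2)
  # raising the minimum count flips a single-co-occurrence hit
  expect_equal(priori_reward(fx$cooc, 0L, 2L, rc, min_count = 2L), -1)
  rec <- fx$ds$records[[1]]
  expect_equal(ground_reward(rec, 4L, rc), 2.5)   # in S_imp
  expect_equal(ground_reward(rec, 6L, rc), 2.5)   # NEG implicit counts
  expect_equal(ground_reward(rec, 7L, rc), -0.5)  # UNK answer
  expect_error(reward_config(ground_hit = Inf), "finite")
})

test_that("trajectory rewards decompose as priori + ground and sum to the return", {
  fx <- make_reward_fixture()
  rec <- fx$ds$records[[1]]
  traj <- structure(
    list(record_id = rec$id, asked = c(4L, 6L, 8L),
         responses = c(ATTR[["POS"]], ATTR[["NEG"]], ATTR[["UNK"]]),
         logp = rep(log(0.2), 3L),
         seq_ids = c(1L, 2L, 4L, 6L, 8L),
         seq_attrs = c(0L, 1L, 1L, 2L, 3L),
         pred_pos = 2:4, masks = list(2L, c(2L, 4L), c(2L, 4L, 6L)),
         mode = "sampling"),
    class = "trajectory")
  rew <- trajectory_rewards(traj, rec, fx$cooc)
  expect_equal(rew$total, rew$priori + rew$ground)
  # two implicit hits (both priori-supported) and one priori-supported
  # ground miss: 2*(1 + 2.5) + (1 - 0.5)
  expect_equal(attr(rew, "R"), 7.5)
})

test_that("teacher-forced NLL is ln(usable vocabulary) at a zeroed output layer", {
  # 42 symptoms, 1 explicit -> 41 usable targets under the action mask
  v <- tiny_vocabs(42L, 2L)
  m <- tiny_model(v)
  m$params$out.W[] <- 0
  m$params$out.b[] <- 0
  rec <- mcr_record("r", pairs_of(2L, ATTR[["POS"]]),
                    pairs_of(10L, ATTR[["POS"]]), 0L)
  expect_equal(mle_pretrain_loss(m, rec), log(41), tolerance = 1e-12)
  # a near-point-mass model drives the loss to zero
  m$params$out.b[10L - 1L] <- 50
  expect_lt(mle_pretrain_loss(m, rec), 1e-6)
  expect_error(mle_pretrain_loss(
    m, mcr_record("e", pairs_of(2L, ATTR[["POS"]]), disease = 0L)),
    "no implicit")
})

test_that("the pre-training loss is sensitive to implicit target order", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  r1 <- mcr_record("r", pairs_of(2L, ATTR[["POS"]]),
                   pairs_of(c(4L, 7L), c(ATTR[["POS"]], ATTR[["NEG"]])),
                   0L)
  r2 <- mcr_record("r", pairs_of(2L, ATTR[["POS"]]),
                   pairs_of(c(7L, 4L), c(ATTR[["NEG"]], ATTR[["POS"]])),
                   0L)
  expect_false(isTRUE(all.equal(mle_pretrain_loss(m, r1),
                                mle_pretrain_loss(m, r2))))
})

test_that("REINFORCE surrogate: zero return gives zero gradient, and rewards scale linearly", {
  v <- tiny_vocabs()
  m <- tiny_model(v)
  rec <- tiny_record(v)
  traj <- decode_rollout(m, rec, 3L, "sampling", seed = 2L)
  rew0 <- data.frame(symptom = traj$asked, priori = 0, ground = 0,
                     total = rep(0, length(traj$asked)))
  attr(rew0, "R") <- 0
  g0 <- new_grads_env()
  expect_equal(reinforce_loss(m, traj, rew0, g = g0), 0)
  expect_true(all(abs(dxagent:::grad_vector(g0)) == 0))
  rew1 <- rew0; rew1$total <- rep(1, nrow(rew1)); attr(rew1, "R") <- 3
  rew2 <- rew0; rew2$total <- rep(2, nrow(rew2)); attr(rew2, "R") <- 6
  g1 <- new_grads_env(); g2 <- new_grads_env()
  l1 <- reinforce_loss(m, traj, rew1, g = g1)
  l2 <- reinforce_loss(m, traj, rew2, g = g2)
  expect_equal(l2, 2 * l1)
  expect_equal(dxagent:::grad_vector(g2), 2 * dxagent:::grad_vector(g1))
  greedy <- decode_rollout(m, rec, 3L, "greedy")
  expect_error(reinforce_loss(m, greedy, rew1), "sampled")
})

test_that("a zero learning rate leaves every parameter unchanged", {
  fx <- make_reward_fixture()
  m <- tiny_model(fx$v)
  before <- lapply(mget(ls(m$params), envir = m$params), identity)
  joint_train_step(m, fx$ds$records, fx$cooc, lr = 0, t_train = 3L)
  for (nm in names(before))
    expect_identical(m$params[[nm]], before[[nm]])
})

test_that("joint training reduces both loss terms on separable data", {
  cfg <- degenerate_config(n_train = 120L, n_dev = 10L, n_test = 10L)
  dat <- generate_dataset(cfg)
  m <- dx_model(dat$train$sym_vocab, dat$train$dis_vocab, hidden = 16L,
                ff = 32L, dec_layers = 2L, enc_layers = 1L, heads = 2L,
                dropout = 0, seed = 4L)
  pretrain(m, dat$train, epochs = 2L, lr = 2e-3, batch_size = 16L,
           seed = 5L)
  cooc <- build_cooccur(dat$train)
  hist <- train_joint(m, dat$train, cooc, steps = 60L, batch_size = 8L,
                      lr = 1e-3, t_train = 6L, seed = 6L)
  first <- utils::head(hist, 10L); last <- utils::tail(hist, 10L)
  expect_gt(mean(last$mean_return), mean(first$mean_return))
  expect_lt(mean(last$mean_ce), mean(first$mean_ce))
})

test_that("pre-training beats the unigram baseline on held-out records", {
  cfg <- degenerate_config(n_train = 200L, n_dev = 60L, n_test = 10L)
  dat <- generate_dataset(cfg)
  m <- dx_model(dat$train$sym_vocab, dat$train$dis_vocab, hidden = 16L,
                ff = 32L, dec_layers = 2L, enc_layers = 1L, heads = 2L,
                dropout = 0, seed = 7L)
  pretrain(m, dat$train, epochs = 8L, lr = 2e-3, batch_size = 16L,
           seed = 8L)
  # unigram baseline: implicit-symptom marginal from the training split
  counts <- numeric(cfg$n_symptoms)
  for (rec in dat$train$records) {
    cols <- rec$implicit$symptom - 1L
    counts[cols] <- counts[cols] + 1L
  }
  p_uni <- (counts + 1) / sum(counts + 1)
  nll_model <- 0; nll_uni <- 0; n_tok <- 0L
  for (rec in dat$dev$records) {
    if (nrow(rec$implicit) == 0L) next
    nll_model <- nll_model + mle_pretrain_loss(m, rec)
    nll_uni <- nll_uni - sum(log(p_uni[rec$implicit$symptom - 1L]))
    n_tok <- n_tok + nrow(rec$implicit)
  }
  expect_lt(nll_model / n_tok, nll_uni / n_tok)
})
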
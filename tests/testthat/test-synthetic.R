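test_that("config validation enforces informativeness and geometry", {
  expect_error(synthetic_config(p_char = 0.1, p_background = 0.2),
               "exceed")
  expect_error(synthetic_config(n_diseases = 10, n_symptoms = 20,
                                char_per_disease = 5, char_overlap = 0),
               "exceed the symptom vocabulary")
  expect_error(synthetic_config(char_overlap = 12), "char_overlap")
  expect_error(synthetic_config(mean_explicit = 0.5), "mean_explicit")
})

test_that("degenerate config yields exactly the characteristic POS set", {
  cfg <- degenerate_config(n_train = 60L, n_dev = 5L, n_test = 5L)
  dat <- generate_dataset(cfg)
  chars <- characteristic_sets(cfg)
  for (rec in dat$train$records) {
    expect_setequal(record_symptoms(rec), chars[[rec$disease + 1L]])
    expect_true(all(c(rec$explicit$attribute, rec$implicit$attribute) ==
                      ATTR[["POS"]]))
  }
})

test_that("generation is deterministic given the config seed", {
  cfg <- small_config(n_train = 40L, n_dev = 5L, n_test = 5L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$train$records, d2$train$records)
  expect_identical(d1$test$records, d2$test$records)
  d3 <- generate_dataset(small_config(seed = 99L, n_train = 40L,
                                      n_dev = 5L, n_test = 5L))
  expect_false(identical(d1$train$records, d3$train$records))
})

test_that("generated records satisfy every dataset invariant", {
  dat <- generate_dataset(small_config(n_train = 150L, n_dev = 10L,
                                       n_test = 10L))
  for (split in c("train", "dev", "test")) {
    ds <- dat[[split]]
    ids <- vapply(ds$records, function(r) r$id, "")
    expect_false(anyDuplicated(ids) > 0L)
    for (rec in ds$records) {
      syms <- record_symptoms(rec)
      expect_false(anyDuplicated(syms) > 0L)
      expect_gt(nrow(rec$explicit), 0L)
    }
  }
})

test_that("empirical implicit mean matches the closed-form expectation", {
  # a config whose exact implicit mean is ~5.5, checked by direct counting
  cfg <- synthetic_config(n_diseases = 6L, n_symptoms = 80L,
                          char_per_disease = 10L, char_overlap = 2L,
                          p_char = 0.55, p_background = 0.01,
                          p_neg_mention = 0.2, mean_explicit = 1.6,
                          n_train = 2000L, n_dev = 10L, n_test = 10L,
                          seed = 31L)
  ex <- synthetic_expectations(cfg)
  expect_gt(ex[["mean_implicit"]], 4.5)
  expect_lt(ex[["mean_implicit"]], 6.5)
  s <- dataset_summary(generate_dataset(cfg)$train)
  expect_lt(abs(s$mean_implicit - ex[["mean_implicit"]]) /
              ex[["mean_implicit"]], 0.1)
  expect_lt(abs(s$mean_explicit - ex[["mean_explicit"]]) /
              ex[["mean_explicit"]], 0.1)
})

test_that("default config reproduces the corpus-scale statistics", {
  cfg <- synthetic_config()
  expect_identical(cfg$n_diseases, 10L)
  expect_identical(cfg$n_symptoms, 331L)
  ex <- synthetic_expectations(cfg)
  expect_lt(abs(ex[["mean_explicit"]] - 1.7), 0.1)
  expect_lt(abs(ex[["mean_implicit"]] - 6.6), 0.2)
})

test_that("Bayes oracle is perfect on separable data and degenerate cases", {
  cfg <- degenerate_config(n_train = 5L, n_dev = 5L, n_test = 60L)
  dat <- generate_dataset(cfg)
  expect_equal(oracle_bayes_accuracy(cfg, dat$test), 1.0)
  one <- synthetic_config(n_diseases = 1L, n_symptoms = 10L,
                          char_per_disease = 3L, char_overlap = 0L,
                          p_char = 0.8, p_background = 0.01,
                          p_neg_mention = 0.1, n_train = 5L, n_dev = 5L,
                          n_test = 40L, seed = 3L)
  expect_equal(oracle_bayes_accuracy(one, generate_dataset(one)$test),
               1.0)
  expect_error(oracle_bayes_accuracy(cfg, generate_dataset(one)$test),
               "mismatch")
})

test_that("full symptom evidence carries more disease information than the explicit part", {
  cfg <- synthetic_config(n_diseases = 4L, n_symptoms = 10L,
                          char_per_disease = 3L, char_overlap = 1L,
                          p_char = 0.7, p_background = 0.02,
                          p_neg_mention = 0.3, mean_explicit = 1.4,
                          n_train = 3000L, n_dev = 5L, n_test = 5L,
                          seed = 17L)
  ds <- generate_dataset(cfg)$train
  key <- function(p) paste(sprintf("%d:%d", p$symptom, p$attribute),
                           collapse = ",")
  full <- vapply(ds$records, function(r) {
    all <- rbind(r$explicit, r$implicit)
    key(all[order(all$symptom), , drop = FALSE])
  }, "")
  expl <- vapply(ds$records, function(r) {
    e <- r$explicit
    key(e[order(e$symptom), , drop = FALSE])
  }, "")
  dis <- vapply(ds$records, function(r) r$disease, 0L)
  H <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  mi <- function(x, y) H(x) + H(y) - H(paste(x, y))
  expect_gt(mi(dis, full), mi(dis, expl))
})
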
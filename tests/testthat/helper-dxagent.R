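# Shared fixtures: small vocabularies, hand-built records, generator
# configs, and lazily trained models reused across test files.

tiny_vocabs <- function(n_sym = 8L, n_dis = 3L) {
  list(sym = symptom_vocabulary(paste0("s", seq_len(n_sym))),
       dis = disease_vocabulary(paste0("d", seq_len(n_dis))))
}

# symptom name -> id shorthand for hand-built records
sid <- function(vocab, names) id_of(vocab, names)

pairs_of <- function(symptom, attribute)
  data.frame(symptom = as.integer(symptom),
             attribute = as.integer(attribute))

# A record over tiny_vocabs(8, 3): explicit s1 POS; implicit s3 POS, s5 NEG.
tiny_record <- function(v = tiny_vocabs()) {
  mcr_record("r1",
             pairs_of(sid(v$sym, "s1"), ATTR[["POS"]]),
             pairs_of(sid(v$sym, c("s3", "s5")),
                      c(ATTR[["POS"]], ATTR[["NEG"]])),
             0L)
}

tiny_model <- function(v = tiny_vocabs(), hidden = 8L, dec_layers = 2L,
                       heads = 2L, seed = 5L, dropout = 0) {
  dx_model(v$sym, v$dis, hidden = hidden, ff = 2L * hidden,
           dec_layers = dec_layers, enc_layers = 1L, heads = heads,
           dropout = dropout, seed = seed)
}

# Degenerate, perfectly separable generator: disjoint characteristic
# sets, every characteristic symptom always present, no background, no
# negative mentions.
degenerate_config <- function(seed = 21L, n_train = 300L, n_dev = 50L,
                              n_test = 100L) {
  synthetic_config(n_diseases = 5L, n_symptoms = 25L,
                   char_per_disease = 4L, char_overlap = 0L,
                   p_char = 1, p_background = 0, p_neg_mention = 0,
                   mean_explicit = 1.5, n_train = n_train, n_dev = n_dev,
                   n_test = n_test, seed = seed)
}

# Small non-degenerate config for fast statistical tests.
small_config <- function(seed = 9L, n_train = 400L, n_dev = 80L,
                         n_test = 120L) {
  synthetic_config(n_diseases = 4L, n_symptoms = 30L,
                   char_per_disease = 6L, char_overlap = 2L,
                   p_char = 0.7, p_background = 0.01,
                   p_neg_mention = 0.25, mean_explicit = 1.5,
                   n_train = n_train, n_dev = n_dev, n_test = n_test,
                   seed = seed)
}

# Pretrain + jointly train a small model on a degenerate config.
train_degenerate <- function(seed) {
  cfg <- degenerate_config(seed = seed)
  dat <- generate_dataset(cfg)
  model <- dx_model(dat$train$sym_vocab, dat$train$dis_vocab,
                    hidden = 16L, ff = 32L, dec_layers = 2L,
                    enc_layers = 1L, heads = 2L, dropout = 0,
                    seed = seed)
  pretrain(model, dat$train, epochs = 10L, lr = 2e-3, batch_size = 16L,
           seed = seed + 1L)
  cooc <- build_cooccur(dat$train)
  train_joint(model, dat$train, cooc, steps = 80L, batch_size = 8L,
              lr = 5e-4, t_train = 8L, seed = seed + 2L)
  list(cfg = cfg, dat = dat, model = model, cooc = cooc)
}

# The default study: generator defaults (corpus-scale disease/symptom
# structure) at a run size chosen for the package's own test turnaround;
# trained once per session and cached.
.dxagent_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (!is.null(.dxagent_cache$study)) return(.dxagent_cache$study)
  cfg <- synthetic_config(n_train = 1200L, n_dev = 200L, n_test = 400L,
                          seed = 5L)
  dat <- generate_dataset(cfg)
  model <- dx_model(dat$train$sym_vocab, dat$train$dis_vocab,
                    hidden = 32L, ff = 64L, dec_layers = 4L,
                    enc_layers = 1L, heads = 4L, dropout = 0.1,
                    seed = 1L)
  pretrain(model, dat$train, epochs = 6L, lr = 1e-3, batch_size = 24L,
           seed = 2L)
  cooc <- build_cooccur(dat$train)
  train_joint(model, dat$train, cooc, steps = 250L, batch_size = 6L,
              lr = 5e-4, t_train = 12L, seed = 3L)
  .dxagent_cache$study <- list(cfg = cfg, dat = dat, model = model,
                               cooc = cooc)
  .dxagent_cache$study
}

# Hand-built reward fixture: disease d1 co-occurs with s1, s3, s5, s7;
# d2 with s2. Record "a" (disease d1) has explicit s1 and implicit
# s3 (POS), s5 (NEG).
make_reward_fixture <- function() {
  v <- tiny_vocabs()
  recs <- list(
    mcr_record("a", pairs_of(2L, ATTR[["POS"]]),
               pairs_of(c(4L, 6L), c(ATTR[["POS"]], ATTR[["NEG"]])), 0L),
    mcr_record("b", pairs_of(3L, ATTR[["POS"]]), disease = 1L),
    mcr_record("c", pairs_of(8L, ATTR[["POS"]]), disease = 0L))
  ds <- mcr_dataset(recs, v$sym, v$dis, "train")
  list(v = v, ds = ds, cooc = build_cooccur(ds))
}

# subset of a dataset (keeps vocabularies)
ds_head <- function(ds, n) {
  mcr_dataset(ds$records[seq_len(min(n, length(ds$records)))],
              ds$sym_vocab, ds$dis_vocab, ds$split)
}
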
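#' Micro-averaged symptom recall
#'
#' `sum |asked ∩ implicit| / sum |implicit|` over episodes (sums taken
#' before dividing). Episodes with no implicit symptoms contribute 0/0
#' and are excluded from both sums.
#'
#' @param episodes List of lists with integer fields `asked` (symptom ids
#'   the agent queried) and `imp` (the record's implicit symptom ids).
#' @return Recall in `[0, 1]`.
#' @export
symptom_recall <- function(episodes) {
  if (length(episodes) == 0L) stop("no episodes")
  num <- 0L; den <- 0L
  for (ep in episodes) {
    m <- length(ep$imp)
    if (m == 0L) next
    num <- num + length(intersect(ep$asked, ep$imp))
    den <- den + m
  }
  if (den == 0L) stop("every episode has an empty implicit set")
  num / den
}

#' Run the full inquiry-then-diagnose inference loop
#'
#' Per record: starting from the explicit symptoms, the decoder greedily
#' picks the next unasked symptom, the simulator answers, and after each
#' turn the encoder re-diagnoses from explicit + collected POS/NEG pairs;
#' inquiry stops when [check_stop()] fires (confidence threshold or turn
#' cap) or no askable symptom remains. The final argmax disease is the
#' prediction. Fully deterministic.
#'
#' @param model A trained [dx_model()].
#' @param ds An [mcr_dataset()] (vocabularies must match the model's).
#' @param crit A [stopping_criterion()].
#' @param include_unk Keep UNK answers in the decoder's history.
#' @return List with `metrics` (one-row data frame: `sx_rec`, `dx_acc`,
#'   `avg_turns`, `n_episodes`) and `traces` (per-episode list of asked
#'   symptoms, responses, prediction, confidence and turn count).
#' @export
run_inference <- function(model, ds, crit = stopping_criterion(),
                          include_unk = TRUE) {
  if (!identical(ds$sym_vocab$symptoms, model$sym_vocab$symptoms) ||
      !identical(ds$dis_vocab$diseases, model$dis_vocab$diseases))
    stop("dataset/model vocabulary mismatch")
  traces <- vector("list", length(ds$records))
  for (i in seq_along(ds$records)) {
    rec <- ds$records[[i]]
    sim <- patient_simulator(rec)
    ids <- c(SYM_BOS, rec$explicit$symptom)
    attrs <- c(ATTR[["PAD"]], rec$explicit$attribute)
    known <- rec$explicit
    asked <- integer(); responses <- integer()
    dist <- diagnose(model, known)
    turn <- 0L
    while (!check_stop(dist, crit, turn)) {
      mask <- unique(c(ids[ids >= N_SPECIAL], asked))
      if (length(mask) >= model$cfg$n_sym) break
      fwd <- dec_forward(model, ids, attrs)
      p <- masked_softmax(fwd$logits[length(ids), ], mask)
      s <- which.max(p) + N_SPECIAL - 1L
      a <- sim_respond(sim, s)
      asked <- c(asked, s); responses <- c(responses, a)
      if (include_unk || a != ATTR[["UNK"]]) {
        ids <- c(ids, s); attrs <- c(attrs, a)
      }
      if (a != ATTR[["UNK"]]) known <- rbind(known, pair_frame(s, a))
      turn <- turn + 1L
      dist <- diagnose(model, known)
    }
    traces[[i]] <- list(record_id = rec$id, asked = asked,
                        responses = responses,
                        imp = rec$implicit$symptom,
                        disease = rec$disease,
                        predicted = dist$predicted,
                        confidence = dist$confidence, turns = turn)
  }
  metrics <- data.frame(
    sx_rec = symptom_recall(traces),
    dx_acc = mean(vapply(traces, function(tr)
      tr$predicted == tr$disease, TRUE)),
    avg_turns = mean(vapply(traces, function(tr) tr$turns, 0L)),
    n_episodes = length(traces))
  list(metrics = metrics, traces = traces)
}

record_features <- function(rec, n_sym, implicit = c("all", "none",
                                                     "pos", "neg")) {
  implicit <- match.arg(implicit)
  x <- numeric(2L * n_sym)
  put <- function(p) {
    for (j in seq_len(nrow(p))) {
      col <- (p$symptom[j] - N_SPECIAL) * 2L +
        (if (p$attribute[j] == ATTR[["POS"]]) 1L else 2L)
      x[col] <<- 1
    }
  }
  put(rec$explicit)
  imp <- rec$implicit
  if (implicit == "pos")
    imp <- imp[imp$attribute == ATTR[["POS"]], , drop = FALSE]
  if (implicit == "neg")
    imp <- imp[imp$attribute == ATTR[["NEG"]], , drop = FALSE]
  if (implicit != "none" && nrow(imp)) put(imp)
  x
}

feature_matrix <- function(ds, implicit) {
  n_sym <- vocab_size(ds$sym_vocab)
  X <- t(vapply(ds$records, record_features, numeric(2L * n_sym),
                n_sym = n_sym, implicit = implicit))
  y <- factor(vapply(ds$records, function(r) r$disease, 0L),
              levels = 0:(vocab_size(ds$dis_vocab) - 1L))
  list(X = X, y = y)
}

svm_cv_acc <- function(X, y, cost, folds, kernel) {
  n <- nrow(X)
  fold_id <- rep(seq_len(folds), length.out = n)[sample.int(n)]
  accs <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                      cost = cost, scale = FALSE)
    mean(stats::predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
  }, 0)
  mean(accs, na.rm = TRUE)
}

#' Accuracy-bound estimation with linear-margin classifiers
#'
#' Bounds the accuracy range available to any inquiry policy: a
#' support-vector classifier over sparse symptom-attribute indicator
#' features is trained on four feature sets — explicit symptoms only (the
#' lower bound, recall 0), all symptoms (the upper bound, recall 1), and
#' explicit + positive-only / negative-only implicit symptoms. The
#' regularization cost is selected by cross-validation on the training
#' split; test-split accuracy is reported.
#'
#' @param train,test Disjoint [mcr_dataset()] splits.
#' @param costs Cost grid for cross-validation.
#' @param folds Cross-validation folds (default 5).
#' @param kernel SVM kernel (`"linear"` default; `"radial"` available).
#' @param seed Seed for the fold assignment.
#' @return Object of class `bounds_report`: `acc_lb`, `acc_ub`,
#'   `acc_ub_p`, `acc_ub_n`, plus the selected costs.
#' @export
estimate_bounds <- function(train, test, costs = c(0.1, 1, 10),
                            folds = 5L, kernel = "linear", seed = 1L) {
  if (length(intersect(vapply(train$records, function(r) r$id, ""),
                       vapply(test$records, function(r) r$id, ""))))
    stop("train and test splits share record ids")
  if (length(unique(vapply(train$records, function(r) r$disease, 0L)))
      < 2L)
    stop("training split is single-class")
  sets <- c(acc_lb = "none", acc_ub = "all", acc_ub_p = "pos",
            acc_ub_n = "neg")
  out <- list(); chosen <- numeric(0)
  withr::with_seed(seed, {
    for (nm in names(sets)) {
      trf <- feature_matrix(train, sets[[nm]])
      tef <- feature_matrix(test, sets[[nm]])
      cv <- vapply(costs, function(cc)
        svm_cv_acc(trf$X, trf$y, cc, folds, kernel), 0)
      best <- costs[which.max(cv)]
      fit <- e1071::svm(trf$X, trf$y, kernel = kernel, cost = best,
                        scale = FALSE)
      out[[nm]] <- mean(stats::predict(fit, tef$X) == tef$y)
      chosen[nm] <- best
    }
  })
  structure(c(out, list(costs = chosen, kernel = kernel)),
            class = "bounds_report")
}

#' @export
print.bounds_report <- function(x, ...) {
  cat(sprintf(
    paste0("accuracy bounds (%s SVM):\n  Acc-LB %.3f  Acc-UB %.3f",
           "  Acc-UB(P) %.3f  Acc-UB(N) %.3f\n"),
    x$kernel, x$acc_lb, x$acc_ub, x$acc_ub_p, x$acc_ub_n))
  invisible(x)
}

#' Sweep the stopping criterion
#'
#' Runs [run_inference()] over a grid of turn caps (at fixed threshold)
#' or thresholds (at fixed cap) and tabulates the metrics — the standard
#' accuracy/efficiency trade-off curves.
#'
#' @param model A trained [dx_model()].
#' @param ds Evaluation [mcr_dataset()].
#' @param t_max_grid Integer grid of turn caps, or `NULL`.
#' @param epsilon_grid Numeric grid of thresholds, or `NULL`. Exactly one
#'   grid must be supplied.
#' @param crit Baseline [stopping_criterion()] providing the fixed
#'   member.
#' @return Data frame: one metrics row per grid point.
#' @export
sweep_metrics <- function(model, ds, t_max_grid = NULL,
                          epsilon_grid = NULL,
                          crit = stopping_criterion()) {
  if (is.null(t_max_grid) == is.null(epsilon_grid))
    stop("supply exactly one of t_max_grid / epsilon_grid")
  grid <- if (!is.null(t_max_grid)) t_max_grid else epsilon_grid
  if (length(grid) == 0L) stop("empty grid")
  rows <- lapply(grid, function(v) {
    cr <- if (!is.null(t_max_grid))
      stopping_criterion(crit$epsilon, v)
    else stopping_criterion(v, crit$t_max)
    m <- run_inference(model, ds, cr)$metrics
    cbind(data.frame(t_max = cr$t_max, epsilon = cr$epsilon), m)
  })
  do.call(rbind, rows)
}
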
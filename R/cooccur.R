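#' Build disease-symptom and symptom-symptom co-occurrence matrices
#'
#' Record-level co-occurrence counts from a training split. The
#' disease-symptom matrix counts, for each (disease, symptom) pair, the
#' training records of that disease mentioning the symptom; it backs the
#' priori reward (positive iff the count exceeds a threshold, zero by
#' default). The symmetric symptom-symptom matrix counts records
#' mentioning both symptoms (its diagonal is each symptom's record
#' frequency) and backs the rule-based inquiry baseline through the
#' conditional co-occurrence probability `counts[i, j] / counts[i, i]`.
#'
#' A mention is any POS or NEG pair, explicit or implicit; set
#' `pos_only = TRUE` to count POS mentions only.
#'
#' @param train Training-split [mcr_dataset()].
#' @param pos_only Count only POS mentions.
#' @return Object of class `cooccur_matrices` with integer matrices `ds`
#'   (`n_diseases x n_symptoms`, dimnames from the vocabularies) and `ss`
#'   (`n_symptoms x n_symptoms`).
#' @export
build_cooccur <- function(train, pos_only = FALSE) {
  if (length(train$records) == 0L) stop("empty training split")
  n_s <- vocab_size(train$sym_vocab)
  n_d <- vocab_size(train$dis_vocab)
  ds <- matrix(0L, n_d, n_s,
               dimnames = list(train$dis_vocab$diseases,
                               train$sym_vocab$symptoms))
  ss <- matrix(0L, n_s, n_s,
               dimnames = list(train$sym_vocab$symptoms,
                               train$sym_vocab$symptoms))
  for (rec in train$records) {
    syms <- record_symptoms(rec)
    if (pos_only) {
      attrs <- c(rec$explicit$attribute, rec$implicit$attribute)
      syms <- syms[attrs == ATTR[["POS"]]]
    }
    if (length(syms) == 0L) next
    cols <- syms - N_SPECIAL + 1L
    ds[rec$disease + 1L, cols] <- ds[rec$disease + 1L, cols] + 1L
    ss[cols, cols] <- ss[cols, cols] + 1L
  }
  structure(list(ds = ds, ss = ss,
                 n_records = length(train$records),
                 pos_only = pos_only),
            class = "cooccur_matrices")
}

#' @export
print.cooccur_matrices <- function(x, ...) {
  cat(sprintf(
    "cooccur_matrices: %d diseases x %d symptoms from %d records (%s)\n",
    nrow(x$ds), ncol(x$ds), x$n_records,
    if (x$pos_only) "POS mentions" else "POS+NEG mentions"))
  invisible(x)
}

#' Write co-occurrence matrices as TSV
#'
#' @param m A `cooccur_matrices` object.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_cooccur_tsv <- function(m, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(m$ds, file.path(path, "disease_symptom.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(m$ss, file.path(path, "symptom_symptom.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Rule-based next-symptom choice
#'
#' The co-occurrence baseline agent: among unasked symptoms, pick the one
#' with the highest mean conditional co-occurrence probability with the
#' POS symptoms collected so far (the anchors). NEG/UNK-answered symptoms
#' are excluded from the anchor set; if no POS anchor exists, all known
#' symptoms anchor. Ties break to the lowest symptom id, so the agent is
#' deterministic given the matrix and the record.
#'
#' @param m A `cooccur_matrices` object (only `ss` is used).
#' @param known Data frame of (symptom, attribute) pairs collected so far.
#' @param asked Integer ids that may not be chosen (typically all known
#'   symptoms plus previous queries).
#' @return One symptom id.
#' @export
rule_based_next_symptom <- function(m, known, asked) {
  if (nrow(known) == 0L) stop("at least one known symptom required")
  anchors <- known$symptom[known$attribute == ATTR[["POS"]]]
  if (length(anchors) == 0L) anchors <- known$symptom
  n_s <- ncol(m$ss)
  candidates <- setdiff(seq_len(n_s) + N_SPECIAL - 1L, asked)
  if (length(candidates) == 0L) stop("all symptoms already asked")
  a_rows <- anchors - N_SPECIAL + 1L
  c_cols <- candidates - N_SPECIAL + 1L
  diag_a <- diag(m$ss)[a_rows]
  prob <- m$ss[a_rows, c_cols, drop = FALSE] /
    ifelse(diag_a > 0L, diag_a, 1L)
  score <- colMeans(prob)
  candidates[which.max(score)]  # which.max takes the first (lowest id) tie
}

#' Run the rule-based agent on one record
#'
#' @param m A `cooccur_matrices` object.
#' @param rec An [mcr_record()].
#' @param t_max Number of inquiries.
#' @return Data frame of asked symptoms and simulator responses, in order.
#' @export
rule_based_rollout <- function(m, rec, t_max) {
  sim <- patient_simulator(rec)
  state <- dialogue_state(rec)
  asked <- integer()
  n_s <- ncol(m$ss)
  for (t in seq_len(t_max)) {
    banned <- c(state$known$symptom, asked)
    if (length(unique(banned)) >= n_s) break
    s <- rule_based_next_symptom(m, state$known, banned)
    state <- dialogue_step(state, sim, s)
    asked <- c(asked, s)
  }
  data.frame(symptom = asked,
             attribute = state$known$attribute[
               nrow(rec$explicit) + seq_along(asked)])
}
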
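#' Symptom attribute codes
#'
#' Integer codes for the patient's relation to a symptom. `POS` (has it) and
#' `NEG` (does not have it) are the only codes allowed inside a stored
#' consultation record; `UNK` is returned by the patient simulator for
#' symptoms the record never mentions, and occurs only in simulator
#' responses and agent histories; `PAD` exists for internal sequence
#' plumbing and never contributes to any loss, reward or pooled
#' representation.
#'
#' @format Named integer vector with entries `PAD = 0`, `POS = 1`,
#'   `NEG = 2`, `UNK = 3`.
#' @export
ATTR <- c(PAD = 0L, POS = 1L, NEG = 2L, UNK = 3L)

#' @keywords internal
attr_name <- function(code) names(ATTR)[match(code, ATTR)]

# Special symptom-token ids. Real symptoms occupy ids 2..(n_symptoms + 1).
SYM_PAD <- 0L
SYM_BOS <- 1L
N_SPECIAL <- 2L

#' Build a symptom vocabulary
#'
#' Maps symptom names to contiguous integer ids. Two special tokens occupy
#' fixed ids: `PAD = 0` and `BOS = 1`; real symptoms are numbered from 2 in
#' the order given, so ids are stable across runs as long as the vocabulary
#' file is unchanged.
#'
#' @param symptoms Character vector of unique symptom names.
#' @return An object of class `symptom_vocabulary`.
#' @export
symptom_vocabulary <- function(symptoms) {
  symptoms <- as.character(symptoms)
  if (anyDuplicated(symptoms)) stop("duplicate symptom names in vocabulary")
  if (any(symptoms %in% c("<PAD>", "<BOS>")))
    stop("symptom names may not collide with special tokens")
  structure(
    list(symptoms = symptoms,
         index = stats::setNames(seq_along(symptoms) + N_SPECIAL - 1L,
                                 symptoms)),
    class = "symptom_vocabulary")
}

#' Build a disease vocabulary
#'
#' Disease names get contiguous ids starting at 0; there are no special
#' tokens.
#'
#' @param diseases Character vector of unique disease names.
#' @return An object of class `disease_vocabulary`.
#' @export
disease_vocabulary <- function(diseases) {
  diseases <- as.character(diseases)
  if (anyDuplicated(diseases)) stop("duplicate disease names in vocabulary")
  structure(
    list(diseases = diseases,
         index = stats::setNames(seq_along(diseases) - 1L, diseases)),
    class = "disease_vocabulary")
}

#' Number of entries in a vocabulary
#' @param vocab A `symptom_vocabulary` or `disease_vocabulary`.
#' @return Integer count of real entries (special tokens excluded).
#' @export
vocab_size <- function(vocab) {
  if (inherits(vocab, "symptom_vocabulary")) length(vocab$symptoms)
  else if (inherits(vocab, "disease_vocabulary")) length(vocab$diseases)
  else stop("not a vocabulary")
}

#' Look up ids by name
#' @param vocab A vocabulary.
#' @param names Character vector of entry names.
#' @return Integer ids.
#' @export
id_of <- function(vocab, names) {
  ids <- vocab$index[names]
  if (anyNA(ids)) stop("unknown name(s): ",
                       paste(names[is.na(ids)], collapse = ", "))
  unname(ids)
}

#' Look up names by id
#' @param vocab A vocabulary.
#' @param ids Integer ids.
#' @return Character names.
#' @export
name_of <- function(vocab, ids) {
  if (inherits(vocab, "symptom_vocabulary")) {
    out <- character(length(ids))
    out[ids == SYM_PAD] <- "<PAD>"
    out[ids == SYM_BOS] <- "<BOS>"
    real <- ids >= N_SPECIAL
    if (any(ids[real] - N_SPECIAL + 1L > length(vocab$symptoms)))
      stop("symptom id out of range")
    out[real] <- vocab$symptoms[ids[real] - N_SPECIAL + 1L]
    out
  } else {
    if (any(ids < 0L | ids >= length(vocab$diseases)))
      stop("disease id out of range")
    vocab$diseases[ids + 1L]
  }
}

#' All real symptom ids of a vocabulary
#' @param vocab A `symptom_vocabulary`.
#' @return Integer vector of queryable symptom ids (specials excluded).
#' @export
symptom_ids <- function(vocab) seq_len(length(vocab$symptoms)) + N_SPECIAL - 1L

#' @export
print.symptom_vocabulary <- function(x, ...) {
  cat("symptom_vocabulary:", length(x$symptoms),
      "symptoms (+ PAD, BOS)\n")
  invisible(x)
}

#' @export
print.disease_vocabulary <- function(x, ...) {
  cat("disease_vocabulary:", length(x$diseases), "diseases\n")
  invisible(x)
}

pair_frame <- function(symptom = integer(), attribute = integer()) {
  data.frame(symptom = as.integer(symptom),
             attribute = as.integer(attribute))
}

#' Construct one structured consultation record
#'
#' A structured medical consultation record (MCR) is an ordered list of
#' (symptom, attribute) pairs split into an explicit part (the patient's
#' self-report, known to the agent at episode start) and an implicit part
#' (mentioned later in the dialogue, discoverable only by querying), plus a
#' disease label.
#'
#' @param id Record identifier (string).
#' @param explicit,implicit Data frames with integer columns `symptom`
#'   (vocabulary ids) and `attribute` (`ATTR["POS"]` or `ATTR["NEG"]`).
#'   `explicit` must be non-empty; `implicit` may be empty.
#' @param disease Integer disease id.
#' @return An object of class `mcr_record`.
#' @export
mcr_record <- function(id, explicit, implicit = pair_frame(), disease) {
  explicit <- as.data.frame(explicit)
  implicit <- as.data.frame(implicit)
  rec <- structure(
    list(id = as.character(id),
         explicit = pair_frame(explicit$symptom, explicit$attribute),
         implicit = if (nrow(implicit))
           pair_frame(implicit$symptom, implicit$attribute)
           else pair_frame(),
         disease = as.integer(disease)),
    class = "mcr_record")
  validate_record(rec)
  rec
}

validate_record <- function(rec, sym_vocab = NULL, dis_vocab = NULL) {
  if (nrow(rec$explicit) == 0L)
    stop("record ", rec$id, ": explicit symptom list is empty")
  syms <- c(rec$explicit$symptom, rec$implicit$symptom)
  attrs <- c(rec$explicit$attribute, rec$implicit$attribute)
  if (anyDuplicated(syms))
    stop("record ", rec$id, ": duplicate symptom across explicit/implicit")
  if (!all(attrs %in% c(ATTR[["POS"]], ATTR[["NEG"]])))
    stop("record ", rec$id, ": attributes must be POS or NEG")
  if (any(syms < N_SPECIAL))
    stop("record ", rec$id, ": special token used as a symptom")
  if (!is.null(sym_vocab) &&
      any(syms - N_SPECIAL + 1L > vocab_size(sym_vocab)))
    stop("record ", rec$id, ": symptom id outside vocabulary")
  if (!is.null(dis_vocab) &&
      (rec$disease < 0L || rec$disease >= vocab_size(dis_vocab)))
    stop("record ", rec$id, ": disease id outside vocabulary")
  invisible(rec)
}

#' All symptom ids mentioned by a record
#' @param rec An `mcr_record`.
#' @return Integer vector (explicit first, then implicit, in record order).
#' @export
record_symptoms <- function(rec)
  c(rec$explicit$symptom, rec$implicit$symptom)

#' @export
print.mcr_record <- function(x, ...) {
  cat(sprintf("mcr_record %s: %d explicit, %d implicit, disease id %d\n",
              x$id, nrow(x$explicit), nrow(x$implicit), x$disease))
  invisible(x)
}

#' Construct a consultation-record dataset
#'
#' Bundles validated records with the symptom and disease vocabularies that
#' define their integer ids.
#'
#' @param records List of [mcr_record()] objects.
#' @param sym_vocab A [symptom_vocabulary()].
#' @param dis_vocab A [disease_vocabulary()].
#' @param split Split name, one of `"train"`, `"dev"`, `"test"`.
#' @return An object of class `mcr_dataset`.
#' @export
mcr_dataset <- function(records, sym_vocab, dis_vocab,
                        split = c("train", "dev", "test")) {
  split <- match.arg(split)
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate record ids within split")
  for (r in records) validate_record(r, sym_vocab, dis_vocab)
  structure(
    list(split = split, records = records,
         sym_vocab = sym_vocab, dis_vocab = dis_vocab),
    class = "mcr_dataset")
}

#' @export
print.mcr_dataset <- function(x, ...) {
  cat(sprintf(
    "mcr_dataset [%s]: %d records, %d symptoms, %d diseases\n",
    x$split, length(x$records), vocab_size(x$sym_vocab),
    vocab_size(x$dis_vocab)))
  invisible(x)
}

#' Read a structured consultation-record dataset from disk
#'
#' Expects `symptoms.txt` and `diseases.txt` (one name per line; line order
#' defines the ids after the special tokens) and `<split>.json` with schema
#' `{"records": [{"id", "explicit": [[name, "POS"|"NEG"], ...],
#' "implicit": [...], "disease": name}, ...]}` in `path`.
#'
#' @param path Directory holding the dataset files.
#' @param split Split name.
#' @return An [mcr_dataset()].
#' @export
read_mcr_dataset <- function(path, split = c("train", "dev", "test")) {
  split <- match.arg(split)
  sv_file <- file.path(path, "symptoms.txt")
  dv_file <- file.path(path, "diseases.txt")
  js_file <- file.path(path, paste0(split, ".json"))
  for (f in c(sv_file, dv_file, js_file))
    if (!file.exists(f)) stop("missing file: ", f)
  sym_vocab <- symptom_vocabulary(readLines(sv_file))
  dis_vocab <- disease_vocabulary(readLines(dv_file))
  raw <- jsonlite::fromJSON(js_file, simplifyVector = FALSE)
  if (is.null(raw$records)) stop("schema violation: no 'records' field")
  records <- lapply(raw$records, function(r) {
    parse_pairs <- function(p, field) {
      if (length(p) == 0L) return(pair_frame())
      sym <- vapply(p, function(x) as.character(x[[1]]), "")
      att <- vapply(p, function(x) as.character(x[[2]]), "")
      if (!all(att %in% c("POS", "NEG")))
        stop("record ", r$id, ": field ", field,
             ": attribute must be POS or NEG")
      pair_frame(id_of(sym_vocab, sym), ATTR[att])
    }
    mcr_record(r$id,
               parse_pairs(r$explicit, "explicit"),
               parse_pairs(r$implicit, "implicit"),
               id_of(dis_vocab, as.character(r$disease)))
  })
  mcr_dataset(records, sym_vocab, dis_vocab, split)
}

#' Write a dataset (records + vocabularies) to disk
#'
#' Inverse of [read_mcr_dataset()]: writing then reading reproduces the
#' dataset exactly, including vocabulary ordering (so ids stay stable).
#'
#' @param ds An [mcr_dataset()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_mcr_dataset <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(ds$sym_vocab$symptoms, file.path(path, "symptoms.txt"))
  writeLines(ds$dis_vocab$diseases, file.path(path, "diseases.txt"))
  fmt_pairs <- function(p)
    lapply(seq_len(nrow(p)), function(i)
      list(name_of(ds$sym_vocab, p$symptom[i]), attr_name(p$attribute[i])))
  recs <- lapply(ds$records, function(r)
    list(id = r$id,
         explicit = fmt_pairs(r$explicit),
         implicit = fmt_pairs(r$implicit),
         disease = name_of(ds$dis_vocab, r$disease)))
  jsonlite::write_json(list(records = recs),
                       file.path(path, paste0(ds$split, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Summary statistics of a dataset
#'
#' Counts of records, diseases and symptoms, and the mean and maximum
#' numbers of explicit and implicit symptoms per record — the statistics
#' typically tabulated for consultation-record corpora.
#'
#' @param ds An [mcr_dataset()].
#' @return A one-row data frame.
#' @export
dataset_summary <- function(ds) {
  if (length(ds$records) == 0L) stop("empty dataset")
  n_exp <- vapply(ds$records, function(r) nrow(r$explicit), 0L)
  n_imp <- vapply(ds$records, function(r) nrow(r$implicit), 0L)
  data.frame(
    split = ds$split,
    n_records = length(ds$records),
    n_diseases = vocab_size(ds$dis_vocab),
    n_symptoms = vocab_size(ds$sym_vocab),
    mean_explicit = mean(n_exp), max_explicit = max(n_exp),
    mean_implicit = mean(n_imp), max_implicit = max(n_imp))
}
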
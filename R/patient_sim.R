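#' Patient simulator backed by one consultation record
#'
#' The simulator answers symptom queries from the record: the recorded
#' attribute (POS/NEG) for any mentioned symptom, `UNK` for everything
#' else. It is stateless — repeated queries return the same answer.
#'
#' @param rec An [mcr_record()].
#' @return An object of class `patient_simulator`.
#' @export
patient_simulator <- function(rec) {
  syms <- record_symptoms(rec)
  attrs <- c(rec$explicit$attribute, rec$implicit$attribute)
  structure(
    list(record = rec,
         lookup = stats::setNames(attrs, syms)),
    class = "patient_simulator")
}

#' Query the simulator for one symptom's attribute
#'
#' @param sim A [patient_simulator()].
#' @param s Integer symptom id.
#' @return `ATTR["POS"]` or `ATTR["NEG"]` for mentioned symptoms,
#'   `ATTR["UNK"]` otherwise.
#' @export
sim_respond <- function(sim, s) {
  if (length(s) != 1L || is.na(s) || s < N_SPECIAL)
    stop("invalid symptom id")
  a <- sim$lookup[as.character(s)]
  if (is.na(a)) ATTR[["UNK"]] else unname(a)
}

#' Initial dialogue state for a record
#'
#' The agent starts from the record's explicit (self-reported) pairs; the
#' turn counter counts inquiries made so far.
#'
#' @param rec An [mcr_record()].
#' @return An object of class `dialogue_state` with fields `known`
#'   (ordered data frame of symptom/attribute pairs), `turn`, and
#'   `terminated`.
#' @export
dialogue_state <- function(rec) {
  structure(
    list(known = rec$explicit, turn = 0L, terminated = FALSE),
    class = "dialogue_state")
}

#' Execute one inquiry turn
#'
#' Appends `(s, respond(s))` to the known pairs — UNK answers included,
#' since the inquiry policy conditions on failed queries too — and
#' increments the turn counter. Re-querying a known symptom is a contract
#' violation (the agent's action mask must prevent it) and raises an
#' error.
#'
#' @param state A [dialogue_state()].
#' @param sim The [patient_simulator()].
#' @param s Integer symptom id to ask about.
#' @return The updated `dialogue_state`.
#' @export
dialogue_step <- function(state, sim, s) {
  if (state$terminated) stop("dialogue already terminated")
  if (s %in% state$known$symptom)
    stop("contract violation: symptom ", s, " already queried/known")
  a <- sim_respond(sim, s)
  state$known <- rbind(state$known, pair_frame(s, a))
  state$turn <- state$turn + 1L
  state
}

#' @export
print.dialogue_state <- function(x, ...) {
  cat(sprintf("dialogue_state: %d known symptoms, turn %d%s\n",
              nrow(x$known), x$turn,
              if (x$terminated) " (terminated)" else ""))
  invisible(x)
}
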
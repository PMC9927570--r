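# Subject-access audit: a lightweight trace of which subjects' data enter
# the two fitting stages that must never see held-out subjects (pair
# scoring and per-edge class-proportion fitting). Used to assert the
# absence of information leakage in evaluation protocols.

.audit <- new.env(parent = emptyenv())
.audit$active <- FALSE
.audit$entries <- list()

audit_record <- function(stage, subjects) {
  if (isTRUE(.audit$active)) {
    .audit$entries[[length(.audit$entries) + 1L]] <-
      list(stage = stage, subjects = subjects)
  }
  invisible(NULL)
}

#' Trace subject access during fitting stages
#'
#' Evaluates an expression while recording, for every internal call that
#' fits pair scores or per-edge class proportions, which subjects' data
#' were used. Intended for leakage checks: run an evaluation protocol under
#' the audit and assert that held-out subjects never appear in a fitting
#' stage.
#'
#' @param expr Expression to evaluate.
#' @return A list with `result` (the expression's value) and `log` (a list
#'   of records, each with `stage` — `"pair_scores"` or `"pair_stats"` —
#'   and `subjects`, the subject ids seen).
#' @export
with_subject_audit <- function(expr) {
  old_active <- .audit$active
  old_entries <- .audit$entries
  .audit$active <- TRUE
  .audit$entries <- list()
  on.exit({
    .audit$active <- old_active
    .audit$entries <- old_entries
  })
  result <- force(expr)
  list(result = result, log = .audit$entries)
}

#' Subjects seen by a given fitting stage in an audit log
#'
#' @param log The `log` element returned by [with_subject_audit()].
#' @param stage `"pair_scores"`, `"pair_stats"`, or `NULL` for all stages.
#' @return Character vector of unique subject ids.
#' @export
audited_subjects <- function(log, stage = NULL) {
  if (!is.null(stage)) log <- Filter(function(e) e$stage == stage, log)
  unique(unlist(lapply(log, `[[`, "subjects")))
}
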
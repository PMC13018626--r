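#' Ordinal triage levels
#'
#' The label space of the three-class triage problem: regular ward,
#' intermediate care unit (IMC) and intensive care unit (ICU), ordered by
#' care intensity. The integer encoding WARD = 0 < IMC = 1 < ICU = 2 is the
#' single source of truth used everywhere in the package: cost matrices,
#' confusion matrices and learner labels all index classes in this order.
#'
#' @return Named integer vector `c(WARD = 0L, IMC = 1L, ICU = 2L)`.
#' @export
#' @examples
#' triage_levels()
triage_levels <- function() {
  c(WARD = 0L, IMC = 1L, ICU = 2L)
}

#' @rdname triage_levels
#' @param x integer vector of triage codes (0, 1, 2).
#' @return `triage_factor()` returns an ordered factor WARD < IMC < ICU.
#' @export
triage_factor <- function(x) {
  stopifnot(all(x %in% 0:2))
  factor(names(triage_levels())[x + 1L],
         levels = names(triage_levels()), ordered = TRUE)
}

# Event columns, one binary column per adverse-event type. ICU events can
# only be managed at ICU level; IMC events at IMC level or above.
icu_event_columns <- function() {
  c("cpr", "csf_drainage", "operative_revision", "catecholamines",
    "reintubation", "dysphagia", "ventilation_gt4h", "impaired_consciousness")
}

imc_event_columns <- function() {
  c("iv_antihypertensive", "cranial_nerve_deficit", "severe_hemiparesis",
    "icp_medication", "mnihss_worsening", "seizure")
}

#' Derive the required triage level from postoperative event flags
#'
#' A patient who experienced at least one ICU-level event requires ICU care
#' regardless of any IMC events (the ICU is the highest tier and manages
#' both event types); a patient with at least one IMC event and no ICU event
#' requires IMC; a patient with neither requires only the regular ward.
#' Adding an event to a record can therefore never lower its label.
#'
#' @param cohort a cohort `data.frame` carrying the 14 binary event columns
#'   (see [cohort_schema()]).
#' @return integer vector of triage codes per [triage_levels()].
#' @export
derive_labels <- function(cohort) {
  icu_cols <- icu_event_columns()
  imc_cols <- imc_event_columns()
  missing <- setdiff(c(icu_cols, imc_cols), names(cohort))
  if (length(missing) > 0L) {
    stop("cohort lacks event column(s): ", paste(missing, collapse = ", "))
  }
  any_icu <- rowSums(as.matrix(cohort[icu_cols])) > 0
  any_imc <- rowSums(as.matrix(cohort[imc_cols])) > 0
  ifelse(any_icu, 2L, ifelse(any_imc, 1L, 0L))
}

#' Class frequencies of a labelled cohort
#'
#' @param labels integer triage codes, or a cohort `data.frame` from which
#'   labels are derived via [derive_labels()].
#' @return numeric 3-vector of WARD/IMC/ICU proportions, summing to 1.
#' @export
#' @examples
#' # main-cohort composition: 674 ward, 265 IMC, 133 ICU of 1072
#' class_frequencies(rep(0:2, c(674, 265, 133)))
class_frequencies <- function(labels) {
  if (is.data.frame(labels)) labels <- derive_labels(labels)
  if (length(labels) == 0L) stop("empty cohort: class frequencies undefined")
  stopifnot(all(labels %in% 0:2))
  as.vector(tabulate(labels + 1L, nbins = 3L)) / length(labels)
}
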
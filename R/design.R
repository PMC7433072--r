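#' Trial design: arms, doses and sample sizes
#'
#' Constructs the design object used throughout the package. An arm table
#' holds one row per arm with its label, dose (in whatever units the trial
#' uses; oxygen toxicity units, OTU, for the motivating hyperbaric-oxygen
#' trial) and planned number of subjects at the interim. Exactly one arm is
#' the control arm; it is sorted first. The scaled covariate `x = dose / 100`
#' is stored alongside the raw dose.
#'
#' `q_c` is the protocol randomization fraction of the control arm, used by
#' the blinded mixture model. It defaults to the realized fraction
#' `n_control / N` but should be set to the protocol value where the two
#' differ (the motivating trial fixes `q_c = 0.2` by protocol while enrolling
#' 11/53 control subjects); both are retained.
#'
#' @param label character vector of arm labels.
#' @param dose numeric vector of non-negative doses, one per arm.
#' @param n integer vector of per-arm sample sizes at the interim.
#' @param control index or label of the control arm (default: first).
#' @param q_c protocol control-arm randomization fraction in (0, 1).
#' @return An object of class `trial_design`: a data frame with columns
#'   `label`, `dose`, `n`, `control`, `x`, and attributes `N` (total
#'   enrolled), `q_c` and `q_t = 1 - q_c`.
#' @seealso [hobit_design()] for the built-in eight-arm fixture,
#'   [validate_design()] for the invariant checks.
#' @export
#' @examples
#' d <- trial_design(c("ctrl", "low", "high"), dose = c(0, 1, 2),
#'                   n = c(10, 10, 10))
#' attr(d, "N")
trial_design <- function(label, dose, n, control = 1L, q_c = NULL) {
  stopifnot(length(label) == length(dose), length(dose) == length(n))
  if (is.character(control)) control <- match(control, label)
  if (is.na(control) || control < 1L || control > length(label))
    stop("'control' does not identify an arm", call. = FALSE)
  arms <- data.frame(label = as.character(label), dose = as.numeric(dose),
                     n = as.integer(n),
                     control = seq_along(label) == control,
                     stringsAsFactors = FALSE)
  arms <- arms[order(!arms$control), , drop = FALSE]
  rownames(arms) <- NULL
  arms$x <- arms$dose / 100
  N <- sum(arms$n)
  if (is.null(q_c)) q_c <- arms$n[1] / N
  out <- structure(arms, class = c("trial_design", "data.frame"),
                   N = N, q_c = q_c, q_t = 1 - q_c)
  validate_design(out)
}

#' Validate a trial design
#'
#' Checks the design invariants: doses non-negative, per-arm sizes positive,
#' exactly one control arm (sorted first), total `N` equal to the sum of the
#' per-arm sizes, `q_c` strictly inside (0, 1), and the scaled covariate
#' consistent with `x = dose / 100`. Returns the (normalized) design or
#' raises an error.
#'
#' @param design a [trial_design()] object.
#' @return The checked design, invisibly usable in pipelines.
#' @export
validate_design <- function(design) {
  if (!inherits(design, "trial_design"))
    stop("not a 'trial_design' object", call. = FALSE)
  if (sum(design$control) != 1L) stop("exactly one control arm required", call. = FALSE)
  if (!design$control[1]) {
    design <- design[order(!design$control), , drop = FALSE]
    rownames(design) <- NULL
  }
  if (any(design$dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (any(design$n < 1)) stop("per-arm sample sizes must be >= 1", call. = FALSE)
  N <- attr(design, "N")
  if (!isTRUE(all.equal(N, sum(design$n))))
    stop("N (", N, ") does not equal the sum of per-arm sizes (",
         sum(design$n), ")", call. = FALSE)
  q_c <- attr(design, "q_c")
  if (!is.numeric(q_c) || q_c <= 0 || q_c >= 1)
    stop("q_c must lie strictly in (0, 1)", call. = FALSE)
  attr(design, "q_t") <- 1 - q_c
  design$x <- design$dose / 100
  design
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d arms, N = %d at interim, q_c = %.3f (protocol)\n",
              nrow(x), attr(x, "N"), attr(x, "q_c")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Adverse-event specifications
#'
#' One row per monitored adverse event (AE): its name, the pre-specified
#' expected pooled incidence rate `pi_M` (from historical or epidemiologic
#' data), and whether the event is anticipated to show a flat dose effect and
#' hence be analyzed active-vs-control. The flat-effect flag is metadata used
#' by the scenario generator and the optional two-arm collapse; the stage-2
#' model itself never branches on it.
#'
#' @param name character vector of AE names.
#' @param pi_M expected pooled incidence rates, each strictly in (0, 1).
#' @param flat_dose_effect logical vector (default all `FALSE`).
#' @return An object of class `ae_spec` (a data frame).
#' @export
ae_spec <- function(name, pi_M, flat_dose_effect = FALSE) {
  stopifnot(length(name) == length(pi_M))
  if (any(pi_M <= 0 | pi_M >= 1))
    stop("pi_M must lie strictly in (0, 1)", call. = FALSE)
  flat_dose_effect <- rep_len(as.logical(flat_dose_effect), length(name))
  structure(data.frame(name = as.character(name), pi_M = as.numeric(pi_M),
                       flat_dose_effect = flat_dose_effect,
                       stringsAsFactors = FALSE),
            class = c("ae_spec", "data.frame"))
}

#' The eight-arm hyperbaric-oxygen (HOBIT) case-study fixture
#'
#' `hobit_design()` returns the eight-arm phase II dose-finding design of the
#' hyperbaric oxygen brain-injury trial used as the running case study:
#' control (1.0 ATA, recorded at 0.01 OTU) with 11 subjects and seven active
#' regimens with 6 subjects each, N = 53 at the first safety interim. The
#' protocol randomization fraction is `q_c = 0.2`, kept distinct from the
#' realized 11/53.
#'
#' `hobit_aes()` returns the seven adverse events of special interest with
#' their expected pooled incidence rates; critical decreased cerebral
#' perfusion pressure, critical hypotension and hypercarbia are marked for
#' active-vs-control analysis (flat anticipated dose effect).
#'
#' @return `hobit_design()`: a [trial_design()]; `hobit_aes()`: an
#'   [ae_spec()] with seven rows.
#' @export
#' @examples
#' hobit_design()
#' hobit_aes()
hobit_design <- function() {
  trial_design(
    label = c("Control (1.0 ATA)", "1.5 ATA", "2 ATA", "NBH", "2.5 ATA",
              "1.5 ATA + NBH", "2 ATA + NBH", "2.5 ATA + NBH"),
    dose  = c(0.01, 2.60, 4.17, 5.40, 5.92, 6.20, 7.76, 9.52),
    n     = c(11L, 6L, 6L, 6L, 6L, 6L, 6L, 6L),
    control = 1L, q_c = 0.2)
}

#' @rdname hobit_design
#' @export
hobit_aes <- function() {
  ae_spec(
    name = c("Pneumothorax", "Signs of Pulmonary Dysfunction", "Pneumonia",
             "Critical decreased CPP", "Critical hypotension",
             "Seizures", "Hypercarbia during transportation"),
    pi_M = c(0.02, 0.25, 0.40, 0.75, 0.75, 0.01, 0.10),
    flat_dose_effect = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
}

#' Hypothetical pooled event-rate tiers for the case-study AEs
#'
#' The case study evaluates stage-1 detection at three joint severity tiers
#' of hypothetical observed pooled rates: events at their expected rates
#' (`"expected"`), moderately elevated (`"elevated"`), and strongly elevated
#' (`"high"`, e.g. Pneumothorax at 17% against an expected 2%). All seven
#' events are simulated jointly at the tier rates.
#'
#' @param tier one of `"expected"`, `"elevated"`, `"high"`.
#' @return Named numeric vector of pooled true rates, one per case-study AE.
#' @export
hobit_rate_tiers <- function(tier = c("expected", "elevated", "high")) {
  tier <- match.arg(tier)
  aes <- hobit_aes()
  rates <- switch(tier,
    expected = aes$pi_M,
    elevated = c(0.12, 0.35, 0.50, 0.85, 0.85, 0.11, 0.20),
    high     = c(0.17, 0.40, 0.55, 0.90, 0.90, 0.16, 0.25))
  stats::setNames(rates, aes$name)
}
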
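#' An interim snapshot of accumulating safety data
#'
#' Bundles the cumulative data available at one interim analysis: the pooled
#' blinded counts, the enrollment total, and a source of unblinded per-arm
#' counts that is consulted **only** for events flagged at stage 1. The
#' unblinded source may be an [unblinded_counts()] table or a function
#' `function(ae_names)` returning one; supplying a function lets the caller
#' audit or gate every unblinding request, and a run that flags nothing
#' never touches per-arm data.
#'
#' @param interim positive interim index.
#' @param blinded a [blinded_counts()] object (cumulative).
#' @param unblinded an [unblinded_counts()] table covering all arms, or an
#'   accessor `function(ae_names)`; may be `NULL` when stage 2 is
#'   unavailable.
#' @return Object of class `interim_snapshot`.
#' @export
interim_snapshot <- function(interim, blinded, unblinded = NULL) {
  stopifnot(interim >= 1, inherits(blinded, "blinded_counts"))
  structure(list(interim = as.integer(interim), blinded = blinded,
                 unblinded = unblinded, N = attr(blinded, "N")),
            class = "interim_snapshot")
}

#' Run one interim of the two-stage monitoring procedure
#'
#' Evaluates stage 1 on the pooled blinded counts of the snapshot, unblinds
#' only the flagged events, fits stage 2 on them and records the decisions.
#' Stage 2 is never invoked — and the unblinded source never read — when no
#' event is flagged.
#'
#' @param snapshot an [interim_snapshot()].
#' @param design a [trial_design()].
#' @param aes an [ae_spec()].
#' @param hp_blinded [blinded_hyperparams()].
#' @param hp_unblinded [unblinded_hyperparams()].
#' @param policy a [decision_policy()].
#' @param control an [mcmc_control()].
#' @param stage1_model `"hierarchical"` or `"independent"`.
#' @param joint passed to [unblinded_safety()].
#' @param min_N minimum enrollment before the first interim may run.
#' @return Object of class `interim_decision`: list with `table` (per
#'   event: `P_S1`, `flagged`, `P_S2` (`NA` unless flagged), `confirmed`),
#'   `interim`, `policy`, and the underlying stage fits.
#' @export
run_interim <- function(snapshot, design, aes,
                        hp_blinded = blinded_hyperparams(),
                        hp_unblinded = unblinded_hyperparams(),
                        policy = decision_policy(),
                        control = mcmc_control(),
                        stage1_model = c("hierarchical", "independent"),
                        joint = TRUE, min_N = 1L) {
  stopifnot(inherits(snapshot, "interim_snapshot"))
  stage1_model <- match.arg(stage1_model)
  if (snapshot$N < min_N)
    stop("interim requires at least ", min_N, " enrolled subjects",
         call. = FALSE)
  s1 <- blinded_safety(snapshot$blinded, aes, model = stage1_model,
                       design = design, hp = hp_blinded, policy = policy,
                       control = control)
  tab <- s1$table[, c("ae", "P_S1", "flagged")]
  tab$P_S2 <- NA_real_
  tab$confirmed <- FALSE
  s2 <- NULL
  flagged <- tab$ae[tab$flagged]
  if (length(flagged)) {
    ub <- snapshot$unblinded
    if (is.null(ub))
      stop("events flagged but no unblinded data source in the snapshot",
           call. = FALSE)
    ub_counts <- if (is.function(ub)) ub(flagged) else ub[ub$ae %in% flagged, , drop = FALSE]
    if (!inherits(ub_counts, "unblinded_counts"))
      ub_counts <- structure(as.data.frame(ub_counts),
                             class = c("unblinded_counts", "data.frame"))
    extra <- setdiff(unique(ub_counts$ae), flagged)
    if (length(extra))
      stop("blinding contract violated: unblinded counts supplied for ",
           "unflagged event(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    s2 <- unblinded_safety(ub_counts, aes, hp = hp_unblinded,
                           policy = policy, control = control, joint = joint)
    m <- match(s2$table$ae, tab$ae)
    tab$P_S2[m] <- s2$table$P_S2
    tab$confirmed[m] <- s2$table$confirmed
  }
  structure(list(table = tab, interim = snapshot$interim, policy = policy,
                 stage1 = s1, stage2 = s2),
            class = "interim_decision")
}

#' @export
print.interim_decision <- function(x, ...) {
  cat(sprintf("Interim %d decisions (P_crit1 = %g, P_crit2 = %g)\n",
              x$interim, x$policy$P_crit1, x$policy$P_crit2))
  print.data.frame(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Run the monitoring loop over successive interims
#'
#' Applies [run_interim()] to an ordered list of snapshots. Each interim is
#' re-evaluated from scratch on its cumulative data: a previously
#' flagged-but-unconfirmed event simply returns to blinded monitoring, and a
#' confirmation is reported again at every later interim at which it
#' recurs. Enrollment must be non-decreasing across snapshots.
#'
#' @param snapshots list of [interim_snapshot()] objects, increasing `N`.
#' @param ... passed to [run_interim()].
#' @return List of `interim_decision` objects (empty list for no
#'   snapshots), class `trial_decisions`.
#' @export
run_trial <- function(snapshots, ...) {
  if (!length(snapshots)) return(structure(list(), class = "trial_decisions"))
  Ns <- vapply(snapshots, `[[`, 0L, "N")
  if (is.unsorted(Ns, strictly = TRUE))
    stop("snapshots must be strictly increasing in enrollment", call. = FALSE)
  structure(lapply(snapshots, run_interim, ...), class = "trial_decisions")
}

#' @export
print.trial_decisions <- function(x, ...) {
  for (d in x) print(d)
  invisible(x)
}
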
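#' Read a blinded counts table
#'
#' Reads a delimited text table with columns `ae`, `y`, `n` (one row per
#' adverse event; `n` is the shared enrollment total) and validates it. When
#' an AE specification is supplied the rows are reordered to match it and
#' unknown or missing events raise an error.
#'
#' @param path file path (CSV by default).
#' @param aes optional [ae_spec()] to align against.
#' @param sep field separator.
#' @return A [blinded_counts()] object.
#' @export
read_blinded_table <- function(path, aes = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("ae", "y", "n")
  if (!all(need %in% names(df)))
    stop("blinded table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(unique(df$n)) != 1L)
    stop("all events must share one enrollment total N", call. = FALSE)
  if (!is.null(aes)) {
    m <- match(aes$name, df$ae)
    if (anyNA(m))
      stop("missing events in blinded table: ",
           paste(aes$name[is.na(m)], collapse = ", "), call. = FALSE)
    df <- df[m, , drop = FALSE]
  }
  blinded_counts(df$ae, df$y, unique(df$n))
}

#' Read an unblinded counts table
#'
#' Reads a tidy delimited table with columns `ae`, `arm`, `dose`, `n`, `y`
#' (one row per event and arm). When a design is supplied, arm labels are
#' checked and rows are normalized to the design's arm order (control
#' first); a table missing the control arm errors.
#'
#' @param path file path.
#' @param design optional [trial_design()] to align against.
#' @param sep field separator.
#' @return An [unblinded_counts()] object.
#' @export
read_unblinded_table <- function(path, design = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("ae", "arm", "dose", "n", "y")
  if (!all(need %in% names(df)))
    stop("unblinded table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(design)) {
    bad <- setdiff(unique(df$arm), design$label)
    if (length(bad))
      stop("unknown arm label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    missing_arms <- setdiff(design$label, unique(df$arm))
    if (length(missing_arms))
      stop("arms missing from unblinded table: ",
           paste(missing_arms, collapse = ", "), call. = FALSE)
    df <- df[order(match(df$ae, unique(df$ae)),
                   match(df$arm, design$label)), , drop = FALSE]
  }
  unblinded_counts(df$ae, df$arm, df$dose, df$n, df$y)
}

#' Write and re-read analysis reports
#'
#' `write_report()` serializes a stage-1 fit, stage-2 fit, interim decision
#' or operating-characteristic result to a structured JSON report carrying
#' the package version, the decision policy (with its named label), seeds
#' and MCMC settings, all probabilities at full precision plus 2-decimal
#' presentation copies, and any sampler warnings. A report of a run that
#' flagged nothing contains no stage-2 section. `read_report()` reads it
#' back as a list.
#'
#' @param x a `blinded_safety`, `unblinded_safety`, `interim_decision` or
#'   `oc_result` object.
#' @param path output path.
#' @return `write_report()` returns `path` invisibly.
#' @export
write_report <- function(x, path) {
  env <- list(tool = "aesignal",
              version = as.character(utils::packageVersion("aesignal")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  policy_block <- function(p)
    list(P_crit1 = p$P_crit1, P_crit2 = p$P_crit2, label = p$label)
  ctrl_block <- function(ct) if (is.null(ct)) NULL else
    list(draws = ct$draws, burn_in = ct$burn_in, chains = ct$chains,
         seed = ct$seed)
  rounded <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], round, 2)
    df
  }
  body <-
    if (inherits(x, "blinded_safety")) {
      list(kind = "stage1", model = x$model, policy = policy_block(x$policy),
           mcmc = ctrl_block(x$draws$control),
           results = x$table, results_rounded = rounded(x$table),
           warning = isTRUE(x$warning))
    } else if (inherits(x, "unblinded_safety")) {
      list(kind = "stage2", policy = policy_block(x$policy),
           mcmc = ctrl_block(if (isTRUE(x$joint)) x$draws$control else
                               x$draws[[1]]$control),
           results = x$table, results_rounded = rounded(x$table),
           warning = isTRUE(x$warning))
    } else if (inherits(x, "interim_decision")) {
      out <- list(kind = "interim", interim = x$interim,
                  policy = policy_block(x$policy),
                  stage1 = x$stage1$table,
                  decisions = x$table, decisions_rounded = rounded(x$table))
      if (!is.null(x$stage2)) out$stage2 <- x$stage2$table
      out
    } else if (inherits(x, "oc_result")) {
      list(kind = "oc",
           scenario = if (!is.null(x$spec)) x$spec$scenario else "custom",
           P_crit1 = x$P_crit1, P_crit2 = x$P_crit2,
           replicates = x$replicates, seed = x$seed,
           model = x$model, mcmc = ctrl_block(x$control),
           per_ae = x$per_ae, per_ae_rounded = rounded(x$per_ae),
           familywise = x$familywise, decision_log = x$log,
           n_nonconverged = x$n_nonconverged)
    } else stop("no report writer for this object", call. = FALSE)
  jsonlite::write_json(c(env, body), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write and read the monitoring configuration
#'
#' Serializes the full analysis configuration — trial design (arms with
#' label, dose, n), AE specification, hyperparameters of both stages,
#' decision policy and MCMC settings — to a YAML file, and reads it back
#' into the same objects. Round-tripping preserves all fields exactly.
#'
#' @param design a [trial_design()].
#' @param aes an [ae_spec()].
#' @param hp_blinded,hp_unblinded hyperparameter objects.
#' @param policy a [decision_policy()].
#' @param control an [mcmc_control()].
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a list with elements `design`, `aes`, `hp_blinded`,
#'   `hp_unblinded`, `policy`, `control`.
#' @export
write_config <- function(design, aes, path,
                         hp_blinded = blinded_hyperparams(),
                         hp_unblinded = unblinded_hyperparams(),
                         policy = decision_policy(),
                         control = mcmc_control()) {
  cfg <- list(
    design = list(arms = lapply(seq_len(nrow(design)), function(i)
                    list(label = design$label[i], dose = design$dose[i],
                         n = design$n[i])),
                  control = design$label[design$control],
                  q_c = attr(design, "q_c")),
    aes = lapply(seq_len(nrow(aes)), function(j)
      list(name = aes$name[j], pi_M = aes$pi_M[j],
           flat_dose_effect = aes$flat_dose_effect[j])),
    hyperparams = list(blinded = unclass(hp_blinded),
                       unblinded = unclass(hp_unblinded)),
    policy = list(P_crit1 = policy$P_crit1, P_crit2 = policy$P_crit2),
    mcmc = list(draws = control$draws, burn_in = control$burn_in,
                chains = control$chains, seed = control$seed))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  arms <- cfg$design$arms
  design <- trial_design(
    label = vapply(arms, `[[`, "", "label"),
    dose = vapply(arms, function(a) as.numeric(a$dose), 0),
    n = vapply(arms, function(a) as.integer(a$n), 0L),
    control = cfg$design$control, q_c = cfg$design$q_c)
  aes <- ae_spec(
    name = vapply(cfg$aes, `[[`, "", "name"),
    pi_M = vapply(cfg$aes, function(a) as.numeric(a$pi_M), 0),
    flat_dose_effect = vapply(cfg$aes, function(a)
      isTRUE(a$flat_dose_effect), TRUE))
  hb <- cfg$hyperparams$blinded; hu <- cfg$hyperparams$unblinded
  mc <- cfg$mcmc
  list(design = design, aes = aes,
       hp_blinded = do.call(blinded_hyperparams, hb),
       hp_unblinded = do.call(unblinded_hyperparams, hu),
       policy = do.call(decision_policy, cfg$policy),
       control = mcmc_control(draws = mc$draws, burn_in = mc$burn_in,
                              chains = mc$chains %||% 1L, seed = mc$seed))
}

#' Emit the case-study fixture files
#'
#' Writes the eight-arm case-study configuration plus example blinded and
#' unblinded counts tables (counts simulated at the expected rates) into a
#' directory, as a starting point for command-line use.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the example counts.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- hobit_design(); aes <- hobit_aes()
  cfg <- file.path(dir, "config.yaml")
  write_config(design, aes, cfg)
  sim <- simulate_trial(scenario_spec("I", aes), aes, design, seed = seed)
  bl <- file.path(dir, "blinded.csv"); ub <- file.path(dir, "unblinded.csv")
  utils::write.csv(as.data.frame(sim$blinded), bl, row.names = FALSE)
  utils::write.csv(as.data.frame(sim$unblinded), ub, row.names = FALSE)
  invisible(c(config = cfg, blinded = bl, unblinded = ub))
}
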
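#' Configure a replication study
#'
#' The full simulation design: a 1000-item, five-attribute bank, a 1000-
#' examinee calibration sample, a 2 x 2 grid of conditions (test length 21
#' or 25 items by 5 or 10 panels), a 0.90 reliability target for every
#' attribute, and a number of replications. The default replication count is
#' scaled to 10 (the original design uses 100; pass `replications = 100` to
#' reproduce it in full).
#'
#' @param k Number of attributes.
#' @param bank_size Items per bank.
#' @param n_examinees Calibration-sample size.
#' @param test_lengths,n_panels Condition levels; their cross product forms
#'   the condition grid.
#' @param replications Replications per condition.
#' @param target Target attribute reliability.
#' @param seed Master seed; every bank, sample and assembly sub-seed is
#'   derived from it deterministically.
#' @param rasch Fit Rasch difficulties in the per-replication evaluation?
#' @param prop_enemy Proportion of enemy items in each generated bank.
#' @return A `cdmst_config` list.
#' @export
study_config <- function(k = 5, bank_size = 1000, n_examinees = 1000,
                         test_lengths = c(21, 25), n_panels = c(5, 10),
                         replications = 10, target = 0.9, seed = 1,
                         rasch = FALSE, prop_enemy = 0.02) {
  stopifnot(k >= 1, bank_size >= 1, n_examinees >= 1, replications >= 1,
            length(test_lengths) >= 1, length(n_panels) >= 1)
  conditions <- expand.grid(test_length = test_lengths, n_panels = n_panels,
                            KEEP.OUT.ATTRS = FALSE)
  conditions$condition <- paste0(conditions$test_length, "items_",
                                 conditions$n_panels, "panels")
  structure(list(k = k, bank_size = bank_size, n_examinees = n_examinees,
                 conditions = as_tibble(conditions),
                 replications = replications, target = target, seed = seed,
                 rasch = rasch, prop_enemy = prop_enemy),
            class = "cdmst_config")
}

#' Run the replication study
#'
#' Executes the full pipeline for every condition and replication: generate
#' a fresh item bank and calibration sample (sub-seeded from the master
#' seed), assemble the panels with the NWADH engine, and evaluate them
#' (reliability deviations, constraint violations, pathway score
#' statistics). A replication whose assembly is infeasible is recorded in
#' `$failures` and the study continues.
#'
#' @param config A [study_config()].
#' @param replications Optional per-condition replication counts (recycled
#'   over conditions), overriding `config$replications`.
#' @param progress Print one line per replication?
#' @return A `cdmst_study` list with tibbles `deviations`, `violations`,
#'   `panel_stats`, `pathway_stats`, `failures`, plus the `config`.
#' @export
run_study <- function(config, replications = NULL, progress = FALSE) {
  conds <- config$conditions
  reps <- rep_len(if (is.null(replications)) config$replications
                  else replications, nrow(conds))
  dev <- list(); viol <- list(); ps <- list(); pws <- list(); fails <- list()
  for (ci in seq_len(nrow(conds))) {
    spec <- test_spec(n_attributes = config$k,
                      test_length = conds$test_length[ci],
                      n_panels = conds$n_panels[ci],
                      target = config$target,
                      calibration_n = config$n_examinees)
    for (r in seq_len(reps[ci])) {
      if (progress) {
        message("condition ", conds$condition[ci], " replication ", r)
      }
      res <- tryCatch(
        run_replication(config, spec, derive_seed(config$seed, ci, r)),
        cdmst_infeasible_error = function(e) e)
      tag <- tibble(condition = conds$condition[ci],
                    test_length = conds$test_length[ci],
                    n_panels = conds$n_panels[ci], replication = r)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1]] <- tibble(tag, message = conditionMessage(res))
        next
      }
      dev[[length(dev) + 1]] <- tibble(tag, res$reliability)
      viol[[length(viol) + 1]] <- tibble(tag, res$violations)
      ps[[length(ps) + 1]] <- tibble(tag, res$panel_stats)
      pws[[length(pws) + 1]] <- tibble(tag, res$pathway_stats)
    }
  }
  structure(list(deviations = dplyr::bind_rows(dev),
                 violations = dplyr::bind_rows(viol),
                 panel_stats = dplyr::bind_rows(ps),
                 pathway_stats = dplyr::bind_rows(pws),
                 failures = dplyr::bind_rows(fails),
                 config = config),
            class = "cdmst_study")
}

run_replication <- function(config, spec, seed) {
  bank <- simulate_item_bank(config$bank_size, config$k,
                             seed = derive_seed(seed, 1),
                             prop_enemy = config$prop_enemy)
  bank <- bin_difficulty(bank)
  states <- simulate_knowledge_states(config$n_examinees, config$k,
                                      derive_seed(seed, 2))
  responses <- simulate_responses(bank, states, derive_seed(seed, 3))
  panels <- assemble_panels(bank, spec,
                            calibration = list(states = states,
                                               responses = responses))
  ev <- evaluate_panels(panels, bank, rasch = config$rasch)
  ev[c("reliability", "violations", "panel_stats", "pathway_stats")]
}

#' Overall constraint-violation rate of a study
#'
#' Summarizes the non-statistical constraint violations across conditions.
#' Under the `"condition"` accounting (default) a constraint category counts
#' as violated within a condition when any primary pathway of any panel of a
#' replication violates it; the denominator is categories x conditions
#' (16 x 4 = 64 for the default design) and rates are averaged over
#' replications. The `"pathway"` accounting keeps pathways separate
#' (denominator categories x pathways x conditions).
#'
#' @param study A `cdmst_study`.
#' @param accounting `"condition"` or `"pathway"`.
#' @return Violation rate in percent.
#' @export
violation_rate <- function(study, accounting = c("condition", "pathway")) {
  accounting <- match.arg(accounting)
  v <- study$violations
  if (nrow(v) == 0) return(NA_real_)
  keys <- if (accounting == "condition") {
    c("condition", "replication", "group", "category")
  } else {
    c("condition", "replication", "pathway", "group", "category")
  }
  cell <- dplyr::summarise(dplyr::group_by(v, dplyr::across(dplyr::all_of(keys))),
                           violated = as.integer(any(violated > 0)),
                           .groups = "drop")
  per_rep <- dplyr::summarise(
    dplyr::group_by(cell, .data$replication),
    rate = mean(.data$violated), .groups = "drop")
  100 * mean(per_rep$rate)
}

#' Table-style pathway report of a study
#'
#' Cross-panel pathway statistics (CD difficulty, expected number-correct
#' score, Cronbach's alpha, and Rasch difficulty when fitted) averaged over
#' replications, one row per condition x pathway.
#'
#' @param study A `cdmst_study`.
#' @return A tibble.
#' @export
pathway_report <- function(study) {
  num <- names(study$pathway_stats)
  num <- setdiff(num[vapply(study$pathway_stats, is.numeric, logical(1))],
                 c("test_length", "n_panels", "replication"))
  dplyr::summarise(
    dplyr::group_by(study$pathway_stats, .data$condition, .data$pathway),
    dplyr::across(dplyr::all_of(num), mean),
    .groups = "drop")
}

#' @export
print.cdmst_study <- function(x, ...) {
  cat("<cdmst_study> ", nrow(x$config$conditions), " condition(s), ",
      length(unique(x$deviations$replication)), " replication(s)\n", sep = "")
  if (nrow(x$deviations)) {
    cat("max |D_ik|: ", round(max(abs(x$deviations$deviation)), 4), "\n",
        sep = "")
    cat("violation rate (condition accounting): ",
        round(violation_rate(x), 2), "%\n", sep = "")
  }
  if (nrow(x$failures)) {
    cat(nrow(x$failures), "failed replication(s)\n")
  }
  invisible(x)
}
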
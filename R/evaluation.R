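#' Reliability deviations from target
#'
#' `D_ik = R_ik - T_ik`: the elementwise difference between observed and
#' target attribute reliability, the primary statistical evaluation
#' criterion. Sign is preserved (negative = under target).
#'
#' @param observed Numeric vector/matrix of observed reliabilities `R_ik`.
#' @param targets Targets `T_ik`, recycled to match.
#' @return Object shaped like `observed` with the elementwise differences.
#' @export
reliability_deviation <- function(observed, targets) {
  if (length(targets) != 1 && length(targets) != length(observed) &&
      (!is.matrix(observed) || length(targets) != ncol(observed))) {
    abort("targets must be scalar or aligned with observed.",
          class = "cdmst_input_error")
  }
  if (is.matrix(observed)) {
    sweep(observed, 2, rep_len(targets, ncol(observed)), "-")
  } else {
    observed - rep_len(targets, length(observed))
  }
}

#' Count non-statistical constraint violations of a pathway
#'
#' Applies every constraint category to a pathway's item set: a
#' minimum-count category is violated when the pathway holds fewer items of
#' that category than `z_min` (or more than a finite `z_max`); the enemy
#' constraint is violated when any enemy group contributes two or more
#' items. The total `V` is the sum of the per-category indicators.
#'
#' @param pathway_bank Item-bank rows of the pathway's items.
#' @param constraints Constraint tibble as from [default_constraints()].
#' @return A tibble with one row per constraint category: `group`,
#'   `category`, `count`, `z_min`, `z_max`, `violated` (0/1).
#' @export
count_violations <- function(pathway_bank, constraints) {
  weighted <- constraints[constraints$group != "enemy", ]
  v <- constraint_indicators(pathway_bank, constraints)
  counts <- colSums(v)
  out <- weighted
  out$count <- as.numeric(counts)
  out$violated <- as.integer(counts < weighted$z_min |
                               (is.finite(weighted$z_max) &
                                  counts > weighted$z_max))
  if (any(constraints$group == "enemy")) {
    en <- pathway_bank$enemy_group
    n_pairs <- sum(table(en[!is.na(en)]) >= 2)
    enemy_row <- constraints[constraints$group == "enemy", ][1, ]
    enemy_row$count <- n_pairs
    enemy_row$violated <- as.integer(n_pairs > 0)
    out <- dplyr::bind_rows(out, enemy_row)
  }
  as_tibble(out)
}

#' Expected number-correct score
#'
#' For each examinee, the sum over the administered items of the true
#' correct-response probabilities `P_j(alpha_e)`: the model-implied expected
#' raw score on the item set.
#'
#' @param bank_rows Item-bank rows of the administered items.
#' @param states Knowledge-state matrix (`N` by `K`).
#' @return Numeric vector of expected scores, one per examinee.
#' @export
expected_number_correct <- function(bank_rows, states) {
  states <- check_binary_matrix(states, "Knowledge-state matrix")
  sp <- bank_state_probs(bank_rows)
  idx <- states %*% 2L^(seq_len(ncol(states)) - 1L) + 1L
  rowSums(sp[idx, , drop = FALSE])
}

#' Cronbach's alpha
#'
#' Classical internal-consistency coefficient
#' `alpha = J/(J-1) * (1 - sum(item variances) / total-score variance)`.
#'
#' @param responses `N` by `J` score matrix (binary or polytomous).
#' @return Scalar alpha (at most 1).
#' @export
cronbach_alpha <- function(responses) {
  x <- as.matrix(responses)
  if (ncol(x) < 2 || nrow(x) < 2) {
    abort("Cronbach's alpha needs at least 2 items and 2 examinees.",
          class = "cdmst_input_error")
  }
  total_var <- var(rowSums(x))
  if (total_var <= 0) {
    abort("Zero total-score variance: alpha is undefined.",
          class = "cdmst_degenerate_error")
  }
  j <- ncol(x)
  (j / (j - 1)) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Correlation between the CD difficulty index and Rasch difficulty
#'
#' Pearson correlation between `Diff_j` (mean correct-response probability
#' over all knowledge states) and Rasch-estimated difficulty `b_j` on the
#' same items. The expected sign is negative — a high `Diff_j` marks an easy
#' item while a high `b_j` marks a hard one — so the magnitude is reported
#' alongside the signed estimate.
#'
#' @param diff CD difficulty vector.
#' @param b Rasch difficulty vector for the same items.
#' @return A one-row tibble: `estimate` (signed r), `magnitude`,
#'   `statistic`, `p.value`, `n`.
#' @export
difficulty_correlation <- function(diff, b) {
  if (length(diff) != length(b)) {
    abort("diff and b must cover the same items.", class = "cdmst_input_error")
  }
  if (var(diff) <= 0 || var(b) <= 0) {
    abort("Zero variance in a difficulty vector.",
          class = "cdmst_degenerate_error")
  }
  ct <- cor.test(diff, b, method = "pearson")
  tibble(estimate = unname(ct$estimate),
         magnitude = abs(unname(ct$estimate)),
         statistic = unname(ct$statistic),
         p.value = ct$p.value,
         n = length(diff))
}

#' Evaluate assembled panels
#'
#' Computes the full evaluation suite for a set of assembled panels on a
#' calibration sample: per-pathway observed attribute reliabilities and their
#' deviations from target, per-pathway constraint-violation counts, and
#' pathway score statistics at two granularities — per panel, and pooled
#' across the panels of the run (the cross-panel item set is what makes the
#' expected number-correct means and Cronbach's alpha comparable to
#' condition-level summaries).
#'
#' @param panels A `cdmst_panels` object from [assemble_panels()].
#' @param bank The item bank the panels were assembled from.
#' @param calibration Optional list with `states` and `responses`; defaults
#'   to the calibration sample attached to `panels`.
#' @param rasch Fit a Rasch model (one joint fit on the union of pathway
#'   items) and add per-pathway mean/SD of `b`? Default `FALSE`.
#' @return A list of class `cdmst_evaluation` with tibbles `reliability`
#'   (panel x pathway x attribute), `violations` (panel x pathway x
#'   category), `panel_stats`, and `pathway_stats` (cross-panel pooled:
#'   difficulty, expected score, alpha, optionally Rasch difficulty).
#' @export
evaluate_panels <- function(panels, bank, calibration = NULL, rasch = FALSE) {
  spec <- attr(panels, "spec")
  if (is.null(calibration)) calibration <- attr(panels, "calibration")
  if (is.null(calibration)) {
    abort("No calibration sample available.", class = "cdmst_input_error")
  }
  states <- calibration$states
  responses <- as_response_matrix(calibration$responses)
  targets <- spec$targets
  labels <- c("easy", "medium", "hard")
  combos <- expand.grid(panel = unique(panels$panel), pathway = labels,
                        stringsAsFactors = FALSE)

  rel <- list(); viol <- list(); pstats <- list()
  for (i in seq_len(nrow(combos))) {
    p <- combos$panel[i]; lab <- combos$pathway[i]
    ids <- pathway_items(panels, p, lab)
    rows <- bank[match(ids, bank$item_id), ]
    x <- responses[, as.character(ids), drop = FALSE]
    u <- attribute_reliability(x, rows)
    rel[[i]] <- tibble(panel = p, pathway = lab,
                       attribute = u$attribute,
                       reliability = u$reliability,
                       target = targets,
                       deviation = u$reliability - targets)
    cv <- count_violations(rows, spec$constraints)
    viol[[i]] <- tibble(panel = p, pathway = lab, cv)
    score <- expected_number_correct(rows, states)
    pstats[[i]] <- tibble(
      panel = p, pathway = lab, n_items = length(ids),
      diff_mean = mean(rows$diff), diff_sd = stats::sd(rows$diff),
      score_mean = mean(score), score_sd = stats::sd(score),
      alpha = cronbach_alpha(x))
  }

  pooled <- lapply(labels, function(lab) {
    ids <- unlist(lapply(unique(panels$panel),
                         function(p) pathway_items(panels, p, lab)))
    ids <- unique(ids)
    rows <- bank[match(ids, bank$item_id), ]
    x <- responses[, as.character(ids), drop = FALSE]
    score <- expected_number_correct(rows, states)
    tibble(pathway = lab, n_items = length(ids),
           diff_mean = mean(rows$diff), diff_sd = stats::sd(rows$diff),
           score_mean = mean(score), score_sd = stats::sd(score),
           alpha = cronbach_alpha(x))
  })
  pathway_stats <- dplyr::bind_rows(pooled)

  if (rasch) {
    all_ids <- unique(unlist(lapply(unique(panels$panel), function(p) {
      unlist(lapply(labels, function(lab) pathway_items(panels, p, lab)))
    })))
    fit <- rasch_calibrate(responses[, as.character(all_ids), drop = FALSE])
    b_map <- stats::setNames(fit$items$b, fit$items$item)
    pathway_stats$rasch_mean <- NA_real_
    pathway_stats$rasch_sd <- NA_real_
    for (lab in labels) {
      ids <- unique(unlist(lapply(unique(panels$panel),
                                  function(p) pathway_items(panels, p, lab))))
      b <- b_map[as.character(ids)]
      pathway_stats$rasch_mean[pathway_stats$pathway == lab] <-
        mean(b, na.rm = TRUE)
      pathway_stats$rasch_sd[pathway_stats$pathway == lab] <-
        stats::sd(b, na.rm = TRUE)
    }
  }

  structure(list(reliability = dplyr::bind_rows(rel),
                 violations = dplyr::bind_rows(viol),
                 panel_stats = dplyr::bind_rows(pstats),
                 pathway_stats = pathway_stats,
                 spec = spec),
            class = "cdmst_evaluation")
}

#' @export
print.cdmst_evaluation <- function(x, ...) {
  cat("<cdmst_evaluation>\n")
  cat("max |D_ik|:", round(max(abs(x$reliability$deviation)), 4), "\n")
  cat("violated constraint categories:",
      sum(x$violations$violated), "of", nrow(x$violations), "\n")
  print(x$pathway_stats)
  invisible(x)
}
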
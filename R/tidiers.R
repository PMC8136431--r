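# broom-style tidiers for the package's fitted/assembled objects.

#' Tidy a Rasch fit
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @return A tibble with one row per item: `item`, `b`, `p_value`.
#' @method tidy rasch_fit
#' @export
tidy.rasch_fit <- function(x, ...) {
  x$items
}

#' One-row summary of a Rasch fit
#'
#' @param x A `rasch_fit`.
#' @param ... Unused.
#' @method glance rasch_fit
#' @export
glance.rasch_fit <- function(x, ...) {
  tibble(n_items = nrow(x$items), logLik = x$loglik,
         iterations = x$iterations, converged = x$converged,
         n_dropped = length(x$dropped))
}

#' Tidy assembled panels
#'
#' @param x A `cdmst_panels`.
#' @param ... Unused.
#' @return The panel/stage/pathway/item tibble without attributes.
#' @method tidy cdmst_panels
#' @export
tidy.cdmst_panels <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of assembled panels
#'
#' @param x A `cdmst_panels`.
#' @param ... Unused.
#' @method glance cdmst_panels
#' @export
glance.cdmst_panels <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble(n_panels = length(unique(x$panel)),
         n_items = nrow(x),
         n_unique_items = length(unique(x$item_id)),
         n_reused = attr(x, "reused_items") %||% NA_integer_,
         test_length = spec$test_length,
         n_attributes = spec$n_attributes)
}

#' Tidy a study: per-replication reliability deviations
#'
#' @param x A `cdmst_study`.
#' @param ... Unused.
#' @method tidy cdmst_study
#' @export
tidy.cdmst_study <- function(x, ...) {
  x$deviations
}

#' One-row summary of a replication study
#'
#' @param x A `cdmst_study`.
#' @param ... Unused.
#' @return A tibble with the headline study metrics: maximum absolute
#'   reliability deviation, mean reliability, condition-level violation
#'   rate (percent), minimum cross-panel Cronbach's alpha, and failure
#'   count.
#' @method glance cdmst_study
#' @export
glance.cdmst_study <- function(x, ...) {
  tibble(
    n_conditions = nrow(x$config$conditions),
    n_replications = length(unique(x$deviations$replication)),
    max_abs_deviation = max(abs(x$deviations$deviation)),
    mean_reliability = mean(x$deviations$reliability),
    violation_rate_pct = violation_rate(x),
    min_alpha = min(x$pathway_stats$alpha),
    n_failures = nrow(x$failures))
}
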
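# On-disk interchange: item banks and responses as CSV, test specifications
# as YAML, assembled panels as JSON.

#' Write / read an item bank as CSV
#'
#' One row per item: `item_id`, the Q-matrix columns, a JSON-encoded
#' reduced-pattern probability table (variable width across items), the
#' difficulty index and the categorical features.
#'
#' @param bank Item-bank tibble.
#' @param path File path.
#' @return `write_item_bank()` returns `path` invisibly; `read_item_bank()`
#'   returns the bank tibble.
#' @export
write_item_bank <- function(bank, path) {
  out <- bank
  out$prob <- vapply(bank$prob, function(p) {
    as.character(jsonlite::toJSON(p, digits = NA))
  }, character(1))
  out$diff_bin <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$prob <- lapply(raw$prob, function(s) jsonlite::fromJSON(s))
  bank <- as_tibble(raw)
  bank$enemy_group <- as.integer(bank$enemy_group)
  bank
}

#' Write / read a binary response matrix as CSV
#'
#' `N` rows by `J` columns of 0/1 with item ids as header.
#'
#' @param responses Response matrix.
#' @param path File path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  storage.mode(x) <- "integer"
  x
}

#' Write / read a test specification as YAML
#'
#' @param spec A [test_spec()].
#' @param path File path.
#' @export
write_test_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$constraints <- lapply(seq_len(nrow(spec$constraints)), function(i) {
    row <- as.list(spec$constraints[i, ])
    row$z_max <- if (is.finite(row$z_max)) row$z_max else ".inf"
    row
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_test_spec
#' @export
read_test_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  cons <- dplyr::bind_rows(lapply(obj$constraints, function(row) {
    row$z_max <- if (identical(row$z_max, ".inf")) Inf else as.numeric(row$z_max)
    as_tibble(row)
  }))
  test_spec(n_attributes = obj$n_attributes, test_length = obj$test_length,
            n_panels = obj$n_panels, target = obj$targets,
            constraints = cons, stage_sizes = obj$stage_sizes,
            pathway_order = obj$pathway_order,
            content_weight_form = obj$content_weight_form,
            calibration_n = obj$calibration_n)
}

#' Write / read assembled panels as JSON
#'
#' Layout: one object per panel with the shared stage-1 item ids and, per
#' pathway label, the stage-2 and stage-3 item ids.
#'
#' @param panels A `cdmst_panels` tibble.
#' @param path File path.
#' @export
write_panels <- function(panels, path) {
  out <- lapply(unique(panels$panel), function(p) {
    sub <- panels[panels$panel == p, ]
    list(
      panel_id = p,
      stage1 = sub$item_id[sub$stage == 1],
      pathways = stats::setNames(lapply(c("easy", "medium", "hard"), function(lab) {
        list(stage2 = sub$item_id[sub$pathway == lab & sub$stage == 2],
             stage3 = sub$item_id[sub$pathway == lab & sub$stage == 3])
      }), c("easy", "medium", "hard"))
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- list()
  for (pn in obj) {
    rows[[length(rows) + 1]] <- tibble(
      panel = pn$panel_id, stage = 1L, pathway = "shared",
      position = seq_along(pn$stage1),
      item_id = vapply(pn$stage1, as.integer, integer(1)))
    for (lab in names(pn$pathways)) {
      for (sg in c("stage2", "stage3")) {
        ids <- vapply(pn$pathways[[lab]][[sg]], as.integer, integer(1))
        rows[[length(rows) + 1]] <- tibble(
          panel = pn$panel_id, stage = as.integer(substr(sg, 6, 6)),
          pathway = lab, position = seq_along(ids), item_id = ids)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cdmst_panels", class(out))
  out
}
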
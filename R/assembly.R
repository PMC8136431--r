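#' Default non-statistical constraint table
#'
#' The constraint specification used by the simulation design: four content
#' categories (at least 4 items each), two item types (at least 8 each), four
#' answer keys (at least 4 each), a minimum of 3 items measuring each
#' attribute, and an enemy-item constraint of 0 (no two items of the same
#' enemy group may co-occur in a pathway; enforced as a hard candidate
#' filter).
#'
#' @param k Number of attributes.
#' @param z_min_content,z_min_type,z_min_answer,z_min_attribute Minimum counts
#'   per category; defaults match the 21/25-item designs.
#' @return A tibble with columns `group`, `category`, `z_min`, `z_max`.
#' @export
default_constraints <- function(k = 5, z_min_content = 4, z_min_type = 8,
                                z_min_answer = 4, z_min_attribute = 3) {
  tibble(
    group = c(rep("content", 4), rep("item_type", 2), rep("answer_key", 4),
              rep("attribute", k), "enemy"),
    category = c(1:4, 1:2, 1:4, seq_len(k), 1L),
    z_min = c(rep(z_min_content, 4), rep(z_min_type, 2),
              rep(z_min_answer, 4), rep(z_min_attribute, k), 0),
    z_max = c(rep(Inf, 10 + k), 0)
  )
}

#' Build a multistage-test specification
#'
#' Collects everything the assembly engine needs: the per-attribute
#' reliability targets, the three-stage structure (stage 1 holds one
#' single-attribute item per attribute; the remaining length is split evenly
#' between stages 2 and 3, so a 21-item test has stages of 5/8/8 items and a
#' 25-item test 5/10/10), the number of parallel panels, and the
#' non-statistical constraint table.
#'
#' @param n_attributes Number of attributes `K`.
#' @param test_length Total pathway length (items across the three stages).
#' @param n_panels Number of parallel panels to assemble.
#' @param target Target attribute reliability (scalar, recycled) or length-`K`
#'   vector.
#' @param constraints Constraint tibble as from [default_constraints()].
#' @param stage_sizes Optional integer vector of three stage sizes; derived
#'   from `test_length` when `NULL`.
#' @param pathway_order Order in which the three primary pathways of a panel
#'   are assembled from the shared pool.
#' @param content_weight_form `"corrected"` (sum over constraints with
#'   complement indicator) or `"printed"` (the `1 + v` variant).
#' @param calibration_n Size of the simulated calibration sample used to
#'   evaluate reliabilities during assembly.
#' @return A `cdmst_spec` list.
#' @examples
#' spec <- test_spec(test_length = 21, n_panels = 5)
#' spec$stage_sizes
#' @export
test_spec <- function(n_attributes = 5, test_length = 21, n_panels = 5,
                      target = 0.9,
                      constraints = default_constraints(n_attributes),
                      stage_sizes = NULL,
                      pathway_order = c("hard", "medium", "easy"),
                      content_weight_form = c("corrected", "printed"),
                      calibration_n = 1000) {
  content_weight_form <- match.arg(content_weight_form)
  targets <- rep_len(target, n_attributes)
  if (any(targets <= 0 | targets > 1)) {
    abort("Reliability targets must lie in (0, 1].",
          class = "cdmst_input_error")
  }
  if (is.null(stage_sizes)) {
    rem <- test_length - n_attributes
    if (rem < 2) abort("test_length too short for three stages.",
                       class = "cdmst_input_error")
    stage_sizes <- c(n_attributes, floor(rem / 2), ceiling(rem / 2))
  }
  if (sum(stage_sizes) != test_length) {
    abort("stage_sizes must sum to test_length.", class = "cdmst_input_error")
  }
  weighted <- constraints[constraints$group != "enemy", ]
  # feasibility: categories within a group partition the items (an item bears
  # exactly one content category, one type, one answer key), so the binding
  # check is the per-group sum of minimums
  per_group <- tapply(weighted$z_min, weighted$group, sum)
  if (any(per_group[names(per_group) != "attribute"] > test_length)) {
    warn("A constraint group's minimum counts exceed the test length; the design is infeasible as stated.")
  }
  structure(
    list(n_attributes = n_attributes, test_length = test_length,
         n_panels = n_panels, targets = targets, stage_sizes = stage_sizes,
         constraints = constraints, pathway_order = pathway_order,
         content_weight_form = content_weight_form,
         calibration_n = calibration_n),
    class = "cdmst_spec")
}

#' @export
print.cdmst_spec <- function(x, ...) {
  cat("<cdmst_spec> ", x$test_length, "-item pathways (stages ",
      paste(x$stage_sizes, collapse = "/"), "), ", x$n_panels,
      " panel(s), K = ", x$n_attributes,
      ", target reliability ", paste(unique(x$targets), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Item-by-constraint indicator matrix
#'
#' `v_ig = 1` when item `i` bears constraint category `g` (its content
#' category, item type, answer key, or a measured attribute). Enemy rows are
#' excluded: the enemy constraint is a hard filter, not a weighted category.
#'
#' @param bank Item-bank tibble.
#' @param constraints Constraint tibble.
#' @return `J` by `G` 0/1 matrix, columns named `group_category`.
#' @export
constraint_indicators <- function(bank, constraints) {
  cons <- constraints[constraints$group != "enemy", ]
  q <- q_matrix(bank)
  v <- vapply(seq_len(nrow(cons)), function(i) {
    g <- cons$group[i]
    cat <- cons$category[i]
    as.integer(switch(g,
      content = bank$content_category == cat,
      item_type = bank$item_type == cat,
      answer_key = bank$answer_key == cat,
      attribute = q[, cat] == 1L,
      abort(paste0("Unknown constraint group: ", g))
    ))
  }, integer(nrow(bank)))
  colnames(v) <- paste(cons$group, cons$category, sep = "_")
  v
}

#' Mean absolute deviation from the reliability targets
#'
#' `d^J = mean_k |T_k - u_k^J|`, the statistical objective the NWADH
#' selection minimizes.
#'
#' @param u Observed attribute reliabilities (length `K`).
#' @param targets Target reliabilities (length `K`).
#' @return Nonnegative scalar.
#' @examples
#' mean_absolute_deviation(c(0.85, 0.7), c(0.9, 0.9)) # 0.125
#' @export
mean_absolute_deviation <- function(u, targets) {
  if (length(u) != length(targets)) {
    abort("u and targets must have equal length.", class = "cdmst_input_error")
  }
  mean(abs(targets - u))
}

#' NWADH priority index
#'
#' Converts candidate deviations into the normalized priority
#' `e_i = 1 - d_i / sum(d)`; the best candidate maximizes `e_i`
#' (equivalently minimizes `d_i`). When every deviation is zero all
#' candidates tie at the limit value `1 - 1/n`.
#'
#' @param d Named vector of candidate deviations `d_i^{J+1}`.
#' @return Vector of priorities, same names.
#' @examples
#' priority_index(c(a = 0.1, b = 0.3)) # 0.75, 0.25
#' @export
priority_index <- function(d) {
  if (length(d) == 0) abort("No candidates.", class = "cdmst_input_error")
  s <- sum(d)
  if (s > 0) 1 - d / s else rep_len(1 - 1 / length(d), length(d))
}

#' Update constraint weights from current counts
#'
#' Dynamic NWADH weights: a category whose selected-count has reached its
#' maximum gets weight 1, a category still below its minimum gets weight 2
#' (it needs items), and a category between its bounds gets the satisfied
#' baseline weight 1.
#'
#' @param counts Current per-category counts among the selected items.
#' @param constraints Constraint tibble (enemy rows ignored); `z_min`/`z_max`
#'   aligned with `counts`.
#' @return Numeric weight vector in `{1, 2}`.
#' @export
update_weights <- function(counts, constraints) {
  cons <- constraints[constraints$group != "enemy", ]
  if (length(counts) != nrow(cons)) {
    abort("counts must align with the weighted constraint categories.",
          class = "cdmst_input_error")
  }
  ifelse(is.finite(cons$z_max) & counts >= cons$z_max, 1,
         ifelse(counts < cons$z_min, 2, 1))
}

#' Content-constraint weight of candidate items
#'
#' Aggregates the dynamic category weights into one scalar per candidate:
#' `c_i = sum_g [v_ig W_g + (1 - v_ig) Wbar]` with
#' `Wbar = max(W) - mean(W)`, so candidates bearing under-filled categories
#' are promoted. The `"printed"` form replaces the complement indicator by
#' `(1 + v_ig)`.
#'
#' @param v Indicator matrix (candidates by categories) or a single item's
#'   indicator vector.
#' @param weights Current category weights from [update_weights()].
#' @param form `"corrected"` (default) or `"printed"`.
#' @return Numeric vector of content weights, one per candidate.
#' @examples
#' content_weight(rep(0, 4), weights = c(2, 1, 1, 1)) # 4 * 0.75 = 3
#' @export
content_weight <- function(v, weights, form = c("corrected", "printed")) {
  form <- match.arg(form)
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  g <- length(weights)
  if (ncol(v) != g) {
    abort("Indicator width must match the number of weighted categories.",
          class = "cdmst_input_error")
  }
  wbar <- max(weights) - mean(weights)
  bearing <- as.numeric(v %*% weights)
  n_bearing <- rowSums(v)
  if (form == "corrected") {
    bearing + (g - n_bearing) * wbar
  } else {
    bearing + (g + n_bearing) * wbar
  }
}

#' Constraint-augmented priority index
#'
#' `e_i* = [1 - d_i / sum(d)] + c_i / sum(c)`: the statistical priority plus
#' the normalized content weight. When every content weight is zero the
#' content term is defined as zero for all candidates.
#'
#' @param e Priority index values from [priority_index()].
#' @param c_i Content weights from [content_weight()].
#' @return Vector of `e_i*` values.
#' @export
constrained_priority <- function(e, c_i) {
  if (length(e) != length(c_i)) {
    abort("e and c_i must cover the same candidates.",
          class = "cdmst_input_error")
  }
  s <- sum(c_i)
  if (s > 0) e + c_i / s else e
}

#' Deviation of every candidate item
#'
#' For each candidate, computes `d_i^{J+1}`: the mean absolute deviation from
#' the reliability targets after appending candidate `i` to the already
#' selected items. The posterior over states is updated incrementally with
#' the single new likelihood factor (never refit from scratch), so scanning a
#' 1000-item pool is cheap.
#'
#' @param responses Calibration response matrix covering the whole bank
#'   (columns named by `item_id`).
#' @param bank Item-bank tibble.
#' @param selected Item ids already selected (may be empty).
#' @param candidates Item ids to score.
#' @param targets Length-`K` reliability targets.
#' @param prior Optional prior over states (uniform when `NULL`).
#' @return A tibble with `item_id`, `d` and one reliability column per
#'   attribute (`u1 ...`).
#' @export
candidate_deviations <- function(responses, bank, selected, candidates,
                                 targets, prior = NULL) {
  if (length(candidates) == 0) {
    abort("Empty candidate pool.", class = "cdmst_infeasible_error")
  }
  x <- as_response_matrix(responses)
  sel_bank <- bank[match(selected, bank$item_id), , drop = FALSE]
  w <- posterior_over_states(x[, as.character(selected), drop = FALSE],
                             sel_bank, prior)
  sp <- bank_state_probs(bank)
  ci <- match(candidates, bank$item_id)
  res <- cpp_candidate_deviations(
    unclass(w), attr(w, "states"),
    sp[, ci, drop = FALSE],
    x[, as.character(candidates), drop = FALSE],
    targets)
  u <- t(res$reliability)
  colnames(u) <- paste0("u", seq_len(ncol(u)))
  tibble(item_id = candidates, d = as.numeric(res$d), as_tibble(u))
}

# ---- internal engine ------------------------------------------------------

assembly_precompute <- function(bank, spec, responses) {
  k <- n_attributes(bank)
  if (k != spec$n_attributes) {
    abort("Bank attribute count does not match the specification.",
          class = "cdmst_input_error")
  }
  if (is.null(bank$diff_bin)) bank <- bin_difficulty(bank)
  x <- as_response_matrix(responses)
  if (!is.null(colnames(x))) x <- x[, as.character(bank$item_id), drop = FALSE]
  q <- q_matrix(bank)
  list(
    bank = bank,
    A = state_space(k),
    sp = bank_state_probs(bank),
    X = x,
    V = constraint_indicators(bank, spec$constraints),
    q = q,
    n_measured = rowSums(q),
    attr_single = ifelse(rowSums(q) == 1L, max.col(q), NA_integer_),
    diff = bank$diff,
    bin = as.character(bank$diff_bin),
    enemy = bank$enemy_group,
    mids = bin_midpoints(attr(bin_difficulty(bank), "cut_points"))
  )
}

uniform_w <- function(pre, n) {
  nc <- nrow(pre$A)
  matrix(1 / nc, n, nc)
}

update_w <- function(w, pvec, x) {
  fac <- outer(x, pvec) + outer(1L - x, 1 - pvec)
  w <- w * fac
  w / rowSums(w)
}

select_idx <- function(pre, w, selected_idx, eligible_idx, spec, mid) {
  if (length(eligible_idx) == 0) {
    abort("Empty eligible pool.", class = "cdmst_infeasible_error")
  }
  res <- cpp_candidate_deviations(
    w, pre$A,
    pre$sp[, eligible_idx, drop = FALSE],
    pre$X[, eligible_idx, drop = FALSE],
    spec$targets)
  e <- priority_index(as.numeric(res$d))
  counts <- colSums(pre$V[selected_idx, , drop = FALSE])
  wts <- update_weights(counts, spec$constraints)
  cvec <- content_weight(pre$V[eligible_idx, , drop = FALSE], wts,
                         form = spec$content_weight_form)
  estar <- constrained_priority(e, cvec)
  # ties: closest to the target bin midpoint, then lowest item id
  ord <- order(-estar, abs(pre$diff[eligible_idx] - mid),
               pre$bank$item_id[eligible_idx])
  eligible_idx[ord[1]]
}

# Candidate filter for one selection step. Items already in the current panel
# are never eligible; unused items (pool) are preferred. Items consumed by
# earlier panels become eligible only (a) when no unused item passes the
# difficulty-bin and enemy filters at all, or (b) for reusable items bearing
# a constraint category that is still below its minimum and has no unused
# bearer left — otherwise a late panel would be forced to violate a minimum
# the bank can still satisfy.
eligible_step <- function(pre, pool, base, panel_idx, pathway_idx, spec) {
  base[panel_idx] <- FALSE
  groups <- pre$enemy[pathway_idx]
  groups <- groups[!is.na(groups)]
  if (length(groups)) base <- base & !(pre$enemy %in% groups)
  prim <- base & pool
  if (!any(prim)) return(which(base))
  counts <- colSums(pre$V[pathway_idx, , drop = FALSE])
  cons <- spec$constraints[spec$constraints$group != "enemy", ]
  deficit <- counts < cons$z_min
  if (any(deficit)) {
    supply <- colSums(pre$V[prim, deficit, drop = FALSE])
    starved <- which(deficit)[supply == 0]
    if (length(starved)) {
      bearers <- rowSums(pre$V[, starved, drop = FALSE]) > 0
      return(which(prim | (base & bearers)))
    }
  }
  which(prim)
}

assemble_stage1_idx <- function(pre, pool, spec, panel_idx = integer(0)) {
  k <- spec$n_attributes
  w <- uniform_w(pre, nrow(pre$X))
  chosen <- integer(0)
  reused <- 0L
  for (a in seq_len(k)) {
    base <- !is.na(pre$attr_single) & pre$attr_single == a &
      pre$bin == "medium"
    elig <- eligible_step(pre, pool, base, c(panel_idx, chosen), chosen, spec)
    if (length(elig) == 0) {
      abort(paste0("Infeasible first stage: no single-attribute ",
                   "medium-difficulty item measures attribute ", a, "."),
            class = "cdmst_infeasible_error")
    }
    pick <- select_idx(pre, w, chosen, elig, spec, pre$mids["medium"])
    reused <- reused + !pool[pick]
    w <- update_w(w, pre$sp[, pick], pre$X[, pick])
    chosen <- c(chosen, pick)
  }
  list(idx = chosen, reused = reused)
}

assemble_pathway_idx <- function(pre, pool, spec, stage1_idx, label,
                                 panel_idx = integer(0)) {
  n_items <- sum(spec$stage_sizes[2:3])
  w <- uniform_w(pre, nrow(pre$X))
  for (i in stage1_idx) w <- update_w(w, pre$sp[, i], pre$X[, i])
  pathway <- stage1_idx
  chosen <- integer(0)
  reused <- 0L
  for (step in seq_len(n_items)) {
    elig <- eligible_step(pre, pool, pre$bin == label,
                          c(panel_idx, chosen), pathway, spec)
    if (length(elig) == 0) {
      abort(paste0("Infeasible assembly: the '", label, "' difficulty bin ",
                   "ran out of eligible items at pathway position ",
                   length(chosen) + 1, " (difficulty-bin, enemy and ",
                   "panel-uniqueness filters applied)."),
            class = "cdmst_infeasible_error")
    }
    pick <- select_idx(pre, w, pathway, elig, spec, pre$mids[label])
    reused <- reused + !pool[pick]
    w <- update_w(w, pre$sp[, pick], pre$X[, pick])
    pathway <- c(pathway, pick)
    chosen <- c(chosen, pick)
    pool[pick] <- FALSE
  }
  list(idx = chosen, reused = reused)
}

#' Assemble the shared first-stage module
#'
#' Selects `K` single-attribute items of medium difficulty, one per
#' attribute, by NWADH priority. First-stage items measure exactly one
#' attribute so that every attribute is identified early in the test.
#'
#' @param bank Binned item-bank tibble ([bin_difficulty()]).
#' @param spec A [test_spec()].
#' @param responses Calibration response matrix over the whole bank.
#' @param exclude Item ids already consumed (e.g. by earlier panels).
#' @return Integer vector of selected item ids (length `K`, in attribute
#'   order).
#' @export
assemble_first_stage <- function(bank, spec, responses, exclude = integer(0)) {
  pre <- assembly_precompute(bank, spec, responses)
  pool <- !(bank$item_id %in% exclude)
  bank$item_id[assemble_stage1_idx(pre, pool, spec,
                                   which(!pool))$idx]
}

#' Assemble one primary pathway
#'
#' Greedy NWADH selection of the stage-2 and stage-3 modules of one primary
#' pathway, restricted to the pathway's difficulty bin, seeded from the
#' shared first-stage items. Enemy items of anything already in the pathway
#' are ineligible.
#'
#' @inheritParams assemble_first_stage
#' @param stage1 Item ids of the panel's shared first-stage module.
#' @param label Pathway difficulty label: `"easy"`, `"medium"` or `"hard"`.
#' @return Integer vector of selected item ids (stage-2 items first).
#' @export
assemble_pathway <- function(bank, spec, responses, stage1, label,
                             exclude = integer(0)) {
  pre <- assembly_precompute(bank, spec, responses)
  pool <- !(bank$item_id %in% c(exclude, stage1))
  res <- assemble_pathway_idx(pre, pool, spec,
                              match(stage1, bank$item_id), label,
                              panel_idx = which(!pool))
  bank$item_id[res$idx]
}

#' Select the single best next item
#'
#' One NWADH step: scores every eligible candidate by the
#' constraint-augmented priority `e_i*` (incremental posterior update,
#' dynamic constraint weights) and returns the argmax. Ties are broken by
#' proximity to the target difficulty-bin midpoint, then by lowest item id.
#'
#' @inheritParams candidate_deviations
#' @param spec A [test_spec()].
#' @param target_mid Difficulty value used for tie-breaking (defaults to the
#'   mean candidate difficulty).
#' @return The selected item id.
#' @export
select_next_item <- function(responses, bank, selected, candidates, spec,
                             target_mid = NULL) {
  pre <- assembly_precompute(bank, spec, responses)
  w <- uniform_w(pre, nrow(pre$X))
  sel_idx <- match(selected, bank$item_id)
  for (i in sel_idx) w <- update_w(w, pre$sp[, i], pre$X[, i])
  elig <- match(candidates, bank$item_id)
  groups <- pre$enemy[sel_idx]
  groups <- groups[!is.na(groups)]
  elig <- elig[!(pre$enemy[elig] %in% groups)]
  if (length(elig) == 0) {
    abort("Empty eligible pool after enemy filtering.",
          class = "cdmst_infeasible_error")
  }
  if (is.null(target_mid)) target_mid <- mean(pre$diff[elig])
  bank$item_id[select_idx(pre, w, sel_idx, elig, spec, target_mid)]
}

#' Assemble parallel multistage-test panels
#'
#' Top-down assembly of `n_panels` parallel panels from one calibrated item
#' bank. Each panel gets a shared medium-difficulty first stage (one
#' single-attribute item per attribute) and three primary pathways (easy,
#' medium, hard) whose stage-2/3 modules are filled by greedy NWADH selection
#' within the pathway's difficulty bin, steering the tetrachoric attribute
#' reliabilities toward the specification targets while balancing the
#' non-statistical constraints. Items are never repeated within a panel and
#' no two items of an enemy group co-occur in a pathway. Across panels the
#' engine prefers unused items for exposure control; only when a difficulty
#' bin's unused pool is exhausted (large panel counts on a bank with thin
#' outer bins) may items from earlier panels be reused, and the number of
#' such selections is reported in the `reused_items` attribute (and by
#' [glance()]).
#'
#' @param bank Item-bank tibble (binned automatically when needed).
#' @param spec A [test_spec()].
#' @param seed Integer seed; drives the simulated calibration sample when
#'   `calibration` is not supplied.
#' @param calibration Optional list with elements `states` (N x K matrix) and
#'   `responses` (N x J matrix over the whole bank) to use as the calibration
#'   sample.
#' @return A `cdmst_panels` tibble with columns `panel`, `stage`, `pathway`
#'   (`"shared"` for stage 1), `position` and `item_id`; the spec, bank seed
#'   and calibration sample are attached as attributes.
#' @examples
#' \donttest{
#' bank <- bin_difficulty(simulate_item_bank(400, 5, seed = 11))
#' spec <- test_spec(test_length = 21, n_panels = 1, calibration_n = 200)
#' panels <- assemble_panels(bank, spec, seed = 1)
#' dplyr::count(panels, pathway)
#' }
#' @export
assemble_panels <- function(bank, spec, seed = NULL, calibration = NULL) {
  if (is.null(bank$diff_bin)) bank <- bin_difficulty(bank)
  k <- n_attributes(bank)
  if (is.null(calibration)) {
    states <- simulate_knowledge_states(spec$calibration_n, k,
                                        derive_seed(seed, 1))
    responses <- simulate_responses(bank, states, derive_seed(seed, 2))
    calibration <- list(states = states, responses = responses)
  }
  pre <- assembly_precompute(bank, spec, calibration$responses)
  pool <- rep(TRUE, nrow(bank))
  rows <- list()
  reused <- 0L
  for (p in seq_len(spec$n_panels)) {
    s1r <- assemble_stage1_idx(pre, pool, spec)
    s1 <- s1r$idx
    reused <- reused + s1r$reused
    pool[s1] <- FALSE
    panel_idx <- s1
    rows[[length(rows) + 1]] <- tibble(
      panel = p, stage = 1L, pathway = "shared",
      position = seq_along(s1), item_id = bank$item_id[s1])
    for (label in spec$pathway_order) {
      res <- assemble_pathway_idx(pre, pool, spec, s1, label,
                                  panel_idx = panel_idx)
      sel <- res$idx
      reused <- reused + res$reused
      pool[sel] <- FALSE
      panel_idx <- c(panel_idx, sel)
      n2 <- spec$stage_sizes[2]
      rows[[length(rows) + 1]] <- tibble(
        panel = p,
        stage = rep(2:3, c(n2, length(sel) - n2)),
        pathway = label,
        position = c(seq_len(n2), seq_len(length(sel) - n2)),
        item_id = bank$item_id[sel])
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, spec = spec, seed = seed, calibration = calibration,
            reused_items = reused,
            class = c("cdmst_panels", class(out)))
}

#' Items of one pathway
#'
#' A pathway is the shared stage-1 module plus the stage-2 and stage-3
#' modules of one difficulty route.
#'
#' @param panels A `cdmst_panels` tibble.
#' @param panel Panel number.
#' @param label Pathway label (`"easy"`, `"medium"`, `"hard"`).
#' @return Integer vector of item ids in administration order.
#' @export
pathway_items <- function(panels, panel, label) {
  p <- panels[panels$panel == panel &
                panels$pathway %in% c("shared", label), ]
  p <- p[order(p$stage, p$position), ]
  p$item_id
}
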
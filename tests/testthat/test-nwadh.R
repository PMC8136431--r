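test_that("mean absolute deviation from targets", {
  expect_equal(mean_absolute_deviation(rep(0.9, 5), rep(0.9, 5)), 0)
  expect_equal(mean_absolute_deviation(rep(0.8, 5), rep(0.9, 5)), 0.1)
  expect_equal(mean_absolute_deviation(c(0.85, 0.7), c(0.9, 0.9)), 0.125)
  expect_error(mean_absolute_deviation(c(0.9, 0.9), 0.9),
               class = "cdmst_input_error")
})

test_that("priority index normalizes deviations", {
  expect_equal(unname(priority_index(c(a = 0.2))), 0)
  expect_equal(unname(priority_index(c(0.3, 0.3))), c(0.5, 0.5))
  expect_equal(unname(priority_index(c(0.1, 0.3))), c(0.75, 0.25))
  # all-zero deviations: every candidate ties at the equal-d limit
  expect_equal(unname(priority_index(c(0, 0, 0, 0))), rep(0.75, 4))
})

test_that("weights react to minimum and maximum counts", {
  cons <- tibble::tibble(group = c("content", "content"), category = 1:2,
                         z_min = c(4, 4), z_max = c(6, Inf))
  expect_equal(update_weights(c(3, 0), cons), c(2, 2))  # below minimum
  expect_equal(update_weights(c(6, 4), cons), c(1, 1))  # at max / satisfied
  expect_equal(update_weights(c(4, 3), cons), c(1, 2))
})

test_that("content weight aggregates category weights", {
  w <- c(2, 1, 1, 1)
  # Wbar = max - mean = 2 - 1.25 = 0.75
  expect_equal(content_weight(rep(0, 4), w), 4 * 0.75)
  expect_equal(content_weight(c(1, 0, 0, 0), w), 2 + 3 * 0.75)
  # all weights equal: Wbar = 0 and c_i reduces to the coverage count
  expect_equal(content_weight(c(1, 1, 0, 0), rep(1, 4)), 2)
  # printed variant uses (1 + v) in place of the complement
  expect_equal(content_weight(c(1, 0, 0, 0), w, form = "printed"),
               2 + 5 * 0.75)
})

test_that("constrained priority adds the normalized content term", {
  expect_equal(constrained_priority(c(0.75, 0.25), c(1, 3)), c(1, 1))
  # equal content weights preserve the statistical ranking
  e <- c(0.9, 0.5, 0.1)
  es <- constrained_priority(e, rep(2, 3))
  expect_equal(order(es), order(e))
  # single candidate: e = 0, content term = 1
  expect_equal(constrained_priority(0, 5), 1)
  # all-zero content weights contribute nothing
  expect_equal(constrained_priority(e, rep(0, 3)), e)
})

test_that("a zero-information candidate leaves the deviation unchanged", {
  w <- small_world(n_items = 10, n_exam = 80, seed = 401)
  flat <- make_bank(list(c(1, 0, 0)), list(c(0.5, 0.5)))
  flat$item_id <- 99L
  bank <- dplyr::bind_rows(w$bank[1:6, ], flat)
  x99 <- simulate_responses(flat, w$states, seed = 402)
  responses <- cbind(w$responses[, 1:6], x99)
  colnames(responses) <- bank$item_id
  u_now <- attribute_reliability(responses[, 1:6], bank[1:6, ])$reliability
  d_now <- mean_absolute_deviation(u_now, rep(0.9, 3))
  cd <- candidate_deviations(responses, bank, selected = 1:6,
                             candidates = 99L, targets = rep(0.9, 3))
  expect_equal(cd$d, d_now, tolerance = 1e-10)
})

test_that("candidate deviations match from-scratch recomputation", {
  w <- small_world(n_items = 30, n_exam = 150, seed = 403)
  selected <- w$bank$item_id[1:5]
  candidates <- w$bank$item_id[6:20]
  targets <- rep(0.9, 3)
  got <- candidate_deviations(w$responses, w$bank, selected, candidates,
                              targets)
  for (i in seq_along(candidates)) {
    ids <- c(selected, candidates[i])
    u <- attribute_reliability(w$responses[, as.character(ids)],
                               w$bank[match(ids, w$bank$item_id), ])
    expect_equal(got$d[i], mean_absolute_deviation(u$reliability, targets),
                 tolerance = 1e-8)
    expect_equal(as.numeric(got[i, paste0("u", 1:3)]), u$reliability,
                 tolerance = 1e-8)
  }
})

test_that("more discriminating candidates reduce the deviation more", {
  # attribute 1 is unmeasured so far; two single-attribute candidates differ
  # only in discrimination
  base_rows <- list(c(0, 1, 0), c(0, 0, 1), c(0, 1, 1))
  cand_rows <- list(c(1, 0, 0), c(1, 0, 0))
  bank <- make_bank(c(base_rows, cand_rows),
                    c(list(c(0.1, 0.9), c(0.1, 0.9), c(0.1, 0.3, 0.5, 0.9)),
                      list(c(0.1, 0.9), c(0.4, 0.6))))
  st <- simulate_knowledge_states(400, 3, seed = 404)
  x <- simulate_responses(bank, st, seed = 405)
  cd <- candidate_deviations(x, bank, selected = 1:3, candidates = 4:5,
                             targets = rep(0.9, 3))
  expect_lt(cd$d[cd$item_id == 4], cd$d[cd$item_id == 5])
})

test_that("select_next_item matches an exhaustive single-step oracle", {
  w <- small_world(n_items = 45, n_exam = 150, seed = 406)
  spec <- test_spec(n_attributes = 3, test_length = 9, n_panels = 1,
                    constraints = generate_fixture(1, "tiny")$spec$constraints,
                    calibration_n = 150)
  selected <- w$bank$item_id[1:4]
  candidates <- setdiff(w$bank$item_id, selected)
  candidates <- candidates[is.na(w$bank$enemy_group[candidates])]
  mid <- 0.5
  got <- select_next_item(w$responses, w$bank, selected, candidates, spec,
                          target_mid = mid)
  # oracle: score every candidate independently through the exported pieces
  cd <- candidate_deviations(w$responses, w$bank, selected, candidates,
                             spec$targets)
  e <- priority_index(cd$d)
  v <- constraint_indicators(w$bank, spec$constraints)
  counts <- colSums(v[match(selected, w$bank$item_id), , drop = FALSE])
  wts <- update_weights(counts, spec$constraints)
  ci <- content_weight(v[match(candidates, w$bank$item_id), , drop = FALSE],
                       wts)
  estar <- constrained_priority(e, ci)
  dist <- abs(w$bank$diff[match(candidates, w$bank$item_id)] - mid)
  want <- candidates[order(-estar, dist, candidates)][1]
  expect_identical(got, want)
})

test_that("selection returns the only eligible item and respects enemies", {
  w <- small_world(n_items = 12, n_exam = 60, seed = 407)
  spec <- test_spec(n_attributes = 3, test_length = 9, n_panels = 1,
                    constraints = generate_fixture(1, "tiny")$spec$constraints,
                    calibration_n = 60)
  expect_identical(
    select_next_item(w$responses, w$bank, w$bank$item_id[1:3],
                     w$bank$item_id[7], spec),
    w$bank$item_id[7])
  # an enemy of a selected item is never chosen
  bank <- w$bank
  bank$enemy_group[c(2, 7)] <- 1L
  expect_identical(
    select_next_item(w$responses, bank, bank$item_id[1:3],
                     bank$item_id[c(7, 8)], spec),
    bank$item_id[8])
  expect_error(
    select_next_item(w$responses, bank, bank$item_id[1:3],
                     bank$item_id[7], spec),
    class = "cdmst_infeasible_error")
})
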
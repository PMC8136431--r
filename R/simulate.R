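#' Simulate examinee knowledge states
#'
#' Draws `n` knowledge states uniformly (with replacement) from the universe
#' of `2^k` binary attribute-mastery vectors, the generating scheme of the
#' simulation study (for `k = 5` the universe has 32 states).
#'
#' @param n Number of examinees.
#' @param k Number of attributes.
#' @param seed Optional integer seed for reproducibility.
#' @return An `n` by `k` integer matrix of 0/1 masteries, columns `a1 ... ak`.
#' @examples
#' simulate_knowledge_states(5, 3, seed = 1)
#' @export
simulate_knowledge_states <- function(n, k, seed = NULL) {
  stopifnot(n >= 1, k >= 1)
  states <- state_space(k)
  idx <- with_seed(seed, sample.int(nrow(states), n, replace = TRUE))
  states[idx, , drop = FALSE]
}

#' Simulate a Q-matrix
#'
#' Draws each item's attribute-loading row uniformly from the `2^k - 1`
#' nonzero binary patterns (31 patterns for `k = 5`); no item can measure
#' zero attributes.
#'
#' @param j Number of items.
#' @param k Number of attributes.
#' @param seed Optional integer seed.
#' @return A `j` by `k` integer 0/1 matrix with no all-zero row.
#' @export
simulate_q_matrix <- function(j, k, seed = NULL) {
  stopifnot(j >= 1, k >= 1)
  patterns <- state_space(k)[-1, , drop = FALSE]
  idx <- with_seed(seed, sample.int(nrow(patterns), j, replace = TRUE))
  patterns[idx, , drop = FALSE]
}

#' Simulate G-DINA item parameters for one Q-matrix row
#'
#' Follows the generating scheme of the study: the guessing-side endpoint
#' `P(0)` and the slip `1 - P(1)` are drawn from `U(0, 0.25)`, so every item
#' is highly discriminating between the no-mastery and full-mastery reduced
#' patterns. The `2^m - 2` intermediate reduced-pattern probabilities (for an
#' item measuring `m` attributes) are drawn i.i.d. `U(P(0), P(1))` and
#' sort-projected onto mastery-count order, which guarantees monotonicity:
#' mastering a superset of measured attributes never lowers the probability.
#'
#' @param q_row Binary attribute-loading vector with at least one 1.
#' @param seed Optional integer seed.
#' @return Numeric probability table of length `2^sum(q_row)` in reduced
#'   binary order.
#' @export
simulate_item_parameters <- function(q_row, seed = NULL) {
  m <- sum(q_row == 1)
  if (m < 1) abort("q_row must measure at least one attribute.",
                   class = "cdmst_input_error")
  with_seed(seed, {
    p0 <- runif(1, 0, 0.25)
    p1 <- 1 - runif(1, 0, 0.25)
    n_mid <- 2^m - 2
    vals <- c(p0, sort(runif(n_mid, p0, p1)), p1)
    # assign sorted values to patterns ordered by mastery count (ties by
    # table index), which enforces monotonicity in the subset partial order
    masks <- 0:(2^m - 1)
    ord <- order(bitcount(masks), masks)
    prob <- numeric(2^m)
    prob[ord] <- vals
    prob
  })
}

#' Simulate a calibrated G-DINA item bank
#'
#' Generates the full item bank of the simulation design: a Q-matrix drawn
#' uniformly from the nonzero patterns, monotone G-DINA probability tables
#' with `P(0) ~ U(0, 0.25)` and `1 - P(1) ~ U(0, 0.25)`, the
#' cognitive-diagnosis difficulty index, and the categorical item features
#' used by the non-statistical assembly constraints (content category and
#' answer key uniform on 1-4, item type uniform on 1-2, and a small
#' proportion of enemy pairs).
#'
#' @param n_items Bank size (the study uses 1000).
#' @param k Number of attributes (the study uses 5).
#' @param seed Optional integer seed.
#' @param prop_enemy Proportion of the bank designated as enemy items,
#'   rounded to whole pairs (default 0.02).
#' @return A tibble with one row per item: `item_id`, `q1 ... qk`, `prob`
#'   (list column of reduced-pattern probability tables), `diff`,
#'   `content_category`, `item_type`, `answer_key`, `enemy_group` (NA for
#'   items without enemies).
#' @examples
#' bank <- simulate_item_bank(20, 3, seed = 7)
#' bank
#' @export
simulate_item_bank <- function(n_items, k, seed = NULL, prop_enemy = 0.02) {
  stopifnot(n_items >= 1, k >= 1)
  with_seed(seed, {
    q <- simulate_q_matrix(n_items, k)
    colnames(q) <- paste0("q", seq_len(k))
    prob <- lapply(seq_len(n_items), function(j) simulate_item_parameters(q[j, ]))
    n_pairs <- floor(n_items * prop_enemy / 2)
    enemy <- rep(NA_integer_, n_items)
    if (n_pairs > 0) {
      chosen <- sample.int(n_items, 2 * n_pairs)
      enemy[chosen] <- rep(seq_len(n_pairs), each = 2)
    }
    bank <- tibble(
      item_id = seq_len(n_items),
      as_tibble(q),
      prob = prob,
      diff = vapply(prob, mean, numeric(1)),
      content_category = sample.int(4, n_items, replace = TRUE),
      item_type = sample.int(2, n_items, replace = TRUE),
      answer_key = sample.int(4, n_items, replace = TRUE),
      enemy_group = enemy
    )
    bank
  })
}

#' Simulate a binary response matrix under the G-DINA model
#'
#' Each response is an independent Bernoulli draw with success probability
#' `P_j(alpha_e)`, the item's correct-response probability for the examinee's
#' knowledge state.
#'
#' @param bank Item-bank tibble.
#' @param states Knowledge-state matrix (`n` by `k`), as from
#'   [simulate_knowledge_states()].
#' @param seed Optional integer seed.
#' @return An `n` by `J` integer 0/1 matrix with item ids as column names.
#' @export
simulate_responses <- function(bank, states, seed = NULL) {
  states <- check_binary_matrix(states, "Knowledge-state matrix")
  if (ncol(states) != n_attributes(bank)) {
    abort("State matrix width does not match the bank's attribute count.",
          class = "cdmst_input_error")
  }
  sp <- bank_state_probs(bank)            # 2^K x J
  idx <- states %*% 2L^(seq_len(ncol(states)) - 1L) + 1L
  pmat <- sp[idx, , drop = FALSE]         # N x J true probabilities
  x <- with_seed(seed, {
    matrix(rbinom(length(pmat), 1L, pmat), nrow(pmat), ncol(pmat))
  })
  colnames(x) <- bank$item_id
  storage.mode(x) <- "integer"
  x
}
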
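# Shared fixtures and independent oracles for the test suite.

# Minimal one-row bank tibble for hand-built items.
make_bank <- function(q_rows, probs, content = NULL, type = NULL,
                      answer = NULL, enemy = NULL) {
  q <- do.call(rbind, q_rows)
  colnames(q) <- paste0("q", seq_len(ncol(q)))
  n <- length(q_rows)
  tibble::tibble(
    item_id = seq_len(n),
    tibble::as_tibble(q),
    prob = probs,
    diff = vapply(probs, mean, numeric(1)),
    content_category = content %||% rep(1L, n),
    item_type = type %||% rep(1L, n),
    answer_key = answer %||% rep(1L, n),
    enemy_group = enemy %||% rep(NA_integer_, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Term-enumeration oracle for the identity-link G-DINA response function:
# sums intercept + main effects + all interactions over mastered measured
# attributes, independent of the package's table-lookup path.
oracle_gdina_prob <- function(delta, q_row, alpha) {
  measured <- which(q_row == 1)
  mastered <- which(alpha[measured] == 1)
  m <- length(measured)
  total <- 0
  for (s in 0:(2^m - 1)) {
    subset <- which(bitwAnd(s, 2^(seq_len(m) - 1)) > 0)
    if (all(subset %in% mastered)) total <- total + delta[s + 1]
  }
  total
}

# Brute-force posterior oracle: explicit loops over states and items.
oracle_posterior <- function(x, bank, prior = NULL) {
  k <- sum(grepl("^q[0-9]+$", names(bank)))
  states <- cdmst::state_space(k)
  nc <- nrow(states)
  if (is.null(prior)) prior <- rep(1 / nc, nc)
  n <- nrow(x)
  w <- matrix(NA_real_, n, nc)
  for (e in seq_len(n)) {
    for (c in seq_len(nc)) {
      lik <- prior[c]
      for (j in seq_len(nrow(bank))) {
        p <- cdmst::response_probability(bank[j, ], states[c, ])
        lik <- lik * ifelse(x[e, j] == 1, p, 1 - p)
      }
      w[e, c] <- lik
    }
    w[e, ] <- w[e, ] / sum(w[e, ])
  }
  w
}

# Independent upper-quadrant probability of the standard bivariate normal:
# 1-D integral of the conditional normal, via stats::integrate (a different
# route than the package's Plackett/Gauss-Legendre path).
oracle_bvn_upper <- function(h, k, rho) {
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((rho * z - k) / sqrt(1 - rho^2))
  }, lower = h, upper = Inf, rel.tol = 1e-10)$value
}

# A small K = 3 world shared by several tests.
small_world <- function(n_items = 40, n_exam = 200, seed = 101) {
  bank <- cdmst::bin_difficulty(
    cdmst::simulate_item_bank(n_items, 3, seed = seed))
  states <- cdmst::simulate_knowledge_states(n_exam, 3, seed + 1)
  responses <- cdmst::simulate_responses(bank, states, seed + 2)
  list(bank = bank, states = states, responses = responses)
}
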
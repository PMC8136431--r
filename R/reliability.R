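#' Posterior distribution over knowledge states
#'
#' Bayes posterior for each examinee over the `2^K` knowledge states, using
#' the items' true G-DINA probability tables as the likelihood:
#' `w_ec` is proportional to `prior(alpha_c) * prod_j P_j(alpha_c)^x *
#' (1 - P_j(alpha_c))^(1 - x)`. Likelihoods are accumulated in log space, so
#' long tests are numerically safe. With no items the posterior equals the
#' prior.
#'
#' @param responses `N` by `J` 0/1 matrix whose columns correspond to
#'   `bank$item_id` (matched by column name when present).
#' @param bank Item-bank tibble holding exactly the administered items.
#' @param prior Prior probability vector over the `2^K` states in
#'   [state_space()] order; uniform when `NULL`.
#' @return An `N` by `2^K` matrix with rows summing to 1, with attributes
#'   `states` (the state matrix) and class `cdm_posterior`.
#' @examples
#' bank <- simulate_item_bank(10, 2, seed = 3)
#' st <- simulate_knowledge_states(20, 2, seed = 4)
#' x <- simulate_responses(bank, st, seed = 5)
#' w <- posterior_over_states(x, bank)
#' rowSums(w)[1:3]
#' @export
posterior_over_states <- function(responses, bank, prior = NULL) {
  k <- n_attributes(bank)
  states <- state_space(k)
  nc <- nrow(states)
  if (is.null(prior)) prior <- rep(1 / nc, nc)
  if (length(prior) != nc || any(prior < 0) || abs(sum(prior) - 1) > 1e-8) {
    abort("prior must be a probability vector over the 2^K states.",
          class = "cdmst_input_error")
  }
  if (nrow(bank) == 0) {
    n <- if (is.null(dim(responses))) 1L else nrow(responses)
    w <- matrix(prior, n, nc, byrow = TRUE)
    return(new_posterior(w, states))
  }
  x <- as_response_matrix(responses)
  if (!is.null(colnames(x))) x <- x[, as.character(bank$item_id), drop = FALSE]
  if (ncol(x) != nrow(bank)) {
    abort("Responses must cover exactly the items in the bank subset.",
          class = "cdmst_input_error")
  }
  sp <- bank_state_probs(bank)                       # 2^K x J
  loglik <- x %*% log(t(sp)) + (1L - x) %*% log(1 - t(sp))
  logw <- sweep(loglik, 2, log(prior), "+")
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  s <- rowSums(w)
  if (any(!is.finite(s)) || any(s <= 0)) {
    abort("Zero total likelihood for at least one examinee.",
          class = "cdmst_degenerate_error")
  }
  new_posterior(w / s, states)
}

new_posterior <- function(w, states) {
  structure(w, states = states, class = c("cdm_posterior", class(w)))
}

#' Incrementally update a posterior with one appended item
#'
#' Multiplies each examinee's posterior by the likelihood factor of a single
#' new item and renormalizes; identical (to numerical tolerance) to refitting
#' [posterior_over_states()] from scratch on the extended item set. This is
#' the update the NWADH candidate scan applies when scoring every remaining
#' item.
#'
#' @param posterior An `cdm_posterior` matrix.
#' @param item A single item (one bank row or `list(q, prob)`).
#' @param x Length-`N` 0/1 response vector to the new item.
#' @return Updated `cdm_posterior`.
#' @export
posterior_append_item <- function(posterior, item, x) {
  states <- attr(posterior, "states")
  p_state <- response_probability(item, states)      # length 2^K
  x <- as.integer(x)
  fac <- outer(x, p_state) + outer(1L - x, 1 - p_state)
  w <- unclass(posterior) * fac
  new_posterior(w / rowSums(w), states)
}

#' Marginal attribute-mastery probabilities
#'
#' `p_hat_ek`, the posterior probability that examinee `e` masters attribute
#' `k`: the sum of posterior mass over states with `alpha_k = 1`.
#'
#' @param posterior A `cdm_posterior` matrix from [posterior_over_states()].
#' @return `N` by `K` matrix of probabilities in `[0, 1]`.
#' @export
marginal_mastery <- function(posterior) {
  states <- attr(posterior, "states")
  m <- unclass(posterior) %*% states
  colnames(m) <- colnames(states)
  m
}

#' Replication contingency table for one attribute
#'
#' The test-retest thought experiment behind attribute reliability: two
#' independent replications of the same attribute classification give a 2x2
#' table whose cells average the products of marginal mastery probabilities
#' across examinees: `p11 = mean(p_hat^2)`,
#' `p10 = p01 = mean(p_hat * (1 - p_hat))`, `p00 = mean((1 - p_hat)^2)`.
#' The table is symmetric and sums to 1 by construction.
#'
#' @param p_hat Vector of marginal mastery probabilities for one attribute.
#' @return A one-row tibble with columns `p11`, `p10`, `p01`, `p00`.
#' @examples
#' replication_table(c(0.8, 0.4))
#' @export
replication_table <- function(p_hat) {
  if (length(p_hat) == 0) abort("Empty mastery vector.",
                                class = "cdmst_input_error")
  if (any(p_hat < 0 | p_hat > 1)) {
    abort("Mastery probabilities must lie in [0, 1].",
          class = "cdmst_input_error")
  }
  tibble(
    p11 = mean(p_hat^2),
    p10 = mean(p_hat * (1 - p_hat)),
    p01 = mean((1 - p_hat) * p_hat),
    p00 = mean((1 - p_hat)^2)
  )
}

#' Tetrachoric correlation of a 2x2 probability table
#'
#' Finds the correlation `rho` of a standard bivariate normal whose quadrant
#' probabilities at thresholds `tau1 = qnorm(p00 + p01)`,
#' `tau2 = qnorm(p00 + p10)` reproduce the table: the `p11` cell equals
#' `P(Z1 > tau1, Z2 > tau2; rho)`. The quadrant probability is computed by
#' Gauss-Legendre quadrature of the Plackett identity and the root is
#' bracketed on `(-1, 1)`.
#'
#' @param p11,p10,p01,p00 Cell probabilities; must be nonnegative and sum
#'   to 1.
#' @param tol Convergence tolerance on the quadrant probability.
#' @return The tetrachoric correlation in `[-1, 1]`.
#' @examples
#' tetrachoric(0.25, 0.25, 0.25, 0.25) # independence: 0
#' tetrachoric(1 / 4 + 1 / 12, 1 / 6, 1 / 6, 1 / 4 + 1 / 12) # 0.5
#' @export
tetrachoric <- function(p11, p10, p01, p00, tol = 1e-10) {
  cells <- c(p11, p10, p01, p00)
  if (any(cells < -1e-12) || abs(sum(cells) - 1) > 1e-6) {
    abort("Cells must be nonnegative and sum to 1.",
          class = "cdmst_input_error")
  }
  m1 <- p11 + p10
  m2 <- p11 + p01
  eps <- 1e-10
  if (m1 <= eps || m1 >= 1 - eps || m2 <= eps || m2 >= 1 - eps) {
    abort("Degenerate margin: attribute classification is deterministic.",
          class = "cdmst_degenerate_error")
  }
  tau1 <- qnorm(1 - m1)
  tau2 <- qnorm(1 - m2)
  f <- function(r) cpp_bvn_upper(tau1, tau2, r) - p11
  lo <- -1 + 1e-9
  hi <- 1 - 1e-9
  if (f(hi) <= 0) return(1)
  if (f(lo) >= 0) return(-1)
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Attribute reliability of an administered item set
#'
#' Composes the reliability pipeline: posterior over states, marginal mastery
#' probabilities, per-attribute replication table, tetrachoric correlation.
#' The resulting `u_k` is the latent test-retest correlation of the
#' attribute-`k` classification and is the quantitative target the assembly
#' engine steers toward. A degenerate table (an attribute classified with
#' certainty for everyone) is mapped to reliability 1 with a warning.
#'
#' @inheritParams posterior_over_states
#' @return A tibble with columns `attribute` and `reliability` (length `K`).
#' @export
attribute_reliability <- function(responses, bank, prior = NULL) {
  w <- posterior_over_states(responses, bank, prior)
  p_hat <- marginal_mastery(w)
  u <- reliability_from_mastery(p_hat)
  tibble(attribute = seq_len(ncol(p_hat)), reliability = u)
}

# Fast path shared with the assembly engine: symmetric-table tetrachoric from
# the first two moments of p-hat. Degenerate margins clamp to 1.
reliability_from_mastery <- function(p_hat) {
  m1 <- colMeans(p_hat)
  m2 <- colMeans(p_hat^2)
  degenerate <- m1 <= 1e-10 | m1 >= 1 - 1e-10
  if (any(degenerate)) {
    warn("Degenerate attribute margin: reliability clamped to 1.")
  }
  as.numeric(cpp_tetrachoric_sym(m1, m2))
}
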
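test_that("identity-link response probability follows the delta expansion", {
  # q = (1,1,0,0,0), intercept 0.2, zero main effects, interaction 0.7
  item <- list(q = c(1, 1, 0, 0, 0),
               prob = probs_from_delta(c(0.2, 0, 0, 0.7)))
  expect_equal(response_probability(item, c(1, 1, 0, 0, 0)), 0.9)
  expect_equal(response_probability(item, c(1, 1, 1, 1, 1)), 0.9)
  # any examinee missing a measured attribute falls back to the intercept
  expect_equal(response_probability(item, c(0, 0, 0, 0, 0)), 0.2)
  expect_equal(response_probability(item, c(1, 0, 1, 1, 1)), 0.2)
  # depends only on the measured entries
  expect_equal(response_probability(item, c(0, 1, 0, 0, 0)),
               response_probability(item, c(0, 1, 1, 1, 1)))
  expect_error(response_probability(item, c(1, 1)),
               class = "cdmst_input_error")
})

test_that("response probability matches the term-enumeration oracle", {
  set.seed(11)
  states4 <- state_space(4)
  for (rep in 1:20) {
    q_row <- simulate_q_matrix(1, 4)[1, ]
    prob <- simulate_item_parameters(q_row)
    delta <- delta_from_probs(prob)
    item <- list(q = q_row, prob = prob)
    for (c in seq_len(nrow(states4))) {
      expect_equal(response_probability(item, states4[c, ]),
                   oracle_gdina_prob(delta, q_row, states4[c, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("delta and probability table are bijective", {
  set.seed(12)
  for (m in 1:4) {
    prob <- sort(runif(2^m))
    expect_equal(probs_from_delta(delta_from_probs(prob)), prob,
                 tolerance = 1e-12)
  }
  # DINA-style item: only intercept and top interaction
  expect_equal(delta_from_probs(c(0.2, 0.2, 0.2, 0.9)), c(0.2, 0, 0, 0.7))
})

test_that("item difficulty is the state-average correct probability", {
  flat <- list(q = c(1, 0, 0), prob = c(0.5, 0.5))
  expect_equal(item_difficulty(flat), 0.5)
  # DINA-like with K = 5: 8 of 32 states master both attributes
  item <- list(q = c(1, 1, 0, 0, 0), prob = c(0.2, 0.2, 0.2, 0.9))
  states <- state_space(5)
  oracle <- mean(response_probability(item, states))
  expect_equal(oracle, (8 * 0.9 + 24 * 0.2) / 32)  # = 0.375
  expect_equal(item_difficulty(item), oracle)
  # linearity: difficulty of an averaged table is the average difficulty
  a <- list(q = c(1, 1, 0), prob = c(0.1, 0.3, 0.4, 0.9))
  b <- list(q = c(1, 1, 0), prob = c(0.2, 0.2, 0.5, 0.7))
  avg <- list(q = c(1, 1, 0), prob = (a$prob + b$prob) / 2)
  expect_equal(item_difficulty(avg),
               (item_difficulty(a) + item_difficulty(b)) / 2)
})

test_that("simulated items are monotone in attribute mastery", {
  set.seed(13)
  for (rep in 1:50) {
    q_row <- simulate_q_matrix(1, 4)[1, ]
    prob <- simulate_item_parameters(q_row)
    m <- sum(q_row)
    for (s in 0:(2^m - 1)) {
      for (t in 0:(2^m - 1)) {
        if (bitwAnd(s, t) == s) expect_lte(prob[s + 1], prob[t + 1])
      }
    }
  }
})

test_that("knowledge-state universe and sampling are correct", {
  expect_equal(nrow(state_space(5)), 32)
  ks <- simulate_knowledge_states(10, 5, seed = 1)
  expect_true(all(ks %in% c(0, 1)))
  expect_equal(dim(ks), c(10, 5))
  # K = 1: mastery proportion converges to 1/2
  ks1 <- simulate_knowledge_states(4000, 1, seed = 2)
  expect_lt(abs(mean(ks1) - 0.5), 0.03)
  # uniformity over the 8 states of K = 3 (chi-square goodness of fit)
  ks3 <- simulate_knowledge_states(16000, 3, seed = 3)
  idx <- ks3 %*% c(1, 2, 4)
  obs <- tabulate(idx + 1, nbins = 8)
  chisq <- sum((obs - 2000)^2 / 2000)
  expect_lt(chisq, qchisq(0.999, df = 7))
  # reproducibility
  expect_identical(simulate_knowledge_states(50, 4, seed = 9),
                   simulate_knowledge_states(50, 4, seed = 9))
})

test_that("Q-matrix rows are uniform over the nonzero patterns", {
  q <- simulate_q_matrix(500, 5, seed = 4)
  expect_true(all(rowSums(q) >= 1))
  expect_equal(nrow(state_space(5)) - 1, 31)  # pattern universe for K = 5
  expect_true(all(simulate_q_matrix(20, 1, seed = 5) == 1))
  # uniformity over the 7 nonzero patterns of K = 3
  q3 <- simulate_q_matrix(14000, 3, seed = 6)
  idx <- q3 %*% c(1, 2, 4)
  obs <- tabulate(idx, nbins = 7)
  chisq <- sum((obs - 2000)^2 / 2000)
  expect_lt(chisq, qchisq(0.999, df = 6))
})

test_that("item-parameter endpoints follow the uniform(0, 0.25) scheme", {
  set.seed(14)
  p0 <- numeric(300)
  p1 <- numeric(300)
  for (i in 1:300) {
    prob <- simulate_item_parameters(c(1, 1, 0))
    p0[i] <- prob[1]
    p1[i] <- prob[4]
    expect_true(all(prob >= prob[1] & prob <= prob[4]))
  }
  expect_true(all(p0 > 0 & p0 < 0.25))
  expect_true(all(p1 > 0.75 & p1 < 1))
  expect_lt(abs(mean(p0) - 0.125), 0.02)
  # single-attribute item: exactly the two endpoints
  prob1 <- simulate_item_parameters(c(0, 1, 0), seed = 15)
  expect_length(prob1, 2)
})

test_that("responses are Bernoulli draws from the item response function", {
  # deterministic item: always correct
  bank <- make_bank(list(c(1, 0)), list(c(1, 1)))
  st <- simulate_knowledge_states(50, 2, seed = 16)
  expect_true(all(simulate_responses(bank, st, seed = 17) == 1))
  # empirical correct proportion per state matches the generating probability
  bank2 <- make_bank(list(c(1, 1)), list(c(0.2, 0.4, 0.6, 0.9)))
  st0 <- rbind(matrix(0L, 4000, 2), matrix(1L, 4000, 2))
  x <- simulate_responses(bank2, st0, seed = 18)
  expect_lt(abs(mean(x[1:4000]) - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
  expect_lt(abs(mean(x[4001:8000]) - 0.9), 3 * sqrt(0.9 * 0.1 / 4000))
  # monotonicity consequence: masters outscore non-masters
  w <- small_world(n_items = 30, n_exam = 600)
  masters <- rowSums(w$states) == 3
  expect_gt(mean(rowSums(w$responses[masters, ])),
            mean(rowSums(w$responses[!masters, ])))
})

test_that("a simulated bank has a plausible difficulty spread", {
  bank <- simulate_item_bank(1000, 5, seed = 19)
  expect_true(all(bank$diff > 0 & bank$diff < 1))
  # spread comparable to the 0.24-0.74 band seen in a full-size bank
  expect_lt(min(bank$diff), 0.40)
  expect_gt(max(bank$diff), 0.60)
  expect_true(all(table(bank$enemy_group) == 2))
  expect_equal(sum(!is.na(bank$enemy_group)), 20)
})
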
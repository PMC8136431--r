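test_that("reliability deviation is the signed elementwise difference", {
  expect_equal(reliability_deviation(rep(0.9, 5), rep(0.9, 5)), rep(0, 5))
  expect_equal(reliability_deviation(0.92, 0.90), 0.02, tolerance = 1e-12)
  m <- matrix(c(0.95, 0.85, 0.9, 0.7), 2)
  expect_equal(reliability_deviation(m, c(0.9, 0.9)),
               matrix(c(0.05, -0.05, 0, -0.2), 2))
})

test_that("violation counting matches a hand-checked fixture", {
  cons <- tibble::tibble(
    group = c(rep("content", 4), rep("item_type", 2), rep("attribute", 2),
              "enemy"),
    category = c(1:4, 1:2, 1:2, 1L),
    z_min = c(rep(1, 4), rep(2, 2), rep(2, 2), 0),
    z_max = c(rep(Inf, 8), 0))
  # 6 items: content {1,1,2,3,4,4}, types {1,1,1,2,2,2},
  # attribute 1 on items 1-2 only (count 2), attribute 2 on items 3-6
  pw <- make_bank(
    list(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 1), c(0, 1)),
    rep(list(c(0.2, 0.9)), 6),
    content = c(1L, 1L, 2L, 3L, 4L, 4L),
    type = c(1L, 1L, 1L, 2L, 2L, 2L))
  v <- count_violations(pw, cons)
  expect_equal(sum(v$violated), 0)
  expect_equal(v$violated, rep(0L, 9))  # Eq-18 additivity over categories
  # now break exactly two categories: drop item 6 (content 4 -> 1 item still
  # fine with z_min 1) and raise minimums instead
  cons2 <- cons
  cons2$z_min[cons2$group == "content"] <- 2  # categories 2 and 3 have 1 item
  v2 <- count_violations(pw, cons2)
  expect_equal(sum(v2$violated), 2)
  expect_equal(v2$violated[v2$group == "content"], c(0L, 1L, 1L, 0L))
})

test_that("enemy pairs inside a pathway are flagged", {
  cons <- default_constraints(2)
  pw <- make_bank(list(c(1, 0), c(0, 1), c(1, 1)),
                  rep(list(c(0.2, 0.9)), 3),
                  enemy = c(3L, 3L, NA))
  v <- count_violations(pw, cons)
  expect_equal(v$violated[v$group == "enemy"], 1L)
  pw2 <- pw
  pw2$enemy_group <- c(3L, 4L, NA)
  expect_equal(count_violations(pw2, cons)$violated[v$group == "enemy"], 0L)
})

test_that("expected number-correct is the sum of true probabilities", {
  bank <- make_bank(rep(list(c(1, 0)), 10),
                    rep(list(c(0.2, 0.9)), 10))
  full <- matrix(1L, 1, 2)
  none <- matrix(0L, 1, 2)
  expect_equal(expected_number_correct(bank, full), 9)
  expect_equal(expected_number_correct(bank, none), 2)
  # flat 0.9 items give 9.0 regardless of state
  bank9 <- make_bank(rep(list(c(1, 0)), 10), rep(list(c(0.9, 0.9)), 10))
  expect_equal(expected_number_correct(bank9, none), 9)
})

test_that("easier item sets yield higher expected scores", {
  bank <- bin_difficulty(simulate_item_bank(200, 3, seed = 601))
  st <- simulate_knowledge_states(100, 3, 602)
  ord <- order(bank$diff)
  hard10 <- bank[ord[1:10], ]
  mid10 <- bank[ord[96:105], ]
  easy10 <- bank[ord[191:200], ]
  expect_gt(mean(expected_number_correct(easy10, st)),
            mean(expected_number_correct(mid10, st)))
  expect_gt(mean(expected_number_correct(mid10, st)),
            mean(expected_number_correct(hard10, st)))
})

test_that("Cronbach's alpha matches hand arithmetic and limiting cases", {
  # two identical items are perfectly correlated: alpha = 1
  x <- cbind(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))
  expect_equal(cronbach_alpha(x), 1)
  # hand-computed 4 x 3 fixture: total-score variance 5/3,
  # item variances 1/4 + 1/3 + 1/4 -> alpha = 1.5 * (1 - (5/6)/(5/3)) = 0.75
  x2 <- matrix(c(1, 1, 0,
                 1, 0, 0,
                 1, 1, 1,
                 0, 0, 0), 4, 3, byrow = TRUE)
  expect_equal(cronbach_alpha(x2), 0.75)
  # independent items: alpha near 0
  set.seed(603)
  x3 <- matrix(rbinom(2000 * 8, 1, 0.5), 2000, 8)
  expect_lt(abs(cronbach_alpha(x3)), 0.1)
  expect_error(cronbach_alpha(cbind(c(1, 1), c(0, 0))),
               class = "cdmst_degenerate_error")
  expect_error(cronbach_alpha(matrix(1, 5, 1)), class = "cdmst_input_error")
})

test_that("Rasch calibration recovers symmetric and ordered difficulties", {
  set.seed(604)
  n <- 1500
  theta <- rnorm(n)
  b_true <- c(-1.5, -0.5, 0, 0.5, 1.5)
  x <- vapply(b_true, function(b) rbinom(n, 1, plogis(theta - b)),
              numeric(n))
  storage.mode(x) <- "integer"
  fit <- rasch_calibrate(x)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$items$b - b_true)), 0.2)
  # easier item (higher p-value) always gets lower b
  expect_equal(order(fit$items$b), order(-fit$items$p_value))
  # b = 0 items sit near zero without any centering step
  expect_lt(abs(fit$items$b[3]), 0.1)
})

test_that("Rasch EM agrees with a brute-force likelihood maximizer", {
  set.seed(605)
  n <- 200
  theta <- rnorm(n)
  b_true <- c(-1, -0.3, 0, 0.6, 1.2)
  x <- vapply(b_true, function(b) rbinom(n, 1, plogis(theta - b)),
              numeric(n))
  storage.mode(x) <- "integer"
  fit <- rasch_calibrate(x)
  # oracle: direct numerical maximization of the marginal likelihood on a
  # plain Riemann grid over ability
  grid <- seq(-6, 6, by = 0.02)
  gw <- dnorm(grid)
  gw <- gw / sum(gw)
  negll <- function(b) {
    p <- plogis(outer(grid, b, "-"))
    ll <- x %*% t(log(p)) + (1L - x) %*% t(log(1 - p))
    -sum(log(exp(ll - apply(ll, 1, max)) %*% gw) + apply(ll, 1, max))
  }
  opt <- optim(rep(0, 5), negll, method = "BFGS",
               control = list(reltol = 1e-12))
  expect_lt(max(abs(fit$items$b - opt$par)), 0.01)
})

test_that("all-0/all-1 items are dropped with a warning", {
  set.seed(606)
  x <- cbind(rbinom(50, 1, 0.5), rbinom(50, 1, 0.6), rep(1L, 50))
  colnames(x) <- c("a", "b", "c")
  expect_warning(fit <- rasch_calibrate(x), "dropped")
  expect_equal(fit$items$item, c("a", "b"))
  expect_equal(fit$dropped, "c")
})

test_that("difficulty correlation reports sign and magnitude", {
  b <- seq(-2, 2, length.out = 50)
  diff <- 0.6 - 0.1 * b
  dc <- difficulty_correlation(diff, b)
  expect_equal(dc$estimate, -1, tolerance = 1e-12)
  expect_equal(dc$magnitude, 1, tolerance = 1e-12)
  # destroying the pairing destroys the correlation
  set.seed(607)
  dc2 <- difficulty_correlation(sample(diff, 200, TRUE) + rnorm(200, 0, 1e-6),
                                sample(b, 200, TRUE))
  expect_lt(dc2$magnitude, 0.2)
  expect_error(difficulty_correlation(rep(0.5, 5), 1:5),
               class = "cdmst_degenerate_error")
})

test_that("panel evaluation is deterministic and internally consistent", {
  fx <- generate_fixture(seed = 3, scale = "tiny")
  panels <- assemble_panels(fx$bank, fx$spec,
                            calibration = list(states = fx$states,
                                               responses = fx$responses))
  ev1 <- evaluate_panels(panels, fx$bank)
  ev2 <- evaluate_panels(panels, fx$bank)
  expect_identical(ev1$reliability, ev2$reliability)
  expect_identical(ev1$pathway_stats, ev2$pathway_stats)
  # deviations are observed minus target
  expect_equal(ev1$reliability$deviation,
               ev1$reliability$reliability - ev1$reliability$target)
  # violation totals add over categories
  tot <- sum(ev1$violations$violated)
  expect_equal(tot, sum(tapply(ev1$violations$violated,
                               ev1$violations$group, sum)))
})
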
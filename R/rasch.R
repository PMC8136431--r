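#' Rasch marginal maximum-likelihood calibration
#'
#' Fits the one-parameter logistic (Rasch) model
#' `P(X = 1 | theta) = plogis(theta - b_j)` by an EM algorithm that
#' marginalizes over a standard-normal ability distribution on a fixed
#' Gauss-Hermite quadrature grid. The N(0, 1) ability prior identifies both
#' the scale and the location of the difficulties, so no post-hoc centering
#' is applied. Items answered identically by everyone (all 0 or all 1) carry
#' no likelihood information about a finite `b` and are dropped with a
#' warning. Used here only to cross-validate the cognitive-diagnosis
#' difficulty index.
#'
#' @param responses `N` by `J` 0/1 matrix; column names become item labels.
#' @param n_nodes Number of Gauss-Hermite quadrature nodes (default 41).
#' @param tol Convergence tolerance on the largest difficulty change.
#' @param max_iter Maximum EM iterations.
#' @return A `rasch_fit` list: `items` (tibble with `item`, `b`, `p_value`),
#'   `loglik`, `iterations`, `converged`, `dropped`.
#' @examples
#' \donttest{
#' bank <- simulate_item_bank(30, 3, seed = 2)
#' st <- simulate_knowledge_states(300, 3, seed = 3)
#' x <- simulate_responses(bank, st, seed = 4)
#' fit <- rasch_calibrate(x)
#' head(tidy(fit))
#' }
#' @export
rasch_calibrate <- function(responses, n_nodes = 41, tol = 1e-6,
                            max_iter = 500) {
  x <- as_response_matrix(responses)
  if (is.null(colnames(x))) colnames(x) <- seq_len(ncol(x))
  p_val <- colMeans(x)
  keep <- p_val > 0 & p_val < 1
  dropped <- colnames(x)[!keep]
  if (length(dropped)) {
    warn(paste0(length(dropped),
                " item(s) with all-0 or all-1 responses dropped."))
    x <- x[, keep, drop = FALSE]
    p_val <- p_val[keep]
  }
  if (ncol(x) == 0) abort("No calibratable items.",
                          class = "cdmst_input_error")
  gh <- gauss_hermite_normal(n_nodes)
  theta <- gh$nodes
  wq <- gh$weights
  j <- ncol(x)
  b <- qnorm(1 - p_val) / sqrt(1 - 0.25)  # crude normal-ogive start
  iter <- 0
  converged <- FALSE
  loglik <- -Inf
  repeat {
    iter <- iter + 1
    pq <- plogis(outer(theta, b, "-"))           # Q x J
    logl_nq <- x %*% t(log(pq)) + (1L - x) %*% t(log(1 - pq))  # N x Q
    logl_nq <- sweep(logl_nq, 2, log(wq), "+")
    mx <- apply(logl_nq, 1, max)
    post <- exp(logl_nq - mx)
    denom <- rowSums(post)
    loglik_new <- sum(log(denom) + mx)
    post <- post / denom                         # N x Q
    nq <- colSums(post)                          # expected count per node
    rqj <- t(post) %*% x                         # Q x J expected corrects
    # M-step: per-item Newton on the expected score equation
    b_new <- b
    for (nr in 1:3) {
      pq <- plogis(outer(theta, b_new, "-"))
      f <- colSums(rqj) - colSums(nq * pq)   # increasing in b
      fp <- colSums(nq * pq * (1 - pq))
      step <- pmin(pmax(f / fp, -1), 1)
      b_new <- b_new - step
    }
    delta <- max(abs(b_new - b))
    b <- b_new
    loglik <- loglik_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(paste0("Rasch EM did not converge in ", iter,
                " iterations (last max change ", signif(delta, 3), ")."))
  }
  structure(list(
    items = tibble(item = colnames(x), b = unname(b), p_value = unname(p_val)),
    loglik = loglik, iterations = iter, converged = converged,
    dropped = dropped, n_nodes = n_nodes),
    class = "rasch_fit")
}

# Gauss-Hermite nodes/weights adapted to a standard-normal weight function
# (Golub-Welsch on the Hermite Jacobi matrix; nodes scaled by sqrt(2),
# weights normalized to sum to 1).
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  jac <- matrix(0, n, n)
  off <- sqrt(i / 2)
  jac[cbind(i, i + 1)] <- off
  jac[cbind(i + 1, i)] <- off
  eig <- eigen(jac, symmetric = TRUE)
  ord <- order(eig$values)
  list(nodes = eig$values[ord] * sqrt(2),
       weights = (eig$vectors[1, ord])^2)
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("<rasch_fit> ", nrow(x$items), " items, loglik ",
      round(x$loglik, 2), ", ", x$iterations, " EM iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}
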
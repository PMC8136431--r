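#' G-DINA correct-response probability
#'
#' Evaluates the saturated identity-link G-DINA item response function: the
#' probability of a correct response depends only on the reduced attribute
#' pattern, i.e. the entries of the knowledge state at the attributes the item
#' measures. The item carries one probability per reduced pattern
#' (`prob`, length `2^{K*_j}`), equivalently an intercept, main-effect and
#' interaction expansion (see [delta_from_probs()]).
#'
#' @param item A single item: either one row of an item-bank tibble (see
#'   [simulate_item_bank()]) or a list with elements `q` (binary vector of
#'   length K) and `prob` (numeric vector of length `2^{sum(q)}`, ordered so
#'   that bit `i` of the zero-based table index is the mastery of the `i`-th
#'   measured attribute).
#' @param alpha Knowledge state: binary vector of length K, or a matrix with
#'   one state per row.
#' @return Correct-response probability in `[0, 1]` (vector if `alpha` is a
#'   matrix).
#' @examples
#' item <- list(q = c(1, 1, 0), prob = c(0.2, 0.2, 0.2, 0.9))
#' response_probability(item, c(1, 1, 0))
#' response_probability(item, c(0, 1, 1))
#' @export
response_probability <- function(item, alpha) {
  item <- as_item(item)
  if (is.matrix(alpha)) {
    return(apply(alpha, 1, function(a) response_probability(item, a)))
  }
  if (length(alpha) != length(item$q)) {
    abort("Knowledge state length does not match the item's Q-matrix row.",
          class = "cdmst_input_error")
  }
  item$prob[reduced_index(as.integer(alpha), item$q)]
}

as_item <- function(item) {
  if (is.data.frame(item)) {
    stopifnot(nrow(item) == 1)
    k <- n_attributes(item)
    list(q = as.integer(item[paste0("q", seq_len(k))]),
         prob = item$prob[[1]])
  } else {
    list(q = as.integer(item$q), prob = as.numeric(item$prob))
  }
}

#' Convert a reduced-pattern probability table to G-DINA delta coefficients
#'
#' The identity-link G-DINA model writes the probability for reduced pattern
#' `alpha*` as the sum of an intercept, main effects for each mastered
#' measured attribute, and interactions of every order among the mastered
#' ones. Given the full probability table this expansion is an exact bijection
#' (Moebius inversion over subsets of measured attributes):
#' `delta_S = sum_{T subset S} (-1)^{|S| - |T|} P(T)`.
#'
#' @param prob Numeric vector of length `2^m`, the probability for each
#'   reduced pattern in binary order (bit `i` = mastery of measured attribute
#'   `i`).
#' @return Numeric vector of delta coefficients, same length and indexing:
#'   entry `s` is the coefficient for the subset with bitmask `s - 1`
#'   (entry 1 is the intercept).
#' @seealso [probs_from_delta()]
#' @examples
#' delta_from_probs(c(0.2, 0.2, 0.2, 0.9)) # intercept 0.2, interaction 0.7
#' @export
delta_from_probs <- function(prob) {
  n <- length(prob)
  m <- as.integer(round(log2(n)))
  if (2^m != n) abort("prob length must be a power of 2.",
                      class = "cdmst_input_error")
  delta <- numeric(n)
  for (s in 0:(n - 1)) {
    tt <- 0:(n - 1)
    subs <- tt[bitwAnd(tt, s) == tt]
    signs <- (-1)^(bitcount(s) - bitcount(subs))
    delta[s + 1] <- sum(signs * prob[subs + 1])
  }
  delta
}

#' Convert G-DINA delta coefficients to a probability table
#'
#' Inverse of [delta_from_probs()]: `P(S) = sum_{T subset S} delta_T`.
#'
#' @param delta Numeric vector of length `2^m` in binary subset order.
#' @return Probability table of the same length.
#' @export
probs_from_delta <- function(delta) {
  n <- length(delta)
  m <- as.integer(round(log2(n)))
  if (2^m != n) abort("delta length must be a power of 2.",
                      class = "cdmst_input_error")
  prob <- numeric(n)
  for (s in 0:(n - 1)) {
    tt <- 0:(n - 1)
    subs <- tt[bitwAnd(tt, s) == tt]
    prob[s + 1] <- sum(delta[subs + 1])
  }
  prob
}

bitcount <- function(x) {
  vapply(x, function(v) sum(bitwAnd(v, 2^(0:30)) > 0), numeric(1))
}

#' Cognitive-diagnosis item difficulty index
#'
#' The difficulty of an item under cognitive diagnosis is its mean
#' correct-response probability over all `2^K` knowledge states:
#' `Diff_j = 2^-K * sum_c P_j(alpha_c)`. Because each reduced pattern
#' corresponds to equally many full states, this equals the unweighted mean of
#' the reduced-pattern probability table. Lower values mean harder items.
#'
#' @param bank An item-bank tibble (or a single item as for
#'   [response_probability()]).
#' @param k Number of attributes; inferred from the bank when omitted.
#' @return Numeric vector of difficulties in `[0, 1]`, one per item.
#' @examples
#' item <- list(q = c(1, 1, 0, 0, 0), prob = c(0.2, 0.2, 0.2, 0.9))
#' item_difficulty(item) # (8 * 0.9 + 24 * 0.2) / 32 = 0.375
#' @export
item_difficulty <- function(bank, k = NULL) {
  if (is.data.frame(bank)) {
    return(vapply(bank$prob, mean, numeric(1)))
  }
  mean(as_item(bank)$prob)
}
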
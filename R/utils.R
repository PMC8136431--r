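# Internal helpers: seeds, state enumeration, input checks.

# Deterministic sub-seed derivation so every generation step of a study is
# reproducible from one master seed. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 9973 + 1) %% 2147483629
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Enumerate all knowledge states
#'
#' Returns the universe of binary attribute-mastery vectors for `k`
#' attributes, one state per row. State `c` encodes the bits of `c - 1`, with
#' attribute 1 in the least significant position, so the all-zero state comes
#' first and the all-ones state last.
#'
#' @param k Number of attributes (`K >= 1`).
#' @return A `2^k` by `k` integer matrix of 0/1 mastery indicators with
#'   columns `a1 ... ak`.
#' @examples
#' state_space(2)
#' @export
state_space <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  k <- as.integer(k)
  m <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- list(NULL, paste0("a", seq_len(k)))
  storage.mode(m) <- "integer"
  m
}

# Index of a reduced pattern within an item's probability table:
# bit i of (index - 1) is the mastery of the i-th measured attribute.
reduced_index <- function(alpha, q_row) {
  bits <- alpha[q_row == 1L]
  sum(bits * 2L^(seq_along(bits) - 1L)) + 1L
}

# 2^K x J matrix of P_j(alpha_c) for every state and bank item.
bank_state_probs <- function(bank) {
  k <- n_attributes(bank)
  states <- state_space(k)
  q <- q_matrix(bank)
  out <- matrix(NA_real_, nrow(states), nrow(bank))
  for (j in seq_len(nrow(bank))) {
    measured <- which(q[j, ] == 1L)
    idx <- states[, measured, drop = FALSE] %*% 2L^(seq_along(measured) - 1L)
    out[, j] <- bank$prob[[j]][idx + 1L]
  }
  colnames(out) <- bank$item_id
  out
}

n_attributes <- function(bank) {
  sum(grepl("^q[0-9]+$", names(bank)))
}

q_matrix <- function(bank) {
  k <- n_attributes(bank)
  m <- as.matrix(bank[paste0("q", seq_len(k))])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

check_binary_matrix <- function(x, what) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(x %in% c(0L, 1L))) {
    abort(paste0(what, " must contain only 0/1 entries."),
          class = "cdmst_input_error")
  }
  storage.mode(x) <- "integer"
  x
}

as_response_matrix <- function(responses) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  check_binary_matrix(responses, "Response matrix")
}
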
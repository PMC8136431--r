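#' Generate a self-contained simulation fixture
#'
#' Builds a complete miniature (or full-scale) study input in one call: a
#' binned item bank, a calibration sample with its response matrix, and a
#' matching test specification. The `"tiny"` scale (3 attributes, 60 items,
#' 100 examinees, one 9-item pathway per label with scaled-down constraint
#' minimums) is intended for examples and fast tests; the `"paper"` scale is
#' the full simulation design (5 attributes, 1000 items, 1000 examinees,
#' 21-item pathways).
#'
#' @param seed Integer seed.
#' @param scale `"tiny"` or `"paper"`.
#' @return A list with `bank`, `states`, `responses`, `spec`.
#' @examples
#' fx <- generate_fixture(seed = 1, scale = "tiny")
#' nrow(fx$bank)
#' @export
generate_fixture <- function(seed = 1, scale = c("tiny", "paper")) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    k <- 3
    bank <- bin_difficulty(simulate_item_bank(60, k, seed = derive_seed(seed, 1),
                                              prop_enemy = 0.1))
    states <- simulate_knowledge_states(100, k, derive_seed(seed, 2))
    responses <- simulate_responses(bank, states, derive_seed(seed, 3))
    cons <- tibble(
      group = c(rep("content", 4), rep("item_type", 2), rep("answer_key", 4),
                rep("attribute", k), "enemy"),
      category = c(1:4, 1:2, 1:4, seq_len(k), 1L),
      z_min = c(rep(1, 4), rep(1, 2), rep(0, 4), rep(1, k), 0),
      z_max = c(rep(Inf, 10 + k), 0))
    spec <- test_spec(n_attributes = k, test_length = 9, n_panels = 1,
                      constraints = cons, calibration_n = 100)
  } else {
    k <- 5
    bank <- bin_difficulty(simulate_item_bank(1000, k,
                                              seed = derive_seed(seed, 1)))
    states <- simulate_knowledge_states(1000, k, derive_seed(seed, 2))
    responses <- simulate_responses(bank, states, derive_seed(seed, 3))
    spec <- test_spec(n_attributes = k, test_length = 21, n_panels = 5)
  }
  list(bank = bank, states = states, responses = responses, spec = spec)
}
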
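#' Bin item difficulties into easy / medium / hard
#'
#' Splits the realized difficulty range of a bank into three equal-width
#' intervals between the minimum and maximum `Diff_j`, mirroring the averaged
#' cut-point scheme used to route multistage-test modules. Because `Diff_j`
#' is a correct-response probability, the highest interval is the *easy* bin
#' and the lowest the *hard* bin. Intervals are half-open `[lower, upper)`
#' except the topmost, which is closed, so every item receives exactly one
#' label.
#'
#' @param bank Item-bank tibble with a `diff` column.
#' @return The bank with an added ordered factor column `diff_bin`
#'   (levels `hard < medium < easy`) and an attribute `cut_points` holding
#'   the four interval boundaries.
#' @examples
#' bank <- simulate_item_bank(50, 3, seed = 1)
#' table(bin_difficulty(bank)$diff_bin)
#' @export
bin_difficulty <- function(bank) {
  if (nrow(bank) == 0) abort("Empty item bank.", class = "cdmst_input_error")
  d <- bank$diff
  lo <- min(d)
  hi <- max(d)
  if (hi - lo < .Machine$double.eps^0.5) {
    abort("Degenerate bank: all item difficulties are identical.",
          class = "cdmst_degenerate_error")
  }
  cuts <- seq(lo, hi, length.out = 4)
  bin <- cut(d, breaks = cuts, labels = c("hard", "medium", "easy"),
             right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
  # cut() with right = FALSE leaves values equal to the top break in the last
  # interval only via include.lowest; make the topmost interval closed:
  bin[d == hi] <- "easy"
  bank$diff_bin <- bin
  attr(bank, "cut_points") <- cuts
  bank
}

#' Difficulty-bin boundaries of a binned bank
#'
#' @param bank A bank processed by [bin_difficulty()].
#' @return A tibble with one row per bin: label, lower and upper boundary.
#' @export
difficulty_cuts <- function(bank) {
  cuts <- attr(bank, "cut_points")
  if (is.null(cuts)) {
    bank <- bin_difficulty(bank)
    cuts <- attr(bank, "cut_points")
  }
  tibble(
    diff_bin = factor(c("hard", "medium", "easy"),
                      levels = c("hard", "medium", "easy"), ordered = TRUE),
    lower = cuts[1:3],
    upper = cuts[2:4]
  )
}

bin_midpoints <- function(cuts) {
  mids <- (cuts[1:3] + cuts[2:4]) / 2
  names(mids) <- c("hard", "medium", "easy")
  mids
}
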
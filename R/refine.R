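#' Sliding-window majority-vote refinement of per-base labels
#'
#' Smooths a raw 0/1 per-base label track: position `i` receives label 1
#' exactly when the sum of the raw labels in the window of size `W` centered
#' at `i` strictly exceeds half the window size, i.e.
#' `sum(p[(i-k):(i+k)]) > W/2` with `k = (W-1)/2`. The vote always reads the
#' raw input track (one pass, no iterative propagation). Near the read ends
#' the window is truncated to valid positions and the strict-majority
#' threshold is half the truncated window size.
#'
#' @param labels Integer 0/1 vector of raw per-base predictions.
#' @param window Odd window size `W >= 1` (default 21). `W = 1` is the
#'   identity.
#' @return The refined integer 0/1 vector, same length as the input.
#' @export
refine_labels <- function(labels, window = 21L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 1 (got ", window,
         "); choose an odd --smooth-window", call. = FALSE)
  }
  stopifnot(all(labels %in% c(0L, 1L)))
  n <- length(labels)
  if (n == 0L) return(integer())
  k <- (window - 1L) %/% 2L
  cs <- c(0L, cumsum(labels))
  idx <- seq_len(n)
  lo <- pmax(idx - k, 1L)
  hi <- pmin(idx + k, n)
  s <- cs[hi + 1L] - cs[lo]
  as.integer(s > (hi - lo + 1L) / 2)
}
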
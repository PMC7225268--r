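#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 pmap imap list_rbind
#' @importFrom stats median rnorm rpois runif rexp lm anova pf cor prcomp
#'   sd quantile setNames aggregate
#' @importFrom mclust Mclust mclustBIC
#' @importFrom utils tail
NULL

# Gaussian consistency constant for median(|x|): qnorm(0.75)
MAD_SCALE <- 0.6745

#' Derive a child seed from a global seed
#'
#' Counter-based fan-out so that each stochastic stage of a run receives an
#' independent, reproducible seed below 2^31.
#'
#' @param seed integer global seed.
#' @param k integer counter (stage index).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2)) s <- (1103515245 * s + 12345 + as.double(k)) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Merge half-open sample intervals
#'
#' Intervals are 0-based half-open `[start, end)`. Overlapping or touching
#' intervals are merged; the result is sorted and disjoint.
#'
#' @param windows two-column matrix (start, end) or NULL.
#' @return A two-column integer-valued matrix, possibly with zero rows.
#' @export
merge_windows <- function(windows) {
  if (is.null(windows) || NROW(windows) == 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  w <- matrix(as.numeric(windows), ncol = 2)
  w <- w[order(w[, 1]), , drop = FALSE]
  out <- w[1, , drop = FALSE]
  for (i in seq_len(nrow(w))[-1]) {
    if (w[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], w[i, 2])
    } else out <- rbind(out, w[i, ])
  }
  colnames(out) <- c("start", "end")
  out
}

# TRUE for samples (0-based indices) inside any window
in_windows <- function(idx, windows) {
  if (is.null(windows) || NROW(windows) == 0) return(rep(FALSE, length(idx)))
  hit <- rep(FALSE, length(idx))
  for (i in seq_len(nrow(windows)))
    hit <- hit | (idx >= windows[i, 1] & idx < windows[i, 2])
  hit
}

stop_invalid <- function(msg) abort(msg, class = "imetk_invalid_parameter")
stop_degenerate <- function(msg) abort(msg, class = "imetk_degenerate_input")
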
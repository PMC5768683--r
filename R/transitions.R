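# Lag-1 transition counting on cluster-labeled frame series.  Separate
# simulations are physically discontinuous, so counting never bridges
# trajectory boundaries.

#' Count lag-1 transitions between cluster labels
#'
#' @param series an integer vector of labels (one trajectory), or a list
#'   of such vectors (one per independent trajectory).  Labels must lie in
#'   `1..k`.
#' @param k number of clusters; default the maximum observed label.
#' @param lag label stride; default 1 saved frame.
#' @return List of class `TransitionMatrix`: `counts` (k x k, row = from),
#'   `frequencies` (counts / total transitions), `k`, `n_transitions`.
#' @export
count_transitions <- function(series, k = NULL, lag = 1L) {
  if (!is.list(series)) series <- list(series)
  series <- lapply(series, as.integer)
  if (is.null(k)) k <- max(unlist(series))
  k <- as.integer(k)
  if (any(unlist(series) < 1L | unlist(series) > k))
    stop("labels outside 1..k")
  counts <- matrix(0L, k, k)
  for (s in series) {
    if (length(s) <= lag) next
    from <- s[seq_len(length(s) - lag)]
    to <- s[-seq_len(lag)]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  total <- sum(counts)
  structure(list(counts = counts,
                 frequencies = if (total > 0) counts / total else counts,
                 k = k, n_transitions = total),
            class = "TransitionMatrix")
}

#' Symmetry score of a transition matrix
#'
#' `1 - sum|C - C^T| / sum(C + C^T)` over off-diagonal entries: 1 for
#' perfectly balanced forward/backward transitions (detailed-balance-like
#' behaviour), 0 for completely one-directional flow.
#'
#' @param m TransitionMatrix from [count_transitions()].
#' @return Number in `[0, 1]`.
#' @export
symmetry_score <- function(m) {
  C <- m$counts
  off <- C; diag(off) <- 0L
  tot <- sum(off + t(off))
  if (tot == 0) stop("no off-diagonal transitions; symmetry undefined")
  1 - sum(abs(off - t(off))) / tot
}
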
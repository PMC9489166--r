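#' Exact two-cluster solution in one dimension
#'
#' Finds the globally optimal k = 2 clustering of a numeric vector by
#' enumerating the contiguous splits of the sorted values and minimizing the
#' within-cluster sum of squares. In one dimension the optimal 2-partition is
#' always contiguous and can keep tied values together, so the enumeration is
#' exact and fully deterministic (no random restarts).
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return list with elements `labels` (integer vector, 1 = lower cluster,
#'   2 = upper cluster, in input order), `centers` (sorted pair of cluster
#'   means), `threshold` (midpoint of the boundary values, strictly between
#'   the centers), and `wss` (the minimized within-cluster sum of squares).
#' @examples
#' kmeans2_1d(c(0, 0, 10, 10))$threshold  # 5
#' @export
kmeans2_1d <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numeric")
  n <- length(values)
  if (n < 2 || length(unique(values)) < 2)
    stop("need at least 2 distinct values for k = 2 clustering")
  o <- order(values)
  s <- values[o]
  cs <- cumsum(s)
  css <- cumsum(s^2)
  i <- seq_len(n - 1)
  wss_left <- css[i] - cs[i]^2 / i
  wss_right <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  wss <- wss_left + wss_right
  # only split between distinct values: ties share a nearest center, so an
  # optimal partition never separates equal values
  valid <- s[i] < s[i + 1]
  wss[!valid] <- Inf
  best <- which.min(wss)
  threshold <- (s[best] + s[best + 1]) / 2
  centers <- c(mean(s[1:best]), mean(s[(best + 1):n]))
  labels <- ifelse(values <= s[best], 1L, 2L)
  list(labels = labels, centers = centers, threshold = threshold,
       wss = wss[best])
}
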
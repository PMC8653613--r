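# Independent brute-force oracles used to verify the package's
# implementations.  Each oracle takes a different computational route than
# the code it checks.

# Two-sided Fisher p by direct enumeration of all 2x2 tables with the
# observed margins, with probabilities from log-binomial coefficients
# (not dhyper).  Tables whose probability does not exceed the observed
# one (relative tolerance 1e-7) contribute.
oracle_fisher_p <- function(overlap, size1, size2, universe_size) {
  xs <- max(0L, size1 + size2 - universe_size):min(size1, size2)
  logp <- lchoose(size1, xs) + lchoose(universe_size - size1, size2 - xs) -
    lchoose(universe_size, size2)
  p <- exp(logp)
  p_obs <- p[xs == overlap]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Exhaustive optimal 1-D clustering for k = 3: optimal clusters are
# contiguous on the sorted values, so enumerate all breakpoint pairs and
# minimize within-cluster sum of squares via prefix sums.
oracle_kmeans3 <- function(x) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  seg <- function(i, j) (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / (j - i + 1)
  best <- Inf
  best_b <- c(1L, 2L)
  for (b1 in 1:(n - 2)) {
    b2 <- (b1 + 1):(n - 1)
    w <- seg(1, b1) + seg(b1 + 1, b2) + seg(b2 + 1, n)
    i <- which.min(w)
    if (w[i] < best - 1e-12) {
      best <- w[i]
      best_b <- c(b1, b2[i])
    }
  }
  labels_sorted <- rep(3L, n)
  labels_sorted[seq_len(best_b[2])] <- 2L
  labels_sorted[seq_len(best_b[1])] <- 1L
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}

# Knee of a descending-sorted curve by explicit point-to-line geometry:
# normalize both axes, take the line through the first and last points,
# and find the point of maximum perpendicular distance above it
# (signed by the line normal pointing up); ties within 1e-12 resolve to
# the middle tied index.
oracle_knee_value <- function(values) {
  y <- sort(values, decreasing = TRUE)
  n <- length(y)
  px <- (seq_len(n) - 1) / (n - 1)
  py <- (y - min(y)) / (max(y) - min(y))
  a <- c(px[1], py[1])
  b <- c(px[n], py[n])
  ab <- b - a
  # signed perpendicular distance, positive above the chord
  d <- (ab[1] * (py - a[2]) - ab[2] * (px - a[1])) / sqrt(sum(ab^2))
  ties <- which(d >= max(d) - 1e-12)
  y[ties[ceiling(length(ties) / 2)]]
}

# Single-linkage clusters at a fixed radius on a precomputed distance
# matrix: connected components of the graph with edges d <= radius.
oracle_single_linkage <- function(D, radius) {
  n <- nrow(D)
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] > 0L) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier) > 0L) {
      nxt <- which(labels == 0L & apply(D[frontier, , drop = FALSE] <= radius, 2, any))
      labels[nxt] <- cl
      frontier <- nxt
    }
  }
  split(seq_len(n), labels)
}
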
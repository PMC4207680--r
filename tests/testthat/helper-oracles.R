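# Independent oracle implementations used to cross-check the package.

# Passing-Bablok by literal enumeration: explicit double loop, explicit sort,
# explicit shifted-median indexing.
oracle_pb <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  b <- if (N %% 2 == 1) slopes[(N + 1) / 2 + K]
       else (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  list(slope = b, intercept = median(y - b * x))
}

# Two-sided Fisher p by hypergeometric summation with choose(); the table is
# rbind(c(a, b), c(c_, d)).
oracle_fisher_p <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  r <- a + b          # first-row margin
  m <- a + c_         # first-column margin
  lo <- max(0, r + m - N); hi <- min(r, m)
  xs <- lo:hi
  pr <- choose(m, xs) * choose(N - m, r - xs) / choose(N, r)
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

# Novel-transcript scanner by per-start rightward extension of the alive
# condition set (okmat: positions x conditions, already masked).
oracle_scan <- function(okmat, k, min_len) {
  L <- nrow(okmat)
  starts <- which(rowSums(okmat) >= k)
  res <- list()
  best_end <- 0L
  for (i in starts) {
    alive <- which(okmat[i, ])
    j <- i
    while (j < L) {
      alive2 <- alive[okmat[j + 1L, alive]]
      if (length(alive2) < k) break
      alive <- alive2
      j <- j + 1L
    }
    J <- j + 1L                       # first base past the interval
    if (J <= best_end) next           # contained in an earlier interval
    best_end <- J
    if (J - i >= min_len)
      res[[length(res) + 1L]] <- c(start = i - 1L, end = J - 1L)
  }
  if (!length(res)) matrix(integer(0), 0, 2,
                           dimnames = list(NULL, c("start", "end")))
  else do.call(rbind, res)
}

# Naive O(n^3) complete-linkage agglomeration over a distance matrix.
# Ties broken by the smallest pair indices (matching label order).
oracle_complete_linkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  steps <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
    }
    steps[[length(steps) + 1L]] <-
      list(height = best_d,
           members = sort(c(clusters[[best[1]]], clusters[[best[2]]])))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  steps
}

# Brute-force per-position bedGraph accumulation
oracle_fill <- function(len, start, end, value) {
  out <- numeric(len)
  for (r in seq_along(start))
    for (p in (start[r] + 1L):end[r]) out[p] <- out[p] + value[r]
  as.integer(out)
}
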
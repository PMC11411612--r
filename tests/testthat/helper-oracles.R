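# Independent oracles and shared fixtures for the test suite.

# Memoised synthetic library so several test files can share one
# generation run (the library itself is deterministic for the spec).
.cache <- new.env(parent = emptyenv())

cachedLibrary <- function(n = 200L, seed = 1L) {
  key <- paste0("lib_", n, "_", seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- suppressWarnings(
      generateLibrary(generatorSpec(n = n, seed = seed))
    )
  }
  .cache[[key]]
}

cachedDescriptors <- function(n = 200L, seed = 1L) {
  key <- paste0("desc_", n, "_", seed)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- computeDescriptors(cachedLibrary(n, seed))
  }
  .cache[[key]]
}

# Brute-force "smallest ring through each edge" oracle: enumerate all
# simple paths between the endpoints of an edge with that edge removed
# (recursive DFS), take the shortest, and maximise over edges. Mirrors
# the definition directly and shares no code with the implementation.
bruteMaxSmallestRing <- function(edges, n) {
  if (nrow(edges) == 0L) return(0L)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  shortestPathAvoiding <- function(from, to, banA, banB) {
    best <- Inf
    walk <- function(node, visited, len) {
      if (len >= best) return()
      if (node == to) { best <<- len; return() }
      for (nb in adj[[node]]) {
        if ((node == banA && nb == banB) || (node == banB && nb == banA)) next
        if (nb %in% visited) next
        walk(nb, c(visited, nb), len + 1L)
      }
    }
    walk(from, from, 0L)
    best
  }
  best <- 0L
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    d <- shortestPathAvoiding(a, b, a, b)
    if (is.finite(d)) best <- max(best, as.integer(d) + 1L)
  }
  best
}

# Random connected graph on n nodes: spanning tree plus extra edges.
randomMoleculeGraph <- function(n, extra = 2L) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1)))
  for (e in seq_len(extra)) {
    repeat {
      cand <- sort(sample.int(n, 2L))
      dup <- any(edges[, 1] == cand[2] & edges[, 2] == cand[1]) ||
             any(edges[, 1] == cand[1] & edges[, 2] == cand[2])
      if (!dup) { edges <- rbind(edges, cand); break }
    }
  }
  unname(edges)
}

# Order-statistic quantile oracle for the (n+1)p rule, written from the
# definition (independent of stats::quantile).
type6Quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n + 1) * p
  lo <- floor(h); hi <- ceiling(h)
  lo <- min(max(lo, 1), n); hi <- min(max(hi, 1), n)
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Permutation oracle for the Tukey-Kramer family-wise test: reference
# distribution of the maximum pairwise |mean difference| / SE under
# label permutation.
permutationMaxQ <- function(values, groups, B = 2000L) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  ns <- tabulate(groups, k)
  maxQ <- function(v, g) {
    means <- tapply(v, g, mean)
    vars <- tapply(v, g, stats::var)
    df <- length(v) - k
    mse <- sum((ns - 1) * vars) / df
    best <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      best <- max(best, abs(means[i] - means[j]) / se)
    }
    best
  }
  obs <- maxQ(values, groups)
  null <- replicate(B, maxQ(values, sample(groups)))
  list(obs = obs, pvalue = mean(null >= obs))
}
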
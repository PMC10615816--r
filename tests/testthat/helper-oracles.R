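# Independent oracles. These deliberately use naive brute force / direct
# summation, never the package's own code paths, so a green test means two
# independent routes agree.

# Naive mixture log-likelihood: direct (non-log-space) summation.
naive_mixture_loglik <- function(x, sd, means, proportions) {
  total <- 0
  for (i in seq_along(x)) {
    dens <- 0
    for (k in seq_along(means)) {
      dens <- dens + proportions[k] *
        exp(-(x[i] - means[k])^2 / (2 * sd[i]^2)) / (sqrt(2 * pi) * sd[i])
    }
    total <- total + log(dens)
  }
  total
}

# Brute-force hotspot scan: slide a window anchored at every midpoint and
# mark every midpoint that belongs to some window of >= min_count members;
# clusters are then the connected stretches of marked midpoints that share
# a qualifying window.
brute_cluster_members <- function(mid, window_bp, min_count) {
  mid <- sort(mid)
  in_cluster <- rep(FALSE, length(mid))
  for (a in mid) {
    memb <- which(mid >= a & mid <= a + window_bp)
    if (length(memb) >= min_count) in_cluster[memb] <- TRUE
  }
  mid[in_cluster]
}

# Brute-force connected components of the interval-intersection graph
# (half-open intervals), via repeated label propagation.
brute_components <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    start[i] < end[j] & start[j] < end[i]
  })
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

# All set partitions of 1..n as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, mx) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (l in seq_len(mx + 1L)) recurse(c(labels, l), max(mx, l))
  }
  recurse(integer(), 0L)
  out
}

# Exhaustive partition oracle for the known-variance mixture + AIC:
# every partition with <= K_max blocks is scored with block means set to
# the blocks' inverse-variance means, proportions to block sizes / n, and
# AIC = -2 logL + 2 (2K - 1). Ties go to fewer blocks, then first found.
oracle_best_partition <- function(x, sd, K_max) {
  best <- NULL
  best_aic <- Inf
  best_k <- Inf
  for (labels in all_partitions(length(x))) {
    k <- max(labels)
    if (k > K_max) next
    mu <- vapply(seq_len(k), function(b) {
      sel <- labels == b
      sum(x[sel] / sd[sel]^2) / sum(1 / sd[sel]^2)
    }, 0)
    prop <- tabulate(labels, k) / length(x)
    ll <- naive_mixture_loglik(x, sd, mu, prop)
    aic <- -2 * ll + 2 * (2 * k - 1)
    if (!is.finite(aic)) next   # naive density underflows for bad partitions
    if (aic < best_aic - 1e-9 ||
        (abs(aic - best_aic) <= 1e-9 && k < best_k)) {
      best <- labels
      best_aic <- aic
      best_k <- k
    }
  }
  list(labels = best, aic = best_aic, k = best_k)
}

# Canonical form of a partition label vector: list of member-index sets,
# each sorted, ordered by smallest member. Two label vectors describe the
# same partition iff their canonical forms are identical.
canonical_partition <- function(labels) {
  blocks <- unname(split(seq_along(labels), labels))
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, min, 0L))]
}

# Brute-force cross-trait co-localization groups: maximal subsets with a
# nonempty common intersection and >= 2 traits (subset enumeration).
brute_coloc_groups <- function(start, end, trait) {
  n <- length(start)
  subsets <- list()
  for (mask in 1:(2^n - 1)) {
    memb <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(memb) < 2) next
    if (length(unique(trait[memb])) < 2) next
    if (max(start[memb]) < min(end[memb])) subsets[[length(subsets) + 1L]] <- memb
  }
  keep <- rep(TRUE, length(subsets))
  for (a in seq_along(subsets)) for (b in seq_along(subsets)) {
    if (a != b && keep[a] && all(subsets[[a]] %in% subsets[[b]]) &&
        length(subsets[[a]]) < length(subsets[[b]])) keep[a] <- FALSE
  }
  subsets[keep]
}
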
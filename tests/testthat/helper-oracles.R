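# Independent oracles used across the suite. All are deliberately naive
# (loops, enumeration) and share no code with the implementation.

# O(n * m) nearest-distance: scan every subject for every query row.
brute_nearest <- function(query, subjects) {
  vapply(seq_len(nrow(query)), function(i) {
    best <- NA_real_
    for (j in seq_len(nrow(subjects))) {
      if (subjects$chrom[j] != query$chrom[i]) next
      d <- if (query$start[i] < subjects$end[j] &&
               subjects$start[j] < query$end[i]) 0
      else max(query$start[i] - subjects$end[j],
               subjects$start[j] - query$end[i])
      if (is.na(best) || d < best) best <- d
    }
    best
  }, numeric(1))
}

# Exact two-sided rank-sum p by enumerating every group assignment.
enum_wilcox <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  idx <- utils::combn(n, n1)
  stats <- abs(colSums(matrix(r[idx], nrow = n1)) - mu)
  mean(stats >= obs - 1e-9)
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 * ties, where
# a lower prediction counts as a higher dependency score.
pairwise_auc <- function(y_true, y_pred, threshold = -0.5) {
  pos <- which(y_true < threshold); neg <- which(y_true >= threshold)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (y_pred[i] < y_pred[j]) + 0.5 * (y_pred[i] == y_pred[j])
  }
  tot / (length(pos) * length(neg))
}

# Cover-weighted conditional expectation of one flattened tree given the
# feature subset S (1-based feature ids).
tree_expvalue <- function(tr, x, S, node = 1) {
  if (tr$left[node] < 0) return(tr$value[node])
  f <- tr$feature[node] + 1
  l <- tr$left[node] + 1; r <- tr$right[node] + 1
  if (f %in% S) {
    if (x[f] <= tr$threshold[node]) tree_expvalue(tr, x, S, l)
    else tree_expvalue(tr, x, S, r)
  } else {
    (tr$cover[l] * tree_expvalue(tr, x, S, l) +
       tr$cover[r] * tree_expvalue(tr, x, S, r)) / tr$cover[node]
  }
}

all_subsets <- function(v) {
  if (length(v) == 0) return(list(integer(0)))
  rest <- all_subsets(v[-1])
  c(rest, lapply(rest, function(s) c(v[1], s)))
}

# Exhaustive Shapley values of tree_expvalue over the features the tree
# actually splits on (dummy features have value 0).
shapley_tree_oracle <- function(tr, x, p) {
  used <- sort(unique(tr$feature[tr$feature >= 0])) + 1
  M <- length(used)
  phi <- numeric(p)
  for (j in used) {
    for (S in all_subsets(setdiff(used, j))) {
      w <- factorial(length(S)) * factorial(M - length(S) - 1) / factorial(M)
      phi[j] <- phi[j] +
        w * (tree_expvalue(tr, x, c(S, j)) - tree_expvalue(tr, x, S))
    }
  }
  phi
}

# Brute-force 1-D 2-means over every split point of the sorted values.
brute_two_means <- function(x) {
  lx <- sort(log1p(x))
  best <- NULL; best_ss <- Inf
  for (k in seq_len(length(lx) - 1)) {
    lo <- lx[seq_len(k)]; hi <- lx[-seq_len(k)]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) { best_ss <- ss; best <- mean(lo) + (mean(hi) - mean(lo)) / 2 }
  }
  ifelse(log1p(x) < best, "I", "II")
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + sample.int(500, n, replace = TRUE))
}
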
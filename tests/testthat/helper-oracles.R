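# Independent brute-force oracles used to pin down the estimator code.
# These deliberately avoid the package's closed-form implementations.

# all permutations of 1..n as rows (n! x n integer matrix)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- matrix(seq_len(n)[-k][p], nrow = nrow(p))
    cbind(k, rest, deparse.level = 0)
  }))
}

# all integer partitions of n (each a non-increasing count vector):
# every possible inventory shape with n records, up to species labels
partitions_of <- function(n, cap = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, cap))) {
    for (rest in partitions_of(n - k, k)) out[[length(out) + 1L]] <- c(k, rest)
  }
  out
}

# exhaustive mean, over all orderings of the records, of the final
# accumulation step S(n) - S(n-1)
slope_perm_oracle <- function(counts, P = NULL) {
  slope_perm_count(counts, P)[["new"]] / slope_perm_count(counts, P)[["total"]]
}

# integer bookkeeping for the exact rational comparison: number of
# orderings whose final record adds a new species, and the total n!
slope_perm_count <- function(counts, P = NULL) {
  v <- rep(seq_along(counts), counts)
  n <- length(v)
  if (is.null(P)) P <- perms(n)
  if (n == 1L) return(c(new = 1L, total = 1L))
  last <- v[P[, n]]
  earlier <- matrix(v[P[, -n, drop = FALSE]], nrow = nrow(P))
  c(new = sum(rowSums(earlier == last) == 0L), total = nrow(P))
}

# brute-force expected richness of an m-record subsample: average over
# every one of the choose(n, m) subsets
rarefy_oracle <- function(counts, m) {
  v <- rep(seq_along(counts), counts)
  if (m == 0L) return(0)
  idx <- utils::combn(length(v), m)
  mean(apply(idx, 2L, function(i) length(unique(v[i]))))
}

# brute-force two-sample K-S sup over every pooled step point
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# random inventory: species counts with a heavy singleton tail
random_counts <- function(max_species = 12L) {
  s <- sample.int(max_species, 1L)
  stats::rgeom(s, prob = 0.5) + 1L
}

# records-as-units incidence matrix for a count vector (rows = records)
incidence_matrix <- function(counts) {
  n <- sum(counts)
  m <- matrix(0L, n, length(counts))
  m[cbind(seq_len(n), rep(seq_along(counts), counts))] <- 1L
  m
}
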
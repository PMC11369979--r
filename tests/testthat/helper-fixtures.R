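# Shared fixtures: small grids and independent oracles used across test files.

small_grid <- function(dims = c(24, 24, 24), vs = c(1, 1, 1)) {
  voxel_grid(dims, vs)
}

phantom_grid <- function() voxel_grid(c(64, 64, 32), c(0.5, 0.5, 1))

# Brute-force pairwise AUC with half-credit for ties (Mann-Whitney
# probability), independent of the ROC construction.
auc_bruteforce <- function(scores, labels, orientation = "lower_is_positive",
                           positive = "PD") {
  s <- if (orientation == "lower_is_positive") -scores else scores
  sp <- s[labels == positive]
  sn <- s[labels != positive]
  total <- 0
  for (a in sp) for (b in sn) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# Exhaustive Youden scan: try predicting positive at s >= v for every distinct
# internal value v (plus the degenerate all-negative rule), return max J.
youden_bruteforce <- function(scores, labels, orientation = "lower_is_positive",
                              positive = "PD") {
  s <- if (orientation == "lower_is_positive") -scores else scores
  pos <- labels == positive
  best <- 0  # all-negative rule: J = 0
  for (v in unique(s)) {
    pred <- s >= v
    J <- mean(pred[pos]) - mean(pred[!pos])
    if (J > best) best <- J
  }
  best
}

# O(n^2) Kendall tau-b by direct pair counting with tie terms.
kendall_bruteforce <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  nx <- sum(sapply(split(seq_along(x), x), function(g) choose(length(g), 2)))
  ny <- sum(sapply(split(seq_along(y), y), function(g) choose(length(g), 2)))
  (C - D) / sqrt((n0 - nx) * (n0 - ny))
}
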
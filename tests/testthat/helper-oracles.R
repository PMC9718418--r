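# Independent oracles used to cross-check the stochastic simulator.

# Exact chemical master equation solution for the binary decision system
# with a FIXED stimulus count and FIXED weight counts (stimulus and weights
# are pure catalysts, so the reachable state space is the simplex
# {(x, y, b) : x + y + b = n_total}).  Built by brute-force enumeration of
# that simplex and matrix-exponentiating the generator; completely
# independent of the SSA code path.
cme_decision_distribution <- function(n_total, x0, y0, stimulus, wx, wy,
                                      t, kNoise = 1, kAM = 1, kBias = 1) {
  states <- list()
  key <- function(x, y) sprintf("%d_%d", x, y)
  for (x in 0:n_total) {
    for (y in 0:(n_total - x)) {
      states[[key(x, y)]] <- c(x = x, y = y, b = n_total - x - y)
    }
  }
  n <- length(states)
  idx <- setNames(seq_len(n), names(states))
  Q <- matrix(0, n, n)
  add <- function(from, to, rate) {
    if (rate > 0) {
      i <- idx[[from]]; j <- idx[[to]]
      Q[i, j] <<- Q[i, j] + rate
      Q[i, i] <<- Q[i, i] - rate
    }
  }
  for (s in names(states)) {
    st <- states[[s]]
    x <- st[["x"]]; y <- st[["y"]]; b <- st[["b"]]
    if (x >= 1) add(s, key(x - 1, y + 1), kNoise * x)            # X -> Y
    if (y >= 1) add(s, key(x + 1, y - 1), kNoise * y)            # Y -> X
    if (x >= 1 && y >= 1)                                        # X+Y+S -> 2B+S
      add(s, key(x - 1, y - 1), kAM * x * y * stimulus)
    if (b >= 1 && x >= 1)                                        # B+X+S -> 2X+S
      add(s, key(x + 1, y), kAM * b * x * stimulus)
    if (b >= 1 && y >= 1)                                        # B+Y+S -> 2Y+S
      add(s, key(x, y + 1), kAM * b * y * stimulus)
    if (b >= 1) {
      add(s, key(x + 1, y), kBias * b * wx)                      # B+WX -> X+WX
      add(s, key(x, y + 1), kBias * b * wy)                      # B+WY -> Y+WY
    }
  }
  p0 <- numeric(n)
  p0[idx[[key(x0, y0)]]] <- 1
  pt <- as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t))))
  setNames(pt, names(states))
}

total_variation <- function(p, q) {
  labels <- union(names(p), names(q))
  pv <- setNames(numeric(length(labels)), labels)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  sum(abs(pv - qv)) / 2
}

# Binomial standard error helper for probability estimates.
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
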
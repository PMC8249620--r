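# Independent dense Kolmogorov-equation oracle. Builds the full transition
# rate matrix (including an explicit sink row) by plain nested loops over
# enumerated states and propagates it with expm::expm() over intervals on
# which the signal is constant. Shares no code with the package's sparse
# generator or RK45 path.

# edge rates computed from first principles (plain arithmetic on the
# parameter values)
oracle_edge_rates <- function(gene, condition, s,
                              suppress_form = "saturating") {
  k <- as.list(gene$rates$k)
  b <- gene$rates$b
  if (condition %in% c("mg132", "both")) b <- gene$inhibitors$mg132$b
  if (condition %in% c("u0126", "both")) k[["01"]] <- gene$inhibitors$u0126$k01
  se <- gene$topology$signal_edge
  if (!is.na(se)) {
    k[[se]] <- if (gene$topology$signal_mode == "enhance") {
      k[[se]] + b * s
    } else if (suppress_form == "saturating") {
      k[[se]] / (1 + b * s)
    } else {
      k[[se]] * max(0, 1 - b * s)
    }
  }
  k
}

# dense generator over states (g, x), x = 0..M, plus a final sink state
oracle_dense_A <- function(gene, condition, s, max_count,
                           suppress_form = "saturating") {
  S <- gene$topology$n_states
  M <- max_count
  k <- oracle_edge_rates(gene, condition, s, suppress_form)
  alpha <- gene$rates$alpha
  delta <- gene$rates$delta
  n <- S * (M + 1) + 1
  idx <- function(g, x) g + S * x + 1  # g in 0..S-1, x in 0..M
  A <- matrix(0, n, n)
  for (g in 0:(S - 1)) {
    for (x in 0:M) {
      from <- idx(g, x)
      for (e in names(k)) {
        if (as.integer(substr(e, 1, 1)) == g) {
          to <- idx(as.integer(substr(e, 2, 2)), x)
          A[to, from] <- A[to, from] + k[[e]]
          A[from, from] <- A[from, from] - k[[e]]
        }
      }
      if (x < M) {
        A[idx(g, x + 1), from] <- A[idx(g, x + 1), from] + alpha[g + 1]
      } else {
        A[n, from] <- A[n, from] + alpha[g + 1]  # sink
      }
      A[from, from] <- A[from, from] - alpha[g + 1]
      if (x > 0) {
        A[idx(g, x - 1), from] <- A[idx(g, x - 1), from] + delta * x
        A[from, from] <- A[from, from] - delta * x
      }
    }
  }
  A
}

# propagate a point-mass (or given) initial law under a piecewise-constant
# signal; returns list(prob = (S*(M+1)) x T matrix, sink = numeric T)
oracle_solve_piecewise <- function(gene, condition, signal_table, out_times,
                                   max_count, init,
                                   suppress_form = "saturating") {
  S <- gene$topology$n_states
  n <- S * (max_count + 1) + 1
  y <- c(init, 0)
  stopifnot(length(y) == n)
  bps <- sort(unique(c(out_times, signal_table$times)))
  bps <- bps[bps >= out_times[1] & bps <= max(out_times)]
  probs <- matrix(NA_real_, n - 1, length(out_times))
  sink <- numeric(length(out_times))
  record <- function(t, y) {
    j <- match(t, out_times)
    if (!is.na(j)) {
      probs[, j] <<- y[-n]
      sink[j] <<- y[n]
    }
  }
  record(bps[1], y)
  for (i in seq_len(length(bps) - 1)) {
    t0 <- bps[i]; t1 <- bps[i + 1]
    s <- signal_table$values[findInterval(t0, signal_table$times)]
    A <- oracle_dense_A(gene, condition, s, max_count, suppress_form)
    y <- as.numeric(expm::expm(A * (t1 - t0)) %*% y)
    record(t1, y)
  }
  list(prob = probs, sink = sink)
}

# total-variation distance between two mRNA marginals given as vectors
tv_dist <- function(p, q) {
  L <- max(length(p), length(q))
  sum(abs(c(p, rep(0, L - length(p))) - c(q, rep(0, L - length(q))))) / 2
}

# mRNA marginal of a flat (g, x) law
oracle_marginal <- function(p, n_states) {
  colSums(matrix(p, nrow = n_states))
}
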
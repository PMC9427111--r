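# Independent oracles used across test files.

# Deterministic within-cycle growth of two synchronized subclones with
# division times d1, d2 (hours). Every cell of a type divides at integer
# multiples of its division time; growth halts the instant the total
# reaches `cap`. Returns the type counts at the halt. Mirrors only the
# arithmetic of synchronized doubling, not the simulator's event queue.
two_type_growth_oracle <- function(n1, n2, d1, d2, cap) {
  t1 <- d1; t2 <- d2
  total <- n1 + n2
  while (total < cap) {
    if (t1 < t2) {
      div <- min(n1, cap - total)
      n1 <- n1 + div; total <- total + div; t1 <- t1 + d1
    } else {
      div <- min(n2, cap - total)
      n2 <- n2 + div; total <- total + div; t2 <- t2 + d2
    }
  }
  c(n1 = n1, n2 = n2)
}

# Exact fixation probability and conditional sweep time of subclone 1 under
# serial cycles of deterministic two-type growth followed by a
# hypergeometric bottleneck of size N. States: number of type-1 cells at
# the bottleneck (0..N; 0 and N absorbing).
two_type_chain_oracle <- function(N, Mt, d1, d2) {
  cap <- 2^Mt * N
  P <- matrix(0, N + 1L, N + 1L)
  P[1L, 1L] <- 1; P[N + 1L, N + 1L] <- 1
  for (i in seq_len(N - 1L)) {
    g <- two_type_growth_oracle(i, N - i, d1, d2, cap)
    P[i + 1L, ] <- stats::dhyper(0:N, g[["n1"]], g[["n2"]], N)
  }
  trans <- 2:N                       # transient states 1..N-1
  Q <- P[trans, trans, drop = FALSE]
  R_fix <- P[trans, N + 1L]
  h <- solve(diag(N - 1L) - Q, R_fix)          # fixation probabilities
  # conditional chain given eventual fixation
  Qc <- Q * outer(1 / h, h)
  t_cond <- solve(diag(N - 1L) - Qc, rep(1, N - 1L))
  list(fix_prob = h, sweep_cycles = t_cond)
}

# Exhaustive enrichment tail: P(category count among a size-k subset >=
# observed) over all k-subsets of the universe.
enrichment_enum_oracle <- function(labels, k, observed_count) {
  n <- length(labels)
  subsets <- utils::combn(n, k)
  hits <- apply(subsets, 2L, function(ix) sum(labels[ix]))
  mean(hits >= observed_count)
}

# Numerical maximal log2 slope of a curve via centered finite differences.
max_log2_slope_oracle <- function(times, counts) {
  l <- log2(counts)
  n <- length(times)
  max((l[3:n] - l[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)]))
}
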
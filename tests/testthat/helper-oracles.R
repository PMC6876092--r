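# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the hypergeometric oracle enumerates subsets, the
# reachability oracle closes a boolean matrix, and the BH oracle is the
# literal step-up definition as a double loop.

# P(X >= k) by exhaustive enumeration of all size-n subsets of 1..N, with
# genes 1..M "annotated"
enum_upper_tail <- function(N, M, n, k) {
  if (n == 0) return(if (k == 0) 1 else NA_real_)
  subs <- utils::combn(N, n)
  overlap <- colSums(subs <= M)
  mean(overlap >= k)
}

# transitive closure of the child->parent relation by boolean matrix powers
closure_matrix <- function(graph) {
  ids <- graph$id
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(graph$edges))
    A[cbind(graph$edges$child, graph$edges$parent)] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# literal BH step-up: adjusted_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
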
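# Independent oracles, deliberately written as literal scalar arithmetic so
# they share no code path with the package implementations they check.

# PCIT by explicit triple loop over trios
pcit_brute <- function(r) {
  n <- nrow(r)
  off <- abs(r) >= 1 & row(r) != col(r)
  r[off] <- sign(r[off]) * (1 - 1e-12)
  tiny <- .Machine$double.xmin
  keep <- matrix(TRUE, n, n)
  diag(keep) <- FALSE
  part <- function(a, b, c) {
    (r[a, b] - r[a, c] * r[b, c]) /
      sqrt((1 - r[a, c]^2) * (1 - r[b, c]^2))
  }
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (x == y) next
      for (z in seq_len(n)) {
        if (z == x || z == y) next
        eps <- (abs(part(x, y, z)) / max(abs(r[x, y]), tiny) +
                  abs(part(x, z, y)) / max(abs(r[x, z]), tiny) +
                  abs(part(y, z, x)) / max(abs(r[y, z]), tiny)) / 3
        if (abs(r[x, y]) <= eps * abs(r[x, z]) &&
            abs(r[x, y]) <= eps * abs(r[y, z])) {
          keep[x, y] <- FALSE
          keep[y, x] <- FALSE
        }
      }
    }
  }
  keep
}

# upper-tail hypergeometric probability by combinatorial enumeration
hyper_enum <- function(N, K, n, k) {
  i <- seq.int(k, min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
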
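# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Textbook BH step-up adjusted values: adj_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# BH step-up REJECTION at level alpha, straight from the definition:
# find the largest k with p_(k) <= k * alpha / m, reject p_(1..k).
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * alpha / m)))
  flags <- logical(m)
  if (is.finite(k) && k >= 1) flags[ord[seq_len(k)]] <- TRUE
  flags
}

# Two-stage adaptive step-up, hand-run: both stages at q' = q/(1+q),
# stage 2 at level q' * m / m0 with m0 = m - (stage-1 rejections).
oracle_bky <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(oracle_bh_reject(p, q1))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  oracle_bh_reject(p, q1 * m / (m - r1))
}

# Sort-and-pick median, independent of stats::median.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# All permutations of 1..n (recursive, small n only).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (s in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

# Toy single-protein topology in the gff3-like dialect.
topo_text <- function(id, segs) {
  paste(sprintf("%s\t%s\t%d\t%d", id,
                vapply(segs, `[[`, "", 1),
                vapply(segs, function(s) as.integer(s[[2]]), 1L),
                vapply(segs, function(s) as.integer(s[[3]]), 1L)),
        collapse = "\n")
}
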
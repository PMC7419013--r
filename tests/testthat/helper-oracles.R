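# Independent oracles, kept deliberately naive so they share no code path
# with the implementation they check.

# upper-tail binomial probability by exhaustive outcome enumeration
enum_binom_tail <- function(nt, nc, p0) {
  n <- nt + nc
  if (nt == 0) return(1)
  total <- 0
  for (k in nt:n) {
    total <- total + choose(n, k) * p0^k * (1 - p0)^(n - k)
  }
  total
}

# stepwise Holm-Bonferroni definition: sort ascending, take the running
# maximum of (m - j + 1) * p_(j), cap at 1, return in input order
holm_stepwise <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}
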
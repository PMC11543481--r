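# Numerical helpers shared across modules.

# p-values below this are floored to avoid log-domain underflow.
P_FLOOR <- 1e-300

# 95% normal CI multiplier.
CI_Z <- 1.959964

two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, P_FLOOR)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; -Inf when the difference underflows
# (including a == b, which is the exact single-SNP H3 case).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Deterministic seed splitting: a single global seed fans out to independent
# child streams (Lehmer-style), so adding a trait or protein never perturbs
# another one's draws. Results always fit in a 32-bit integer.
child_seed <- function(seed, index) {
  as.integer(((seed %% 2147483647) * 48271 + index * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
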
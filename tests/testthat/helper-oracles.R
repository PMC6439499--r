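# Independent oracles used by both the unit and the acceptance tests.
# These deliberately share no code path with the package implementation.

# Weir & Cockerham (1984) two-population theta, transcribed per allele
wc84_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  theta_components <- function(freqs, hets) {
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 / (r * nbar) + n2^2 / (r * nbar))) / (r - 1)
    pbar <- (n1 * freqs[1] + n2 * freqs[2]) / (r * nbar)
    s2 <- (n1 * (freqs[1] - pbar)^2 + n2 * (freqs[2] - pbar)^2) /
      ((r - 1) * nbar)
    hbar <- (n1 * hets[1] + n2 * hets[2]) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c <- hbar / 2
    c(a, b, c)
  }
  comp <- theta_components(c(p1, p2), c(h1, h2)) +
    theta_components(c(1 - p1, 1 - p2), c(h1, h2))
  sum(comp[1]) / sum(comp)
}

# posterior-predictive genotype probability by numerical integration of the
# binomial genotype likelihood against the Beta(1/2, 1/2)-posterior
beta_integral_prob <- function(g, n_alt, n_total) {
  f <- function(p) {
    choose(2, g) * p^g * (1 - p)^(2 - g) *
      stats::dbeta(p, n_alt + 0.5, n_total - n_alt + 0.5)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
}
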
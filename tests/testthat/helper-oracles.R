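# Independent oracles. These deliberately avoid the package's own code paths:
# the slope oracle is the closed-form covariance ratio, the LD oracle counts
# phased haplotypes directly, and the two-locus ML oracle is a coarse-to-fine
# grid search over the frequency simplex.

# closed-form simple-regression slope cov(g, y) / var(g)
slope_oracle <- function(g, y) {
  stats::cov(g, y) / stats::var(g)
}

# D, D', r2 from known haplotype counts (order: AB, Ab, aB, ab where A/B are
# the counted alleles at each site)
hap_ld_oracle <- function(n_AB, n_Ab, n_aB, n_ab) {
  tot <- n_AB + n_Ab + n_aB + n_ab
  pAB <- n_AB / tot
  pA <- (n_AB + n_Ab) / tot
  pB <- (n_AB + n_aB) / tot
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, Dprime = abs(D) / Dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# log-likelihood of two-locus genotype data under HWE given haplotype
# frequencies f = (f_ab, f_Ab, f_aB, f_AB) indexed by (gA, gB) in 0..2
twolocus_loglik <- function(counts9, f) {
  # counts9: 3x3 matrix of genotype counts, rows gA = 0,1,2, cols gB = 0,1,2
  # haplotype indices: 1 = ab, 2 = Ab, 3 = aB, 4 = AB
  P <- matrix(0, 3, 3)
  P[1, 1] <- f[1]^2                     # ab/ab
  P[2, 1] <- 2 * f[1] * f[2]            # ab/Ab
  P[3, 1] <- f[2]^2
  P[1, 2] <- 2 * f[1] * f[3]
  P[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]  # double heterozygote
  P[3, 2] <- 2 * f[2] * f[4]
  P[1, 3] <- f[3]^2
  P[2, 3] <- 2 * f[3] * f[4]
  P[3, 3] <- f[4]^2
  sum(counts9 * log(pmax(P, 1e-320)))
}

# maximum-likelihood two-locus haplotype frequencies by nested grid search
# over the 3-simplex (refined to ~2e-5 resolution); independent of the EM
grid_ml_2locus <- function(g1, g2) {
  counts9 <- matrix(0, 3, 3)
  for (i in seq_along(g1)) counts9[g1[i] + 1, g2[i] + 1] <-
      counts9[g1[i] + 1, g2[i] + 1] + 1
  best <- rep(0.25, 4)
  width <- 1
  for (round in 1:7) {  # final grid resolution ~2e-5
    step <- width / 10
    grid <- expand.grid(f1 = seq(max(0, best[1] - width / 2),
                                 min(1, best[1] + width / 2), by = step),
                        f2 = seq(max(0, best[2] - width / 2),
                                 min(1, best[2] + width / 2), by = step),
                        f3 = seq(max(0, best[3] - width / 2),
                                 min(1, best[3] + width / 2), by = step))
    grid$f4 <- 1 - grid$f1 - grid$f2 - grid$f3
    grid <- grid[grid$f4 >= 0 & grid$f4 <= 1, ]
    ll <- apply(as.matrix(grid), 1, function(f) twolocus_loglik(counts9, f))
    best <- as.numeric(grid[which.max(ll), ])
    width <- 2.5 * step
  }
  names(best) <- c("ab", "Ab", "aB", "AB")
  best
}
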
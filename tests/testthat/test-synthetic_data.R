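test_that("generator is deterministic under a fixed seed", {
  cfg <- small_config(n = 100, m = 40, seed = 77)
  p1 <- build_haplotype_pool(cfg, "AFR_AM")
  p2 <- build_haplotype_pool(cfg, "AFR_AM")
  expect_identical(p1, p2)
  g1 <- sample_genotypes(p1, 100, seed = 5)
  g2 <- sample_genotypes(p1, 100, seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  expect_false(identical(g1$dosages, sample_genotypes(p1, 100, seed = 6)$dosages))
})

test_that("pools share variant metadata but differ in frequencies; forced monomorphism holds", {
  cfg <- small_config(n = 100, m = 50, seed = 3,
                      monomorphic = list(L1_v005 = "EUR"))
  afr <- build_haplotype_pool(cfg, "AFR_AM")
  eur <- build_haplotype_pool(cfg, "EUR")
  expect_identical(afr$variants$id, eur$variants$id)
  expect_identical(afr$variants$pos, eur$variants$pos)
  expect_false(identical(afr$eaf, eur$eaf))
  expect_identical(unname(eur$eaf["L1_v005"]), 0)
  panel <- sample_genotypes(eur, 400, seed = 1)
  expect_identical(unname(eaf(panel)["L1_v005"]), 0)
})

test_that("sampled frequencies match pool frequencies within 3 binomial SEs", {
  cfg <- small_config(n = 100, m = 60, seed = 21)
  pool <- build_haplotype_pool(cfg, "EAS")
  n <- 5000
  panel <- sample_genotypes(pool, n, seed = 8)
  f_hat <- eaf(panel)
  f_pool <- pool$eaf
  se <- sqrt(pmax(f_pool * (1 - f_pool), 1e-12) / (2 * n))
  poly <- f_pool > 0 & f_pool < 1
  # allow a single 3-sigma excursion among ~60 variants
  expect_lte(sum(abs(f_hat - f_pool)[poly] > 3 * se[poly] + 1e-9), 1)
})

test_that("MAF spectrum covers rare, less common and common classes", {
  cfg <- small_config(n = 100, m = 300, seed = 10, pop_specific_frac = 0)
  pool <- build_haplotype_pool(cfg, "AFR_AM")
  maf <- pmin(pool$eaf, 1 - pool$eaf)
  maf <- maf[maf > 0]
  expect_gt(sum(maf < 0.005), 0)
  expect_gt(sum(maf >= 0.005 & maf < 0.05), 0)
  expect_gt(sum(maf >= 0.05), 0)
})

test_that("Hardy-Weinberg proportions hold (random mating by construction)", {
  cfg <- small_config(n = 100, m = 40, seed = 14)
  pool <- build_haplotype_pool(cfg, "EUR")
  panel <- sample_genotypes(pool, 4000, seed = 2)
  f <- eaf(panel)
  j <- which(f > 0.1 & f < 0.9)[1:5]
  for (jj in j) {
    g <- panel$dosages[, jj]
    p <- f[jj]
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2) * length(g)
    observed <- tabulate(g + 1, 3)
    chi2 <- sum((observed - expected)^2 / pmax(expected, 1))
    expect_lt(chi2, qchisq(0.999, df = 2))
  }
})

test_that("degenerate one-effective-founder blocks give identical individuals", {
  cfg <- small_config(n = 10, m = 6, seed = 9)
  pool <- build_haplotype_pool(cfg, "EUR")
  # collapse every block to a single founder with all mass
  pool$blocks <- lapply(pool$blocks, function(bl) {
    bl$freqs <- c(1, rep(0, length(bl$freqs) - 1)); bl
  })
  pool$rare_overlay[] <- 0
  panel <- sample_genotypes(pool, 20, seed = 4)
  expect_true(all(panel$dosages %in% c(0, 2)))
  expect_equal(nrow(unique(panel$dosages)), 1L)
})

test_that("config validation rejects degenerate parameters", {
  expect_error(small_config(n_founders = c(AFR_AM = 1L, EAS = 6L, EUR = 5L)),
               "at least 2 founder")
  expect_error(small_config(recomb = c(AFR_AM = 1.2, EAS = 0.5, EUR = 0.4)),
               "recombination")
  expect_error(sim_config(study_split = data.frame(study_id = "a",
                                                   ancestry = "EUR", n = 0)),
               "sample sizes")
})

test_that("phenotype model: pure noise variance and analytic variance share", {
  cfg <- small_config(n = 100, m = 20, seed = 33)
  pool <- build_haplotype_pool(cfg, "EUR")
  panel <- sample_genotypes(pool, 10000, seed = 3)
  spec0 <- causal_spec(sigma = 1, covariate_effects = c(age = 0, sex = 0),
                       trait = "y")
  ph <- simulate_phenotype(panel, spec0, seed = 5)
  expect_lt(abs(var(ph$y) - 1), 0.05)

  # one causal SNP: variance share 2p(1-p)b^2 / (2p(1-p)b^2 + sigma^2)
  f <- pool$eaf
  v <- names(which(f > 0.2 & f < 0.5))[1]
  b <- 0.35
  spec1 <- causal_spec(data.frame(variant_id = v, beta = b, ancestries = "all"),
                       sigma = 1, covariate_effects = c(age = 0, sex = 0),
                       trait = "y")
  panel2 <- sample_genotypes(pool, 20000, seed = 11)
  ph1 <- simulate_phenotype(panel2, spec1, seed = 6)
  g <- panel2$dosages[, v]
  share_obs <- var(b * g) / var(ph1$y)
  p_true <- mean(g) / 2
  share_exp <- 2 * p_true * (1 - p_true) * b^2 /
    (2 * p_true * (1 - p_true) * b^2 + 1)
  expect_lt(abs(share_obs - share_exp), 0.01)
})

test_that("log-normal traits are positive and log_e regression recovers beta", {
  cfg <- small_config(n = 100, m = 20, seed = 12)
  pool <- build_haplotype_pool(cfg, "EUR")
  panel <- sample_genotypes(pool, 3000, seed = 2)
  v <- names(which(pool$eaf > 0.2 & pool$eaf < 0.6))[1]
  spec <- causal_spec(data.frame(variant_id = v, beta = 0.3, ancestries = "all"),
                      sigma = 0.5, covariate_effects = c(age = 0, sex = 0),
                      trait = "TG", scale = "log_normal")
  ph <- simulate_phenotype(panel, spec, seed = 9)
  expect_true(all(ph$TG > 0))
  res <- run_association(panel, ph, "TG", transform = "log_e")
  j <- match(v, res$variant_id)
  expect_lt(abs(res$beta[j] - 0.3), 3 * res$se[j])
  expect_error(causal_spec(sigma = 0), "sigma")
})

test_that("multi-ancestry study: 11 bundles, shared pools, ancestry-restricted EAF 0", {
  split <- default_study_split()
  split$n <- pmax(40L, round(split$n / 100))
  cfg <- sim_config(study_split = split, n_loci = 1, variants_per_locus = 40,
                    seed = 19, pop_specific_frac = 0)
  spec <- causal_spec(data.frame(variant_id = "L1_v010", beta = 0.3,
                                 ancestries = "AFR_AM"),
                      sigma = 1, trait = "y")
  # force the causal variant out of the other ancestries
  cfg$monomorphic <- list(L1_v010 = c("EAS", "EUR"))
  bundle <- make_multi_ancestry_study(cfg, spec)
  expect_length(bundle$studies, 11L)
  expect_equal(bundle$study_order, default_study_split()$study_id)
  eas <- bundle$studies$CLHNS$panel
  eur <- bundle$studies$Finnish_T2D$panel
  expect_identical(unname(eaf(eas)["L1_v010"]), 0)
  expect_identical(unname(eaf(eur)["L1_v010"]), 0)
  afr <- bundle$studies$ARIC$panel
  expect_gt(eaf(afr)["L1_v010"], 0)
})

test_that("AFR_AM pools show lower average pairwise r2 than EUR pools", {
  cfg <- small_config(n = 100, m = 48, seed = 55, pop_specific_frac = 0)
  afr <- sample_genotypes(build_haplotype_pool(cfg, "AFR_AM"), 5000, seed = 1)
  eur <- sample_genotypes(build_haplotype_pool(cfg, "EUR"), 5000, seed = 1)
  mean_r2 <- function(panel) {
    f <- eaf(panel)
    keep <- f > 0.05 & f < 0.95
    cm <- suppressWarnings(cor(panel$dosages[, keep]))^2
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  }
  expect_lt(mean_r2(afr), mean_r2(eur))
})
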
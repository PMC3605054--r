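test_that("phase-unambiguous genotypes are counted exactly (no EM needed)", {
  # AABB x2 and aabb x2: all homozygotes, phase determined
  dos <- rbind(c(2, 2), c(2, 2), c(0, 0), c(0, 0))
  colnames(dos) <- c("s1", "s2"); rownames(dos) <- paste0("i", 1:4)
  panel <- manual_panel(dos)
  hs <- em_haplotype_frequencies(panel, c("s1", "s2"))
  f <- sort(hs$frequencies, decreasing = TRUE)
  expect_equal(unname(f), c(0.5, 0.5))
  expect_setequal(names(f), c("A-A", "G-G"))
})

test_that("EM matches the grid-search ML oracle on a double-heterozygote fixture", {
  tl <- twolocus_panel(20, c(0.35, 0.15, 0.10, 0.40), seed = 101)
  g <- tl$panel$dosages
  expect_gt(sum(g[, 1] == 1 & g[, 2] == 1), 0)  # ambiguity present
  hs <- em_haplotype_frequencies(tl$panel, c("snp1", "snp2"), tol = 1e-12)
  oracle <- grid_ml_2locus(g[, "snp1"], g[, "snp2"])
  # map package labels (effect-allele A, other G) onto oracle coding
  lab <- c("G-G" = "ab", "A-G" = "Ab", "G-A" = "aB", "A-A" = "AB")
  est <- setNames(rep(0, 4), c("ab", "Ab", "aB", "AB"))
  est[lab[names(hs$frequencies)]] <- hs$frequencies
  expect_lt(max(abs(est - oracle[names(est)])), 1e-4)
})

test_that("EM log-likelihood is nondecreasing and posteriors sum to 2", {
  for (seed in 1:5) {
    tl <- twolocus_panel(60, c(0.3, 0.25, 0.25, 0.2), seed = seed)
    hs <- em_haplotype_frequencies(tl$panel, c("snp1", "snp2"))
    expect_true(all(diff(hs$loglik_trace) >= -1e-9))
    expect_equal(sum(hs$frequencies), 1, tolerance = 1e-10)
    expect_equal(unname(rowSums(hs$posterior_dosages)),
                 rep(2, hs$n), tolerance = 1e-10)
  }
  # 3-site run with multi-start
  cfg <- small_config(n = 100, m = 12, seed = 6)
  panel <- sample_genotypes(build_haplotype_pool(cfg, "EUR"), 200, seed = 3)
  ids <- names(which(eaf(panel) > 0.1 & eaf(panel) < 0.9))[1:3]
  hs3 <- em_haplotype_frequencies(panel, ids, n_starts = 4, seed = 11)
  expect_true(all(diff(hs3$loglik_trace) >= -1e-9))
  expect_equal(sum(hs3$frequencies), 1, tolerance = 1e-10)
})

test_that("EM site-count contract and missing-genotype exclusion", {
  dos <- cbind(a = c(0, 1, 2, NA), b = c(0, 1, 2, 1), c = c(1, 1, 0, 0))
  rownames(dos) <- paste0("i", 1:4)
  panel <- manual_panel(dos)
  hs <- em_haplotype_frequencies(panel, c("a", "b"))
  expect_equal(hs$n, 3L)  # the individual missing at 'a' is excluded
  expect_error(em_haplotype_frequencies(panel, "a"), "2-8")
})

test_that("ld_stats: perfect LD, direct-count oracle, independence, errors", {
  set.seed(5)
  g <- rbinom(200, 2, 0.4)
  dos <- cbind(x = g, y = g, mono = rep(0, 200))
  rownames(dos) <- paste0("i", 1:200)
  panel <- manual_panel(dos)
  ld <- ld_stats(panel, "x", "y")
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_equal(ld$Dprime, 1, tolerance = 1e-6)
  expect_error(ld_stats(panel, "x", "mono"), "monomorphic")
  expect_error(ld_stats(panel, "x", "x"), "itself")

  # phased pool 40/10/10/40, paired homozygously so phase is certain:
  # direct counting gives D = 0.4 - 0.25 = 0.15, D' = 0.6, r2 = 0.36
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  idx <- rep(1:4, c(40, 10, 10, 40))
  dos2 <- hap[idx, ] + hap[idx, ]
  colnames(dos2) <- c("a", "b"); rownames(dos2) <- paste0("h", 1:100)
  oracle <- hap_ld_oracle(40, 10, 10, 40)
  expect_equal(oracle$D, 0.15)
  expect_equal(oracle$Dprime, 0.6)
  expect_equal(oracle$r2, 0.36)
  ld2 <- ld_stats(manual_panel(dos2), "a", "b")
  expect_equal(ld2$D, oracle$D, tolerance = 1e-6)
  expect_equal(ld2$Dprime, oracle$Dprime, tolerance = 1e-6)
  expect_equal(ld2$r2, oracle$r2, tolerance = 1e-6)

  # variants on distant blocks decorrelate at large n
  cfg <- small_config(n = 100, m = 60, seed = 23, pop_specific_frac = 0)
  panel3 <- sample_genotypes(build_haplotype_pool(cfg, "EUR"), 10000, seed = 2)
  f <- eaf(panel3)
  ids <- names(which(f > 0.2 & f < 0.8))
  pair <- c(ids[1], ids[length(ids)])  # first and last block
  expect_lt(ld_stats(panel3, pair[1], pair[2])$r2, 0.01)
})

test_that("r2 and D' are invariant under allele relabeling", {
  tl <- twolocus_panel(300, c(0.4, 0.2, 0.15, 0.25), seed = 42)
  ld_a <- ld_stats(tl$panel, "snp1", "snp2")
  ld_b <- ld_stats(flip_alleles(tl$panel, "snp1"), "snp1", "snp2")
  expect_equal(ld_b$r2, ld_a$r2, tolerance = 1e-9)
  expect_equal(ld_b$Dprime, ld_a$Dprime, tolerance = 1e-9)
  expect_equal(ld_b$D, -ld_a$D, tolerance = 1e-9)
})

test_that("haplotype regression: reference coding arithmetic and null behavior", {
  tl <- twolocus_panel(500, c(0.35, 0.15, 0.3, 0.2), seed = 77)
  set.seed(1)
  ph <- pheno_from_y(tl$panel, rnorm(500))
  ha <- haplotype_regression(tl$panel, c("snp1", "snp2"), ph, "y")
  hs <- attr(ha, "haplotype_set")
  k <- sum(hs$frequencies >= 0.01)
  expect_equal(nrow(ha), k - 1L)  # all haplotypes common, no rare column
  expect_false(attr(ha, "reference") %in% ha$haplotype)
  expect_error(haplotype_regression(tl$panel, c("snp1", "snp2"), ph, "y",
                                    reference = "A-A", freq_floor = 0.5),
               "below the floor")
})

test_that("haplotype regression recovers a planted haplotype effect", {
  freqs <- c(AB = 0.20, Ab = 0.15, aB = 0.65, ab = 0)
  tl <- twolocus_panel(3000, freqs, seed = 123)
  set.seed(124)
  # -0.3 per copy of the A-G haplotype (effect-increasing allele at snp1,
  # decreasing at snp2), relative to A-A
  y <- 0.39 * (tl$hap_counts[, "AB"] + tl$hap_counts[, "Ab"]) -
    0.3 * tl$hap_counts[, "Ab"] -
    0.39 * 0 + rnorm(3000)
  ph <- pheno_from_y(tl$panel, y)
  ha <- haplotype_regression(tl$panel, c("snp1", "snp2"), ph, "y",
                             reference = "A-A")
  j <- match("A-G", ha$haplotype)
  expect_false(is.na(j))
  expect_lt(abs(ha$beta[j] - (-0.3)), 2 * ha$se[j])
})
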
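test_that("empty conditioned set reproduces the plain association scan", {
  pl <- planted_locus(seed = 3, n = 800, m = 60, shares = 0.02)
  plain <- run_association(pl$panel, pl$pheno, "y")
  cond <- conditional_scan(pl$panel, pl$pheno, "y", conditioned_set = character(0))
  expect_equal(cond$beta, plain$beta)
  expect_equal(cond$p, plain$p)
  expect_false(any(cond$ld_flagged))
})

test_that("conditioning on the sole causal SNP removes the signal", {
  # with ~80 quasi-independent null tests per scan, min-p excursions below
  # 1e-3 are expected in ~8% of scans, so the locus-wide check uses the
  # scan's own threshold scale (1e-4); LD proxies of the conditioned causal
  # variant must be flat at p > 0.01
  hits <- 0L; proxy_ok <- 0L; proxy_n <- 0L
  for (seed in 1:20) {
    pl <- planted_locus(seed = seed + 200, n = 1500, m = 80, shares = 0.02)
    cond <- conditional_scan(pl$panel, pl$pheno, "y",
                             conditioned_set = pl$planted)
    if (min(cond$p) > 1e-4) hits <- hits + 1L
    r2 <- vapply(cond$variant_id, function(v)
      geno_r2(pl$panel, v, pl$planted), numeric(1))
    prox <- which(r2 > 0.5)
    proxy_n <- proxy_n + length(prox)
    proxy_ok <- proxy_ok + sum(cond$p[prox] > 0.01)
  }
  expect_gte(hits, 18L)
  expect_gte(proxy_ok / max(proxy_n, 1), 0.95)
})

test_that("sequential conditional admits planted signals in effect order", {
  pl <- planted_locus(seed = 501, n = 5000, m = 150,
                      shares = c(0.015, 0.008))
  st <- sequential_conditional(pl$panel, pl$pheno, "y")
  expect_equal(nrow(st), 2L)
  expect_equal(st$p_conditional[1], st$p_initial[1])  # signal 1 invariant
  expect_equal(st$conditioned_on, c("", st$variant_id[1]))
  # leads are the planted SNPs or near-perfect proxies, larger effect first
  r2_first <- geno_r2(pl$panel, st$variant_id[1], pl$planted[1])
  r2_second <- geno_r2(pl$panel, st$variant_id[2], pl$planted[2])
  expect_gt(r2_first, 0.9)
  expect_gt(r2_second, 0.9)
  expect_true(all(st$admitted_by == "threshold"))
})

test_that("the annotation override admits and its removal demotes (R46L-style rule)", {
  set.seed(61)
  n <- 2000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- rbinom(n, 2, 0.3)
  noise <- matrix(rbinom(n * 10, 2, 0.25), n, 10)
  dos <- cbind(s1 = g1, s2 = g2, noise)
  colnames(dos) <- c("s1", "s2", paste0("n", 1:10))
  rownames(dos) <- paste0("i", 1:n)
  y <- 0.22 * g1 + 0.12 * g2 + rnorm(n)
  ann_panel <- manual_panel(dos, annotation = c("intron", "nonsynonymous",
                                                rep("intron", 10)))
  ph <- pheno_from_y(ann_panel, y)
  st <- sequential_conditional(ann_panel, ph, "y")
  expect_equal(nrow(st), 2L)
  expect_equal(st$variant_id, c("s1", "s2"))
  expect_gt(st$p_conditional[2], 1e-4)  # in the override window
  expect_lt(st$p_conditional[2], 1e-2)
  expect_equal(st$admitted_by, c("threshold", "functional_annotation"))

  plain_panel <- manual_panel(dos, annotation = "intron")
  st0 <- sequential_conditional(plain_panel, ph, "y")
  expect_equal(nrow(st0), 1L)
})

test_that("permuted phenotypes yield no signals", {
  zeros <- 0L
  for (seed in 1:20) {
    pl <- planted_locus(seed = seed + 400, n = 1000, m = 100, shares = 0.02)
    set.seed(seed)
    ph <- pheno_from_y(pl$panel, sample(pl$pheno$y))
    st <- sequential_conditional(pl$panel, ph, "y")
    if (nrow(st) == 0L) zeros <- zeros + 1L
  }
  expect_gte(zeros, 18L)
})

test_that("max_signals truncation warns; threshold validation", {
  pl <- planted_locus(seed = 88, n = 3000, m = 60, shares = c(0.02, 0.015))
  expect_warning(sequential_conditional(pl$panel, pl$pheno, "y",
                                        max_signals = 1L),
                 "truncated")
  expect_error(sequential_conditional(pl$panel, pl$pheno, "y", threshold = 1.5),
               "threshold")
})

test_that("population specificity follows the monomorphic-elsewhere rule", {
  mk <- function(eafs) {
    dos <- vapply(eafs, function(f) {
      if (f == 0) rep(0, 200) else if (f == 1) rep(2, 200)
      else rbinom(200, 2, f)
    }, numeric(200))
    colnames(dos) <- paste0("v", seq_along(eafs))
    rownames(dos) <- paste0("i", 1:200)
    manual_panel(dos)
  }
  set.seed(12)
  panels <- list(AFR_AM = mk(c(0.05, 0.110)), EAS = mk(c(0, 0.086)),
                 EUR = mk(c(0, 0.056)))
  # rare AFR-only variant: monomorphic in both other groups -> specific
  expect_true(suppressMessages(
    classify_population_specific("v1", panels, "AFR_AM")))
  # polymorphic everywhere (rs7412-like frequencies) -> not specific
  expect_false(suppressMessages(
    classify_population_specific("v2", panels, "AFR_AM")))
  # monomorphic everywhere -> untestable
  panels0 <- list(AFR_AM = mk(c(0)), EAS = mk(c(0)), EUR = mk(c(0)))
  expect_error(suppressMessages(
    classify_population_specific("v1", panels0, "AFR_AM")), "untestable")
})

test_that("reference pools participate in the specificity decision", {
  set.seed(13)
  mkp <- function(f) {
    dos <- cbind(v1 = if (f == 0) rep(0, 100) else rbinom(100, 2, f))
    rownames(dos) <- paste0("i", 1:100)
    manual_panel(dos)
  }
  panels <- list(AFR_AM = mkp(0.05), EAS = mkp(0), EUR = mkp(0))
  refs <- list(EAS = mkp(0), EUR = mkp(0.03))  # polymorphic in a reference
  expect_true(suppressMessages(classify_population_specific("v1", panels, "AFR_AM")))
  expect_false(classify_population_specific("v1", panels, "AFR_AM",
                                            reference_pools = refs))
})

test_that("dependence report separates masked, independent and self pairs", {
  # repulsion-phase fixture: decreasing allele of snp2 rides on haplotypes
  # carrying the increasing allele of snp1 -> masked marginally
  freqs <- c(AB = 0.15, Ab = 0.20, aB = 0, ab = 0.65)
  tl <- twolocus_panel(3000, freqs, seed = 9)
  set.seed(10)
  dosA1 <- tl$panel$dosages[, "snp1"]
  dosB2 <- tl$panel$dosages[, "snp2"]
  y <- 0.392 * dosA1 - 0.3 * dosB2 + rnorm(3000)
  ph <- pheno_from_y(tl$panel, y)
  rep_masked <- dependence_report("snp1", "snp2", tl$panel, ph, "y")
  expect_equal(rep_masked$classification, "masked")
  expect_lt(rep_masked$p_conditional, rep_masked$p_initial)
  expect_gt(rep_masked$Dprime, 0.9)

  # uncorrelated causal SNPs are independent
  set.seed(11)
  g1 <- rbinom(3000, 2, 0.3); g2 <- rbinom(3000, 2, 0.3)
  dos <- cbind(u1 = g1, u2 = g2); rownames(dos) <- paste0("i", 1:3000)
  pan <- manual_panel(dos)
  y2 <- 0.15 * g1 + 0.15 * g2 + rnorm(3000)
  rep_ind <- dependence_report("u1", "u2", pan, pheno_from_y(pan, y2), "y")
  expect_equal(rep_ind$classification, "independent")

  expect_error(dependence_report("u1", "u1", pan, pheno_from_y(pan, y2), "y"),
               "itself")
})
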
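# Fixture builders. Everything is generated in code at test time; no binary
# files. Simulation scales here are smaller than the generator's full-study
# defaults to keep the suite fast; the acceptance tests state their scales
# explicitly.

# a minimal single-study config
small_config <- function(n = 500, m = 60, seed = 42, ancestry = "EUR",
                         ...) {
  sim_config(study_split = data.frame(study_id = "S1", ancestry = ancestry,
                                      n = n, stringsAsFactors = FALSE),
             n_loci = 1L, variants_per_locus = m, seed = seed, ...)
}

# panel with dosages specified directly (variants get 1 kb spacing)
manual_panel <- function(dosages, annotation = "unknown", ancestry = "other",
                         study_id = "study1") {
  m <- ncol(dosages)
  ids <- colnames(dosages) %||% paste0("v", seq_len(m))
  vt <- variant_table(ids, "1", 1000L * seq_len(m), "A", "G",
                      annotation = annotation)
  genotype_panel(dosages, vt, rownames(dosages), study_id, ancestry,
                 max_missing = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pheno_from_y <- function(panel, y, trait = "y") {
  phenotype_table(data.frame(sample_id = panel$sample_ids, y = y,
                             stringsAsFactors = FALSE),
                  traits = trait)
}

# Panel of n individuals built from two-locus haplotypes drawn with the given
# frequencies (order: AB, Ab, aB, ab in effect-allele coding). Returns panel
# plus the phased haplotype matrix and per-individual haplotype copy counts.
twolocus_panel <- function(n, freqs, seed) {
  set.seed(seed)
  hap_alleles <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  idx <- sample.int(4L, 2L * n, replace = TRUE, prob = freqs)
  H <- hap_alleles[idx, , drop = FALSE]
  a <- seq(1L, 2L * n, by = 2L)
  dos <- H[a, ] + H[a + 1L, ]
  colnames(dos) <- c("snp1", "snp2")
  rownames(dos) <- paste0("I", seq_len(n))
  hap_counts <- vapply(1:4, function(k)
    (idx[a] == k) + (idx[a + 1L] == k), numeric(n))
  colnames(hap_counts) <- c("AB", "Ab", "aB", "ab")
  list(panel = manual_panel(dos), hap_counts = hap_counts, hap_idx = idx)
}

# A locus with m_signals planted causal variants in well-separated blocks.
# Variance shares (of a sigma=1 trait) default to 1.2% / 0.9% / 0.7% -- all
# above the 0.5% floor, sized a priori for high marginal power at p < 1e-4.
# Causal variants are planted at sites without moderate-LD neighbours
# (max r2 to any other variant <= 0.5): lead identity between statistically
# near-interchangeable variants is not what signal recovery measures.
planted_locus <- function(seed, n = 5000, m = 300,
                          shares = c(0.012, 0.009, 0.007),
                          m_signals = length(shares), ancestry = "EUR") {
  cfg <- small_config(n = n, m = m, seed = seed, ancestry = ancestry,
                      pop_specific_frac = 0)
  pool <- build_haplotype_pool(cfg, ancestry)
  panel <- sample_genotypes(pool, n, seed = seed + 7L)
  f <- eaf(panel)
  cand <- which(f > 0.15 & f < 0.5)
  C2 <- suppressWarnings(cor(panel$dosages[, cand, drop = FALSE],
                             panel$dosages))^2
  for (i in seq_along(cand)) C2[i, cand[i]] <- 0
  max_r2 <- apply(C2, 1L, max, na.rm = TRUE)
  clean <- cand[max_r2 <= 0.5]
  if (length(clean) < m_signals)
    clean <- cand[order(max_r2)][seq_len(max(m_signals, 2L))]
  clean <- sort(clean)
  # greedy spread: planted signals mutually uncorrelated and well separated
  gap <- max(5L, min(25L, m %/% (m_signals + 1L)))
  picks_idx <- clean[1L]
  for (j in clean[-1L]) {
    if (length(picks_idx) >= m_signals) break
    r2_to_picked <- suppressWarnings(
      cor(panel$dosages[, j], panel$dosages[, picks_idx, drop = FALSE]))^2
    if (j - picks_idx[length(picks_idx)] >= gap &&
        all(r2_to_picked < 0.05, na.rm = TRUE))
      picks_idx <- c(picks_idx, j)
  }
  if (length(picks_idx) < m_signals) {  # fallback: relax the spacing
    for (j in setdiff(clean, picks_idx)) {
      if (length(picks_idx) >= m_signals) break
      r2_to_picked <- suppressWarnings(
        cor(panel$dosages[, j], panel$dosages[, picks_idx, drop = FALSE]))^2
      if (all(r2_to_picked < 0.05, na.rm = TRUE)) picks_idx <- c(picks_idx, j)
    }
  }
  if (length(picks_idx) < m_signals)
    stop("panel does not admit ", m_signals,
         " mutually uncorrelated planted signals")
  picks_idx <- picks_idx[seq_len(m_signals)]
  picks <- pool$variants$id[picks_idx]
  pe <- f[picks_idx]
  shares <- shares[seq_len(m_signals)]
  beta <- sqrt(shares / (2 * pe * (1 - pe)))
  spec <- causal_spec(data.frame(variant_id = picks, beta = beta,
                                 ancestries = "all",
                                 stringsAsFactors = FALSE),
                      sigma = 1, covariate_effects = c(age = 0, sex = 0),
                      trait = "y")
  pheno <- simulate_phenotype(panel, spec, seed = seed + 13L)
  list(panel = panel, pheno = pheno, planted = picks, pool = pool)
}

# genotype r2 between two variants of a panel
geno_r2 <- function(panel, a, b) {
  j <- match(c(a, b), panel$variants$id)
  suppressWarnings(cor(panel$dosages[, j[1]], panel$dosages[, j[2]],
                       use = "complete.obs"))^2
}

write_toy_vcf <- function(path, extra_lines = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trsA\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0",
    extra_lines)
  writeLines(lines, path)
  path
}
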
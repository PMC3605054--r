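# Synthetic multi-ancestry genotype/phenotype generator.
#
# The LD model is a block-mosaic founder-haplotype scheme: each ancestry has
# its own set of founder haplotypes per block; an individual haplotype copies
# one founder within each block and switches founders between blocks with a
# fixed recombination probability. African-American panels use shorter blocks,
# more founders and a higher between-block switch rate (plus a two-subpool
# 0.8/0.2 admixture approximation), producing the lower average pairwise r2
# that trans-ethnic refinement exploits.

#' Default 11-group study subdivision
#'
#' Five African-American, two East Asian and four European study groups.
#' Totals per ancestry are 6,832 / 9,449 / 10,829; the within-ancestry split
#' is synthetic except where single-cohort sizes are known (CLHNS 1,716,
#' TAICHI 7,733).
#' @return data.frame with columns study_id, ancestry, n.
#' @export
default_study_split <- function() {
  data.frame(
    study_id = c("ARIC", "MEC", "WHI_batch1", "WHI_batch2", "HyperGEN",
                 "CLHNS", "TAICHI",
                 "Finnish_T2D", "Finnish_unaffected", "Norwegian_T2D",
                 "Norwegian_unaffected"),
    ancestry = c(rep("AFR_AM", 5), rep("EAS", 2), rep("EUR", 4)),
    n = c(2500L, 1500L, 600L, 1000L, 1232L,
          1716L, 7733L,
          2300L, 5000L, 1200L, 2329L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults state the emulated design: three ancestry groups subdivided into
#' 11 studies, ~300 variants per locus spanning the full MAF spectrum (rare
#' <0.005, less common 0.005-0.05, common >=0.05), ancestry-specific block
#' LD (short blocks / many founders / frequent switches for AFR_AM), and a
#' fraction of variants restricted to a single ancestry.
#'
#' @param study_split data.frame(study_id, ancestry, n); see
#'   [default_study_split()].
#' @param n_loci number of independent loci.
#' @param variants_per_locus variants per locus.
#' @param maf_mix class probabilities for rare / less common / common targets.
#' @param block_size,n_founders,recomb named per-ancestry LD parameters.
#'   `recomb` is the probability of redrawing the founder at each block
#'   boundary; defaults are high so LD is concentrated within blocks (the
#'   haplotype-block regime) and the ancestry contrast is carried by block
#'   length and founder count.
#' @param admix_prop AFR_AM founder-subpool mixing proportion.
#' @param pop_specific_frac fraction of variants restricted to one ancestry.
#' @param spacing_bp inter-variant spacing in base pairs.
#' @param monomorphic optional named list `variant_id -> ancestries` forced
#'   monomorphic (EAF exactly 0) there.
#' @param seed integer master seed; fixing it makes every product of the
#'   generator deterministic.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(study_split = default_study_split(),
                       n_loci = 2L, variants_per_locus = 300L,
                       maf_mix = c(rare = 0.10, less_common = 0.20, common = 0.70),
                       block_size = c(AFR_AM = 8L, EAS = 20L, EUR = 25L),
                       n_founders = c(AFR_AM = 16L, EAS = 6L, EUR = 5L),
                       recomb = c(AFR_AM = 0.95, EAS = 0.9, EUR = 0.8),
                       admix_prop = 0.8,
                       pop_specific_frac = 0.10,
                       spacing_bp = 1000L,
                       monomorphic = list(),
                       seed = 1L) {
  stopifnot(is.data.frame(study_split),
            all(c("study_id", "ancestry", "n") %in% names(study_split)))
  if (any(study_split$n <= 0)) stop_tf("study sample sizes must be > 0")
  if (any(n_founders < 2L)) stop_tf("need at least 2 founder haplotypes per block")
  if (any(recomb < 0 | recomb > 1)) stop_tf("recombination probability must be in [0,1]")
  assert_scalar_number(pop_specific_frac, "pop_specific_frac", 0, 1)
  assert_scalar_number(admix_prop, "admix_prop", 0, 1)
  structure(list(study_split = study_split, n_loci = as.integer(n_loci),
                 variants_per_locus = as.integer(variants_per_locus),
                 maf_mix = maf_mix / sum(maf_mix),
                 block_size = block_size, n_founders = n_founders,
                 recomb = recomb, admix_prop = admix_prop,
                 pop_specific_frac = pop_specific_frac,
                 spacing_bp = as.integer(spacing_bp),
                 monomorphic = monomorphic,
                 seed = as.integer(seed)),
            class = "sim_config")
}

ancestry_offset <- function(ancestry) {
  match(ancestry, ANCESTRY_LEVELS) * 7919L
}

# Shared (ancestry-independent) per-locus variant plan: ids, positions,
# alleles, target allele frequencies and population restriction.
locus_variant_plan <- function(config, locus) {
  m <- config$variants_per_locus
  set.seed(derive_seed(config$seed, 31L * locus))
  cls <- sample(names(config$maf_mix), m, replace = TRUE, prob = config$maf_mix)
  target <- numeric(m)
  target[cls == "rare"] <- runif(sum(cls == "rare"), 0.001, 0.005)
  target[cls == "less_common"] <- runif(sum(cls == "less_common"), 0.005, 0.05)
  target[cls == "common"] <- runif(sum(cls == "common"), 0.05, 0.5)
  restricted <- rep(NA_character_, m)
  n_restrict <- round(config$pop_specific_frac * m)
  if (n_restrict > 0) {
    idx <- sample.int(m, n_restrict)
    # African-American panels harbour most of the population-specific variation
    restricted[idx] <- sample(c("AFR_AM", "EAS", "EUR"), n_restrict,
                              replace = TRUE, prob = c(0.6, 0.2, 0.2))
  }
  alle <- t(replicate(m, sample(c("A", "C", "G", "T"), 2L)))
  ids <- sprintf("L%d_v%03d", locus, seq_len(m))
  vt <- variant_table(ids, chrom = as.character(locus),
                      pos = 1000000L * locus + config$spacing_bp * seq_len(m),
                      effect_allele = alle[, 1], other_allele = alle[, 2],
                      locus_id = paste0("locus", locus))
  list(variants = vt, target = target, restricted = restricted)
}

rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, alpha)
  g / sum(g)
}

#' Build an ancestry-specific founder haplotype pool
#'
#' Pools for different ancestries share variant ids, positions and alleles but
#' differ in founder haplotypes, founder frequencies, block lengths and the
#' between-block switch rate. Variants restricted to other ancestries (and any
#' configured monomorphic variants) carry the effect allele on no founder, so
#' their EAF is exactly 0. Rare targets (<0.005) are realized as independent
#' per-haplotype Bernoulli overlays rather than founder alleles, since founder
#' frequency granularity cannot represent them.
#'
#' @param config a [sim_config()].
#' @param ancestry ancestry group to build.
#' @param locus locus index (1-based).
#' @return object of class `haplotype_pool`.
#' @export
build_haplotype_pool <- function(config, ancestry, locus = 1L) {
  stopifnot(inherits(config, "sim_config"))
  ancestry <- match.arg(ancestry, ANCESTRY_LEVELS)
  plan <- locus_variant_plan(config, locus)
  m <- nrow(plan$variants)
  K <- as.integer(config$n_founders[[ancestry]])
  if (is.na(K) || K < 2L) stop_tf("need at least 2 founder haplotypes per block")
  bs <- as.integer(config$block_size[[ancestry]])
  rho <- config$recomb[[ancestry]]
  block_of <- ceiling(seq_len(m) / bs)
  n_blocks <- max(block_of)

  target <- plan$target
  off <- !is.na(plan$restricted) & plan$restricted != ancestry
  forced <- names(config$monomorphic)[vapply(config$monomorphic, function(a)
    ancestry %in% a, logical(1))]
  off <- off | plan$variants$id %in% forced
  target[off] <- 0
  rare <- target > 0 & target < 0.005

  set.seed(derive_seed(config$seed, 131L * locus + ancestry_offset(ancestry)))
  # one founder-frequency vector per pool: the mosaic founder-index chain then
  # has this distribution as its marginal at every block, so pool EAFs are the
  # exact expectations of sampled frequencies
  freqs <- if (ancestry == "AFR_AM" && K >= 4L) {
    k1 <- K %/% 2L
    c(config$admix_prop * rdirichlet1(k1),
      (1 - config$admix_prop) * rdirichlet1(K - k1))
  } else rdirichlet1(K)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    vb <- which(block_of == b)
    founders <- matrix(0L, K, length(vb))
    for (jj in seq_along(vb)) {
      v <- vb[jj]
      if (rare[v] || target[v] == 0) next  # overlay or monomorphic
      # greedy founder subset whose total frequency best matches the target
      ord <- sample.int(K)
      cs <- c(0, cumsum(freqs[ord]))
      k_star <- which.min(abs(cs - target[v])) - 1L
      if (k_star >= K) k_star <- K - 1L  # keep polymorphic
      if (k_star == 0L) {
        founders[which.min(freqs), jj] <- 1L  # rarest founder keeps it polymorphic
      } else {
        founders[ord[seq_len(k_star)], jj] <- 1L
      }
    }
    blocks[[b]] <- list(founders = founders, freqs = freqs, variant_idx = vb)
  }

  pool_eaf <- numeric(m)
  for (b in seq_len(n_blocks)) {
    bl <- blocks[[b]]
    pool_eaf[bl$variant_idx] <- as.numeric(crossprod(bl$freqs, bl$founders))
  }
  pool_eaf[rare] <- target[rare]

  structure(list(ancestry = ancestry, locus = locus,
                 variants = plan$variants, blocks = blocks,
                 block_of = block_of, recomb = rho,
                 rare_overlay = setNames(target * rare, plan$variants$id),
                 eaf = setNames(pool_eaf, plan$variants$id)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("<haplotype_pool> %s locus %d: %d variants, %d blocks, switch %.2f\n",
              x$ancestry, x$locus, nrow(x$variants), length(x$blocks), x$recomb))
  invisible(x)
}

# Sample 2n haplotypes from a pool as block mosaics; returns 0/1 matrix.
sample_haplotypes <- function(pool, n_hap) {
  m <- nrow(pool$variants)
  H <- matrix(0L, n_hap, m)
  idx_prev <- NULL
  for (b in seq_along(pool$blocks)) {
    bl <- pool$blocks[[b]]
    K <- length(bl$freqs)
    draw <- sample.int(K, n_hap, replace = TRUE, prob = bl$freqs)
    if (is.null(idx_prev)) {
      idx <- draw
    } else {
      keep <- runif(n_hap) >= pool$recomb
      idx <- ifelse(keep, idx_prev, draw)
    }
    H[, bl$variant_idx] <- bl$founders[idx, , drop = FALSE]
    idx_prev <- idx
  }
  ov <- which(pool$rare_overlay > 0)
  for (v in ov) H[, v] <- rbinom(n_hap, 1L, pool$rare_overlay[v])
  H
}

#' Sample a genotype panel from a haplotype pool
#'
#' Each individual is the sum of two independently drawn mosaic haplotypes
#' (random mating, hence Hardy-Weinberg proportions by construction).
#'
#' @param pool a [build_haplotype_pool()] result.
#' @param n number of individuals.
#' @param seed integer seed.
#' @param study_id panel label; sample ids are `<study_id>_1..n`.
#' @param keep_haplotypes if TRUE, the phased 2n x m haplotype matrix is
#'   attached as attribute `"haplotypes"` (useful for fixtures with known
#'   phase).
#' @return a [genotype_panel()].
#' @export
sample_genotypes <- function(pool, n, seed = 1L, study_id = "study1",
                             keep_haplotypes = FALSE) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (n < 1L) stop_tf("n must be >= 1")
  set.seed(seed)
  H <- sample_haplotypes(pool, 2L * n)
  dos <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(dos) <- paste0(study_id, "_", seq_len(n))
  p <- genotype_panel(dos, pool$variants, rownames(dos), study_id,
                      pool$ancestry, max_missing = 0)
  if (keep_haplotypes) attr(p, "haplotypes") <- H
  p
}

#' Specify the additive generative model for a quantitative trait
#'
#' The trait is `y = sum_j beta_j g_j + sum_k gamma_k c_k + e`,
#' `e ~ N(0, sigma^2)`. With `scale = "log_normal"` the reported value is
#' `exp(y)` (strictly positive), so natural-log transformation recovers the
#' linear model — the convention used for triglycerides.
#'
#' @param effects data.frame(variant_id, beta, ancestries); `ancestries` is
#'   `"all"` or a comma/semicolon list restricting where the effect is active.
#' @param sigma residual standard deviation (> 0), trait units.
#' @param covariate_effects named numeric vector (units per covariate unit).
#' @param trait trait name.
#' @param scale `"linear"` or `"log_normal"`.
#' @export
causal_spec <- function(effects = data.frame(variant_id = character(0),
                                             beta = numeric(0),
                                             ancestries = character(0)),
                        sigma = 1, covariate_effects = c(age = 0.01, sex = 0.1),
                        trait = "trait", scale = c("linear", "log_normal")) {
  scale <- match.arg(scale)
  assert_scalar_number(sigma, "sigma", 0, strict_lower = TRUE)
  if (nrow(effects) && !"ancestries" %in% names(effects)) effects$ancestries <- "all"
  structure(list(effects = effects, sigma = sigma,
                 covariate_effects = covariate_effects,
                 trait = trait, scale = scale),
            class = "causal_spec")
}

sim_covariates <- function(sample_ids, seed) {
  set.seed(seed)
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             age = runif(n, 30, 70),
             sex = rbinom(n, 1L, 0.5),
             stringsAsFactors = FALSE)
}

#' Simulate a quantitative trait for a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param spec a [causal_spec()].
#' @param covariates optional data.frame with `sample_id` plus covariate
#'   columns; simulated (age, sex) if NULL.
#' @param seed integer seed.
#' @return a [phenotype_table()] with the trait and covariate columns.
#' @export
simulate_phenotype <- function(panel, spec, covariates = NULL, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(spec, "causal_spec"))
  if (is.null(covariates))
    covariates <- sim_covariates(panel$sample_ids, derive_seed(seed, 17L))
  covariates <- covariates[match(panel$sample_ids, covariates$sample_id), ,
                           drop = FALSE]
  set.seed(seed)
  n <- length(panel$sample_ids)
  y <- rnorm(n, 0, spec$sigma)
  eff <- spec$effects
  if (nrow(eff)) {
    active <- vapply(eff$ancestries, function(a)
      a == "all" || panel$ancestry %in% strsplit(a, "[,;]\\s*")[[1]], logical(1))
    for (i in which(active)) {
      j <- match(eff$variant_id[i], panel$variants$id)
      if (is.na(j))
        stop_tf("causal variant absent from panel: ", eff$variant_id[i])
      g <- panel$dosages[, j]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      y <- y + eff$beta[i] * g
    }
  }
  for (cn in names(spec$covariate_effects)) {
    if (!cn %in% names(covariates)) next
    y <- y + spec$covariate_effects[[cn]] * covariates[[cn]]
  }
  value <- if (spec$scale == "log_normal") exp(y) else y
  df <- covariates
  df[[spec$trait]] <- value
  # log_normal traits are reported on the raw (positive) scale
  phenotype_table(df, traits = spec$trait,
                  covariates = setdiff(names(covariates), "sample_id"),
                  scale = setNames("linear", spec$trait))
}

#' Generate the full multi-ancestry study
#'
#' One genotype panel + phenotype table per study group; groups of one
#' ancestry share the same founder pools. Loci are generated independently
#' and concatenated into a single panel per study.
#'
#' @param config a [sim_config()].
#' @param spec a [causal_spec()].
#' @return list with elements `studies` (named list of
#'   `list(panel, phenotypes)`), `pools` (per ancestry, list over loci),
#'   `study_order`, and `config`.
#' @export
make_multi_ancestry_study <- function(config, spec) {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "causal_spec"))
  ancestries <- unique(config$study_split$ancestry)
  pools <- lapply(setNames(ancestries, ancestries), function(a)
    lapply(seq_len(config$n_loci), function(l) build_haplotype_pool(config, a, l)))
  studies <- list()
  for (i in seq_len(nrow(config$study_split))) {
    sid <- config$study_split$study_id[i]
    anc <- config$study_split$ancestry[i]
    n <- config$study_split$n[i]
    seed_i <- derive_seed(config$seed, 977L * i)
    panels <- lapply(seq_len(config$n_loci), function(l)
      sample_genotypes(pools[[anc]][[l]], n, derive_seed(seed_i, l), sid))
    panel <- if (length(panels) == 1L) panels[[1L]] else {
      dos <- do.call(cbind, lapply(panels, function(p) p$dosages))
      vt <- do.call(rbind, lapply(panels, function(p) p$variants))
      class(vt) <- c("variant_table", "data.frame")
      genotype_panel(dos, vt, panels[[1L]]$sample_ids, sid, anc, max_missing = 0)
    }
    pheno <- simulate_phenotype(panel, spec, seed = derive_seed(seed_i, 5000L))
    studies[[sid]] <- list(panel = panel, phenotypes = pheno)
  }
  list(studies = studies, pools = pools,
       study_order = config$study_split$study_id, config = config)
}

#' Pool the study groups of one ancestry into a single panel + phenotype table
#'
#' Dosage matrices are stacked; a categorical `study` covariate column records
#' group membership so pooled regressions can adjust for study.
#'
#' @param study_bundle result of [make_multi_ancestry_study()].
#' @param ancestry ancestry group to pool.
#' @return list(panel, phenotypes) with study indicator covariates appended.
#' @export
pool_ancestry <- function(study_bundle, ancestry) {
  sel <- names(study_bundle$studies)[
    vapply(study_bundle$studies, function(s) s$panel$ancestry == ancestry,
           logical(1))]
  if (!length(sel)) stop_tf("no studies with ancestry ", ancestry)
  dos <- do.call(rbind, lapply(study_bundle$studies[sel], function(s) s$panel$dosages))
  vt <- study_bundle$studies[[sel[1]]]$panel$variants
  ph <- do.call(rbind, lapply(sel, function(sid) {
    d <- as.data.frame(study_bundle$studies[[sid]]$phenotypes)
    d$study <- sid
    d
  }))
  # study indicator dummies (first study is the baseline)
  if (length(sel) > 1L)
    for (sid in sel[-1L]) ph[[paste0("study_", sid)]] <- as.numeric(ph$study == sid)
  tr <- attr(study_bundle$studies[[sel[1]]]$phenotypes, "traits")
  cov0 <- attr(study_bundle$studies[[sel[1]]]$phenotypes, "covariates")
  covs <- c(cov0, if (length(sel) > 1L) paste0("study_", sel[-1L]))
  panel <- genotype_panel(dos, vt, ph$sample_id, paste0(ancestry, "_pooled"),
                          ancestry, max_missing = 0)
  list(panel = panel,
       phenotypes = phenotype_table(ph[, c("sample_id", tr, covs)], tr, covs))
}
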
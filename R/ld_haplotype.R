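# Haplotype-frequency estimation by EM from unphased genotypes, pairwise LD
# statistics, and haplotype regression against a reference haplotype.
#
# The EM treats each individual's multilocus genotype as an unordered pair of
# haplotypes drawn under random mating. E-step: diplotype posterior
# probabilities proportional to f_j f_k (times 2 for heterozygous pairs);
# M-step: expected haplotype counts over 2N chromosomes. The log-likelihood
# is recorded every iteration and is guaranteed nondecreasing.

hap_label <- function(alleles01, variants) {
  # 0 -> other allele, 1 -> effect allele, joined by '-'
  apply(alleles01, 1L, function(a)
    paste(ifelse(a == 1L, variants$effect_allele, variants$other_allele),
          collapse = "-"))
}

# Enumerate, for one multilocus genotype (vector over L sites of 0/1/2), the
# compatible haplotype pairs as indices into the 2^L haplotype table whose
# row r encodes bits of r-1 (site 1 = least significant bit).
compatible_pairs <- function(geno) {
  L <- length(geno)
  het <- which(geno == 1L)
  base <- sum((geno == 2L) * 2^(seq_len(L) - 1L))
  if (!length(het)) return(matrix(base + 1L, 1L, 2L))
  h <- length(het)
  combos <- as.matrix(expand.grid(rep(list(0:1), h)))
  h1 <- base + combos %*% 2^(het - 1L)
  h2 <- base + (1L - combos) %*% 2^(het - 1L)
  pair <- cbind(as.integer(h1) + 1L, as.integer(h2) + 1L)
  # unordered: keep each pair once
  pair <- pair[pair[, 1L] <= pair[, 2L], , drop = FALSE]
  unique(pair)
}

#' EM haplotype-frequency estimation from unphased genotypes
#'
#' @param panel a [genotype_panel()] (or a 0/1/2 dosage matrix).
#' @param variant_ids 2 to 8 variant ids (columns for a bare matrix).
#' @param tol stop when the log-likelihood gain drops below this.
#' @param max_iter iteration cap; exceeding it sets `converged = FALSE`.
#' @param n_starts number of EM starts; the first start is at linkage
#'   equilibrium (product of allele frequencies), further seeded random
#'   starts guard against multimodality for 3+ sites.
#' @param seed seed for the random starts.
#' @param prune haplotypes with final frequency below this are dropped from
#'   the output (posterior mass renormalized).
#' @return object of class `haplotype_set`: `variant_ids`, `alleles` (0/1
#'   matrix), `labels`, `frequencies`, `posterior_dosages` (n x H, rows sum
#'   to 2), `loglik_trace` (nondecreasing), `converged`, `n`.
#' @export
em_haplotype_frequencies <- function(panel, variant_ids, tol = 1e-8,
                                     max_iter = 1000L, n_starts = 1L,
                                     seed = NULL, prune = 1e-6) {
  if (inherits(panel, "genotype_panel")) {
    j <- match(variant_ids, panel$variants$id)
    if (anyNA(j)) stop_tf("variant id(s) absent from panel: ",
                          paste(variant_ids[is.na(j)], collapse = ", "))
    Gm <- panel$dosages[, j, drop = FALSE]
    variants <- panel$variants[j, , drop = FALSE]
  } else {
    Gm <- as.matrix(panel)[, variant_ids, drop = FALSE]
    variants <- variant_table(variant_ids, "?", seq_along(variant_ids), "A", "G")
  }
  L <- ncol(Gm)
  if (L < 2L || L > 8L) stop_tf("em_haplotype_frequencies supports 2-8 variants")
  cc <- complete.cases(Gm)
  Gm <- Gm[cc, , drop = FALSE]
  n <- nrow(Gm)
  if (n < 1L) stop_tf("no individuals with complete genotypes at these sites")

  H <- 2L^L
  hap_alleles <- t(vapply(seq_len(H) - 1L,
                          function(r) as.integer(bitwAnd(r, 2^(seq_len(L) - 1L)) > 0),
                          integer(L)))

  # group identical genotype rows; precompute compatible diplotypes per group
  key <- apply(Gm, 1L, paste, collapse = ",")
  grp <- split(seq_len(n), key)
  g_rows <- t(vapply(strsplit(names(grp), ","), as.integer, integer(L)))
  if (L == 1L) g_rows <- matrix(g_rows, ncol = 1L)
  counts <- lengths(grp)
  pairs <- lapply(seq_len(nrow(g_rows)), function(i) compatible_pairs(g_rows[i, ]))

  af <- colMeans(Gm) / 2
  le_start <- apply(hap_alleles, 1L, function(a) prod(ifelse(a == 1L, af, 1 - af)))

  run_em <- function(f0) {
    f <- f0 / sum(f0)
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # per-group diplotype probabilities under current f
      pp <- lapply(pairs, function(pr) {
        w <- f[pr[, 1L]] * f[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
        w
      })
      lik_g <- vapply(pp, sum, numeric(1))
      ll <- sum(counts * log(pmax(lik_g, 1e-320)))
      trace <- c(trace, ll)
      # expected haplotype counts
      cnt <- numeric(H)
      for (gi in seq_along(pairs)) {
        pr <- pairs[[gi]]
        post <- pp[[gi]] / lik_g[gi]
        add <- counts[gi] * post
        for (r in seq_len(nrow(pr))) {
          cnt[pr[r, 1L]] <- cnt[pr[r, 1L]] + add[r]
          cnt[pr[r, 2L]] <- cnt[pr[r, 2L]] + add[r]
        }
      }
      f_new <- cnt / (2 * n)
      if (it > 1L && ll - ll_prev < tol) { converged <- TRUE; f <- f_new; break }
      ll_prev <- ll
      f <- f_new
    }
    list(f = f, trace = trace, converged = converged)
  }

  best <- run_em(le_start)
  if (n_starts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (s in seq_len(n_starts - 1L)) {
      cand <- run_em(rdirichlet1(H))
      if (max(cand$trace) > max(best$trace)) best <- cand
    }
  }
  f <- best$f

  # posterior expected haplotype copy counts per individual
  post_d <- matrix(0, n, H)
  for (gi in seq_along(pairs)) {
    pr <- pairs[[gi]]
    w <- f[pr[, 1L]] * f[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
    if (sum(w) == 0) w <- rep(1 / length(w), length(w))
    post <- w / sum(w)
    dvec <- numeric(H)
    for (r in seq_len(nrow(pr))) {
      dvec[pr[r, 1L]] <- dvec[pr[r, 1L]] + post[r]
      dvec[pr[r, 2L]] <- dvec[pr[r, 2L]] + post[r]
    }
    post_d[grp[[gi]], ] <- matrix(dvec, length(grp[[gi]]), H, byrow = TRUE)
  }

  keep <- f >= prune
  f_out <- f[keep] / sum(f[keep])
  post_out <- post_d[, keep, drop = FALSE]
  post_out <- post_out * (2 / rowSums(post_out))
  labels <- hap_label(hap_alleles[keep, , drop = FALSE], variants)
  colnames(post_out) <- labels
  if (inherits(panel, "genotype_panel"))
    rownames(post_out) <- panel$sample_ids[cc]
  structure(list(variant_ids = variants$id,
                 alleles = hap_alleles[keep, , drop = FALSE],
                 labels = labels,
                 frequencies = setNames(f_out, labels),
                 posterior_dosages = post_out,
                 loglik_trace = best$trace,
                 converged = best$converged, n = n),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d sites, %d haplotypes, n=%d, %s\n",
              length(x$variant_ids), length(x$frequencies), x$n,
              if (x$converged) "converged" else "NOT converged"))
  print(round(sort(x$frequencies, decreasing = TRUE), 4))
  invisible(x)
}

#' Pairwise linkage disequilibrium (D, D', r2) between two variants
#'
#' Two-locus haplotype frequencies are estimated by
#' [em_haplotype_frequencies()]; `D = p_AB - p_A p_B` (A, B the effect
#' alleles), `D' = |D| / D_max`, `r2 = D^2 / (p_A q_A p_B q_B)`.
#'
#' @param panel a [genotype_panel()].
#' @param variant_a,variant_b variant ids, both polymorphic.
#' @return list of class `ld_stats`: `D`, `Dprime`, `r2`,
#'   `haplotype_freqs` (length 4), `n_effective`.
#' @export
ld_stats <- function(panel, variant_a, variant_b) {
  if (identical(variant_a, variant_b))
    stop_tf("LD of a variant with itself is excluded")
  j <- match(c(variant_a, variant_b), panel$variants$id)
  if (anyNA(j)) stop_tf("variant id(s) absent from panel")
  for (jj in j) {
    g <- panel$dosages[, jj]
    if (var(g, na.rm = TRUE) == 0)
      stop_tf("LD undefined: variant ", panel$variants$id[jj],
              " is monomorphic in this panel")
  }
  hs <- em_haplotype_frequencies(panel, c(variant_a, variant_b))
  # frequencies of the four two-locus haplotypes in effect-allele coding
  f4 <- numeric(4)  # order: 00, 10, 01, 11 (a-site bit first)
  idx <- hs$alleles[, 1L] + 2L * hs$alleles[, 2L] + 1L
  f4[idx] <- hs$frequencies
  pA <- f4[2L] + f4[4L]
  pB <- f4[3L] + f4[4L]
  D <- f4[4L] - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dprime <- if (Dmax > 0) abs(D) / Dmax else 0
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(variant_pair = c(variant_a, variant_b), D = D,
                 Dprime = min(Dprime, 1), r2 = min(r2, 1),
                 haplotype_freqs = setNames(f4, c("00", "10", "01", "11")),
                 n_effective = hs$n),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("<ld_stats> %s x %s: r2=%.3f D'=%.3f (D=%.4f, n=%d)\n",
              x$variant_pair[1L], x$variant_pair[2L], x$r2, x$Dprime, x$D,
              x$n_effective))
  invisible(x)
}

#' Haplotype regression with a reference haplotype
#'
#' Regresses the trait on posterior expected copy counts of each non-reference
#' haplotype (haplotypes below `freq_floor` pooled into a single `rare`
#' column) plus covariates. Each coefficient is the expected trait change per
#' additional copy of that haplotype relative to the reference. This is a
#' single-step expectation substitution, not an iterated EM-GLM; at common
#' haplotype frequencies the two agree closely.
#'
#' @param panel a [genotype_panel()].
#' @param variant_ids 2-8 variant ids defining the haplotypes.
#' @param pheno a [phenotype_table()].
#' @param trait trait column.
#' @param covariates covariate columns.
#' @param reference reference haplotype label (e.g. `"A-G"`); default the
#'   most frequent haplotype. Must have frequency >= `freq_floor`.
#' @param freq_floor haplotypes below this frequency are pooled.
#' @param ... passed to [em_haplotype_frequencies()].
#' @return data.frame of class `haplotype_assoc` (one row per non-reference
#'   haplotype incl. pooled rare): haplotype, frequency, beta, se, p; the
#'   reference and the haplotype set ride along as attributes.
#' @export
haplotype_regression <- function(panel, variant_ids, pheno, trait,
                                 covariates = character(0), reference = NULL,
                                 freq_floor = 0.01, ...) {
  hs <- em_haplotype_frequencies(panel, variant_ids, ...)
  if (is.null(reference)) reference <- names(which.max(hs$frequencies))
  if (!reference %in% hs$labels)
    stop_tf("reference haplotype not present: ", reference)
  if (hs$frequencies[[reference]] < freq_floor)
    stop_tf("reference haplotype frequency ", hs$frequencies[[reference]],
            " is below the floor ", freq_floor)
  common_hap <- hs$labels[hs$frequencies >= freq_floor]
  rare_hap <- setdiff(hs$labels, common_hap)
  design_haps <- setdiff(common_hap, reference)
  Xh <- hs$posterior_dosages[, design_haps, drop = FALSE]
  freq_out <- hs$frequencies[design_haps]
  if (length(rare_hap)) {
    Xh <- cbind(Xh, rare = rowSums(hs$posterior_dosages[, rare_hap, drop = FALSE]))
    freq_out <- c(freq_out, rare = sum(hs$frequencies[rare_hap]))
  }

  ids <- rownames(hs$posterior_dosages)
  ph <- as.data.frame(pheno)[match(ids, pheno$sample_id), , drop = FALSE]
  keep <- !is.na(ph[[trait]])
  if (length(covariates))
    keep <- keep & complete.cases(ph[, covariates, drop = FALSE])
  y <- ph[[trait]][keep]
  X <- matrix(1, sum(keep), 1L, dimnames = list(NULL, "(Intercept)"))
  if (length(covariates))
    X <- cbind(X, as.matrix(ph[keep, covariates, drop = FALSE]))
  X <- cbind(X, Xh[keep, , drop = FALSE])
  fit <- stats::lm.fit(X, y)
  dfr <- length(y) - fit$rank
  s2 <- sum(fit$residuals^2) / dfr
  XtXinv <- chol2inv(qr.R(fit$qr))
  se_all <- sqrt(s2 * diag(XtXinv))[order(fit$qr$pivot)]
  hap_cols <- colnames(Xh)
  bi <- match(hap_cols, names(fit$coefficients))
  beta <- fit$coefficients[bi]
  se <- se_all[bi]
  p <- pmax(2 * pt(abs(beta / se), dfr, lower.tail = FALSE), P_FLOOR)
  out <- data.frame(haplotype = hap_cols, frequency = unname(freq_out),
                    beta = unname(beta), se = unname(se), p = unname(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("haplotype_assoc", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "freq_floor") <- freq_floor
  attr(out, "haplotype_set") <- hs
  out
}
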
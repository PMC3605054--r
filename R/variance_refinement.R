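# Variance-explained decomposition, signal-region construction and
# trans-ethnic narrowing, and analytic power for a quantitative trait.

r2_of_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Variance explained by the lead signal and by all signals at a locus
#'
#' Fits three nested OLS models on the complete cases shared by all of them:
#' covariates only, covariates + lead SNP, covariates + all signal SNPs.
#' `delta_lead` and `delta_all` are the R-squared increments over the
#' covariate-only model; `fold = delta_all / delta_lead`. SNPs collinear with
#' the design accumulated so far are dropped with a warning (R-squared is
#' unaffected by dropping an exactly collinear column). Estimates for SNPs
#' selected by significance in the same data carry winner's-curse inflation;
#' no correction is applied.
#'
#' @inheritParams run_association
#' @param snp_set variant ids of all signal SNPs, strongest first.
#' @param lead lead SNP id (default: first of `snp_set`).
#' @return list of class `variance_result`: r2_base, r2_lead, r2_all,
#'   delta_lead, delta_all, fold, n, n_signals.
#' @export
delta_r2 <- function(panel, pheno, trait, covariates = character(0),
                     snp_set, lead = snp_set[[1L]],
                     transform = c("identity", "log_e")) {
  if (!length(snp_set)) stop_tf("snp_set must be non-empty")
  j <- match(snp_set, panel$variants$id)
  if (anyNA(j)) stop_tf("variant id(s) absent from panel: ",
                        paste(snp_set[is.na(j)], collapse = ", "))
  common <- intersect(panel$sample_ids, pheno$sample_id)
  ph <- as.data.frame(pheno)[match(common, pheno$sample_id), , drop = FALSE]
  keep <- !is.na(ph[[trait]])
  if (length(covariates))
    keep <- keep & complete.cases(ph[, covariates, drop = FALSE])
  y <- transform_trait(ph[[trait]][keep], match.arg(transform))
  rows <- match(common[keep], panel$sample_ids)
  G <- panel$dosages[rows, j, drop = FALSE]
  G <- apply(G, 2L, impute_mean)
  mono <- apply(G, 2L, function(g) var(g) == 0)
  if (any(mono)) stop_tf("monomorphic SNP(s) in snp_set: ",
                         paste(snp_set[mono], collapse = ", "))
  X0 <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  if (length(covariates))
    X0 <- cbind(X0, as.matrix(ph[keep, covariates, drop = FALSE]))
  add_cols <- function(X, ids) {
    for (id in ids) {
      g <- G[, match(id, snp_set)]
      Xc <- cbind(X, g)
      if (qr(Xc)$rank < ncol(Xc)) {
        warning("dropping collinear SNP ", id)
        next
      }
      X <- Xc
    }
    X
  }
  r2_base <- r2_of_fit(X0, y)
  r2_lead <- r2_of_fit(add_cols(X0, lead), y)
  r2_all <- r2_of_fit(add_cols(X0, snp_set), y)
  delta_lead <- r2_lead - r2_base
  delta_all <- r2_all - r2_base
  structure(list(locus_id = panel$variants$locus_id[j[1L]],
                 r2_base = r2_base, r2_lead = r2_lead, r2_all = r2_all,
                 delta_lead = delta_lead, delta_all = delta_all,
                 fold = fold_increase(delta_lead, delta_all),
                 n = length(y), n_signals = length(snp_set)),
            class = "variance_result")
}

#' Fold increase in explained variance
#' @param delta_lead,delta_all R-squared increments of lead-only and
#'   all-signals models over the covariate-only model.
#' @export
fold_increase <- function(delta_lead, delta_all) {
  if (delta_lead <= 0) return(NA_real_)
  delta_all / delta_lead
}

#' Mean fold increase over multi-signal loci
#'
#' Loci with a single signal are excluded (their fold is 1 by construction).
#' @param variance_results list of [delta_r2()] results.
#' @return mean of `fold` over loci with >= 2 signals.
#' @export
fold_increase_summary <- function(variance_results) {
  multi <- Filter(function(v) v$n_signals >= 2L, variance_results)
  if (!length(multi)) stop_tf("no multi-signal loci")
  mean(vapply(multi, function(v) v$fold, numeric(1)))
}

#' Association signal region
#'
#' Members are either all variants with `p < threshold`
#' (`mode = "p_threshold"`) or all variants with genotype `r2 > r2_cut` to the
#' lead (`mode = "ld_with_lead"`, needs a panel). The span is the base-pair
#' distance between the outermost members.
#'
#' @param assoc an association or meta table with `variant_id`, `pos` and a p
#'   column (`p` or `p_meta`).
#' @param mode `"p_threshold"` or `"ld_with_lead"`.
#' @param threshold p-value cut for `p_threshold` mode.
#' @param r2_cut LD cut for `ld_with_lead` mode.
#' @param panel panel supplying genotypes for r2 (required in
#'   `ld_with_lead` mode).
#' @param lead lead variant id (default: smallest p).
#' @param label free-text label (ancestry or "meta").
#' @return list of class `signal_region`: members, lead, span_bp, n_snps.
#' @export
signal_region <- function(assoc, mode = c("p_threshold", "ld_with_lead"),
                          threshold = 1e-4, r2_cut = 0.8, panel = NULL,
                          lead = NULL, label = NULL) {
  mode <- match.arg(mode)
  pcol <- if ("p" %in% names(assoc)) assoc$p else assoc$p_meta
  if (is.null(pcol)) stop_tf("no p or p_meta column")
  lead <- lead %||% assoc$variant_id[which.min(pcol)]
  members <- if (mode == "p_threshold") {
    assoc$variant_id[pcol < threshold]
  } else {
    if (is.null(panel)) stop_tf("ld_with_lead mode requires a panel")
    jl <- match(lead, panel$variants$id)
    jt <- match(assoc$variant_id, panel$variants$id)
    r <- suppressWarnings(as.numeric(
      cor(panel$dosages[, jt, drop = FALSE], panel$dosages[, jl],
          use = "pairwise.complete.obs")))
    assoc$variant_id[!is.na(r) & r^2 > r2_cut]
  }
  if (!length(members)) stop_tf("no variant passes the ", mode, " criterion")
  pos <- assoc$pos[match(members, assoc$variant_id)]
  structure(list(members = members, member_pos = pos, lead = lead,
                 span_bp = max(pos) - min(pos), n_snps = length(members),
                 start = min(pos), end = max(pos), mode = mode,
                 label = label),
            class = "signal_region")
}

#' @export
print.signal_region <- function(x, ...) {
  cat(sprintf("<signal_region>%s %d SNPs spanning %d bp (lead %s, %s)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$n_snps, x$span_bp, x$lead, x$mode))
  invisible(x)
}

#' Trans-ethnic refinement report
#'
#' Intersects the per-ancestry signal regions and restricts the combined
#' (meta-analysis) region's members to that intersection. Disjoint ancestry
#' regions — distinct signals, not a shared one — are flagged rather than
#' intersected.
#'
#' @param regions named list of per-ancestry [signal_region()]s (>= 2).
#' @param meta_region the [signal_region()] of the trans-ethnic meta-analysis.
#' @return list of class `refinement_report`: per-ancestry spans, meta span,
#'   intersection start/end/span, `overlap` flag, `narrowed` member ids and
#'   their span.
#' @export
transethnic_refinement <- function(regions, meta_region) {
  if (length(regions) < 2L) stop_tf("need at least 2 ancestry regions")
  starts <- vapply(regions, function(r) r$start, numeric(1))
  ends <- vapply(regions, function(r) r$end, numeric(1))
  lo <- max(starts); hi <- min(ends)
  overlap <- lo <= hi
  narrowed <- character(0); nspan <- NA_real_
  if (overlap) {
    inside <- meta_region$member_pos >= lo & meta_region$member_pos <= hi
    narrowed <- meta_region$members[inside]
    if (length(narrowed))
      nspan <- diff(range(meta_region$member_pos[inside]))
  }
  structure(list(ancestry_spans = setNames(ends - starts, names(regions)),
                 meta_span = meta_region$span_bp,
                 intersection = c(start = lo, end = hi),
                 intersection_span = if (overlap) hi - lo else NA_real_,
                 overlap = overlap, narrowed = narrowed,
                 narrowed_span = nspan),
            class = "refinement_report")
}

#' Analytic power for a single-variant additive association test
#'
#' Noncentrality `ncp = n * 2 p (1-p) * beta^2 / sigma^2`; power is the upper
#' tail of the noncentral chi-square(1, ncp) beyond the central chi-square
#' critical value at level `alpha` (two-sided test).
#'
#' @param maf allele frequency `p` in (0, 1).
#' @param n sample size (>= 2).
#' @param beta effect size, trait units per allele.
#' @param sigma residual standard deviation (> 0), same units.
#' @param alpha significance level in (0, 1).
#' @return power in `[0, 1]`; exactly `alpha` when `beta = 0`.
#' @export
power_quantitative <- function(maf, n, beta, sigma, alpha = 0.05) {
  assert_scalar_number(maf, "maf", 0, 1, TRUE, TRUE)
  assert_scalar_number(n, "n", 2)
  assert_scalar_number(sigma, "sigma", 0, strict_lower = TRUE)
  assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  ncp <- n * 2 * maf * (1 - maf) * beta^2 / sigma^2
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
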
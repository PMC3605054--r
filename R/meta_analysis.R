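# Inverse-variance fixed-effect meta-analysis with heterogeneity statistics.
#
# Weights are w_i = 1/se_i^2; the combined estimate is
# beta_meta = sum(w b)/sum(w) with se_meta = 1/sqrt(sum(w)), and p_meta is the
# two-sided normal tail of beta_meta/se_meta (normal, not t, matching the
# standard fixed-effect convention). Heterogeneity uses Cochran's
# Q = sum w (b - beta_meta)^2 with df = k-1, p_het from the chi-square tail
# and I2 = max(0, (Q - df)/Q) * 100 in percent.

#' Inverse-variance fixed-effect meta-analysis of one variant
#'
#' @param inputs either an association table (rows = studies, one variant,
#'   consistent trait and effect-allele orientation) or a list/data.frame
#'   with `beta` and `se` columns.
#' @param p_floor smallest reported p value.
#' @return list of class `meta_result` with fields `variant_id`, `k`,
#'   `beta_meta`, `se_meta`, `z`, `p_meta`, `neglog10_p`, `Q`, `df`, `p_het`,
#'   `I2`.
#' @export
ivw_meta <- function(inputs, p_floor = P_FLOOR) {
  if (is.data.frame(inputs)) {
    if (all(c("variant_id", "effect_allele") %in% names(inputs))) {
      if (length(unique(inputs$variant_id)) != 1L)
        stop_tf("ivw_meta expects a single variant")
      if (length(unique(paste(inputs$effect_allele, inputs$other_allele))) != 1L)
        stop_tf("mismatched alleles across studies for ",
                inputs$variant_id[1L])
      if ("trait" %in% names(inputs) && length(unique(inputs$trait)) != 1L)
        stop_tf("mismatched traits across studies")
    }
    beta <- inputs$beta; se <- inputs$se
    vid <- if ("variant_id" %in% names(inputs)) inputs$variant_id[1L] else NA_character_
  } else {
    beta <- inputs$beta; se <- inputs$se
    vid <- inputs$variant_id %||% NA_character_
  }
  k <- length(beta)
  if (k == 0L) stop_tf("no studies to combine")
  if (length(se) != k || any(!is.finite(se) | se <= 0))
    stop_tf("all standard errors must be finite and > 0")
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  tail <- normal_p2(z)
  het <- if (k >= 2L) heterogeneity(beta, se, beta_meta)
         else list(Q = 0, df = 0L, p_het = 1, I2 = 0)
  structure(list(variant_id = vid, k = k, beta_meta = beta_meta,
                 se_meta = se_meta, z = z,
                 p_meta = max(tail$p, p_floor), neglog10_p = tail$neglog10,
                 Q = het$Q, df = het$df, p_het = het$p_het, I2 = het$I2),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s: k=%d beta=%.4g se=%.4g p=%.3g (I2=%.1f%%, p_het=%.3g)\n",
              x$variant_id, x$k, x$beta_meta, x$se_meta, x$p_meta, x$I2, x$p_het))
  invisible(x)
}

#' Cochran's Q, heterogeneity p value and I-squared
#'
#' @param beta,se per-study effect estimates and standard errors (k >= 2).
#' @param beta_meta optional fixed-effect combined estimate (computed if
#'   missing).
#' @return list(Q, df, p_het, I2); `I2` in percent, floored at 0; `p_het = 1`
#'   when Q = 0.
#' @export
heterogeneity <- function(beta, se, beta_meta = NULL) {
  k <- length(beta)
  if (k < 2L) stop_tf("heterogeneity needs at least 2 studies")
  if (any(!is.finite(se) | se <= 0)) stop_tf("all standard errors must be > 0")
  w <- 1 / se^2
  if (is.null(beta_meta)) beta_meta <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - beta_meta)^2)
  df <- k - 1L
  p_het <- pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df, p_het = p_het, I2 = I2)
}

#' Recover a standard error from a printed effect size and p value
#'
#' Inverts the two-sided normal test: `se = |beta| / z` with
#' `z = Phi^{-1}(1 - p/2)`. This is how full inverse-variance weights are
#' reconstructed from published (beta, P) pairs.
#'
#' @param beta effect estimate (nonzero).
#' @param p two-sided p value strictly inside (0, 1).
#' @return standard error.
#' @export
se_from_beta_p <- function(beta, p) {
  if (any(beta == 0)) stop_tf("se is unidentifiable when beta = 0")
  if (any(p <= 0 | p >= 1)) stop_tf("p must lie strictly in (0, 1)")
  z <- qnorm(p / 2, lower.tail = FALSE)
  abs(beta) / z
}

#' Per-study effect direction string
#'
#' One character per study in `study_order`: `+` for a positive effect, `-`
#' for negative, `?` when the study has no estimate (absent or monomorphic).
#'
#' @param betas named numeric vector of per-study effect estimates.
#' @param study_order character vector fixing the output order.
#' @export
direction_string <- function(betas, study_order) {
  if (!length(study_order)) stop_tf("study_order must be non-empty")
  chars <- vapply(study_order, function(s) {
    if (is.null(names(betas)) || !s %in% names(betas)) return("?")
    b <- betas[[s]]
    if (is.na(b)) "?" else if (b > 0) "+" else if (b < 0) "-" else "?"
  }, character(1))
  paste(chars, collapse = "")
}

#' Meta-analyse an association table across studies, per variant
#'
#' Combines all rows sharing a (variant_id, trait) pair by [ivw_meta()] and
#' appends the per-study direction string.
#'
#' @param assoc an association table with rows from several studies.
#' @param study_order studies defining the direction-string order (default:
#'   order of appearance).
#' @return data.frame of class `meta_table`: one row per variant/trait with
#'   beta_meta, se_meta, p_meta, neglog10_p, k, Q, p_het, I2, direction.
#' @export
meta_table <- function(assoc, study_order = unique(assoc$study_id)) {
  validate_assoc(assoc)
  key <- paste(assoc$variant_id, assoc$trait, sep = "\r")
  rows <- split(seq_len(nrow(assoc)), key)
  out <- lapply(rows, function(i) {
    a <- assoc[i, , drop = FALSE]
    m <- ivw_meta(a)
    data.frame(variant_id = a$variant_id[1L], chrom = a$chrom[1L],
               pos = a$pos[1L], effect_allele = a$effect_allele[1L],
               other_allele = a$other_allele[1L], trait = a$trait[1L],
               k = m$k, n = sum(a$n), beta_meta = m$beta_meta,
               se_meta = m$se_meta, p_meta = m$p_meta,
               neglog10_p = m$neglog10_p, Q = m$Q, p_het = m$p_het, I2 = m$I2,
               direction = direction_string(setNames(a$beta, a$study_id),
                                            study_order),
               locus_id = if ("locus_id" %in% names(a)) a$locus_id[1L] else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$trait, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("meta_table", "data.frame")
  out
}
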
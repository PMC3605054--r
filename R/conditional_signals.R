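# Sequential conditional association analysis with an annotation-aware
# stopping rule, population-specificity classification, and the
# masked/shared/independent dependence report for signal pairs.

#' Conditional association scan
#'
#' Runs [run_association()] with the dosages of `conditioned_set` entered as
#' covariates. Conditioned variants themselves are excluded from testing;
#' tested variants in strong LD (genotype r2 > `flag_r2`) with any conditioned
#' variant are flagged in the `ld_flagged` column but retained. Variants that
#' are exactly collinear with the conditioned set are skipped with a reason
#' rather than raising an error.
#'
#' @inheritParams run_association
#' @param conditioned_set variant ids to condition on (may be empty, in which
#'   case the scan equals a plain association scan).
#' @param flag_r2 LD threshold for flagging.
#' @return an `assoc_table` with an extra logical column `ld_flagged`.
#' @export
conditional_scan <- function(panel, pheno, trait, covariates = character(0),
                             conditioned_set = character(0),
                             transform = c("identity", "log_e"),
                             flag_r2 = 0.95) {
  res <- run_association(panel, pheno, trait, covariates,
                         conditioned_on = conditioned_set,
                         transform = transform, collinear = "skip")
  flagged <- rep(FALSE, nrow(res))
  if (length(conditioned_set)) {
    jc <- match(conditioned_set, panel$variants$id)
    jt <- match(res$variant_id, panel$variants$id)
    r <- suppressWarnings(cor(panel$dosages[, jt, drop = FALSE],
                              panel$dosages[, jc, drop = FALSE],
                              use = "pairwise.complete.obs"))
    flagged <- apply(r^2, 1L, function(x) any(x > flag_r2, na.rm = TRUE))
  }
  res$ld_flagged <- flagged
  res
}

#' Sequential conditional signal discovery
#'
#' Iteratively: scan all regional variants conditioning on the leads admitted
#' so far, take the variant with the smallest conditional p (ties broken by
#' smaller se, then lower position), and admit it as the next signal if
#' `p < threshold`, or — the annotation override — if `p < functional_floor`
#' and the variant is annotated as a nonsense or nonsynonymous substitution.
#' Otherwise the procedure stops. The override is what lets a protein-altering
#' variant that narrowly misses the threshold still count as a signal, while
#' the `functional_floor` bound guarantees termination.
#'
#' @inheritParams run_association
#' @param annotation optional named character vector (variant id ->
#'   annotation class), e.g. from [read_annotations()]; defaults to the
#'   panel's own annotation column.
#' @param threshold conditional significance threshold (default 1e-4).
#' @param functional_floor upper bound on conditional p for
#'   annotation-admitted signals (default 1e-2).
#' @param max_signals hard cap; reaching it returns the table with a warning.
#' @param locus_id,ancestry labels stored on the result.
#' @return data.frame of class `signal_table`: one row per admitted signal
#'   with order, variant_id, annotation, EAF, beta_initial, p_initial,
#'   beta_conditional, p_conditional, admitted_by, conditioned_on. The first
#'   signal's conditional statistics equal its initial ones.
#' @export
sequential_conditional <- function(panel, pheno, trait,
                                   covariates = character(0),
                                   annotation = NULL, threshold = 1e-4,
                                   functional_floor = 1e-2, max_signals = 10L,
                                   transform = c("identity", "log_e"),
                                   locus_id = NULL, ancestry = panel$ancestry) {
  assert_scalar_number(threshold, "threshold", 0, 1, TRUE, TRUE)
  assert_scalar_number(functional_floor, "functional_floor", 0, 1, TRUE, TRUE)
  ann <- annotation %||% setNames(panel$variants$annotation, panel$variants$id)
  poly <- apply(panel$dosages, 2L, function(g) var(g, na.rm = TRUE) > 0)
  if (sum(poly, na.rm = TRUE) < 2L)
    stop_tf("sequential conditional analysis needs at least 2 polymorphic variants")

  leads <- character(0)
  rows <- list()
  initial <- NULL
  truncated <- FALSE
  repeat {
    scan <- conditional_scan(panel, pheno, trait, covariates,
                             conditioned_set = leads, transform = transform)
    if (is.null(initial)) initial <- scan
    if (!nrow(scan)) break
    ord <- order(scan$p, scan$se, scan$pos)
    top <- scan[ord[1L], , drop = FALSE]
    a <- ann[[top$variant_id]] %||% "unknown"
    admitted_by <- if (top$p < threshold) "threshold"
      else if (top$p < functional_floor && a %in% c("nonsense", "nonsynonymous"))
        "functional_annotation"
      else NA_character_
    if (is.na(admitted_by)) break
    ini <- initial[match(top$variant_id, initial$variant_id), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      order = length(leads) + 1L, variant_id = top$variant_id,
      annotation = a, EAF = top$EAF,
      beta_initial = if (nrow(ini)) ini$beta else NA_real_,
      p_initial = if (nrow(ini)) ini$p else NA_real_,
      beta_conditional = top$beta, p_conditional = top$p,
      admitted_by = admitted_by,
      conditioned_on = paste(leads, collapse = ";"),
      stringsAsFactors = FALSE)
    leads <- c(leads, top$variant_id)
    if (length(leads) >= max_signals) {
      truncated <- TRUE
      warning("max_signals (", max_signals, ") reached; signal table truncated")
      break
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(order = integer(0), variant_id = character(0),
               annotation = character(0), EAF = numeric(0),
               beta_initial = numeric(0), p_initial = numeric(0),
               beta_conditional = numeric(0), p_conditional = numeric(0),
               admitted_by = character(0), conditioned_on = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("signal_table", "data.frame")
  attr(out, "locus_id") <- locus_id %||% panel$variants$locus_id[1L]
  attr(out, "trait") <- trait
  attr(out, "ancestry") <- ancestry
  attr(out, "threshold") <- threshold
  attr(out, "functional_floor") <- functional_floor
  attr(out, "truncated") <- truncated
  attr(out, "initial_scan") <- initial
  out
}

#' Is a signal variant population-specific?
#'
#' TRUE iff the variant is monomorphic (EAF exactly 0 or 1) in the study
#' panels of both other ancestry groups and, when reference pools are
#' supplied, in the corresponding reference pools as well. When no reference
#' pools are given the study panels alone decide (a message notes this).
#'
#' @param variant_id variant to classify.
#' @param panels_by_ancestry named list of [genotype_panel()]s, one per
#'   ancestry group.
#' @param focal_ancestry the ancestry in which the signal was found.
#' @param reference_pools optional named list (per ancestry) of
#'   [build_haplotype_pool()] pools or panels standing in for external
#'   reference panels.
#' @return logical.
#' @export
classify_population_specific <- function(variant_id, panels_by_ancestry,
                                         focal_ancestry,
                                         reference_pools = NULL) {
  freq_of <- function(obj) {
    if (inherits(obj, "genotype_panel")) {
      j <- match(variant_id, obj$variants$id)
      if (is.na(j)) return(NA_real_)
      unname(eaf(obj)[j])
    } else if (inherits(obj, "haplotype_pool")) {
      unname(obj$eaf[variant_id])
    } else stop_tf("unsupported reference object")
  }
  fr <- vapply(panels_by_ancestry, freq_of, numeric(1))
  if (all(is.na(fr) | fr %in% c(0, 1)))
    stop_tf("variant ", variant_id,
            " is monomorphic in every panel; population specificity is untestable")
  if (!focal_ancestry %in% names(panels_by_ancestry))
    stop_tf("focal ancestry not among panels: ", focal_ancestry)
  others <- setdiff(names(panels_by_ancestry), focal_ancestry)
  study_mono <- all(is.na(fr[others]) | fr[others] %in% c(0, 1))
  if (is.null(reference_pools)) {
    message("no reference pools supplied; study panels alone decide")
    return(study_mono)
  }
  rf <- vapply(reference_pools[intersect(others, names(reference_pools))],
               freq_of, numeric(1))
  study_mono && all(is.na(rf) | rf %in% c(0, 1))
}

#' Dependence report for a pair of signals
#'
#' Reports pairwise LD between a lead and a partner variant together with how
#' the partner's p value moves under conditioning on the lead:
#' `p_shift = p_conditional / p_initial`. Pairs are classified as
#' `"independent"` (shift within one order of magnitude), `"masked"`
#' (conditional p more than an order of magnitude smaller — the pattern of a
#' trait-decreasing allele carried on haplotypes bearing the other signal's
#' trait-increasing allele), or `"shared"` (conditional p more than an order
#' of magnitude larger, i.e. the two tag the same signal).
#'
#' @param lead_id,partner_id variant ids (must differ, both polymorphic).
#' @inheritParams run_association
#' @return list of class `dependence_report`: `r2`, `Dprime`, `p_initial`,
#'   `p_conditional`, `p_shift`, `classification`.
#' @export
dependence_report <- function(lead_id, partner_id, panel, pheno, trait,
                              covariates = character(0),
                              transform = c("identity", "log_e")) {
  if (identical(lead_id, partner_id))
    stop_tf("a variant cannot be paired with itself")
  ld <- ld_stats(panel, lead_id, partner_id)
  ini <- run_association(panel, pheno, trait, covariates, transform = transform)
  con <- conditional_scan(panel, pheno, trait, covariates,
                          conditioned_set = lead_id, transform = transform)
  p0 <- ini$p[match(partner_id, ini$variant_id)]
  p1 <- con$p[match(partner_id, con$variant_id)]
  if (is.na(p0) || is.na(p1))
    stop_tf("partner variant not testable in this panel")
  shift <- p1 / p0
  classification <- if (abs(log10(shift)) <= 1) "independent"
                    else if (shift < 1) "masked" else "shared"
  structure(list(lead = lead_id, partner = partner_id, r2 = ld$r2,
                 Dprime = ld$Dprime, p_initial = p0, p_conditional = p1,
                 p_shift = shift, classification = classification),
            class = "dependence_report")
}

#' @export
print.dependence_report <- function(x, ...) {
  cat(sprintf("<dependence_report> %s | %s: r2=%.3f D'=%.3f p %.3g -> %.3g (%s)\n",
              x$partner, x$lead, x$r2, x$Dprime, x$p_initial, x$p_conditional,
              x$classification))
  invisible(x)
}
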
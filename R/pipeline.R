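# End-to-end orchestration: simulate -> per-study association -> ancestry
# meta -> trans-ethnic meta -> sequential conditional per ancestry ->
# variance decomposition -> signal regions and trans-ethnic refinement.
# Every stage is a pure function of the config and its seed; the summary and
# all stage TSVs are reproducible byte-identically under a fixed seed.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param spec a [causal_spec()] for the trait generative model.
#' @param trait trait name (taken from `spec` by default).
#' @param covariates covariate columns used in every regression.
#' @param transform trait transform for association (`"log_e"` for TG-style
#'   log-normal traits).
#' @param threshold association/conditional significance threshold.
#' @param functional_floor annotation-override bound, see
#'   [sequential_conditional()].
#' @param r2_cut LD cut for LD-defined regions.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, spec, trait = spec$trait,
                            covariates = c("age", "sex"),
                            transform = c("identity", "log_e"),
                            threshold = 1e-4, functional_floor = 1e-2,
                            r2_cut = 0.8) {
  stopifnot(inherits(sim, "sim_config"), inherits(spec, "causal_spec"))
  assert_scalar_number(threshold, "threshold", 0, 1, TRUE, TRUE)
  assert_scalar_number(functional_floor, "functional_floor", 0, 1, TRUE, TRUE)
  assert_scalar_number(r2_cut, "r2_cut", 0, 1)
  structure(list(sim = sim, spec = spec, trait = trait,
                 covariates = covariates, transform = match.arg(transform),
                 threshold = threshold, functional_floor = functional_floor,
                 r2_cut = r2_cut),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_tf("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full fine-mapping pipeline on a synthetic study
#'
#' Stages, in order: data generation; per-study association scans; ancestry
#' level inverse-variance meta-analysis; combined trans-ethnic meta-analysis
#' (with the 11-group direction string); sequential conditional analysis on
#' the pooled samples of each ancestry; population-specificity classification
#' of every signal; variance-explained decomposition per multi-signal locus;
#' per-ancestry and meta signal regions plus the trans-ethnic refinement
#' report. Stage outputs are written as TSVs under `out_dir` together with a
#' machine-readable `summary.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); NULL to skip writing.
#' @return (invisibly) list with `assoc`, `meta_ancestry`, `meta_trans`,
#'   `signals`, `population_specific`, `variance`, `fold_summary`, `regions`,
#'   `refinement`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  trait <- config$trait

  bundle <- run_stage("simulate", make_multi_ancestry_study(config$sim, config$spec))
  ancestries <- unique(config$sim$study_split$ancestry)

  assoc <- run_stage("association", {
    res <- lapply(bundle$studies, function(s) {
      covs <- intersect(config$covariates,
                        attr(s$phenotypes, "covariates"))
      run_association(s$panel, s$phenotypes, trait, covs,
                      transform = config$transform)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    class(out) <- c("assoc_table", "data.frame")
    out
  })

  meta_ancestry <- run_stage("ancestry_meta", {
    lapply(setNames(ancestries, ancestries), function(a) {
      sids <- config$sim$study_split$study_id[config$sim$study_split$ancestry == a]
      meta_table(assoc[assoc$study_id %in% sids, , drop = FALSE],
                 study_order = sids)
    })
  })

  meta_trans <- run_stage("transethnic_meta",
                          meta_table(assoc, study_order = bundle$study_order))

  pooled <- run_stage("pool_ancestries",
                      lapply(setNames(ancestries, ancestries),
                             function(a) pool_ancestry(bundle, a)))

  signals <- run_stage("conditional", {
    out <- list()
    for (a in ancestries) {
      pl <- pooled[[a]]
      covs <- intersect(c(config$covariates,
                          grep("^study_", attr(pl$phenotypes, "covariates"),
                               value = TRUE)),
                        attr(pl$phenotypes, "covariates"))
      for (loc in unique(pl$panel$variants$locus_id)) {
        sub <- subset_panel(pl$panel, pl$panel$variants$locus_id == loc)
        st <- sequential_conditional(sub, pl$phenotypes, trait, covs,
                                     threshold = config$threshold,
                                     functional_floor = config$functional_floor,
                                     transform = config$transform,
                                     locus_id = loc, ancestry = a)
        out[[paste(a, loc, sep = ".")]] <- st
      }
    }
    out
  })

  population_specific <- run_stage("population_specific", {
    panels_by_anc <- lapply(pooled, function(pl) pl$panel)
    res <- list()
    for (nm in names(signals)) {
      st <- signals[[nm]]
      if (!nrow(st)) next
      a <- attr(st, "ancestry")
      res[[nm]] <- vapply(st$variant_id, function(v)
        suppressMessages(classify_population_specific(v, panels_by_anc, a)),
        logical(1))
    }
    res
  })

  variance <- run_stage("variance", {
    res <- list()
    for (nm in names(signals)) {
      st <- signals[[nm]]
      if (!nrow(st)) next
      a <- attr(st, "ancestry"); loc <- attr(st, "locus_id")
      pl <- pooled[[a]]
      covs <- intersect(c(config$covariates,
                          grep("^study_", attr(pl$phenotypes, "covariates"),
                               value = TRUE)),
                        attr(pl$phenotypes, "covariates"))
      res[[nm]] <- delta_r2(pl$panel, pl$phenotypes, trait, covs,
                            snp_set = st$variant_id,
                            transform = config$transform)
    }
    res
  })

  fold_summary <- if (any(vapply(variance, function(v) v$n_signals >= 2L,
                                 logical(1))))
    fold_increase_summary(variance) else NA_real_

  regions <- run_stage("regions", {
    out <- list()
    for (loc in unique(assoc$locus_id)) {
      anc_regions <- list()
      for (a in ancestries) {
        ma <- meta_ancestry[[a]]
        ma <- ma[ma$locus_id == loc, , drop = FALSE]
        reg <- tryCatch(signal_region(ma, "p_threshold", config$threshold,
                                      label = a),
                        error = function(e) NULL)
        if (!is.null(reg)) anc_regions[[a]] <- reg
      }
      mt <- meta_trans[meta_trans$locus_id == loc, , drop = FALSE]
      meta_reg <- tryCatch(signal_region(mt, "p_threshold", config$threshold,
                                         label = "meta"),
                           error = function(e) NULL)
      out[[loc]] <- list(ancestry = anc_regions, meta = meta_reg)
    }
    out
  })

  refinement <- run_stage("refinement", {
    lapply(regions, function(rg) {
      if (length(rg$ancestry) >= 2L && !is.null(rg$meta))
        transethnic_refinement(rg$ancestry, rg$meta)
      else NULL
    })
  })

  summary <- list(
    trait = trait,
    n_studies = length(bundle$studies),
    signal_counts = lapply(signals, nrow),
    multi_signal_loci = names(Filter(function(s) nrow(s) >= 2L, signals)),
    population_specific = lapply(population_specific, function(x)
      names(x)[x]),
    fold_increase_mean = fold_summary,
    refinement = lapply(refinement, function(r) if (is.null(r)) NULL else
      list(overlap = r$overlap, narrowed = r$narrowed,
           intersection_span = r$intersection_span))
  )

  result <- list(assoc = assoc, meta_ancestry = meta_ancestry,
                 meta_trans = meta_trans, signals = signals,
                 population_specific = population_specific,
                 variance = variance, fold_summary = fold_summary,
                 regions = regions, refinement = refinement,
                 summary = summary, bundle = bundle, pooled = pooled)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_assoc_table(assoc, file.path(out_dir, "assoc.tsv"))
    data.table::fwrite(meta_trans, file.path(out_dir, "meta_trans.tsv"),
                       sep = "\t", quote = FALSE)
    for (a in names(meta_ancestry))
      data.table::fwrite(meta_ancestry[[a]],
                         file.path(out_dir, paste0("meta_", a, ".tsv")),
                         sep = "\t", quote = FALSE)
    sig_df <- do.call(rbind, lapply(names(signals), function(nm) {
      st <- signals[[nm]]
      if (!nrow(st)) return(NULL)
      cbind(ancestry = attr(st, "ancestry"), locus_id = attr(st, "locus_id"),
            as.data.frame(st),
            population_specific = unname(population_specific[[nm]]))
    }))
    if (!is.null(sig_df))
      data.table::fwrite(sig_df, file.path(out_dir, "signals.tsv"),
                         sep = "\t", quote = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(result)
}

#' Restrict a panel to a subset of variants
#' @param panel a [genotype_panel()].
#' @param which logical or integer index over variants.
#' @export
subset_panel <- function(panel, which) {
  vt <- panel$variants[which, , drop = FALSE]
  class(vt) <- c("variant_table", "data.frame")
  genotype_panel(panel$dosages[, which, drop = FALSE], vt, panel$sample_ids,
                 panel$study_id, panel$ancestry, max_missing = 1)
}
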
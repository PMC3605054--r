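#' @importFrom stats complete.cases cor pchisq pnorm pt qchisq qnorm rbinom
#'   rnorm runif setNames var
#' @importFrom utils head
NULL

# ---- shared data model -------------------------------------------------------

#' Functional annotation classes recognized by the stopping rule
#' @export
ANNOTATION_LEVELS <- c("nonsense", "nonsynonymous", "splice", "UTR", "intron",
                       "upstream", "downstream", "intergenic", "unknown")

#' Ancestry groups of the study design
#' @export
ANCESTRY_LEVELS <- c("AFR_AM", "EAS", "EUR", "other")

#' Construct a variant metadata table
#'
#' One row per variant with identifier, 1-based position, allele orientation
#' and functional annotation. The `effect_allele` is the allele counted by
#' dosages and the allele to which regression coefficients refer.
#'
#' @param id character vector of unique variant identifiers.
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions.
#' @param effect_allele,other_allele allele codes; must differ per variant.
#' @param annotation functional class, one of [ANNOTATION_LEVELS].
#' @param locus_id locus membership label.
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(id, chrom, pos, effect_allele, other_allele,
                          annotation = "unknown", locus_id = "locus1") {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   pos = as.integer(pos),
                   effect_allele = as.character(effect_allele),
                   other_allele = as.character(other_allele),
                   annotation = rep_len(as.character(annotation), length(id)),
                   locus_id = rep_len(as.character(locus_id), length(id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop_tf("duplicate variant id(s): ",
            paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(df$pos < 1L)) stop_tf("positions must be >= 1")
  if (any(df$effect_allele == df$other_allele))
    stop_tf("effect and other allele must differ")
  bad <- !df$annotation %in% ANNOTATION_LEVELS
  if (any(bad))
    stop_tf("unknown annotation class: ",
            paste(unique(df$annotation[bad]), collapse = ", "))
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Construct a genotype panel
#'
#' Container for one study group: an effect-allele dosage matrix
#' (samples x variants, values 0/1/2 or NA) plus variant metadata.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants a [variant_table()] matching the columns.
#' @param sample_ids sample identifiers; defaults to the matrix rownames.
#' @param study_id study label.
#' @param ancestry one of [ANCESTRY_LEVELS].
#' @param max_missing maximum tolerated per-variant missingness fraction.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = rownames(dosages),
                           study_id = "study1", ancestry = "other",
                           max_missing = 1) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (length(sample_ids) != nrow(dosages))
    stop_tf("sample_ids length does not match dosage rows")
  if (anyDuplicated(sample_ids)) stop_tf("sample_ids must be unique")
  if (!inherits(variants, "variant_table"))
    variants <- do.call(variant_table, as.list(variants))
  if (nrow(variants) != ncol(dosages))
    stop_tf("variant table rows do not match dosage columns")
  ancestry <- match.arg(ancestry, ANCESTRY_LEVELS)
  ok <- is.na(dosages) | (dosages %in% c(0, 1, 2))
  if (!all(ok)) stop_tf("dosages must be 0, 1, 2 or NA")
  miss <- colMeans(is.na(dosages))
  if (any(miss > max_missing))
    stop_tf("per-variant missingness exceeds cap ", max_missing, " at: ",
            paste(head(variants$id[miss > max_missing], 5L), collapse = ", "))
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(study_id = study_id, ancestry = ancestry,
                 sample_ids = as.character(sample_ids),
                 variants = variants, dosages = dosages),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> study '%s' (%s): %d samples x %d variants\n",
              x$study_id, x$ancestry, length(x$sample_ids), nrow(x$variants)))
  invisible(x)
}

#' Effect-allele frequency of each variant in a panel
#'
#' Computed as mean dosage over non-missing samples divided by 2.
#' @param panel a [genotype_panel()].
#' @return named numeric vector.
#' @export
eaf <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  colMeans(panel$dosages, na.rm = TRUE) / 2
}

#' Flip the effect/other allele orientation of selected variants
#'
#' Dosages become `2 - dosage` and the allele columns are swapped, so EAF maps
#' to `1 - EAF` and downstream regression coefficients change sign.
#' @param panel a [genotype_panel()].
#' @param ids variant ids to flip (default: all).
#' @export
flip_alleles <- function(panel, ids = panel$variants$id) {
  stopifnot(inherits(panel, "genotype_panel"))
  j <- match(ids, panel$variants$id)
  if (anyNA(j)) stop_tf("unknown variant id(s) in flip_alleles")
  panel$dosages[, j] <- 2 - panel$dosages[, j]
  ea <- panel$variants$effect_allele[j]
  panel$variants$effect_allele[j] <- panel$variants$other_allele[j]
  panel$variants$other_allele[j] <- ea
  panel
}

# ---- genotype readers --------------------------------------------------------

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF parsing (GT field only) is delegated to `VariantAnnotation::readVcf`;
#' diploid genotype calls are converted to counts of the effect allele, which
#' is the ALT allele by default. Multi-allelic records are rejected unless
#' `multiallelic = "split"`, in which case one biallelic record per ALT allele
#' is emitted (ids suffixed `_alt<k>`). Missing calls (`./.`) become missing
#' dosages.
#'
#' The dosage TSV dialect is tab-separated with header
#' `sample_id<TAB>var1<TAB>var2...` and cells in `{0,1,2,NA}`. A sidecar
#' `<path>.variants` file written by [write_dosage()] restores full variant
#' metadata; without it placeholder metadata is synthesized.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @param study_id,ancestry panel labels.
#' @param multiallelic `"error"` (default) or `"split"`.
#' @param effect `"alt"` (default) or `"minor"`: with `"minor"` variants whose
#'   ALT frequency exceeds 0.5 are flipped to minor-allele orientation.
#' @param max_missing per-variant missingness cap (default 1: no cap at read
#'   time; configure a cap to enforce genotyping QC).
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                           study_id = "study1", ancestry = "other",
                           multiallelic = c("error", "split"),
                           effect = c("alt", "minor"), max_missing = 1) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  effect <- match.arg(effect)
  if (!file.exists(path)) stop_tf("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  panel <- if (format == "vcf") {
    read_vcf_panel(path, study_id, ancestry, multiallelic, max_missing)
  } else {
    read_dosage_panel(path, study_id, ancestry, max_missing)
  }
  if (effect == "minor") {
    flip <- eaf(panel) > 0.5
    if (any(flip)) panel <- flip_alleles(panel, panel$variants$id[flip])
  }
  panel
}

read_vcf_panel <- function(path, study_id, ancestry, multiallelic, max_missing) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop_tf("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  if (anyDuplicated(ids))
    stop_tf("duplicate variant id(s) in VCF: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  if (any(n_alt > 1L) && multiallelic == "error")
    stop_tf("multi-allelic record(s) rejected (set multiallelic = 'split'): ",
            paste(head(ids[n_alt > 1L], 5L), collapse = ", "))

  count_allele <- function(gt_row, k) {
    # dosage of ALT allele k from unphased or phased diploid GT strings
    miss <- gt_row %in% c("./.", ".|.", ".")
    toks <- strsplit(gt_row, "[/|]")
    d <- vapply(toks, function(tk) sum(tk == as.character(k)), numeric(1))
    bad <- !miss & (lengths(toks) != 2L |
                      vapply(toks, function(tk) anyNA(suppressWarnings(as.integer(tk))),
                             logical(1)))
    if (any(bad))
      stop_tf("malformed GT at variant row(s): ",
              paste(head(which(bad), 3L), collapse = ", "))
    d[miss] <- NA_real_
    d
  }

  out_dos <- list(); out_id <- out_chrom <- out_pos <- out_ea <- out_oa <- character(0)
  for (i in seq_along(ids)) {
    alts <- as.character(alt_list[[i]])
    for (k in seq_along(alts)) {
      out_dos[[length(out_dos) + 1L]] <- count_allele(gt[i, ], k)
      out_id <- c(out_id, if (length(alts) > 1L) paste0(ids[i], "_alt", k) else ids[i])
      out_chrom <- c(out_chrom, chrom[i]); out_pos <- c(out_pos, pos[i])
      out_ea <- c(out_ea, alts[k]); out_oa <- c(out_oa, ref[i])
    }
  }
  dos <- do.call(cbind, out_dos)
  rownames(dos) <- colnames(gt)
  vt <- variant_table(out_id, out_chrom, as.integer(out_pos), out_ea, out_oa)
  genotype_panel(dos, vt, colnames(gt), study_id, ancestry, max_missing)
}

read_dosage_panel <- function(path, study_id, ancestry, max_missing) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "sample_id"))
  if (!"sample_id" %in% names(dt))
    stop_tf("dosage TSV must have a 'sample_id' column: ", path)
  ids <- setdiff(names(dt), "sample_id")
  if (anyDuplicated(ids)) stop_tf("duplicate variant id(s) in dosage TSV")
  dos <- as.matrix(dt[, ids, with = FALSE])
  storage.mode(dos) <- "double"
  side <- paste0(path, ".variants")
  vt <- if (file.exists(side)) {
    v <- data.table::fread(side, sep = "\t", header = TRUE)
    variant_table(v$id, v$chrom, v$pos, v$effect_allele, v$other_allele,
                  v$annotation, v$locus_id)
  } else {
    variant_table(ids, "?", seq_along(ids), "A", "G")
  }
  if (!identical(vt$id, ids)) stop_tf("sidecar variant metadata does not match header")
  genotype_panel(dos, vt, dt$sample_id, study_id, ancestry, max_missing)
}

#' Write a panel's dosage matrix (and variant metadata sidecar) as TSV
#'
#' @param panel a [genotype_panel()].
#' @param path output TSV; metadata goes to `<path>.variants`.
#' @export
write_dosage <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  dt <- data.table::data.table(sample_id = panel$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(panel$dosages))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(panel$variants, paste0(path, ".variants"), sep = "\t",
                     quote = FALSE)
  invisible(path)
}

# ---- phenotypes and annotations ---------------------------------------------

#' Construct a phenotype/covariate table
#'
#' @param data data.frame containing a `sample_id` column plus trait and
#'   covariate columns.
#' @param traits names of trait columns.
#' @param covariates names of covariate columns.
#' @param scale named character giving the scale of each trait: `"linear"` or
#'   `"log_e"` (already natural-log transformed). Defaults to `"linear"`.
#' @return data.frame of class `phenotype_table` with `traits`, `covariates`
#'   and `trait_scale` attributes.
#' @export
phenotype_table <- function(data, traits, covariates = character(0),
                            scale = NULL) {
  if (!"sample_id" %in% names(data)) stop_tf("missing 'sample_id' column")
  if (anyDuplicated(data$sample_id)) stop_tf("sample_id values must be unique")
  missing_cols <- setdiff(c(traits, covariates), names(data))
  if (length(missing_cols))
    stop_tf("requested column(s) absent: ", paste(missing_cols, collapse = ", "))
  scale <- scale %||% setNames(rep("linear", length(traits)), traits)
  if (is.null(names(scale))) names(scale) <- traits
  if (!all(scale %in% c("linear", "log_e"))) stop_tf("trait scale must be 'linear' or 'log_e'")
  df <- data[, c("sample_id", traits, covariates), drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  for (cn in c(traits, covariates)) {
    v <- df[[cn]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(as.character(v)))
    df[[cn]] <- v
  }
  structure(df, traits = traits, covariates = covariates, trait_scale = scale,
            class = c("phenotype_table", "data.frame"))
}

#' Read a phenotype/covariate TSV
#'
#' Non-numeric cells in trait or covariate columns become missing values; the
#' sample row is retained.
#'
#' @param path TSV with a `sample_id` column.
#' @param trait_names,covariate_names columns to keep.
#' @param scale trait scale flags, see [phenotype_table()].
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, trait_names, covariate_names = character(0),
                            scale = NULL) {
  if (!file.exists(path)) stop_tf("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  phenotype_table(dt, trait_names, covariate_names, scale)
}

#' Read a variant annotation TSV
#'
#' Expected columns: `variant_id<TAB>annotation` (optional free-text columns
#' are ignored). Returns a named character vector keyed by variant id.
#' @param path TSV path.
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("variant_id", "annotation") %in% names(dt)))
    stop_tf("annotation TSV needs columns variant_id, annotation")
  if (anyDuplicated(dt$variant_id)) stop_tf("duplicate variant id(s) in annotation table")
  ann <- as.character(dt$annotation)
  bad <- !ann %in% ANNOTATION_LEVELS
  if (any(bad)) stop_tf("unknown annotation class: ",
                        paste(unique(ann[bad]), collapse = ", "))
  setNames(ann, dt$variant_id)
}

# ---- association result tables ----------------------------------------------

ASSOC_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "EAF", "n", "beta", "se", "p", "trait", "study_id")

validate_assoc <- function(df) {
  missing_cols <- setdiff(ASSOC_COLS, names(df))
  if (length(missing_cols))
    stop_tf("association table missing column(s): ",
            paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop_tf("association table is empty")
  if (any(!is.finite(df$se) | df$se <= 0)) stop_tf("se must be > 0")
  if (any(!is.finite(df$p) | df$p <= 0 | df$p > 1)) stop_tf("p must lie in (0, 1]")
  if (any(df$EAF < 0 | df$EAF > 1)) stop_tf("EAF must lie in [0, 1]")
  invisible(df)
}

#' Write / read per-variant association summary statistics
#'
#' Columns: variant_id, chrom, pos, effect_allele, other_allele, EAF, n, beta,
#' se, p, trait, study_id (plus conditioned_on when present). Reading inverts
#' writing at the stored precision.
#' @param results association results data.frame (e.g. from [run_association()]).
#' @param path TSV path.
#' @export
write_assoc_table <- function(results, path) {
  validate_assoc(results)
  data.table::fwrite(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_assoc_table
#' @export
read_assoc_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = "chrom"))
  validate_assoc(df)
  class(df) <- c("assoc_table", "data.frame")
  df
}
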
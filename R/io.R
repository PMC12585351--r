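# File formats and input preparation.
#
# The interchange format is a long-format tab-separated table with one row
# per (sample, SNP): sample_id, snp_id, ref_count, var_count, group
# (control/case). Columns are matched by name, not position; extra columns
# (e.g., chrom) are carried through.

#' Validate a long-format allele-count table
#'
#' Checks column presence, non-negative integer counts, uniqueness of
#' (sample_id, snp_id) pairs, and group labels.
#'
#' @param counts Data frame to validate.
#' @param require_group Must a `group` column with values
#'   `"control"`/`"case"` be present?
#' @return The validated data frame (invisibly modified: counts coerced to
#'   integer).
#' @export
validate_allele_counts <- function(counts, require_group = TRUE) {
  need <- c("sample_id", "snp_id", "ref_count", "var_count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("allele-count table misses column(s): ",
                         paste(miss, collapse = ", "))
  for (cl in c("ref_count", "var_count")) {
    v <- counts[[cl]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stop(cl, " must be non-negative integers")
    counts[[cl]] <- as.integer(round(v))
  }
  if (anyDuplicated(counts[, c("sample_id", "snp_id")]))
    stop("(sample_id, snp_id) pairs must be unique")
  if (require_group) {
    if (is.null(counts$group)) stop("allele-count table needs a 'group' column")
    bad <- setdiff(unique(counts$group), c("control", "case"))
    if (length(bad)) stop("group labels must be 'control'/'case'; found: ",
                          paste(bad, collapse = ", "))
    if (!all(c("control", "case") %in% counts$group))
      stop("both a control and a case group are required")
  }
  counts
}

#' Read / write the long-format allele-count TSV
#'
#' @param path File path. The file must be tab-separated with a header;
#'   column order is free.
#' @param require_group Passed to [validate_allele_counts()].
#' @return `read_allele_counts()`: validated data frame.
#' @export
read_allele_counts <- function(path, require_group = TRUE) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_allele_counts(counts, require_group = require_group)
}

#' @rdname read_allele_counts
#' @param x Data frame to write.
#' @export
write_allele_counts <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP-to-gene annotation TSV
#'
#' Expected columns: `snp_id`, `gene_id`, `category` (see
#' [resolve_gene_assignment()] for the category vocabulary).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_snp_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "gene_id", "category")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table misses column(s): ",
                         paste(miss, collapse = ", "))
  ann
}

#' Select the two modeled alleles from raw 4-nucleotide counts
#'
#' The mixture models permit only two alleles. Per SNP, nucleotide counts are
#' summed over samples; the most common nucleotide becomes the reference
#' allele and the second most common the variant allele, optionally
#' restricted to `allowed_alleles` (e.g., the alleles a variant database
#' lists for the SNP). Ties are broken randomly (reproducibly under a fixed
#' seed). Counts of the remaining nucleotides are dropped.
#'
#' @param raw Data frame with columns `sample_id`, `snp_id`, and nucleotide
#'   count columns `A`, `C`, `G`, `T`; optionally `group` (carried through).
#' @param allowed_alleles Optional named list mapping `snp_id` to a character
#'   vector of permitted nucleotides.
#' @return List with `counts` (long-format allele-count table) and `alleles`
#'   (per-SNP data frame of the chosen reference/variant nucleotides).
#'   Monomorphic SNPs (no second allele observed) are excluded with a
#'   warning.
#' @export
select_biallelic <- function(raw, allowed_alleles = NULL) {
  nucs <- c("A", "C", "G", "T")
  miss <- setdiff(c("sample_id", "snp_id", nucs), names(raw))
  if (length(miss)) stop("raw count table misses column(s): ",
                         paste(miss, collapse = ", "))
  out <- list(); sel <- list(); dropped <- character(0)
  for (id in unique(raw$snp_id)) {
    d <- raw[raw$snp_id == id, , drop = FALSE]
    tot <- vapply(nucs, function(nc) sum(d[[nc]]), numeric(1))
    if (!is.null(allowed_alleles) && !is.null(allowed_alleles[[id]])) {
      tot <- tot[names(tot) %in% allowed_alleles[[id]]]
    }
    tot <- tot[tot > 0]
    if (length(tot) < 2) {
      dropped <- c(dropped, id)
      next
    }
    # rank with random tie-breaking (reproducible under set.seed)
    ord <- order(tot + stats::runif(length(tot)) * 0.5, decreasing = TRUE)
    ref <- names(tot)[ord[1]]; var <- names(tot)[ord[2]]
    res <- data.frame(sample_id = d$sample_id, snp_id = id,
                      ref_count = d[[ref]], var_count = d[[var]],
                      stringsAsFactors = FALSE)
    if (!is.null(d$group)) res$group <- d$group
    out[[id]] <- res
    sel[[id]] <- data.frame(snp_id = id, ref = ref, var = var,
                            stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("excluded monomorphic SNP(s): ", paste(dropped, collapse = ", "))
  if (!length(out)) stop("no biallelic SNP left after allele selection")
  list(counts = do.call(rbind, c(out, list(make.row.names = FALSE))),
       alleles = do.call(rbind, c(sel, list(make.row.names = FALSE))))
}

#' Drop SNPs observed in too few samples
#'
#' Retains SNPs with a nonzero total allelic count in at least `k` samples.
#'
#' @param counts Long-format allele-count table.
#' @param k Minimum number of covering samples (inclusive).
#' @param verbose Log the number of dropped SNPs?
#' @return Filtered table.
#' @export
prevalence_filter <- function(counts, k = 10L, verbose = FALSE) {
  covered <- tapply(counts$ref_count + counts$var_count > 0, counts$snp_id, sum)
  keep <- names(covered)[covered >= k]
  dropped <- length(covered) - length(keep)
  if (verbose) message(dropped, " SNP(s) dropped by the prevalence filter (k = ", k, ")")
  out <- counts[counts$snp_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
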
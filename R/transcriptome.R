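# Probe-level microarray expression processing into a left-hemisphere
# parcel x gene matrix: invalid-ID removal, intensity-based (above
# background) filtering, RNA-seq-guided selection of one probe per gene,
# aggregation by parcel, and risk-gene co-expression.

probe_table_columns <- c("probe_id", "gene_id", "donor_id", "sample_id",
                         "parcel_label", "intensity", "above_background")

check_probe_table <- function(probes) {
  miss <- setdiff(probe_table_columns, names(probes))
  if (length(miss))
    imgtx_stop(paste("probe table is missing column(s):",
                     paste(miss, collapse = ", ")))
  invisible(probes)
}

#' Filter probes by gene-ID validity and above-background presence
#'
#' Removes rows whose gene id is invalid (missing or empty), then drops
#' every probe whose fraction of samples flagged above background falls
#' below `min_donor_fraction` — probes present in less than half of the
#' donor samples, at the default 0.5.
#'
#' @param probes Probe table (data.frame, one row per probe x sample).
#' @param min_donor_fraction Minimum fraction of a probe's samples that
#'   must be above background.
#' @return The filtered probe table.
#' @export
filter_probes <- function(probes, min_donor_fraction = 0.5) {
  check_probe_table(probes)
  if (!nrow(probes)) imgtx_stop("empty probe table")
  valid <- !is.na(probes$gene_id) & probes$gene_id != ""
  probes <- probes[valid, , drop = FALSE]
  if (!nrow(probes)) return(probes)
  frac <- tapply(probes$above_background, probes$probe_id, mean)
  keep_probe <- names(frac)[frac >= min_donor_fraction]
  probes[probes$probe_id %in% keep_probe, , drop = FALSE]
}

# Mean intensity per (probe, parcel): the probe's regional expression
# pattern used both for probe selection and the final matrix.
probe_parcel_means <- function(probes) {
  agg <- stats::aggregate(intensity ~ probe_id + parcel_label, data = probes,
                          FUN = mean)
  agg
}

#' Select one probe per gene by agreement with an RNA-seq reference
#'
#' For genes measured by several probes, each probe's parcel-level mean
#' expression pattern is compared with the gene's RNA-seq reference
#' profile by Spearman rank correlation over the shared parcels, and the
#' probe with the highest correlation is kept. Single-probe genes pass
#' through. A probe constant across parcels has undefined correlation and
#' is treated as -Inf (never selected over a valid probe). Ties break by
#' probe id, lexicographically. Multi-probe genes absent from the
#' reference fall back to the probe with the highest mean intensity, with
#' a warning.
#'
#' @param probes Filtered probe table.
#' @param ref RNA-seq reference: data.frame with `gene_id`,
#'   `parcel_label`, `expression`.
#' @return Probe table restricted to the selected probes.
#' @export
select_probe_per_gene <- function(probes, ref) {
  check_probe_table(probes)
  pp <- probe_parcel_means(probes)
  probe_gene <- unique(probes[, c("probe_id", "gene_id")])
  fallback_genes <- character()
  selected <- character()
  for (g in unique(probe_gene$gene_id)) {
    cand <- sort(probe_gene$probe_id[probe_gene$gene_id == g])
    if (length(cand) == 1L) { selected <- c(selected, cand); next }
    rg <- ref[ref$gene_id == g, , drop = FALSE]
    if (!nrow(rg)) {
      fallback_genes <- c(fallback_genes, g)
      mi <- vapply(cand, function(p)
        mean(probes$intensity[probes$probe_id == p]), numeric(1))
      selected <- c(selected, cand[which.max(mi)])
      next
    }
    rho <- vapply(cand, function(p) {
      pat <- pp[pp$probe_id == p, , drop = FALSE]
      shared <- intersect(pat$parcel_label, rg$parcel_label)
      if (length(shared) < 3L)
        imgtx_stop(sprintf("probe %s shares fewer than 3 parcels with the reference", p))
      x <- pat$intensity[match(shared, pat$parcel_label)]
      y <- rg$expression[match(shared, rg$parcel_label)]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
      stats::cor(x, y, method = "spearman")
    }, numeric(1))
    selected <- c(selected, cand[which.max(rho)])   # first max: lexicographic tie-break
  }
  if (length(fallback_genes))
    warning(sprintf(
      "gene(s) %s absent from the RNA-seq reference; kept highest-mean-intensity probe",
      paste(fallback_genes, collapse = ", ")), call. = FALSE)
  probes[probes$probe_id %in% selected, , drop = FALSE]
}

#' Aggregate selected probes into a parcel x gene expression matrix
#'
#' Mean intensity per (parcel, gene) over samples, restricted to the
#' requested hemisphere. Parcels with no samples are dropped from the
#' matrix. Gene columns are z-scored across parcels when `standardize` is
#' set.
#'
#' @param probes Filtered, probe-selected table.
#' @param parcellation A `parcellation` (used for the hemisphere lookup).
#' @param hemisphere "left", "right" or "all".
#' @param standardize Z-score each gene column across parcels.
#' @return Object of class `expression_matrix`: `values` (parcels x
#'   genes), `parcels`, `genes`, `standardized`.
#' @export
aggregate_to_parcels <- function(probes, parcellation, hemisphere = "left",
                                 standardize = TRUE) {
  check_probe_table(probes)
  if (hemisphere != "all") {
    want <- if (hemisphere == "left") "L" else "R"
    ok <- names(parcellation$hemisphere)[parcellation$hemisphere == want]
    probes <- probes[as.character(probes$parcel_label) %in% ok, , drop = FALSE]
  }
  if (!nrow(probes)) imgtx_stop("no probe samples left after hemisphere filter")
  agg <- stats::aggregate(intensity ~ parcel_label + gene_id, data = probes,
                          FUN = mean)
  parcels <- sort(unique(agg$parcel_label))
  genes <- sort(unique(agg$gene_id))
  m <- matrix(NA_real_, length(parcels), length(genes),
              dimnames = list(as.character(parcels), genes))
  m[cbind(match(agg$parcel_label, parcels), match(agg$gene_id, genes))] <-
    agg$intensity
  if (anyNA(m)) {
    # a gene unmeasured in some sampled parcel would leave holes; the
    # generator's donor coverage makes this rare, but guard anyway
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    imgtx_stop(paste("gene(s) with missing parcel coverage:",
                     paste(bad, collapse = ", ")))
  }
  if (standardize) m <- scale(m)[, , drop = FALSE]
  structure(list(values = unclass(m[, , drop = FALSE]), parcels = parcels,
                 genes = genes, standardized = standardize),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d parcels x %d genes%s\n",
              length(x$parcels), length(x$genes),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Co-expression of a gene list across parcels
#'
#' Pearson correlation between the regional expression profiles of the
#' listed genes. Genes missing from the matrix are reported and skipped;
#' constant profiles yield missing correlations with a warning.
#'
#' @param expr An `expression_matrix`.
#' @param gene_list Character vector of gene ids.
#' @return Symmetric correlation matrix with unit diagonal over the genes
#'   found, with attribute `missing_genes`.
#' @export
risk_gene_coexpression <- function(expr, gene_list) {
  stopifnot(inherits(expr, "expression_matrix"))
  found <- intersect(gene_list, expr$genes)
  missing <- setdiff(gene_list, expr$genes)
  if (length(missing))
    warning(paste("gene(s) not in the expression matrix:",
                  paste(missing, collapse = ", ")), call. = FALSE)
  if (length(found) < 2L) imgtx_stop("need at least 2 genes present")
  x <- expr$values[, found, drop = FALSE]
  const <- apply(x, 2, stats::sd) == 0
  if (any(const))
    warning(paste("constant expression profile(s):",
                  paste(found[const], collapse = ", ")), call. = FALSE)
  cc <- suppressWarnings(stats::cor(x))
  cc[const, ] <- NA; cc[, const] <- NA
  diag(cc) <- 1
  attr(cc, "missing_genes") <- missing
  cc
}
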
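#' Per-gene expression summary statistics
#'
#' Computes, for each gene of an expression matrix, the mean expression value
#' (MV), the sample standard deviation (SD, n-1 denominator) across conditions,
#' and the coefficient of variation CV = SD / MV. The CV is the screening
#' statistic for candidate reference genes: genes whose transcript abundance
#' barely moves across conditions have a low CV regardless of their absolute
#' expression level.
#'
#' Genes with zero mean expression have an undefined CV; they are flagged
#' (`cv_defined = FALSE`, `cv = NA`) rather than raising, so genome-scale
#' matrices survive screening.
#'
#' @param m Expression matrix (genes x conditions), see
#'   [read_expression_matrix()].
#' @return A `data.frame` with columns `gene`, `mv`, `sd`, `cv`, `cv_defined`,
#'   one row per gene, in matrix row order.
#' @export
expression_stats <- function(m) {
  validate_expression_matrix(m)
  mv <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  cv <- ifelse(mv > 0, sd / mv, NA_real_)
  data.frame(gene = rownames(m), mv = mv, sd = sd, cv = cv,
             cv_defined = mv > 0, row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen candidate reference genes by coefficient of variation
#'
#' Retains genes with a defined CV strictly below `cv_max` (default 0.3, the
#' customary transcriptome-screening cut-off for stably expressed genes) and
#' orders them by increasing CV, ties broken lexicographically by gene id.
#'
#' @param stats Output of [expression_stats()].
#' @param cv_max Strict upper bound on CV; must be > 0.
#' @return Character vector of gene ids, most stable first.
#' @export
filter_candidates <- function(stats, cv_max = 0.3) {
  if (!is.data.frame(stats) || !all(c("gene", "cv") %in% names(stats))) {
    stop("stats must be the data.frame returned by expression_stats()")
  }
  if (!is.numeric(cv_max) || length(cv_max) != 1 || is.na(cv_max) || cv_max <= 0) {
    stop("cv_max must be a positive number")
  }
  keep <- !is.na(stats$cv) & stats$cv < cv_max
  sel <- stats[keep, , drop = FALSE]
  sel$gene[order(sel$cv, sel$gene)]
}
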
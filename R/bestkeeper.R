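#' BestKeeper descriptive stability statistics
#'
#' Computes the BestKeeper per-gene dispersion summary directly on the Ct
#' scale: the "SD" is the mean absolute deviation of a gene's Ct values from
#' their arithmetic mean (in cycles), and the "CV" is that deviation as a
#' percent of the mean Ct. Genes are ranked ascending by SD, ties broken by
#' CV then gene id. A gene whose SD exceeds 1 cycle is flagged unacceptable
#' as a reference (`acceptable = FALSE`) but is kept in the table.
#'
#' Note this CV is a percent-of-cycles measure on the Ct scale; it is a
#' different quantity from the dimensionless expression CV of
#' [expression_stats()] and the two are never comparable.
#'
#' Missing cells (NA) are tolerated per gene with a warning, since the
#' descriptive statistics remain defined on the observed samples.
#'
#' @param ct A `ct_matrix`, or a numeric gene x sample matrix of mean Ct.
#' @param samples Optional sample-id subset (>= 2 samples).
#' @return A `bestkeeper_result` data.frame with columns `rank`, `gene`, `n`,
#'   `mean_ct`, `geo_mean_ct`, `min_ct`, `max_ct`, `sd`, `cv`, `acceptable`,
#'   sorted by rank.
#' @export
bestkeeper_stats <- function(ct, samples = NULL) {
  m <- if (inherits(ct, "ct_matrix")) ct$ct else ct
  if (!is.matrix(m) || !is.numeric(m)) stop("ct must be a ct_matrix or numeric matrix")
  if (!is.null(samples)) {
    unknown <- setdiff(samples, colnames(m))
    if (length(unknown) > 0) stop("unknown sample(s): ", paste(unknown, collapse = ", "))
    m <- m[, samples, drop = FALSE]
  }
  if (ncol(m) < 2) stop("BestKeeper needs at least 2 samples")
  if (anyNA(m)) warning("missing Ct cells; per-gene statistics use observed samples only")
  stat_row <- function(x) {
    x <- x[!is.na(x)]
    mu <- mean(x)
    c(n = length(x), mean_ct = mu, geo_mean_ct = exp(mean(log(x))),
      min_ct = min(x), max_ct = max(x),
      sd = mean(abs(x - mu)), cv = 100 * mean(abs(x - mu)) / mu)
  }
  s <- t(apply(m, 1, stat_row))
  df <- data.frame(gene = rownames(m), s, row.names = NULL, stringsAsFactors = FALSE)
  df$acceptable <- df$sd <= 1
  df <- df[order(df$sd, df$cv, df$gene), , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  class(df) <- c("bestkeeper_result", "data.frame")
  df
}

#' BestKeeper index and per-gene correlations
#'
#' The BestKeeper index for a sample is the geometric mean of the listed
#' genes' Ct values at that sample. Each gene's Ct row is then correlated
#' (Pearson) with the index; genes tracking the common expression trend have
#' r close to 1. A constant gene row has an undefined correlation, reported
#' as NA with a warning.
#'
#' @param ct A `ct_matrix`, or a numeric gene x sample Ct matrix (complete).
#' @param genes Gene ids to build the index from (>= 2; >= 3 samples needed).
#' @return List with `index` (named per-sample vector) and `r` (named per-gene
#'   Pearson correlation with the index).
#' @export
bestkeeper_index <- function(ct, genes = NULL) {
  m <- if (inherits(ct, "ct_matrix")) ct$ct else ct
  if (is.null(genes)) genes <- rownames(m)
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown) > 0) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (length(genes) < 1) stop("the index needs at least 1 gene")
  if (ncol(m) < 3) stop("correlations need at least 3 samples")
  sub <- m[genes, , drop = FALSE]
  index <- exp(colMeans(log(sub)))
  r <- vapply(genes, function(g) {
    if (stats::sd(sub[g, ]) == 0) NA_real_ else stats::cor(sub[g, ], index)
  }, numeric(1))
  if (anyNA(r)) {
    warning("constant Ct row(s): correlation undefined for ",
            paste(names(r)[is.na(r)], collapse = ", "))
  }
  list(index = index, r = r)
}
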
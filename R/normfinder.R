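#' Log2 relative quantities
#'
#' Element-wise log2 of a relative-quantity matrix. For efficiency 2 this is
#' exactly -dCt, the scale on which the NormFinder model is linear.
#'
#' @param q Relative-quantity matrix (values > 0).
#' @return Numeric matrix of the same shape.
#' @export
log_quantities <- function(q) {
  if (any(q <= 0)) stop("relative quantities must be positive")
  lq <- log2(q)
  attr(lq, "groups") <- attr(q, "groups")
  lq
}

#' NormFinder model-based stability values
#'
#' Fits the NormFinder variance-decomposition model to sample-centered log
#' quantities. Each sample's column is centered by its mean over genes, which
#' removes sample-wide loading/efficiency effects and each gene's overall
#' abundance from the analysis. Per gene and experimental group the model
#' estimates (i) the intragroup variance — the gene's residual noise, with the
#' shared-noise bias term subtracted and negative estimates floored at 0 —
#' and (ii) the intergroup deviation d — the gene's systematic shift in that
#' group relative to its grand mean — shrunk toward 0 in proportion to its
#' sampling variance. The stability value is the mean over groups of
#' |shrunken d| plus the posterior standard error; lower is more stable.
#'
#' With a single group the model degenerates and the gene's stability is the
#' square root of its (bias-corrected) intragroup variance.
#'
#' @param logq Log2 relative-quantity matrix (genes x samples), >= 3 genes.
#' @param groups Named character vector mapping every sample (column) to its
#'   experimental group; every group needs >= 2 samples. Defaults to the
#'   `"groups"` attribute carried over from [relative_quantities()].
#' @return A `normfinder_result`: list with `stability` (named vector, input
#'   gene order), `ranking` (data.frame `gene`, `stability`, `rank`, ascending),
#'   `intragroup_var` and `intergroup_dev` (genes x groups matrices; the
#'   deviation matrix holds the shrunken d values), and `groups`.
#' @export
normfinder_stability <- function(logq, groups = attr(logq, "groups")) {
  if (nrow(logq) < 3) stop("NormFinder needs at least 3 genes (sample-centering is degenerate)")
  if (is.null(groups)) stop("a sample-to-group mapping is required")
  if (!all(colnames(logq) %in% names(groups))) stop("groups must cover every sample")
  groups <- groups[colnames(logq)]
  if (any(!is.finite(logq))) stop("log-quantity matrix must be complete and finite")
  glev <- unique(groups)
  n_g <- table(factor(groups, levels = glev))
  if (any(n_g < 2)) {
    stop("every group needs at least 2 samples; offending group(s): ",
         paste(glev[n_g < 2], collapse = ", "))
  }
  I <- nrow(logq)
  G <- length(glev)
  genes <- rownames(logq)
  z <- sweep(logq, 2, colMeans(logq))  # sample-centering

  s2 <- matrix(NA_real_, I, G, dimnames = list(genes, glev))   # raw within-group var
  zbar <- matrix(NA_real_, I, G, dimnames = list(genes, glev)) # group means
  for (g in seq_along(glev)) {
    zg <- z[, groups == glev[g], drop = FALSE]
    zbar[, g] <- rowMeans(zg)
    s2[, g] <- apply(zg, 1, stats::var)
  }
  # bias-corrected intragroup variance: sample-centering mixes 2/I of each
  # gene's own noise and 1/I^2 of everyone's into each centered value
  sigma2 <- sweep(s2, 2, colSums(s2) / (I * (I - 1))) * I / (I - 2)
  sigma2 <- pmax(sigma2, 0)

  if (G == 1) {
    stability <- sqrt(sigma2[, 1])
    d_shrunk <- matrix(0, I, 1, dimnames = list(genes, glev))
  } else {
    d <- zbar - rowMeans(zbar)                       # intergroup deviation, sums to 0 over groups
    vard <- sweep(sigma2, 2, as.numeric(n_g), `/`)   # sampling variance of d-hat
    gamma2 <- max(0, sum(d ^ 2) / ((I - 1) * (G - 1)) - mean(vard))
    shrink <- if (gamma2 > 0) gamma2 / (gamma2 + vard) else vard * 0
    d_shrunk <- d * shrink
    post_se <- sqrt(vard * shrink)
    stability <- rowMeans(abs(d_shrunk) + post_se)
  }
  names(stability) <- genes
  ranking <- data.frame(gene = genes, stability = as.numeric(stability),
                        row.names = NULL, stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$stability, ranking$gene), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  structure(list(stability = stability, ranking = ranking,
                 intragroup_var = sigma2, intergroup_dev = d_shrunk,
                 groups = groups),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability (", ncol(x$intragroup_var), " group(s); lower = more stable):\n", sep = "")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.normfinder_result <- function(x, ...) x$ranking
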
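#' Convert mean Ct values to relative quantities
#'
#' Transforms each gene's Ct row to relative quantities
#' `q[g, s] = E_g^-(Ct[g, s] - min_s Ct[g, s])`, i.e. the classical
#' `2^-dCt` transformation when the amplification efficiency E is 2. Each
#' gene is anchored at its own minimum Ct, so quantities lie in (0, 1] with a
#' per-gene maximum of exactly 1; absolute abundance differences between genes
#' are deliberately removed.
#'
#' @param ct A `ct_matrix` (see [aggregate_replicates()]).
#' @param efficiencies Optional named numeric vector of per-gene amplification
#'   efficiencies; genes not listed default to 2.
#' @return Numeric gene x sample matrix of relative quantities, with the
#'   sample-to-group mapping attached as attribute `"groups"`.
#' @export
relative_quantities <- function(ct, efficiencies = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  e <- efficiency_table(rownames(ct$ct), efficiencies)
  dct <- ct$ct - apply(ct$ct, 1, min)
  q <- e ^ -dct  # e recycles down columns: one efficiency per gene row
  dimnames(q) <- dimnames(ct$ct)
  attr(q, "groups") <- ct$groups
  q
}

#' Geometric-mean normalization factor
#'
#' The per-sample normalization factor NF is the geometric mean of the
#' selected reference genes' relative quantities — the geNorm construction.
#' The geometric mean is used (not the arithmetic one) so no single abundant
#' reference dominates the factor.
#'
#' @param q Relative-quantity matrix from [relative_quantities()].
#' @param ref_genes Character vector of reference gene ids (length >= 1).
#' @return Named numeric vector, one positive factor per sample.
#' @export
normalization_factor <- function(q, ref_genes) {
  if (length(ref_genes) < 1) stop("at least one reference gene is required")
  unknown <- setdiff(ref_genes, rownames(q))
  if (length(unknown) > 0) stop("unknown reference gene(s): ", paste(unknown, collapse = ", "))
  exp(colMeans(log(q[ref_genes, , drop = FALSE])))
}

#' Fold change of a target gene by the 2^-ddCt method
#'
#' Computes the relative expression of a target gene in a treated sample set
#' versus a control sample set, normalized to one or more reference genes:
#' per sample, dCt = Ct(target) - mean Ct(references); per group, dCt values
#' are averaged; ddCt = dCt(treated) - dCt(control); fold = 2^-ddCt.
#' With several references, averaging their Ct values is equivalent to
#' dividing by the geometric-mean normalization factor on the quantity scale.
#'
#' @param ct A `ct_matrix` of mean Ct values.
#' @param target Target gene id (must not be among `refs`).
#' @param refs Character vector of reference gene ids.
#' @param control_samples,treated_samples Non-empty sample-id vectors.
#' @return One-row `data.frame` with columns `target`, `dct_control`,
#'   `dct_treated`, `ddct` and `fold`.
#' @export
ddct_fold_change <- function(ct, target, refs, control_samples, treated_samples) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (target %in% refs) stop("target gene must not be among the reference genes")
  if (length(control_samples) == 0 || length(treated_samples) == 0) {
    stop("control and treated sample lists must be non-empty")
  }
  genes <- rownames(ct$ct)
  unknown <- setdiff(c(target, refs), genes)
  if (length(unknown) > 0) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  unknown_s <- setdiff(c(control_samples, treated_samples), colnames(ct$ct))
  if (length(unknown_s) > 0) stop("unknown sample(s): ", paste(unknown_s, collapse = ", "))
  dct <- ct$ct[target, ] - colMeans(ct$ct[refs, , drop = FALSE])
  dct_c <- mean(dct[control_samples])
  dct_t <- mean(dct[treated_samples])
  ddct <- dct_t - dct_c
  data.frame(target = target, dct_control = dct_c, dct_treated = dct_t,
             ddct = ddct, fold = 2 ^ -ddct, stringsAsFactors = FALSE)
}
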
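#' Pairwise variation between two genes
#'
#' The building block of the geNorm M value: the sample standard deviation
#' (n-1) across samples of the log2 expression ratio of two genes. Two genes
#' that are perfectly co-regulated (or both perfectly stable) have a constant
#' ratio and a pairwise variation of 0.
#'
#' @param q Relative-quantity matrix (genes x samples), values > 0.
#' @param j,k Distinct gene ids present in `q`.
#' @return Non-negative scalar.
#' @export
pairwise_gene_variation <- function(q, j, k) {
  if (identical(j, k)) stop("pairwise variation requires two distinct genes")
  unknown <- setdiff(c(j, k), rownames(q))
  if (length(unknown) > 0) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (ncol(q) < 2) stop("at least 2 samples are required")
  stats::sd(log2(q[j, ] / q[k, ]))
}

#' geNorm M values for a gene set
#'
#' For each gene, M is the arithmetic mean of its pairwise variations against
#' every other gene in the set. Lower M means more stable expression; the
#' customary interpretation treats M below 1.5 as acceptably stable.
#'
#' @param q Relative-quantity matrix.
#' @param gene_set Gene ids to evaluate (default: all rows of `q`); at least 2.
#' @return Named numeric vector of M values in `gene_set` order.
#' @export
m_values <- function(q, gene_set = rownames(q)) {
  if (length(gene_set) < 2) stop("M values need at least 2 genes")
  unknown <- setdiff(gene_set, rownames(q))
  if (length(unknown) > 0) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  lg <- log2(q[gene_set, , drop = FALSE])
  k <- length(gene_set)
  v <- matrix(0, k, k, dimnames = list(gene_set, gene_set))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      s <- stats::sd(lg[a, ] - lg[b, ])
      v[a, b] <- s
      v[b, a] <- s
    }
  }
  rowSums(v) / (k - 1)
}

#' geNorm stepwise stability ranking
#'
#' Repeatedly computes M over the remaining genes and excludes the gene with
#' the highest M (ties resolved by excluding the lexicographically last gene
#' id, recorded in the result), until two genes remain. The final two genes
#' cannot be separated by the method — their M values in a 2-gene set are
#' identical — and share the best rank (reported as mean rank 1.5 each).
#'
#' @param q Relative-quantity matrix with >= 3 genes.
#' @param stable_threshold M value below which a gene is flagged stable
#'   (default 1.5).
#' @return A `genorm_result`: list with `ranking` (data.frame `gene`, `m`
#'   — the gene's M at the step it was excluded, or the final-pair M —,
#'   `rank`, `stable`), `exclusion_order` (least stable first) and
#'   `final_pair`.
#' @export
genorm_rank <- function(q, stable_threshold = 1.5) {
  genes <- rownames(q)
  if (length(genes) < 3) stop("stepwise geNorm ranking needs at least 3 genes")
  remaining <- genes
  exclusion_order <- character(0)
  m_at_exclusion <- numeric(0)
  while (length(remaining) > 2) {
    m <- m_values(q, remaining)
    worst <- max(m)
    cand <- names(m)[m >= worst - 1e-12]
    drop_gene <- sort(cand)[length(cand)]  # lexicographically last on ties
    exclusion_order <- c(exclusion_order, drop_gene)
    m_at_exclusion <- c(m_at_exclusion, m[[drop_gene]])
    remaining <- setdiff(remaining, drop_gene)
  }
  final_m <- m_values(q, remaining)  # equal for both members of the pair
  ranking <- data.frame(
    gene = c(sort(remaining), rev(exclusion_order)),
    m = c(final_m[sort(remaining)], rev(m_at_exclusion)),
    rank = c(1.5, 1.5, seq(3, length(genes))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ranking$stable <- ranking$m < stable_threshold
  structure(list(ranking = ranking, exclusion_order = exclusion_order,
                 final_pair = sort(remaining)),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stepwise ranking (most stable first):\n")
  print(x$ranking, row.names = FALSE)
  cat("final (tied) pair:", paste(x$final_pair, collapse = "/"), "\n")
  invisible(x)
}

#' @export
as.data.frame.genorm_result <- function(x, ...) x$ranking

#' Pairwise variation series V(n/n+1)
#'
#' Determines how many reference genes are needed: for each n from 2 to K-1,
#' builds normalization factors NF_n and NF_(n+1) from the n and n+1 most
#' stable genes (geNorm ranking order) and computes V_n as the sample standard
#' deviation across samples of log2(NF_n / NF_(n+1)). A V_n below the
#' threshold (canonically 0.15) means the (n+1)-th gene adds nothing, so n
#' genes suffice; `optimal_n` is the smallest such n, or NA if every V is at
#' or above the threshold.
#'
#' @param q Relative-quantity matrix.
#' @param ranking A `genorm_result` for `q`, or a character vector giving an
#'   explicit gene order (most stable first). Default: compute
#'   [genorm_rank()] on `q`.
#' @param threshold Decision threshold on V (default 0.15).
#' @return A `pv_series`: list with `v` (data.frame `n`, `label`, `v`),
#'   `threshold` and `optimal_n`.
#' @export
pairwise_variation_series <- function(q, ranking = NULL, threshold = 0.15) {
  if (is.null(ranking)) ranking <- genorm_rank(q)
  ord <- if (inherits(ranking, "genorm_result")) {
    r <- ranking$ranking
    r$gene[order(r$rank, r$gene)]
  } else {
    as.character(ranking)
  }
  if (length(ord) < 3) stop("pairwise variation needs a ranking over at least 3 genes")
  unknown <- setdiff(ord, rownames(q))
  if (length(unknown) > 0) stop("unknown gene(s) in ranking: ", paste(unknown, collapse = ", "))
  k <- length(ord)
  ns <- 2:(k - 1)
  v <- vapply(ns, function(n) {
    nf_n <- normalization_factor(q, ord[seq_len(n)])
    nf_n1 <- normalization_factor(q, ord[seq_len(n + 1)])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1))
  below <- which(v < threshold)
  optimal_n <- if (length(below) > 0) ns[below[1]] else NA_integer_
  structure(list(
    v = data.frame(n = ns, label = paste0("V", ns, "/", ns + 1), v = v,
                   row.names = NULL, stringsAsFactors = FALSE),
    threshold = threshold, optimal_n = optimal_n
  ), class = "pv_series")
}

#' @export
print.pv_series <- function(x, ...) {
  cat("geNorm pairwise variation (threshold ", x$threshold, "):\n", sep = "")
  print(x$v, row.names = FALSE)
  if (is.na(x$optimal_n)) {
    cat("no V below the threshold: more genes, or a pragmatic choice, required\n")
  } else {
    cat("optimal number of reference genes:", x$optimal_n, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pv_series <- function(x, ...) x$v
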
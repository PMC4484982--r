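#' Extract a per-gene rank map from a method result
#'
#' Returns the named numeric rank vector a stability method assigns to each
#' gene, in a common form the consensus aggregation can consume. geNorm's
#' tied best pair enters as mean rank 1.5 each; NormFinder ties (identical
#' stability values) enter as mean ranks.
#'
#' @param x A `genorm_result`, `normfinder_result` or `bestkeeper_result`.
#' @return Named numeric vector of ranks.
#' @export
method_ranks <- function(x) {
  if (inherits(x, "genorm_result")) {
    stats::setNames(x$ranking$rank, x$ranking$gene)
  } else if (inherits(x, "normfinder_result")) {
    stats::setNames(rank(x$stability, ties.method = "average"), names(x$stability))
  } else if (inherits(x, "bestkeeper_result")) {
    stats::setNames(as.numeric(x$rank), x$gene)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("cannot extract ranks from an object of class ", paste(class(x), collapse = "/"))
  }
}

#' Aggregate per-method rankings into a consensus ranking
#'
#' Combines the rank each stability algorithm assigns to a gene into one
#' comprehensive score: the geometric mean of ranks (the RefFinder-style
#' convention, default) or the arithmetic mean. Genes are ordered by
#' increasing score, ties broken lexicographically by gene id, so the final
#' ranks are a permutation of 1..K.
#'
#' @param rankings Named list of per-method rank maps (named numeric vectors,
#'   e.g. from [method_ranks()]); all must cover the same gene set. Tied ranks
#'   are encoded as mean ranks.
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return A `consensus_ranking` data.frame: one rank column per input method,
#'   plus `score` and `rank`, sorted by final rank.
#' @export
aggregate_ranks <- function(rankings, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  if (length(rankings) < 1) stop("at least one ranking is required")
  gene_sets <- lapply(rankings, names)
  base_set <- gene_sets[[1]]
  for (i in seq_along(gene_sets)) {
    extra <- setdiff(gene_sets[[i]], base_set)
    miss <- setdiff(base_set, gene_sets[[i]])
    if (length(extra) > 0 || length(miss) > 0) {
      stop("rankings cover different gene sets; symmetric difference: ",
           paste(c(extra, miss), collapse = ", "))
    }
  }
  if (is.null(names(rankings))) names(rankings) <- paste0("method", seq_along(rankings))
  rmat <- vapply(rankings, function(r) r[base_set], numeric(length(base_set)))
  score <- if (method == "geometric") {
    exp(rowMeans(log(rmat)))
  } else {
    rowMeans(rmat)
  }
  df <- data.frame(gene = base_set, rmat, score = score,
                   row.names = NULL, stringsAsFactors = FALSE, check.names = FALSE)
  df <- df[order(df$score, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "aggregation") <- method
  class(df) <- c("consensus_ranking", "data.frame")
  df
}

#' Run the complete reference-gene stability workflow
#'
#' Orchestrates every stage on one Ct dataset: optional CV screening of an
#' expression matrix, then — for the full sample set and for each treatment
#' subset — geNorm stepwise ranking with the pairwise-variation series,
#' NormFinder, BestKeeper, and the consensus ranking, plus optional
#' 2^-ddCt validation of target genes against the top consensus references.
#'
#' Treatment subsets pair each non-control group's samples with the control
#' samples, so NormFinder retains a two-group structure within a subset; if
#' `control_group` is absent a subset holds a single group and NormFinder
#' falls back to its variance ranking.
#'
#' @param ct Replicate-level Ct records (data.frame) or an aggregated
#'   `ct_matrix`.
#' @param expression Optional expression matrix for candidate screening.
#' @param efficiencies Optional named per-gene amplification efficiencies.
#' @param cv_max CV cut-off for screening (default 0.3).
#' @param v_threshold Pairwise-variation threshold (default 0.15).
#' @param control_group Group label holding the control/untreated samples;
#'   default `"control"` when present among the group labels, else none.
#' @param aggregation Consensus rule, `"geometric"` or `"arithmetic"`.
#' @param n_refs Number of top consensus genes used as references for
#'   validation (default 3; at least three references are the conventional
#'   recommendation for reliable normalization).
#' @param targets Optional character vector of target gene ids to validate by
#'   [ddct_fold_change()] in each treatment subset.
#' @return A `refstab_report`: list with `mining` (or NULL), `subsets` (one
#'   entry per subset with `genorm`, `v_series`, `normfinder`, `bestkeeper`,
#'   `consensus`), and `validation` (or NULL).
#' @export
run_full_analysis <- function(ct, expression = NULL, efficiencies = NULL,
                              cv_max = 0.3, v_threshold = 0.15,
                              control_group = NULL, aggregation = "geometric",
                              n_refs = 3, targets = NULL) {
  if (is.data.frame(ct)) ct <- aggregate_replicates(ct)
  if (!inherits(ct, "ct_matrix")) stop("ct must be Ct records or a ct_matrix")

  mining <- NULL
  if (!is.null(expression)) {
    st <- expression_stats(expression)
    mining <- list(stats = st, candidates = filter_candidates(st, cv_max))
  }

  groups <- ct$groups
  glev <- unique(groups)
  if (is.null(control_group) && "control" %in% glev) control_group <- "control"
  treatment_levels <- setdiff(glev, control_group)
  subset_samples <- c(
    list(all = colnames(ct$ct)),
    stats::setNames(lapply(treatment_levels, function(g) {
      names(groups)[groups %in% c(control_group, g)]
    }), treatment_levels)
  )

  analyse_subset <- function(samp) {
    sub_ct <- ct_matrix(ct$ct[, samp, drop = FALSE], groups = groups[samp],
                        n_reps = ct$n_reps[, samp, drop = FALSE])
    q <- relative_quantities(sub_ct, efficiencies)
    gn <- genorm_rank(q)
    vs <- pairwise_variation_series(q, gn, threshold = v_threshold)
    sub_groups <- groups[samp]
    nf <- if (length(unique(sub_groups)) >= 2 && all(table(sub_groups) >= 2)) {
      normfinder_stability(log_quantities(q), sub_groups)
    } else {
      one <- stats::setNames(rep("all", length(samp)), samp)
      normfinder_stability(log_quantities(q), one)
    }
    bk <- bestkeeper_stats(sub_ct)
    cons <- aggregate_ranks(list(geNorm = method_ranks(gn),
                                 NormFinder = method_ranks(nf),
                                 BestKeeper = method_ranks(bk)),
                            method = aggregation)
    list(samples = samp, genorm = gn, v_series = vs, normfinder = nf,
         bestkeeper = bk, consensus = cons)
  }
  subsets <- lapply(subset_samples, analyse_subset)

  validation <- NULL
  if (!is.null(targets) && !is.null(control_group)) {
    control_samples <- names(groups)[groups == control_group]
    rows <- list()
    for (tg in targets) {
      for (g in treatment_levels) {
        cons <- subsets[[g]]$consensus
        refs <- utils::head(setdiff(cons$gene, tg), n_refs)
        fc <- ddct_fold_change(ct, tg, refs, control_samples,
                               names(groups)[groups == g])
        fc$group <- g
        fc$refs <- paste(refs, collapse = ",")
        rows[[length(rows) + 1]] <- fc
      }
    }
    validation <- do.call(rbind, rows)
  }

  structure(list(mining = mining, subsets = subsets, validation = validation,
                 control_group = control_group, aggregation = aggregation),
            class = "refstab_report")
}

#' @export
print.refstab_report <- function(x, ...) {
  cat("reference-gene stability report:", length(x$subsets), "subset(s):",
      paste(names(x$subsets), collapse = ", "), "\n")
  for (nm in names(x$subsets)) {
    cons <- x$subsets[[nm]]$consensus
    cat("  ", nm, ": top genes ", paste(utils::head(cons$gene, 3), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a full report bundle to a directory
#'
#' Emits one TSV per method per subset, the consensus and pairwise-variation
#' tables, optional mining and validation tables, and a small JSON manifest
#' (package version, aggregation rule, file list) for provenance.
#'
#' @param report A `refstab_report` from [run_full_analysis()].
#' @param dir Output directory (created if absent).
#' @param seed Optional integer recorded in the manifest for simulated inputs.
#' @return The manifest path, invisibly.
#' @export
write_report_bundle <- function(report, dir, seed = NULL) {
  stopifnot(inherits(report, "refstab_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    write_report(obj, p)
    files <<- c(files, basename(p))
  }
  if (!is.null(report$mining)) emit(report$mining$stats, "mining")
  for (nm in names(report$subsets)) {
    s <- report$subsets[[nm]]
    emit(s$genorm, paste0(nm, "_genorm"))
    emit(s$v_series, paste0(nm, "_pairwise_variation"))
    emit(s$normfinder, paste0(nm, "_normfinder"))
    emit(s$bestkeeper, paste0(nm, "_bestkeeper"))
    emit(s$consensus, paste0(nm, "_consensus"))
  }
  if (!is.null(report$validation)) emit(report$validation, "validation")
  manifest <- list(package = "refstab",
                   version = as.character(utils::packageVersion("refstab")),
                   aggregation = report$aggregation,
                   control_group = report$control_group,
                   seed = seed, files = sort(files))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(mp)
}
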
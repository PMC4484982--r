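# delimiter from file extension, overridable
guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",", "\t")
}

#' Read a gene-by-condition expression matrix
#'
#' Reads a delimited file whose first column holds gene identifiers and whose
#' remaining columns hold non-negative expression values (FPKM or any similar
#' abundance estimate), one column per condition. The delimiter is inferred
#' from the extension (`.tsv` tab, `.csv` comma) unless `sep` is given.
#'
#' @param path Path to the file. A header row is mandatory.
#' @param sep Field delimiter; `NULL` (default) infers it from the extension.
#' @return A numeric matrix with genes as row names and conditions as column
#'   names, in file order.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path, sep),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("expression matrix needs a gene column plus at least one condition column")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  validate_expression_matrix(m)
  m
}

#' Validate an expression matrix
#'
#' Checks the invariants every downstream screen assumes: numeric,
#' non-negative, finite values; unique gene and condition identifiers; and at
#' least two conditions (a coefficient of variation is undefined otherwise).
#'
#' @param m Numeric matrix, genes in rows, conditions in columns.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m))) stop("expression matrix must have gene row names")
  if (ncol(m) < 2) stop("at least 2 conditions are required (CV undefined otherwise)")
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene ids: ", paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
    stop("duplicate condition ids: ", paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(m)[bad[1, 1]]
    cond <- if (is.null(colnames(m))) bad[1, 2] else colnames(m)[bad[1, 2]]
    stop("negative or non-finite expression value for gene ", g, ", condition ", cond)
  }
  invisible(m)
}

ct_required_cols <- c("sample_id", "group_label", "gene_id", "bio_rep", "tech_rep", "ct")

#' Read a long-format Ct table
#'
#' Reads replicate-level qRT-PCR cycle-threshold records. The file must have a
#' header naming the columns `sample_id`, `group_label`, `gene_id`, `bio_rep`,
#' `tech_rep` and `ct` (any column order; extra columns are ignored).
#'
#' @inheritParams read_expression_matrix
#' @return A `data.frame` of validated Ct records (see [validate_ct_table()]).
#' @export
read_ct_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path, sep),
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "")
  missing_cols <- setdiff(ct_required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("Ct table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    out <- data.frame(sample_id = character(), group_label = character(),
                      gene_id = character(), bio_rep = integer(),
                      tech_rep = integer(), ct = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  num <- suppressWarnings(as.numeric(df$ct))
  if (anyNA(num)) {
    # +1 for the header row so the message points at the file line
    stop("non-numeric ct value at line ", which(is.na(num))[1] + 1L, " of ", path)
  }
  out <- data.frame(sample_id = df$sample_id, group_label = df$group_label,
                    gene_id = df$gene_id,
                    bio_rep = as.integer(df$bio_rep),
                    tech_rep = as.integer(df$tech_rep),
                    ct = num, stringsAsFactors = FALSE)
  validate_ct_table(out)
}

#' Validate a table of Ct records
#'
#' Enforces the record invariants: finite positive Ct (values outside the
#' plausible (5, 40) cycle window only warn), replicate indices >= 1, a unique
#' (sample, gene, bio_rep, tech_rep) key, and one group label per sample.
#'
#' @param records A `data.frame` with the long-format Ct columns.
#' @return The validated `data.frame`.
#' @export
validate_ct_table <- function(records) {
  missing_cols <- setdiff(ct_required_cols, names(records))
  if (length(missing_cols) > 0) {
    stop("Ct table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) return(records)
  if (any(!is.finite(records$ct) | records$ct <= 0)) {
    stop("ct values must be finite and > 0 (first bad row: ",
         which(!is.finite(records$ct) | records$ct <= 0)[1], ")")
  }
  if (any(records$ct <= 5 | records$ct >= 40)) {
    warning("ct values outside the usual (5, 40) cycle range; check the instrument export")
  }
  if (any(records$bio_rep < 1) || any(records$tech_rep < 1)) {
    stop("replicate indices must be >= 1")
  }
  key <- paste(records$sample_id, records$gene_id, records$bio_rep, records$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate replicate key: sample ", d$sample_id, ", gene ", d$gene_id,
         ", bio_rep ", d$bio_rep, ", tech_rep ", d$tech_rep)
  }
  grp <- unique(records[, c("sample_id", "group_label")])
  if (anyDuplicated(grp$sample_id)) {
    stop("sample(s) mapped to more than one group: ",
         paste(unique(grp$sample_id[duplicated(grp$sample_id)]), collapse = ", "))
  }
  records
}

#' Aggregate replicate Ct records into a gene-by-sample matrix
#'
#' Collapses technical and biological replicates to one mean Ct per
#' (gene, sample) cell. The default is a two-stage mean: technical replicates
#' are averaged within each biological replicate, then the biological-replicate
#' means are averaged. For balanced designs (equal technical counts per
#' biological replicate) this equals the pooled mean over all replicates,
#' available via `method = "pooled"`.
#'
#' @param records Validated Ct records (see [read_ct_table()]).
#' @param method `"two_stage"` (default) or `"pooled"`.
#' @return A `ct_matrix` object: a list with `ct` (numeric gene x sample mean-Ct
#'   matrix), `n_reps` (replicate counts per cell) and `groups` (named character
#'   vector mapping sample id to experimental group).
#' @export
aggregate_replicates <- function(records, method = c("two_stage", "pooled")) {
  method <- match.arg(method)
  records <- validate_ct_table(records)
  if (nrow(records) == 0) stop("no Ct records to aggregate")
  genes <- unique(records$gene_id)
  samples <- unique(records$sample_id)
  # completeness: stability analyses need every (gene, sample) cell
  have <- unique(paste(records$gene_id, records$sample_id, sep = "\r"))
  want <- as.vector(outer(genes, samples, paste, sep = "\r"))
  miss <- setdiff(want, have)
  if (length(miss) > 0) {
    pairs <- do.call(rbind, strsplit(miss, "\r", fixed = TRUE))
    stop("missing (gene, sample) cells: ",
         paste(utils::head(paste0(pairs[, 1], "/", pairs[, 2]), 10), collapse = ", "),
         if (length(miss) > 10) " ..." else "")
  }
  gf <- factor(records$gene_id, levels = genes)
  sf <- factor(records$sample_id, levels = samples)
  if (method == "two_stage") {
    bio_means <- stats::aggregate(ct ~ gene_id + sample_id + bio_rep, data = records, FUN = mean)
    gf2 <- factor(bio_means$gene_id, levels = genes)
    sf2 <- factor(bio_means$sample_id, levels = samples)
    ct <- tapply(bio_means$ct, list(gf2, sf2), mean)
  } else {
    ct <- tapply(records$ct, list(gf, sf), mean)
  }
  n_reps <- tapply(records$ct, list(gf, sf), length)
  grp_map <- unique(records[, c("sample_id", "group_label")])
  groups <- stats::setNames(grp_map$group_label, grp_map$sample_id)[samples]
  structure(list(ct = ct, n_reps = n_reps, groups = groups), class = "ct_matrix")
}

#' Construct a ct_matrix from a mean-Ct matrix
#'
#' Wraps an already-aggregated gene x sample matrix of mean Ct values, e.g.
#' instrument software output, into the container the stability methods take.
#'
#' @param ct Numeric matrix, genes in rows, samples in columns.
#' @param groups Named character vector mapping each sample id to its group;
#'   default puts every sample in one group `"all"`.
#' @param n_reps Optional replicate-count matrix; defaults to 1 per cell.
#' @return A `ct_matrix` object.
#' @export
ct_matrix <- function(ct, groups = NULL, n_reps = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct)) stop("ct must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct))) stop("ct needs gene row names and sample column names")
  if (any(!is.finite(ct))) stop("mean Ct matrix must be complete and finite")
  if (is.null(groups)) groups <- stats::setNames(rep("all", ncol(ct)), colnames(ct))
  if (!all(colnames(ct) %in% names(groups))) stop("groups must cover every sample")
  if (is.null(n_reps)) {
    n_reps <- matrix(1L, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  }
  structure(list(ct = ct, n_reps = n_reps, groups = groups[colnames(ct)]),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("ct_matrix: ", nrow(x$ct), " genes x ", ncol(x$ct), " samples (",
      length(unique(x$groups)), " groups)\n", sep = "")
  cat("mean Ct range: ", round(min(x$ct), 2), "-", round(max(x$ct), 2), " cycles\n", sep = "")
  invisible(x)
}

#' Per-gene amplification efficiencies
#'
#' Builds a complete named vector of per-gene amplification efficiencies E
#' (the per-cycle amplification base; 2 means perfect doubling). Genes absent
#' from `e` default to 2. Values must lie in (1, 2.2]; values outside the
#' usual [1.8, 2.1] assay range warn.
#'
#' @param genes Character vector of gene ids the table must cover.
#' @param e Optional named numeric vector of efficiencies for a subset of genes.
#' @return Named numeric vector of efficiencies, one per gene.
#' @export
efficiency_table <- function(genes, e = NULL) {
  out <- stats::setNames(rep(2, length(genes)), genes)
  if (!is.null(e)) {
    if (is.null(names(e))) stop("efficiencies must be a named vector")
    unknown <- setdiff(names(e), genes)
    if (length(unknown) > 0) warning("efficiencies for unknown genes ignored: ",
                                     paste(unknown, collapse = ", "))
    keep <- intersect(names(e), genes)
    out[keep] <- e[keep]
  }
  if (any(out <= 1 | out > 2.2)) {
    stop("amplification efficiency must satisfy 1 < E <= 2.2 (gene ",
         names(out)[which(out <= 1 | out > 2.2)[1]], ")")
  }
  if (any(out < 1.8 | out > 2.1)) {
    warning("efficiency outside the usual [1.8, 2.1] range for: ",
            paste(names(out)[out < 1.8 | out > 2.1], collapse = ", "))
  }
  out
}

#' Read a two-column gene/efficiency table
#'
#' @inheritParams read_expression_matrix
#' @return Named numeric vector of amplification efficiencies.
#' @export
read_efficiency_table <- function(path, sep = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path, sep),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("efficiency table needs gene and efficiency columns")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write a stage result to TSV or JSON
#'
#' Writes any tabular stage output with a deterministic column order and fixed
#' float precision (3 decimals by default, the precision qPCR tables are
#' conventionally reported at). Result objects that are lists with a canonical
#' table (geNorm, NormFinder, pairwise-variation results) are flattened to
#' that table first.
#'
#' @param x A `data.frame` or a result object with an `as.data.frame` method.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`; default inferred from the extension.
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = NULL, digits = 3) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  if (format == "tsv") {
    out <- df
    out[num] <- lapply(out[num], function(v) formatC(v, digits = digits, format = "f"))
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write report to ", path)
  } else {
    out <- df
    out[num] <- lapply(out[num], function(v) round(v, digits))
    ok <- tryCatch({
      jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write report to ", path)
  }
  invisible(path)
}

#' Path to a bundled example data file
#'
#' @param file File name under the package's `extdata` directory; `NULL` lists
#'   the available files.
#' @return A file path, or a character vector of file names.
#' @export
refstab_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "refstab"))
  } else {
    system.file("extdata", file, package = "refstab", mustWork = TRUE)
  }
}
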
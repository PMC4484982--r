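#' Describe one simulated gene
#'
#' A gene is simulated on the Ct (cycle) scale as
#' `baseline + group_effect + bio + tech`, with Gaussian biological and
#' technical noise. Baseline Ct encodes abundance (qPCR assays typically span
#' roughly 16-30 cycles); group effects are systematic Ct shifts under a
#' treatment — the instability the ranking methods must detect.
#'
#' @param gene_id Gene identifier.
#' @param baseline_ct Baseline mean Ct in cycles (> 0).
#' @param group_effects Named numeric vector of per-group Ct shifts (cycles);
#'   groups not listed get 0.
#' @param sigma_bio,sigma_tech Standard deviations (cycles, >= 0) of the
#'   biological-replicate and technical-replicate noise.
#' @param efficiency Amplification efficiency, default 2.
#' @return A `gene_profile` list.
#' @export
gene_profile <- function(gene_id, baseline_ct, group_effects = NULL,
                         sigma_bio = 0, sigma_tech = 0, efficiency = 2) {
  if (!is.character(gene_id) || length(gene_id) != 1) stop("gene_id must be a single string")
  if (!is.finite(baseline_ct) || baseline_ct <= 0) stop("baseline_ct must be > 0")
  if (sigma_bio < 0 || sigma_tech < 0) stop("noise standard deviations must be >= 0")
  if (!is.null(group_effects) && is.null(names(group_effects))) {
    stop("group_effects must be a named vector")
  }
  structure(list(gene_id = gene_id, baseline_ct = baseline_ct,
                 group_effects = group_effects %||% stats::setNames(numeric(0), character(0)),
                 sigma_bio = sigma_bio, sigma_tech = sigma_tech,
                 efficiency = efficiency),
            class = "gene_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a simulation configuration
#'
#' @param profiles List of [gene_profile()] objects with unique gene ids.
#' @param samples A `data.frame` with columns `sample_id` and `group_label`,
#'   one row per sample.
#' @param n_bio,n_tech Biological and technical replicates per sample (>= 1).
#' @param seed Integer seed; mandatory — the simulator has no implicit
#'   randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(profiles, samples, n_bio = 3, n_tech = 3, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_bio < 1 || n_tech < 1) stop("replicate counts must be >= 1")
  ids <- vapply(profiles, function(p) p$gene_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene ids in profiles")
  if (!all(c("sample_id", "group_label") %in% names(samples))) {
    stop("samples needs sample_id and group_label columns")
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  structure(list(profiles = profiles, samples = samples,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic 31-bit hash of a gene id, used to derive per-gene substreams:
# draws for one gene do not depend on which other genes are present
gene_substream_seed <- function(seed, gene_id) {
  h <- 0
  for (ch in utf8ToInt(gene_id)) h <- (h * 131 + ch) %% 2147483629
  as.integer((seed %% 2147483629 + h) %% 2147483629)
}

# run expr under a private seed, leaving the caller's RNG state untouched
with_substream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a replicate-level Ct table
#'
#' Draws `Ct[g, s, b, t] = baseline_g + effect_g[group(s)] + B_gsb + e_gsbt`
#' with `B ~ N(0, sigma_bio^2)` shared by a biological replicate's technical
#' wells and `e ~ N(0, sigma_tech^2)` per well — additive Gaussian noise on
#' the cycle scale, the standard qPCR error model. Each gene draws from its
#' own deterministic substream of the root seed.
#'
#' @param config A [sim_config()].
#' @return A long-format `data.frame` of Ct records (see [read_ct_table()]
#'   for the column contract).
#' @export
simulate_ct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- config$samples
  n_s <- nrow(samples)
  rows <- vector("list", length(config$profiles))
  for (i in seq_along(config$profiles)) {
    p <- config$profiles[[i]]
    eff <- ifelse(samples$group_label %in% names(p$group_effects),
                  p$group_effects[samples$group_label], 0)
    mu <- p$baseline_ct + eff
    draws <- with_substream(gene_substream_seed(config$seed, p$gene_id), {
      list(b = matrix(stats::rnorm(n_s * config$n_bio, 0, p$sigma_bio),
                      n_s, config$n_bio),
           e = array(stats::rnorm(n_s * config$n_bio * config$n_tech, 0, p$sigma_tech),
                     c(n_s, config$n_bio, config$n_tech)))
    })
    b <- draws$b
    e <- draws$e
    grid <- expand.grid(tech_rep = seq_len(config$n_tech),
                        bio_rep = seq_len(config$n_bio),
                        s = seq_len(n_s))
    ct <- mu[grid$s] + b[cbind(grid$s, grid$bio_rep)] +
      e[cbind(grid$s, grid$bio_rep, grid$tech_rep)]
    rows[[i]] <- data.frame(sample_id = samples$sample_id[grid$s],
                            group_label = samples$group_label[grid$s],
                            gene_id = p$gene_id,
                            bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
                            ct = ct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_ct_table(out)
}

#' Multi-stress qRT-PCR study preset
#'
#' Builds a [sim_config()] mirroring a typical abiotic-stress reference-gene
#' study: a control plus three stress treatments (drought, cold, salt) sampled
#' over a 0/3/6/12 h time course, with every 0 h sample untreated (grouped as
#' control), 3 biological x 3 technical replicates, and 12 genes whose
#' baseline Ct values span 16-30 cycles. Three genes (`REF1`-`REF3`) are
#' simulated as ideal references — no group effects and ~0.1 cycles of total
#' replicate noise — while nine stress-responsive genes (`RSP1`-`RSP9`) carry
#' fixed per-treatment Ct shifts with magnitudes from 0.5 to 2.5 cycles in
#' gene-specific directions, plus larger replicate noise.
#'
#' @param seed Integer seed.
#' @param n_bio,n_tech Replicate counts, default 3 each.
#' @return A `sim_config` with 12 genes and 13 samples.
#' @export
stress_preset <- function(seed, n_bio = 3, n_tech = 3) {
  treatments <- c("drought", "cold", "salt")
  samples <- data.frame(
    sample_id = c("CK_0h",
                  paste0(rep(treatments, each = 4), "_",
                         rep(c(0, 3, 6, 12), times = 3), "h")),
    stringsAsFactors = FALSE
  )
  # all time-zero samples are untreated, hence grouped as control
  samples$group_label <- ifelse(grepl("_0h$", samples$sample_id), "control",
                                sub("_.*$", "", samples$sample_id))
  stable <- lapply(1:3, function(i) {
    gene_profile(paste0("REF", i), baseline_ct = c(18, 22, 26)[i],
                 sigma_bio = 0.08, sigma_tech = 0.06)
  })
  # distinct effect directions so no two responsive genes are co-regulated
  patterns <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                    c(1, -1, 0), c(0, 1, -1), c(-1, 0, 1),
                    c(1, 1, -1), c(-1, 1, 1), c(1, -1, 1))
  mags <- seq(0.5, 2.5, length.out = 9)
  baselines <- seq(16, 30, length.out = 9)
  responsive <- lapply(1:9, function(i) {
    gene_profile(paste0("RSP", i), baseline_ct = baselines[i],
                 group_effects = stats::setNames(mags[i] * patterns[i, ], treatments),
                 sigma_bio = 0.25, sigma_tech = 0.15)
  })
  sim_config(c(stable, responsive), samples, n_bio = n_bio, n_tech = n_tech,
             seed = seed)
}

#' Simulate an expression matrix with target coefficients of variation
#'
#' Draws each gene's row from a log-normal distribution parameterized to hit
#' a requested mean and coefficient of variation exactly in expectation
#' (`sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2 / 2`). A target
#' CV of 0 yields a constant row at the mean.
#'
#' @param means Named numeric vector of per-gene target means (> 0).
#' @param cvs Named numeric vector of per-gene target CVs (>= 0), same genes.
#' @param n_conditions Number of condition columns.
#' @param seed Integer seed.
#' @return Numeric gene x condition matrix.
#' @export
simulate_expression <- function(means, cvs, n_conditions, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (is.null(names(means)) || !setequal(names(means), names(cvs))) {
    stop("means and cvs must be named vectors over the same genes")
  }
  if (any(means <= 0)) stop("target means must be > 0")
  if (any(cvs < 0)) stop("target CVs must be >= 0")
  if (any(!is.finite(log1p(cvs ^ 2)))) stop("target CV implies non-finite log-variance")
  genes <- names(means)
  m <- matrix(NA_real_, length(genes), n_conditions,
              dimnames = list(genes, paste0("cond", seq_len(n_conditions))))
  for (g in genes) {
    if (cvs[[g]] == 0) {
      m[g, ] <- means[[g]]
    } else {
      sdlog2 <- log1p(cvs[[g]] ^ 2)
      m[g, ] <- with_substream(gene_substream_seed(seed, g), {
        stats::rlnorm(n_conditions, meanlog = log(means[[g]]) - sdlog2 / 2,
                      sdlog = sqrt(sdlog2))
      })
    }
  }
  validate_expression_matrix(m)
  m
}
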
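two_group_labels <- function(n_per = 4) {
  stats::setNames(rep(c("ctrl", "trt"), each = n_per),
                  paste0("s", seq_len(2 * n_per)))
}

test_that("log quantities invert the 2^-dCt transform", {
  q <- rbind(a = c(1, 0.5, 0.25))
  expect_equal(unname(log_quantities(q)[1, ]), c(0, -1, -2))
  ones <- rbind(a = c(1, 1, 1))
  expect_equal(unname(log_quantities(ones)[1, ]), c(0, 0, 0))
  qq <- random_q(4, 5, seed = 3)
  expect_equal(2 ^ log_quantities(qq), qq, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(log_quantities(rbind(a = c(1, 0))), "positive")
})

test_that("noise-free data yields zero stability for every gene", {
  # constant centered values within and across groups: no variance, no deviation
  m <- rbind(g1 = rep(20, 8), g2 = rep(24, 8), g3 = rep(28, 8))
  colnames(m) <- paste0("s", 1:8)
  nf <- normfinder_stability(log_quantities(relative_quantities(make_ct(m))),
                             two_group_labels())
  expect_equal(unname(nf$stability), c(0, 0, 0))
  expect_equal(unname(nf$intragroup_var), matrix(0, 3, 2), ignore_attr = TRUE)
})

test_that("a gene with a group offset is less stable than a quiet gene", {
  for (seed in 1:10) {
    set.seed(seed)
    groups <- two_group_labels(5)
    n <- length(groups)
    m <- rbind(A = 22 + stats::rnorm(n, 0, 0.1),
               B = 24 + ifelse(seq_len(n) > 5, 2, 0) + stats::rnorm(n, 0, 0.1),
               C = 26 + stats::rnorm(n, 0, 0.4),
               D = 20 + stats::rnorm(n, 0, 0.6))
    colnames(m) <- names(groups)
    nf <- normfinder_stability(log_quantities(relative_quantities(make_ct(m))), groups)
    expect_lt(nf$stability[["A"]], nf$stability[["B"]])
  }
})

test_that("the vectorized model matches the explicit-loop oracle", {
  for (seed in 1:20) {
    q <- random_q(4, 6, seed = 100 + seed)
    groups <- stats::setNames(rep(c("g1", "g2"), each = 3), colnames(q))
    lq <- log_quantities(q)
    got <- normfinder_stability(lq, groups)
    want <- oracle_normfinder(lq, groups[colnames(lq)])
    expect_equal(got$stability, want$stability, tolerance = 1e-10)
    expect_equal(got$intragroup_var, want$sigma2, tolerance = 1e-10)
  }
})

test_that("stability is invariant to per-gene offsets and per-sample shifts", {
  set.seed(55)
  m <- matrix(stats::runif(40, 18, 30), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  groups <- two_group_labels()
  lq <- log_quantities(relative_quantities(make_ct(m)))
  base <- normfinder_stability(lq, groups)

  # per-gene constant offset on the log scale: a 44-fold abundance gap
  # between genes must not move the ranking
  shifted_gene <- normfinder_stability(lq + stats::runif(5, -6, 6), groups)
  expect_equal(shifted_gene$stability, base$stability, tolerance = 1e-10)

  # per-sample global shift (loading differences) is absorbed by centering
  shifted_sample <- normfinder_stability(sweep(lq, 2, stats::runif(8, -2, 2), `+`), groups)
  expect_equal(shifted_sample$stability, base$stability, tolerance = 1e-10)
})

test_that("more injected noise means a worse (higher) stability value on average", {
  mean_stab <- function(sigma) {
    vals <- vapply(1:15, function(seed) {
      set.seed(seed)
      groups <- two_group_labels()
      m <- rbind(A = 22 + stats::rnorm(8, 0, sigma),
                 B = 24 + stats::rnorm(8, 0, 0.2),
                 C = 26 + stats::rnorm(8, 0, 0.2),
                 D = 28 + stats::rnorm(8, 0, 0.2))
      colnames(m) <- names(groups)
      nf <- normfinder_stability(log_quantities(relative_quantities(make_ct(m))), groups)
      nf$stability[["A"]]
    }, numeric(1))
    mean(vals)
  }
  expect_lt(mean_stab(0.1), mean_stab(0.8))
  expect_lt(mean_stab(0.8), mean_stab(2.0))
})

test_that("degenerate inputs are rejected and one group falls back to variance", {
  q <- random_q(4, 6, seed = 1)
  lq <- log_quantities(q)
  bad <- stats::setNames(c("a", "a", "a", "a", "a", "b"), colnames(q))
  expect_error(normfinder_stability(lq, bad), "at least 2 samples")
  expect_error(normfinder_stability(lq[1:2, ], two_group_labels(3)), "at least 3 genes")

  one <- stats::setNames(rep("all", 6), colnames(q))
  nf <- normfinder_stability(lq, one)
  want <- oracle_normfinder(lq, one[colnames(lq)])
  expect_equal(nf$stability, want$stability, tolerance = 1e-10)
})
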
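test_that("rank aggregation reproduces hand-computed scores and symmetry", {
  r <- list(bk = c(A = 4, B = 1, C = 2, D = 3),
            nf = c(A = 1, B = 2, C = 3, D = 4),
            gn = c(A = 3, B = 1.5, C = 1.5, D = 4))
  cons <- aggregate_ranks(r)
  expect_equal(cons$score[cons$gene == "A"], 12 ^ (1 / 3), tolerance = 1e-10)
  expect_equal(cons$gene[1], "B")  # best under every aggregation view

  perm <- aggregate_ranks(r[c(3, 1, 2)])
  expect_equal(cons$score[order(cons$gene)], perm$score[order(perm$gene)],
               tolerance = 1e-12)

  ari <- aggregate_ranks(r, method = "arithmetic")
  expect_equal(ari$score[ari$gene == "A"], mean(c(4, 1, 3)))

  unanimous <- list(a = c(X = 1, Y = 2, Z = 3), b = c(X = 1, Y = 3, Z = 2),
                    c = c(X = 1, Y = 2, Z = 3))
  expect_equal(aggregate_ranks(unanimous)$gene[1], "X")
  expect_equal(aggregate_ranks(unanimous, method = "arithmetic")$gene[1], "X")

  expect_error(aggregate_ranks(list(c(A = 1, B = 2), c(A = 1, C = 2))),
               "symmetric difference")
})

test_that("method_ranks exposes each algorithm's ranking, with geNorm's tied pair", {
  # group-structured data so every method separates the genes
  set.seed(13)
  groups <- stats::setNames(rep(c("a", "b"), each = 4), paste0("s", 1:8))
  m <- rbind(g1 = 20 + stats::rnorm(8, 0, 0.1),
             g2 = 22 + stats::rnorm(8, 0, 0.2),
             g3 = 24 + c(rep(0, 4), rep(1, 4)) + stats::rnorm(8, 0, 0.2),
             g4 = 26 + c(rep(0, 4), rep(2, 4)) + stats::rnorm(8, 0, 0.3),
             g5 = 28 + c(rep(0, 4), rep(3, 4)) + stats::rnorm(8, 0, 0.5))
  colnames(m) <- names(groups)
  ct <- make_ct(m, groups = groups)
  q <- relative_quantities(ct)
  gn <- method_ranks(genorm_rank(q))
  expect_equal(sort(unname(gn)), c(1.5, 1.5, 3, 4, 5))
  nf <- method_ranks(normfinder_stability(log_quantities(q), groups))
  expect_setequal(unname(nf), 1:5)
  bk <- method_ranks(bestkeeper_stats(ct))
  expect_setequal(unname(bk), 1:5)
  expect_error(method_ranks(list()), "cannot extract")
})

test_that("the full analysis produces the declared report shape deterministically", {
  rec <- simulate_ct(stress_preset(seed = 21))
  rep1 <- run_full_analysis(rec)
  expect_named(rep1$subsets, c("all", "drought", "cold", "salt"))
  for (s in rep1$subsets) {
    expect_equal(nrow(s$consensus), 12)
    expect_setequal(s$consensus$rank, 1:12)
    expect_equal(nrow(s$v_series$v), 10)
    expect_true(all(c("geNorm", "NormFinder", "BestKeeper") %in% names(s$consensus)))
  }

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report_bundle(rep1, d1, seed = 21)
  write_report_bundle(run_full_analysis(simulate_ct(stress_preset(seed = 21))), d2, seed = 21)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  man <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 21)
  expect_equal(length(man$files), 20)  # 4 subsets x 5 tables, no mining/validation
})

test_that("validation wires the top consensus genes into ddCt fold changes", {
  rec <- simulate_ct(stress_preset(seed = 33))
  rep <- run_full_analysis(rec, targets = "RSP9", n_refs = 3)
  v <- rep$validation
  expect_equal(nrow(v), 3)  # one fold change per treatment
  expect_setequal(v$group, c("drought", "cold", "salt"))
  for (i in seq_len(nrow(v))) {
    refs <- strsplit(v$refs[i], ",")[[1]]
    expect_length(refs, 3)
    expect_false("RSP9" %in% refs)
    cons <- rep$subsets[[v$group[i]]]$consensus
    expect_equal(refs, utils::head(setdiff(cons$gene, "RSP9"), 3))
  }
  # RSP9 carries a 2.5-cycle salt shift: the fold change must reflect it
  salt_fold <- v$fold[v$group == "salt"]
  expect_gt(abs(log2(salt_fold)), 1)
})

test_that("a gene screened and mined flows through when an expression matrix is given", {
  rec <- simulate_ct(stress_preset(seed = 8))
  rep <- run_full_analysis(rec, expression = fpkm_fixture())
  expect_equal(length(rep$mining$candidates), 12)
  expect_equal(nrow(rep$mining$stats), 12)
})
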
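test_that("expression matrix reader validates shape, sign and identifiers", {
  m <- fpkm_fixture()
  expect_equal(dim(m), c(12L, 4L))
  expect_equal(rownames(m)[1], "18S")
  expect_equal(unname(m["HIS", "CK_FPKM"]), 654.76)

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,a,b", "g1,1.0,1.0"), f)
  one <- read_expression_matrix(f)
  expect_equal(dim(one), c(1L, 2L))

  writeLines(c("gene,a,b", "g1,1.0,-5.0"), f)
  expect_error(read_expression_matrix(f), "negative")

  writeLines(c("gene,a,b", "g1,1,2", "g1,3,4"), f)
  expect_error(read_expression_matrix(f), "duplicate gene")

  expect_error(validate_expression_matrix(matrix(1:4, 2, 2,
    dimnames = list(c("a", "b"), NULL))[, 1, drop = FALSE] * 1.0), "2 conditions")
})

test_that("Ct table reader preserves rows and rejects malformed records", {
  rec <- simulate_ct(stress_preset(seed = 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ct_table(f)
  expect_equal(nrow(back), 12 * 13 * 9)
  expect_equal(back$ct, rec$ct, tolerance = 1e-12)

  writeLines("sample_id\tgroup_label\tgene_id\tbio_rep\ttech_rep\tct", f)
  expect_equal(nrow(read_ct_table(f)), 0L)

  writeLines(c("sample_id\tgroup_label\tgene_id\tbio_rep\ttech_rep\tct",
               "s1\tg\tA\t1\t1\t20", "s1\tg\tA\t1\t1\t21"), f)
  expect_error(read_ct_table(f), "duplicate replicate key")

  writeLines(c("sample_id\tgroup_label\tgene_id\tbio_rep\ttech_rep\tct",
               "s1\tg\tA\t1\t1\t20", "s1\tg\tA\t1\t2\toops"), f)
  expect_error(read_ct_table(f), "line 3")
})

test_that("Ct validation flags bad cycles and inconsistent grouping", {
  rec <- data.frame(sample_id = "s1", group_label = "g", gene_id = "A",
                    bio_rep = 1L, tech_rep = 1L, ct = -1)
  expect_error(validate_ct_table(rec), "finite and > 0")
  rec$ct <- 45
  expect_warning(validate_ct_table(rec), "cycle range")
  two <- data.frame(sample_id = c("s1", "s1"), group_label = c("g1", "g2"),
                    gene_id = c("A", "B"), bio_rep = 1L, tech_rep = 1L,
                    ct = c(20, 21))
  expect_error(validate_ct_table(two), "more than one group")
})

test_that("replicate aggregation is two-stage by default and pooled on request", {
  rec <- data.frame(
    sample_id = "s1", group_label = "g", gene_id = "A",
    bio_rep = c(1L, 1L, 2L), tech_rep = c(1L, 2L, 1L),
    ct = c(20, 22, 25))
  expect_equal(unname(aggregate_replicates(rec)$ct["A", "s1"]), 23)
  expect_equal(unname(aggregate_replicates(rec, method = "pooled")$ct["A", "s1"]),
               mean(c(20, 22, 25)))

  const <- data.frame(sample_id = "s1", group_label = "g", gene_id = "A",
                      bio_rep = 1L, tech_rep = 1:3, ct = c(20, 20, 20))
  expect_equal(unname(aggregate_replicates(const)$ct["A", "s1"]), 20)
})

test_that("aggregation is permutation-invariant and matches pooled on balanced designs", {
  rec <- simulate_ct(stress_preset(seed = 3))
  agg <- aggregate_replicates(rec)
  expect_equal(dim(agg$ct), c(12L, 13L))
  expect_true(all(agg$n_reps == 9))

  set.seed(42)
  shuffled <- rec[sample(nrow(rec)), ]
  agg2 <- aggregate_replicates(shuffled)
  expect_equal(agg$ct[rownames(agg$ct), colnames(agg$ct)],
               agg2$ct[rownames(agg$ct), colnames(agg$ct)], tolerance = 1e-12)

  pooled <- aggregate_replicates(rec, method = "pooled")
  expect_equal(agg$ct, pooled$ct, tolerance = 1e-12)
})

test_that("missing (gene, sample) cells are a hard completeness error", {
  rec <- simulate_ct(stress_preset(seed = 5))
  holed <- rec[!(rec$gene_id == "REF1" & rec$sample_id == "CK_0h"), ]
  expect_error(aggregate_replicates(holed), "REF1/CK_0h")
})

test_that("efficiency tables default to 2 and enforce bounds", {
  e <- efficiency_table(c("A", "B"), c(A = 1.9))
  expect_equal(unname(e), c(1.9, 2))
  expect_error(efficiency_table("A", c(A = 0.9)), "1 < E")
  expect_error(efficiency_table("A", c(A = 2.5)), "1 < E")
  expect_warning(efficiency_table("A", c(A = 1.5)), "1.8")
  eff <- read_efficiency_table(refstab_example("primer_efficiencies.tsv"))
  expect_length(eff, 12)
  expect_equal(unname(eff["HIS"]), 2.047)
})

test_that("reports round-trip with fixed precision in both formats", {
  q <- random_q(12, 8, seed = 7)
  gn <- genorm_rank(q)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(gn, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 12)
  expect_true(all(c("gene", "m", "rank") %in% names(tab)))
  expect_equal(tab$m, round(gn$ranking$m, 3), tolerance = 5e-4)

  vs <- pairwise_variation_series(q, gn)
  fv <- withr::local_tempfile(fileext = ".tsv")
  write_report(vs, fv)
  expect_equal(nrow(utils::read.table(fv, header = TRUE, sep = "\t")), 10)

  fj <- withr::local_tempfile(fileext = ".json")
  write_report(gn, fj, format = "json")
  back <- jsonlite::fromJSON(fj)
  expect_equal(back$m, gn$ranking$m, tolerance = 5e-4)
  expect_equal(back$gene, gn$ranking$gene)
})
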
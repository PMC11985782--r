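test_that("STAGE 1 keeps baits with non-zero counts differing by >= 10", {
  s1 <- stage1_filter(c("1" = 12, "2" = 5, "4" = 7),
                      c("1" = 1, "3" = 0, "4" = 17))
  expect_equal(s1$bait_ids, c("1", "4"))  # diffs 11 and 10; bait 2 diff 5
  s1b <- stage1_filter(c("1" = 5), c("2" = 0))
  expect_equal(s1b$bait_ids, character(0))  # diff 5 < 10
  # strict both-nonzero mode drops baits silent in one condition
  s1c <- stage1_filter(c("1" = 12, "2" = 30), c("1" = 1), nonzero = "both")
  expect_equal(s1c$bait_ids, "1")
})

test_that("stage filters equal brute-force scans and nest monotonically", {
  set.seed(41)
  for (rep in 1:20) {
    baits <- as.character(1:60)
    cc <- stats::setNames(stats::rpois(60, 8), baits)
    ct <- stats::setNames(stats::rpois(60, 8), baits)
    s1 <- stage1_filter(cc, ct)
    bf1 <- baits[pmax(cc, ct) > 0 & abs(cc - ct) >= 10]
    expect_equal(s1$bait_ids, sort(bf1))
    diffb <- sample(baits, 20)
    s2 <- stage2_filter(s1, diffb)
    expect_equal(s2$bait_ids, sort(intersect(bf1, diffb)))
    affb <- sample(baits, 15)
    s3 <- stage3_filter(s2, affb)
    expect_equal(s3$bait_ids, sort(intersect(intersect(bf1, diffb), affb)))
    expect_true(all(s3$bait_ids %in% s2$bait_ids))
    expect_true(all(s2$bait_ids %in% s1$bait_ids))
  }
})

test_that("stage 2 and 3 handle disjoint and superset inputs", {
  s1 <- stage1_filter(c("1" = 20, "2" = 15), c("1" = 0, "2" = 0))
  expect_equal(stage2_filter(s1, character(0))$bait_ids, character(0))
  expect_equal(stage2_filter(s1, as.character(1:99))$bait_ids, s1$bait_ids)
  s2 <- stage2_filter(s1, c("1", "2"))
  expect_equal(stage3_filter(s2, character(0))$bait_ids, character(0))
})

test_that("other-end annotation is multi-label with per-class counts", {
  x <- make_interactions(
    bait_id = 1:3, oe_id = 4:6, bait_chrom = "chr1", bait_start = 0,
    bait_end = 100, oe_chrom = "chr1",
    oe_start = c(1000, 2000, 3000), oe_end = c(1500, 2500, 3500),
    n_reads = 5, score = 6)
  ccres <- data.frame(chrom = "chr1",
                      start = c(1400, 2100, 2200, 9000),
                      end = c(1600, 2300, 2400, 9500),
                      ccre_class = c("dELS", "pELS", "CTCF", "PLS"),
                      stringsAsFactors = FALSE)
  ann <- annotate_other_ends(x, ccres)
  expect_equal(ann$labels[[1]], "dELS")
  expect_equal(ann$labels[[2]], c("CTCF", "pELS"))
  expect_equal(ann$labels[[3]], "none")
  expect_equal(unname(ann$class_counts[c("dELS", "pELS", "CTCF", "PLS", "none")]),
               c(1L, 1L, 1L, 0L, 1L))
})

test_that("annotation matches brute-force all-pairs overlap on random tracks", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 200
    oe_start <- sample.int(50000, n)
    x <- make_interactions(
      bait_id = seq_len(n), oe_id = n + seq_len(n),
      bait_chrom = "chr1", bait_start = 0, bait_end = 100,
      oe_chrom = sample(c("chr1", "chr2"), n, TRUE),
      oe_start = oe_start, oe_end = oe_start + sample.int(500, n),
      n_reads = 1, score = 6)
    cs <- sample.int(50000, 100)
    ccres <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                        start = cs, end = cs + sample.int(400, 100),
                        ccre_class = sample(c("PLS", "pELS", "dELS",
                                              "DNase-H3K4me3", "CTCF"),
                                            100, TRUE),
                        stringsAsFactors = FALSE)
    ann <- annotate_other_ends(x, ccres)
    expect_equal(ann$labels, bf_annotate(x, ccres))
  }
})

test_that("DE genes are kept iff they overlap a differential bait fragment", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), symbol = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(100, 5000, 100), end = c(900, 6000, 900),
                      strand = "+", biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  fm <- data.frame(frag_id = 1:2, chrom = c("chr1", "chr1"),
                   start = c(0, 1000), end = c(1000, 2000),
                   is_bait = TRUE, gene_ids = "", stringsAsFactors = FALSE)
  de <- annotate_de_table(data.frame(gene_id = c("g1", "g2", "g3"),
                                     log2fc = 1, fdr = c(0.01, 0.01, 0.01),
                                     stringsAsFactors = FALSE))
  kept <- overlap_de_with_differential_baits(de, genes, 1L, fm)
  expect_equal(kept$gene_id, "g1")  # g2 off the bait, g3 wrong chromosome
  de$fdr[1] <- 0.2
  de <- annotate_de_table(de)
  expect_equal(nrow(overlap_de_with_differential_baits(de, genes, 1L, fm)), 0L)
})

test_that("boundary-bait filtering applies the start-position rule", {
  fm <- data.frame(frag_id = 1:3, chrom = "chr1",
                   start = c(500, 1500, 2500), end = c(1500, 2500, 3500),
                   is_bait = TRUE, gene_ids = "", stringsAsFactors = FALSE)
  boundaries <- data.frame(chrom = "chr1", start = 1000, end = 2000)
  # frag 1 starts before the boundary (ends inside): dropped; frag 2
  # starts inside: kept; frag 3 starts after: dropped
  expect_equal(baits_at_tad_boundaries(fm, boundaries), 2L)
  set.seed(43)
  for (rep in 1:10) {
    starts <- sort(sample.int(10000, 50))
    fm2 <- data.frame(frag_id = 1:50, chrom = "chr1", start = starts,
                      end = starts + 10, is_bait = TRUE, gene_ids = "",
                      stringsAsFactors = FALSE)
    bs <- sort(sample.int(10000, 8))
    bd <- data.frame(chrom = "chr1", start = bs, end = bs + 100)
    bf <- fm2$frag_id[vapply(fm2$start, function(s)
      any(s >= bd$start & s < bd$end), TRUE)]
    expect_equal(baits_at_tad_boundaries(fm2, bd), bf)
  }
})

test_that("target selection demands the conjunction of all four criteria", {
  w <- simulate_world(simulation_config(seed = 5))
  res <- run_world_pipeline(w)
  tr <- w$truth
  expect_setequal(res$report$gene_id, tr$planted_target_gene_ids)
  expect_false(any(tr$decoy_gene_ids %in% res$report$gene_id))
  # every reported record satisfies the criteria conjunction
  expect_true(all(res$report$has_enhancer_loop))
  expect_true(all(res$report$in_disrupted_tad))
  expect_true(all(res$report$gene_id %in% res$affected))
  expect_true(all(res$report$log2fc > 0 & res$report$fdr <= 0.05))
  # ranking is by descending capture count
  expect_true(all(diff(res$report$capture_count) <= 0))
  # each decoy is attributed to exactly its violated criterion
  d <- attr(res$report, "diagnostics")
  viol <- stats::setNames(
    d$violated[match(tr$decoy_gene_ids, d$gene_id)], names(tr$decoy_gene_ids))
  expect_equal(unname(viol["no_loop"]), "enhancer_loop")
  expect_equal(unname(viol["conserved_tad"]), "disrupted_tad")
  expect_equal(unname(viol["not_upregulated"]), "upregulated")
  expect_equal(unname(viol["low_capture"]), "high_capture")
  # top_k truncation keeps the leading ranks
  res_top <- select_target_genes(res$stage3, res$annotations, res$affected,
                                 annotate_de_table(w$de_table),
                                 w$fragment_map, res$capture_counts$case,
                                 top_k = 2)
  expect_equal(res_top$gene_id, res$report$gene_id[1:2])
})

test_that("report writing produces a TSV and manifest that round-trip", {
  w <- simulate_world(simulation_config(seed = 6))
  res <- run_world_pipeline(w)
  dir <- withr::local_tempdir()
  input <- file.path(dir, "input.tsv")
  writeLines("x", input)
  path <- file.path(dir, "targets.tsv")
  manifest <- write_report(res$report,
                           list(STAGE1 = res$stage1, STAGE2 = res$stage2,
                                STAGE3 = res$stage3),
                           path, params = res$params, input_paths = input,
                           seed = 6)
  back <- read_target_report(path)
  expect_equal(back$gene_id, res$report$gene_id)
  expect_equal(back$capture_count, res$report$capture_count)
  expect_equal(back$log2fc, res$report$log2fc, tolerance = 1e-8)
  expect_equal(manifest$stage_counts$STAGE3$baits,
               length(res$stage3$bait_ids))
  # manifest digest changes iff the input file changes
  m1 <- jsonlite::read_json(file.path(dir, "targets.manifest.json"))
  writeLines("y", input)
  write_report(res$report, list(), path, input_paths = input)
  m2 <- jsonlite::read_json(file.path(dir, "targets.manifest.json"))
  expect_false(identical(m1$input_md5, m2$input_md5))
  # empty report still writes a header-only TSV
  write_report(res$report[0, ], list(), path)
  expect_equal(nrow(read_target_report(path)), 0L)
})
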
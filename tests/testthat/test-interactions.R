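random_interaction_table <- function(n, chroms = c("chr1", "chr2")) {
  bait_start <- sample.int(1e6, n)
  oe_start <- sample.int(1e6, n)
  make_interactions(
    bait_id = sample.int(500, n, replace = TRUE),
    oe_id = 500L + sample.int(500, n, replace = TRUE),
    bait_chrom = sample(chroms, n, TRUE), bait_start = bait_start,
    bait_end = bait_start + 5000, oe_chrom = sample(chroms, n, TRUE),
    oe_start = oe_start, oe_end = oe_start + 5000,
    n_reads = stats::rpois(n, 20), score = round(stats::rexp(n, 1 / 4), 4))
}

test_that("ibed tables round-trip through write and read", {
  set.seed(31)
  x <- random_interaction_table(200)
  tmp <- withr::local_tempfile(fileext = ".ibed")
  write_ibed(x, tmp)
  back <- read_interactions(tmp, "ibed")
  expect_equal(back, x, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("chinput tables resolve coordinates through the fragment map", {
  fm <- data.frame(frag_id = 1:4, chrom = "chr1",
                   start = c(0, 100, 200, 300), end = c(100, 200, 300, 400),
                   is_bait = c(TRUE, FALSE, FALSE, FALSE),
                   gene_ids = c("G1", "", "", ""), stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".chinput")
  writeLines(c("baitID\totherEndID\tN", "1\t3\t12"), tmp)
  x <- read_interactions(tmp, "chinput", fragment_map = fm)
  expect_equal(x$bait_start, 0)
  expect_equal(x$oe_start, 200)
  expect_true(is.na(x$score))  # scoreless rows filter only by count
  writeLines(c("baitID\totherEndID\tN", "1\t9\t12"), tmp)
  expect_error(read_interactions(tmp, "chinput", fragment_map = fm),
               "not in fragment map")
})

test_that("significance filter keeps score >= 5 at >= 10 kb, inclusive bounds", {
  x <- make_interactions(
    bait_id = 1:4, oe_id = 5:8, bait_chrom = "chr1", bait_start = 0,
    bait_end = 1000, oe_chrom = "chr1",
    oe_start = c(20000, 20000, 9000, 9500) - 500,
    oe_end = c(20000, 20000, 9000, 9500) + 500,
    n_reads = 10, score = c(5.0, 4.99, 6, 5))
  # midpoints: bait 500; oe 20000, 20000, 9000, 9500 -> distances 19500,
  # 19500, 8500, 9000
  kept <- filter_significant(x)
  expect_equal(kept$bait_id, 1L)
  # trans-chromosomal pairs pass the distance filter by definition
  x$oe_chrom[3] <- "chr2"
  kept <- filter_significant(x)
  expect_equal(kept$bait_id, c(1L, 3L))
  # idempotence
  expect_equal(filter_significant(kept), kept)
})

test_that("significance filter matches a brute-force scan on random tables", {
  set.seed(32)
  x <- random_interaction_table(10000)
  kept <- filter_significant(x)
  bf_keep <- vapply(seq_len(nrow(x)), function(i) {
    d <- if (x$bait_chrom[i] != x$oe_chrom[i]) NA else
      abs(floor((x$oe_start[i] + x$oe_end[i]) / 2) -
            floor((x$bait_start[i] + x$bait_end[i]) / 2))
    x$score[i] >= 5 && (is.na(d) || d >= 10000)
  }, TRUE)
  expect_equal(kept, x[bf_keep, ], ignore_attr = TRUE)
})

test_that("per-bait and per-chromosome tallies conserve the interaction total", {
  set.seed(33)
  x <- random_interaction_table(500)
  pb <- per_bait_counts(x)
  pc <- per_chromosome_counts(x)
  expect_equal(sum(pb), nrow(x))
  expect_equal(sum(pc), nrow(x))
  expect_equal(unname(pb[as.character(x$bait_id[1])]),
               sum(x$bait_id == x$bait_id[1]))
  expect_length(per_bait_counts(x[0, ]), 0L)
})

test_that("share_proportions rounds half away from zero and sums to 100 unrounded", {
  sp <- share_proportions(c(A = 10, B = 0))
  expect_equal(sp$percent, c(A = 100L, B = 0L))
  expect_equal(sum(sp$unrounded), 100)
  expect_error(share_proportions(c(A = 0, B = 0)), "zero")
  set.seed(34)
  for (rep in 1:10) {
    cnt <- stats::setNames(sample.int(1e6, 3), c("x", "y", "z"))
    sp <- share_proportions(cnt)
    expect_equal(sum(sp$unrounded), 100)
    expect_lte(abs(sum(sp$percent) - 100), 2)
  }
})

test_that("Venn regions partition the union for 1 to 3 bait sets", {
  expect_equal(shared_bait_sets(list(A = 1:3, B = 1:3)),
               c(A = 0L, B = 0L, "A&B" = 3L))
  expect_equal(shared_bait_sets(list(A = 1:2, B = 3:4)),
               c(A = 2L, B = 2L, "A&B" = 0L))
  expect_error(shared_bait_sets(list(A = 1, B = 1, C = 1, D = 1)),
               "1 to 3")
  set.seed(35)
  for (rep in 1:20) {
    sets <- list(A = sample.int(50, 20), B = sample.int(50, 25),
                 C = sample.int(50, 10))
    got <- shared_bait_sets(sets)
    expect_equal(got, bf_venn(lapply(sets, unique))[names(got)])
    expect_equal(sum(got), length(unique(unlist(sets))))
  }
})

test_that("differential scoring is null at equal counts and drops 0/0 pairs", {
  base <- make_interactions(
    bait_id = c(1L, 2L), oe_id = c(11L, 12L), bait_chrom = "chr1",
    bait_start = c(0, 50000), bait_end = c(5000, 55000),
    oe_chrom = "chr1", oe_start = c(100000, 150000),
    oe_end = c(105000, 155000), n_reads = c(40, 0), score = 6)
  d <- differential_score(base, base)
  expect_equal(nrow(d), 1L)  # the 0/0 pair is excluded
  expect_equal(d$log2_ratio, 0)
  expect_false(d$significant)
})

test_that("differential scoring is antisymmetric under condition swap", {
  set.seed(36)
  a <- random_interaction_table(300)
  b <- a
  b$n_reads <- stats::rpois(300, 20)
  d_ab <- differential_score(a, b)
  d_ba <- differential_score(b, a)
  key <- paste(d_ab$bait_id, d_ab$oe_id)
  m <- match(key, paste(d_ba$bait_id, d_ba$oe_id))
  expect_equal(d_ab$log2_ratio, -d_ba$log2_ratio[m])
  expect_equal(d_ab$diff_score, d_ba$diff_score[m], tolerance = 1e-10)
  expect_equal(d_ab$significant, d_ba$significant[m])
})

test_that("BH adjustment inside the scorer matches the reference implementation", {
  set.seed(37)
  for (rep in 1:20) {
    p <- stats::runif(200)^2
    expect_equal(stats::p.adjust(p, "BH"), bf_bh(p))
  }
})

test_that("window_around_bait keeps cis pairs within 500 kb of the bait midpoint", {
  fm <- data.frame(frag_id = c(1L, 2L, 3L, 4L), chrom = "chr1",
                   start = c(0, 499000, 499500, 700000) + c(0, 0, 0, 0),
                   end = c(1000, 500000, 500500, 701000),
                   is_bait = c(TRUE, FALSE, FALSE, FALSE), gene_ids = "",
                   stringsAsFactors = FALSE)
  # bait midpoint 500; oe midpoints at +499999, +500002 and trans
  d <- data.frame(bait_id = 1L, oe_id = c(2L, 3L, 4L),
                  bait_chrom = "chr1", bait_start = 0, bait_end = 1000,
                  oe_chrom = c("chr1", "chr1", "chr2"),
                  oe_start = c(500499, 500502, 100) - 1,
                  oe_end = c(500499, 500502, 100) + 1,
                  count_a = 5, count_b = 1, log2_ratio = 1,
                  diff_score = 6, significant = TRUE,
                  stringsAsFactors = FALSE)
  kept <- window_around_bait(d, 1L, fm)
  expect_equal(kept$oe_id, 2L)
  expect_error(window_around_bait(d, 99L, fm), "unknown bait")
})
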
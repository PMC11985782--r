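block_matrix <- function(n_blocks, block_bins, within = 10, between = 0) {
  n <- n_blocks * block_bins
  m <- matrix(between, n, n)
  for (b in seq_len(n_blocks) - 1L)
    m[b * block_bins + seq_len(block_bins),
      b * block_bins + seq_len(block_bins)] <- within
  m
}

test_that("noiseless block-diagonal matrices yield boundaries exactly at block joins", {
  cm <- contact_matrix("chr1", 20000, block_matrix(3, 50))
  b <- call_tad_boundaries(cm, 60000, 120000, 20000)
  expect_equal(attr(b, "bins"), c(51L, 101L))
  expect_equal(b$start, c(50, 100) * 20000)
})

test_that("a constant matrix has a flat insulation profile and no boundaries", {
  cm <- contact_matrix("chr1", 20000, matrix(7, 100, 100))
  expect_equal(nrow(call_tad_boundaries(cm)), 0L)
})

test_that("boundary calls are invariant under uniform count scaling", {
  set.seed(21)
  cuts <- c(1e6, 2.4e6, 4e6)
  cm <- simulate_contact_matrix("chr1", 5e6, 2e4, cuts)
  b1 <- attr(call_tad_boundaries(cm), "bins")
  cm5 <- contact_matrix(cm$chrom, cm$bin_size, cm$counts * 5)
  expect_equal(attr(call_tad_boundaries(cm5), "bins"), b1)
})

test_that("the caller rejects undersized and asymmetric matrices", {
  expect_error(call_tad_boundaries(contact_matrix("chr1", 2e4, matrix(1, 8, 8))),
               "too small")
  m <- matrix(1, 30, 30); m[1, 2] <- 5
  expect_error(contact_matrix("chr1", 2e4, m), "symmetric")
})

test_that("planted boundaries are recovered within one bin under Poisson noise", {
  tot <- 0L; rec <- 0L
  for (s in 1:20) {
    set.seed(s)
    cuts <- tadcapture:::.sample_tad_cuts(1e7, 2e4, 10, 6e5)
    cm <- simulate_contact_matrix("chr1", 1e7, 2e4, cuts)
    got <- attr(call_tad_boundaries(cm), "bins")
    true_bins <- cuts / 2e4 + 1
    tot <- tot + length(true_bins)
    rec <- rec + sum(vapply(true_bins, function(tb)
      any(abs(got - tb) <= 1), TRUE))
  }
  expect_gte(rec / tot, 0.95)
})

test_that("boundaries_to_tads tiles the chromosome without overlap", {
  b <- data.frame(chrom = "chr1", start = c(1e6, 3e6), end = c(1e6, 3e6) + 2e4)
  tads <- boundaries_to_tads(b, "chr1", 5e6, "case")
  expect_equal(tads$start, c(0, 1e6, 3e6))
  expect_equal(tads$end, c(1e6, 3e6, 5e6))
  expect_equal(tads$start[-1], tads$end[-3])
})

test_that("pair_tads applies the max-overlap rule with deterministic ties", {
  ta <- data.frame(tad_id = "A1", chrom = "chr1", start = 0, end = 1000)
  tb <- data.frame(tad_id = c("B1", "B2"), chrom = "chr1",
                   start = c(0, 600), end = c(600, 1000))
  p <- pair_tads(ta, tb)
  expect_equal(p$tad_b, "B1")
  expect_equal(p$overlap, 600L)
  # identical lists pair identically with full-length overlap
  p2 <- pair_tads(tb, tb)
  expect_equal(p2$tad_b, tb$tad_id)
  expect_equal(p2$overlap, as.integer(tb$end - tb$start))
})

test_that("pair_tads equals the brute-force argmax on random partitions", {
  set.seed(22)
  for (rep in 1:20) {
    ta <- random_tad_partition("chr1", 1000L, 5L, "A")
    tb <- random_tad_partition("chr1", 1000L, 7L, "B")
    expect_equal(pair_tads(ta, tb), bf_pair_tads(ta, tb), ignore_attr = TRUE)
  }
})

test_that("gene-to-TAD assignment is TSS-based and half-open", {
  tads <- data.frame(tad_id = c("T1", "T2"), chrom = "chr1",
                     start = c(0, 500), end = c(500, 1000))
  genes <- data.frame(gene_id = c("g1", "g2"), symbol = c("g1", "g2"),
                      chrom = "chr1", start = c(100, 480), end = c(150, 500),
                      strand = c("+", "-"), biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  asg <- assign_genes_to_tads(genes, tads)
  expect_equal(asg$T1, c("g1", "g2"))  # g2 TSS = 499 (minus strand)
  expect_equal(asg$T2, character(0))
  # TSS exactly at a TAD end belongs to the next domain
  genes$start[1] <- 500; genes$end[1] <- 600
  asg <- assign_genes_to_tads(genes, tads)
  expect_equal(asg$T2, "g1")
})

test_that("gene assignment equals the brute-force per-gene scan", {
  set.seed(23)
  for (rep in 1:10) {
    tads <- random_tad_partition("chr1", 1000L, 6L, "A")
    starts <- sample.int(950, 40)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:40),
                        symbol = sprintf("g%02d", 1:40), chrom = "chr1",
                        start = starts, end = starts + sample.int(50, 40),
                        strand = sample(c("+", "-"), 40, TRUE),
                        biotype = "protein_coding", stringsAsFactors = FALSE)
    expect_equal(assign_genes_to_tads(genes, tads), bf_assign_genes(genes, tads))
  }
})

test_that("classification is strict set equality and symmetric under condition swap", {
  pairs <- data.frame(tad_a = c("A1", "A2"), tad_b = c("B1", "B2"),
                      overlap = c(100, 100), stringsAsFactors = FALSE)
  ga <- list(A1 = c("g1", "g2"), A2 = c("g1", "g2"))
  gb <- list(B1 = c("g2", "g1"), B2 = c("g1", "g2", "g3"))
  cls <- classify_tad_pairs(pairs, ga, gb)
  expect_equal(cls$label, c("conserved", "disrupted"))
  # swap conditions: labels unchanged
  rev_pairs <- data.frame(tad_a = pairs$tad_b, tad_b = pairs$tad_a,
                          overlap = pairs$overlap, stringsAsFactors = FALSE)
  cls_rev <- classify_tad_pairs(rev_pairs, gb, ga)
  expect_equal(cls_rev$label, cls$label)
  expect_equal(sum(attr(cls, "counts")), nrow(cls))
})

test_that("require_de_gene drops pairs without any DE gene", {
  pairs <- data.frame(tad_a = c("A1", "A2"), tad_b = c("B1", "B2"),
                      overlap = c(100, 100), stringsAsFactors = FALSE)
  ga <- list(A1 = "g1", A2 = "g2")
  gb <- list(B1 = "g1", B2 = c("g2", "g3"))
  cls <- classify_tad_pairs(pairs, ga, gb, require_de_gene = TRUE,
                            de_genes = "g3")
  expect_equal(cls$tad_a, "A2")
  expect_error(classify_tad_pairs(pairs, ga, gb, require_de_gene = TRUE),
               "de_genes")
})

test_that("affected_genes unions disrupted pairs only and tallies biotypes", {
  pairs <- data.frame(tad_a = c("A1", "A2"), tad_b = c("B1", "B2"),
                      overlap = c(100, 100), stringsAsFactors = FALSE)
  ga <- list(A1 = "g1", A2 = c("g1", "g2"))
  gb <- list(B1 = "g1", B2 = c("g1", "g2", "g3"))
  cls <- classify_tad_pairs(pairs, ga, gb)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      biotype = c("protein_coding", "lncRNA", "protein_coding"),
                      stringsAsFactors = FALSE)
  aff <- affected_genes(cls, genes)
  expect_equal(as.character(aff), c("g1", "g2", "g3"))
  expect_equal(unname(attr(aff, "coding_fraction")), 2 / 3)
  # all-conserved input yields an empty set
  cls0 <- classify_tad_pairs(pairs[1, ], ga["A1"], gb["B1"])
  expect_length(affected_genes(cls0), 0L)
})

test_that("common_gene_fraction is intersection over union with empty-set error", {
  expect_equal(common_gene_fraction(c("a", "b"), c("b", "a")), 1)
  expect_equal(common_gene_fraction("a", "b"), 0)
  expect_error(common_gene_fraction(character(0), character(0)), "undefined")
  set.seed(24)
  for (rep in 1:20) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    expect_equal(common_gene_fraction(a, b),
                 length(intersect(a, b)) / length(union(a, b)))
  }
})

test_that("contact matrices round-trip through the dense TSV format", {
  set.seed(25)
  cm <- simulate_contact_matrix("chr3", 2e6, 2e4, 4e5, within = 8)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(cm, tmp)
  back <- read_contact_matrix(tmp)
  expect_equal(back$chrom, "chr3")
  expect_equal(back$bin_size, 2e4)
  expect_equal(back$counts, cm$counts)
})
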
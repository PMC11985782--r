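# Brute-force oracles and small random-instance generators shared across
# tests.  Oracles enumerate or scan naively and stay independent of the
# package's implementation paths.

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(50, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# per-base enumeration of overlap size
bf_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L)))
}

# O(n*m) argmax pairing of TADs by overlap, earlier-starting B on ties
bf_pair_tads <- function(ta, tb) {
  out <- data.frame(tad_a = ta$tad_id, tad_b = NA_character_, overlap = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ta))) {
    best_ov <- 0; best_j <- NA_integer_
    for (j in seq_len(nrow(tb))) {
      ov <- bf_overlap_bp(ta[i, ], tb[j, ])
      better <- ov > best_ov ||
        (ov == best_ov && ov > 0 && !is.na(best_j) &&
           tb$start[j] < tb$start[best_j])
      if (better) { best_ov <- ov; best_j <- j }
    }
    if (!is.na(best_j) && best_ov > 0) {
      out$tad_b[i] <- tb$tad_id[best_j]
      out$overlap[i] <- best_ov
    }
  }
  out
}

# per-gene scan of TSS membership
bf_assign_genes <- function(genes, tads) {
  out <- stats::setNames(rep(list(character(0)), nrow(tads)), tads$tad_id)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  for (g in seq_len(nrow(genes)))
    for (t in seq_len(nrow(tads)))
      if (genes$chrom[g] == tads$chrom[t] &&
          tss[g] >= tads$start[t] && tss[g] < tads$end[t])
        out[[tads$tad_id[t]]] <- c(out[[tads$tad_id[t]]], genes$gene_id[g])
  lapply(out, function(x) sort(unique(x)))
}

# membership-pattern enumeration for Venn regions
bf_venn <- function(sets) {
  nms <- names(sets)
  universe <- unique(unlist(sets))
  patterns <- unlist(lapply(seq_along(sets), function(m)
    utils::combn(nms, m, paste, collapse = "&", simplify = FALSE)))
  out <- stats::setNames(integer(length(patterns)), patterns)
  for (el in universe) {
    inset <- nms[vapply(sets, function(s) el %in% s, TRUE)]
    key <- paste(inset, collapse = "&")
    out[key] <- out[key] + 1L
  }
  out
}

# reference BH: sort, cummin of n * p / rank from the largest down
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# naive all-pairs cCRE annotation of other ends
bf_annotate <- function(interactions, ccres) {
  lapply(seq_len(nrow(interactions)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(ccres))) {
      if (interactions$oe_chrom[i] == ccres$chrom[j] &&
          interactions$oe_start[i] < ccres$end[j] &&
          ccres$start[j] < interactions$oe_end[i])
        hits <- c(hits, ccres$ccre_class[j])
    }
    if (length(hits)) sort(unique(hits)) else "none"
  })
}

# non-overlapping sorted random TAD partition of [0, chrom_len)
random_tad_partition <- function(chrom, chrom_len, n_tads, condition) {
  cuts <- sort(sample(seq(10L, chrom_len - 10L, by = 10L), n_tads - 1L))
  starts <- c(0L, cuts); ends <- c(cuts, chrom_len)
  data.frame(tad_id = sprintf("%s_%s_%02d", condition, chrom,
                              seq_len(n_tads)),
             chrom = chrom, start = starts, end = ends,
             condition = condition, stringsAsFactors = FALSE)
}

# minimal interaction-table constructor for filter tests
make_interactions <- function(bait_id, oe_id, bait_chrom, bait_start,
                              bait_end, oe_chrom, oe_start, oe_end,
                              n_reads, score) {
  data.frame(bait_id = bait_id, oe_id = oe_id, bait_chrom = bait_chrom,
             bait_start = bait_start, bait_end = bait_end,
             oe_chrom = oe_chrom, oe_start = oe_start, oe_end = oe_end,
             n_reads = n_reads, score = score, stringsAsFactors = FALSE)
}
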
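# TAD boundary calling from contact matrices, cross-condition TAD pairing,
# and conserved/disrupted classification by gene-content equality.

#' Construct a contact matrix
#'
#' A per-chromosome symmetric matrix of interaction counts over fixed-size
#' genomic bins.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in base pairs.
#' @param counts Square symmetric numeric matrix with non-negative entries.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("contact matrix must be square")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("contact matrix must be symmetric")
  if (any(counts < 0))
    stop("contact matrix must be non-negative")
  structure(list(chrom = as.character(chrom),
                 bin_size = as.numeric(bin_size),
                 counts = unname(counts)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins of %s bp\n",
              x$chrom, nrow(x$counts),
              format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' Read a contact matrix from dense TSV
#'
#' Expects a header line `#chrom=<name> bin_size=<bp>` followed by an n-by-n
#' tab-separated count matrix.
#'
#' @param path File path.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#chrom=(\\S+)\\s+bin_size=(\\d+)", header))[[1]]
  if (length(m) < 3L)
    stop("contact matrix header must be '#chrom=<name> bin_size=<bp>'")
  counts <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                        header = FALSE))
  contact_matrix(m[2], as.numeric(m[3]), counts)
}

#' Write a contact matrix to dense TSV
#'
#' @param mat A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom=%s bin_size=%s", mat$chrom,
                     format(mat$bin_size, scientific = FALSE)), con)
  utils::write.table(mat$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Multi-window insulation profile of a contact matrix
#'
#' For a boundary position before bin `i` (1-based) and window size `w`
#' bins, the insulation score is the mean count in the `w`-by-`w` square of
#' contacts crossing the position (`counts[(i-w):(i-1), i:(i+w-1)]`).
#' Scores are averaged over window sizes from `min_depth` to `max_depth` in
#' steps of `step` (all in base pairs, multiples of the bin size).
#' Positions too close to either matrix edge for the largest window are NA.
#'
#' @param mat A `contact_matrix`.
#' @param min_depth,max_depth,step Window range in base pairs.
#' @return Numeric vector of length `nbins + 1`; element `i` is the score of
#'   the boundary position before bin `i`.
#' @export
insulation_profile <- function(mat, min_depth = 60000, max_depth = 120000,
                               step = 20000) {
  bs <- mat$bin_size
  if (min_depth >= max_depth) stop("min_depth must be < max_depth")
  depths <- seq(min_depth, max_depth, by = step)
  if (any(depths %% bs != 0))
    stop("min_depth, max_depth and step must be multiples of bin_size")
  ws <- depths / bs
  n <- nrow(mat$counts)
  wmax <- max(ws)
  if (n < 2 * wmax)
    stop("matrix too small: need at least ", 2 * wmax, " bins for max_depth")
  ins <- rep(NA_real_, n + 1L)
  for (i in (wmax + 1L):(n - wmax + 1L)) {
    acc <- 0
    for (w in ws)
      acc <- acc + mean(mat$counts[(i - w):(i - 1L), i:(i + w - 1L)])
    ins[i] <- acc / length(ws)
  }
  ins
}

# internal: indices of strict local minima of x (NAs ignored at the flanks);
# plateaus of equal values yield their first index.
.local_minima <- function(x) {
  idx <- which(!is.na(x))
  v <- x[idx]
  n <- length(v)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  for (j in 2:(n - 1L)) {
    if (v[j] > v[j - 1L] || v[j] > v[j + 1L]) next
    # walk left over any plateau
    l <- j - 1L
    while (l > 1L && v[l] == v[j]) l <- l - 1L
    r <- j + 1L
    while (r < n && v[r] == v[j]) r <- r + 1L
    if (v[l] > v[j] && v[r] > v[j] && (j == 2L || v[j - 1L] > v[j]))
      out <- c(out, idx[j])
  }
  out
}

#' Call TAD boundaries from a contact matrix
#'
#' Boundaries are local minima of the multi-window insulation profile (see
#' [insulation_profile()]) whose prominence relative to the flanking maxima
#' exceeds `delta`.  The default `delta` is 0.01 of the chromosome-mean
#' insulation score, which makes the boundary set invariant under uniform
#' scaling of the counts.  Each boundary is reported as a one-bin interval
#' starting at the first bin of the downstream domain.
#'
#' @param mat A `contact_matrix`.
#' @param min_depth,max_depth,step Insulation window range in base pairs
#'   (defaults follow common 20-kb-bin Hi-C practice: 60/120/20 kb).
#' @param delta Minimum prominence of a boundary minimum; `NULL` (default)
#'   uses 0.01 of the mean insulation score.
#' @return Interval data frame of one-bin boundaries with a `name` column
#'   (`"boundary_<k>"`), plus attribute `"bins"` giving the 1-based index of
#'   the first bin after each boundary.
#' @export
#' @examples
#' blocks <- matrix(0, 60, 60)
#' for (b in 0:2) blocks[b * 20 + 1:20, b * 20 + 1:20] <- 10
#' mat <- contact_matrix("chr1", 20000, blocks)
#' call_tad_boundaries(mat, 60000, 120000, 20000)
call_tad_boundaries <- function(mat, min_depth = 60000, max_depth = 120000,
                                step = 20000, delta = NULL) {
  ins <- insulation_profile(mat, min_depth, max_depth, step)
  if (is.null(delta)) delta <- 0.01 * mean(ins, na.rm = TRUE)
  mins <- .local_minima(ins)
  if (length(mins)) {
    valid <- which(!is.na(ins))
    lo <- min(valid); hi <- max(valid)
    seps <- c(lo, mins, hi)
    keep <- logical(length(mins))
    for (k in seq_along(mins)) {
      left <- max(ins[seps[k]:mins[k]], na.rm = TRUE)
      right <- max(ins[mins[k]:seps[k + 2L]], na.rm = TRUE)
      keep[k] <- (min(left, right) - ins[mins[k]]) >= delta
    }
    mins <- mins[keep]
  }
  bs <- mat$bin_size
  out <- data.frame(chrom = rep(mat$chrom, length(mins)),
                    start = (mins - 1L) * bs,
                    end = mins * bs,
                    name = if (length(mins))
                      paste0("boundary_", seq_along(mins)) else character(0),
                    stringsAsFactors = FALSE)
  attr(out, "bins") <- mins
  out
}

#' Partition a chromosome into TADs between called boundaries
#'
#' @param boundaries Boundary intervals from [call_tad_boundaries()] (their
#'   `start` positions are the cut points).
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in base pairs.
#' @param condition Condition label stored with each TAD.
#' @return TAD data frame (`tad_id`, `chrom`, `start`, `end`, `condition`).
#' @export
boundaries_to_tads <- function(boundaries, chrom, chrom_length, condition) {
  cuts <- sort(boundaries$start[boundaries$chrom == chrom])
  cuts <- cuts[cuts > 0 & cuts < chrom_length]
  starts <- c(0, cuts)
  ends <- c(cuts, chrom_length)
  data.frame(tad_id = sprintf("%s_%s_tad%02d", condition, chrom,
                              seq_along(starts)),
             chrom = chrom, start = starts, end = ends,
             condition = condition, stringsAsFactors = FALSE)
}

#' Validate a per-condition TAD set
#'
#' TADs of one condition must be non-overlapping and sorted per chromosome.
#'
#' @param tads TAD data frame.
#' @return `tads`, invisibly (sorted).
#' @export
validate_tads <- function(tads) {
  validate_intervals(tads, what = "TAD")
  tads <- tads[order(tads$chrom, tads$start), , drop = FALSE]
  for (ch in unique(tads$chrom)) {
    sub <- tads[tads$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("TADs overlap on ", ch)
  }
  invisible(tads)
}

#' Pair TADs across two conditions by maximal overlap
#'
#' Each condition-A TAD is paired with the condition-B TAD of maximal
#' base-pair overlap; ties are broken by the earlier-starting B TAD.  A TADs
#' with no overlapping B TAD are reported unpaired (`tad_b` is NA).
#'
#' @param tads_a,tads_b TAD data frames (columns `tad_id`, `chrom`, `start`,
#'   `end`), sorted per chromosome.
#' @return Data frame with one row per A TAD: `tad_a`, `tad_b`, `overlap`.
#' @export
pair_tads <- function(tads_a, tads_b) {
  validate_tads(tads_a); validate_tads(tads_b)
  out <- data.frame(tad_a = tads_a$tad_id, tad_b = NA_character_,
                    overlap = 0, stringsAsFactors = FALSE)
  if (nrow(tads_a) == 0L || nrow(tads_b) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(.as_granges(tads_a), .as_granges(tads_b))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    ov <- overlap_bp(tads_a[qh, , drop = FALSE], tads_b[sh, , drop = FALSE])
    for (q in unique(qh)) {
      sel <- which(qh == q)
      best <- sel[order(-ov[sel], tads_b$start[sh[sel]])][1]
      out$tad_b[q] <- tads_b$tad_id[sh[best]]
      out$overlap[q] <- ov[best]
    }
  }
  out
}

#' Assign genes to TADs
#'
#' With the default `"tss"` mode a gene belongs to a TAD iff its TSS lies in
#' `[start, end)`, which partitions genes (at most one TAD per gene per
#' condition).  `"body"` mode assigns a gene to every TAD its body overlaps
#' by at least 1 bp.
#'
#' @param genes Gene table (see [read_gene_table()]).
#' @param tads TAD data frame.
#' @param mode `"tss"` (default) or `"body"`.
#' @return Named list mapping `tad_id` to a character vector of gene ids
#'   (every TAD present, possibly empty).
#' @export
assign_genes_to_tads <- function(genes, tads, mode = c("tss", "body")) {
  mode <- match.arg(mode)
  out <- stats::setNames(rep(list(character(0)), nrow(tads)), tads$tad_id)
  if (nrow(genes) == 0L || nrow(tads) == 0L) return(out)
  if (mode == "tss") {
    tss <- gene_tss(genes)
    q <- data.frame(chrom = genes$chrom, start = tss, end = tss + 1,
                    stringsAsFactors = FALSE)
  } else {
    q <- genes[, c("chrom", "start", "end")]
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(q), .as_granges(tads))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in seq_along(qh)) {
    tid <- tads$tad_id[sh[k]]
    out[[tid]] <- c(out[[tid]], genes$gene_id[qh[k]])
  }
  lapply(out, function(g) sort(unique(g)))
}

#' Classify paired TADs as conserved or disrupted
#'
#' A pair is conserved iff the gene-id sets of the two TADs are equal as
#' sets; any other overlapping pair is disrupted.  Unpaired A TADs are not
#' classified.  With `require_de_gene`, only pairs containing at least one
#' differentially expressed gene (in either TAD) are classified; the rest
#' are dropped.
#'
#' @param pairs Output of [pair_tads()].
#' @param genes_a_by_tad,genes_b_by_tad Named lists from
#'   [assign_genes_to_tads()] for the two conditions.
#' @param require_de_gene If TRUE, classify only pairs containing a DE gene.
#' @param de_genes Character vector of DE gene ids (needed when
#'   `require_de_gene`).
#' @return Data frame with columns `tad_a`, `tad_b`, `overlap`, `label`
#'   (`"conserved"`/`"disrupted"`) and list columns `genes_a`, `genes_b`;
#'   attribute `"counts"` holds the per-label tally.
#' @export
classify_tad_pairs <- function(pairs, genes_a_by_tad, genes_b_by_tad,
                               require_de_gene = FALSE, de_genes = NULL) {
  keep <- !is.na(pairs$tad_b) & pairs$overlap > 0
  pairs <- pairs[keep, , drop = FALSE]
  ga <- lapply(pairs$tad_a, function(t) {
    g <- genes_a_by_tad[[t]]; if (is.null(g)) character(0) else g
  })
  gb <- lapply(pairs$tad_b, function(t) {
    g <- genes_b_by_tad[[t]]; if (is.null(g)) character(0) else g
  })
  if (require_de_gene) {
    if (is.null(de_genes))
      stop("require_de_gene = TRUE needs de_genes")
    has_de <- mapply(function(a, b) any(c(a, b) %in% de_genes), ga, gb)
    pairs <- pairs[has_de, , drop = FALSE]
    ga <- ga[has_de]; gb <- gb[has_de]
  }
  label <- mapply(function(a, b)
    if (setequal(a, b)) "conserved" else "disrupted", ga, gb)
  out <- data.frame(tad_a = pairs$tad_a, tad_b = pairs$tad_b,
                    overlap = pairs$overlap,
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  out$genes_a <- ga
  out$genes_b <- gb
  attr(out, "counts") <- c(conserved = sum(out$label == "conserved"),
                           disrupted = sum(out$label == "disrupted"))
  out
}

#' Genes affected by TAD disruption
#'
#' The union of the gene sets of both TADs over disrupted pairs only.  When
#' a gene table is supplied, per-biotype counts and the protein-coding
#' versus non-coding split are attached.
#'
#' @param classifications Output of [classify_tad_pairs()].
#' @param genes Optional gene table for the biotype tally.
#' @return Character vector of affected gene ids (sorted); attributes
#'   `"biotype_counts"` and `"coding_fraction"` when `genes` is given.
#' @export
affected_genes <- function(classifications, genes = NULL) {
  disr <- classifications[classifications$label == "disrupted", , drop = FALSE]
  ids <- sort(unique(c(unlist(disr$genes_a), unlist(disr$genes_b))))
  if (!is.null(genes) && length(ids)) {
    bt <- genes$biotype[match(ids, genes$gene_id)]
    tab <- table(factor(bt, levels = .BIOTYPES))
    attr(ids, "biotype_counts") <- c(tab)
    attr(ids, "coding_fraction") <-
      unname(tab["protein_coding"] / length(ids))
  }
  ids
}

#' Jaccard fraction of common genes between two sets
#'
#' `|A intersect B| / |A union B|`.  Both sets empty is undefined and an
#' error.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return Fraction in `[0, 1]`.
#' @export
common_gene_fraction <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- union(set_a, set_b)
  if (length(u) == 0L)
    stop("common_gene_fraction is undefined for two empty sets")
  length(intersect(set_a, set_b)) / length(u)
}
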
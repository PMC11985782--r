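# Promoter-capture interaction tables: ibed/chinput readers, significance
# and distance filtering, per-bait/per-chromosome accounting, Venn-style
# bait sharing, and a count-based differential interaction scorer.

.INTERACTION_COLS <- c("bait_id", "oe_id", "bait_chrom", "bait_start",
                       "bait_end", "oe_chrom", "oe_start", "oe_end",
                       "n_reads", "score")

.empty_interactions <- function() {
  data.frame(bait_id = integer(0), oe_id = integer(0),
             bait_chrom = character(0), bait_start = numeric(0),
             bait_end = numeric(0), oe_chrom = character(0),
             oe_start = numeric(0), oe_end = numeric(0),
             n_reads = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Validate an interaction table
#'
#' @param x Interaction data frame.
#' @return `x`, invisibly.
#' @export
validate_interactions <- function(x) {
  if (!all(.INTERACTION_COLS %in% names(x)))
    stop("interaction table missing columns: ",
         paste(setdiff(.INTERACTION_COLS, names(x)), collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  validate_intervals(data.frame(chrom = x$bait_chrom, start = x$bait_start,
                                end = x$bait_end), what = "bait")
  validate_intervals(data.frame(chrom = x$oe_chrom, start = x$oe_start,
                                end = x$oe_end), what = "other end")
  if (any(x$bait_id == x$oe_id))
    stop("interaction row ", which(x$bait_id == x$oe_id)[1],
         ": bait and other end are the same fragment")
  if (any(x$n_reads < 0, na.rm = TRUE))
    stop("negative read count")
  if (any(x$score < 0, na.rm = TRUE))
    stop("negative significance score")
  invisible(x)
}

#' Bait to other-end distance of each interaction
#'
#' Distance between fragment midpoints; NA for trans-chromosomal pairs.
#'
#' @param x Interaction table.
#' @return Numeric vector of distances in base pairs.
#' @export
interaction_distance <- function(x) {
  d <- abs(.midpoint(x$oe_start, x$oe_end) - .midpoint(x$bait_start, x$bait_end))
  d[x$bait_chrom != x$oe_chrom] <- NA_real_
  d
}

#' Read a promoter-capture interaction table
#'
#' `"ibed"` tables carry coordinates inline (tab-separated, header
#' `bait_chr bait_start bait_end bait_name oe_chr oe_start oe_end oe_name
#' N score`; the name columns hold integer fragment ids).  `"chinput"`
#' tables are pair lists (`baitID otherEndID N [score]`) whose coordinates
#' are resolved through a fragment map; rows lacking a score get `NA`
#' (filterable only by count).
#'
#' @param path File path.
#' @param format `"ibed"` or `"chinput"`.
#' @param fragment_map Fragment map, required for `"chinput"`.
#' @return Interaction data frame (columns `bait_id`, `oe_id`,
#'   `bait_chrom`, `bait_start`, `bait_end`, `oe_chrom`, `oe_start`,
#'   `oe_end`, `n_reads`, `score`).
#' @export
read_interactions <- function(path, format = c("ibed", "chinput"),
                              fragment_map = NULL) {
  format <- match.arg(format)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(.empty_interactions())
  if (format == "ibed") {
    need <- c("bait_chr", "bait_start", "bait_end", "bait_name",
              "oe_chr", "oe_start", "oe_end", "oe_name", "N", "score")
    if (!all(need %in% names(raw)))
      stop("ibed table missing columns: ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    x <- data.frame(bait_id = as.integer(raw$bait_name),
                    oe_id = as.integer(raw$oe_name),
                    bait_chrom = as.character(raw$bait_chr),
                    bait_start = as.numeric(raw$bait_start),
                    bait_end = as.numeric(raw$bait_end),
                    oe_chrom = as.character(raw$oe_chr),
                    oe_start = as.numeric(raw$oe_start),
                    oe_end = as.numeric(raw$oe_end),
                    n_reads = as.numeric(raw$N),
                    score = as.numeric(raw$score),
                    stringsAsFactors = FALSE)
  } else {
    need <- c("baitID", "otherEndID", "N")
    if (!all(need %in% names(raw)))
      stop("chinput table missing columns: ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    if (is.null(fragment_map))
      stop("chinput format needs a fragment_map to resolve coordinates")
    bi <- match(as.integer(raw$baitID), fragment_map$frag_id)
    oi <- match(as.integer(raw$otherEndID), fragment_map$frag_id)
    if (anyNA(bi) || anyNA(oi))
      stop("chinput row ", which(is.na(bi) | is.na(oi))[1],
           ": fragment id not in fragment map")
    x <- data.frame(bait_id = as.integer(raw$baitID),
                    oe_id = as.integer(raw$otherEndID),
                    bait_chrom = fragment_map$chrom[bi],
                    bait_start = fragment_map$start[bi],
                    bait_end = fragment_map$end[bi],
                    oe_chrom = fragment_map$chrom[oi],
                    oe_start = fragment_map$start[oi],
                    oe_end = fragment_map$end[oi],
                    n_reads = as.numeric(raw$N),
                    score = if ("score" %in% names(raw))
                      as.numeric(raw$score) else NA_real_,
                    stringsAsFactors = FALSE)
  }
  bad <- which(is.na(x$bait_start) | is.na(x$oe_start) | is.na(x$n_reads))
  if (length(bad))
    stop(format, " row ", bad[1], ": coordinate or count parse failure")
  validate_interactions(x)
  x
}

#' Write an interaction table in ibed format
#'
#' @param x Interaction table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibed <- function(x, path) {
  out <- data.frame(bait_chr = x$bait_chrom,
                    bait_start = format(x$bait_start, scientific = FALSE, trim = TRUE),
                    bait_end = format(x$bait_end, scientific = FALSE, trim = TRUE),
                    bait_name = x$bait_id,
                    oe_chr = x$oe_chrom,
                    oe_start = format(x$oe_start, scientific = FALSE, trim = TRUE),
                    oe_end = format(x$oe_end, scientific = FALSE, trim = TRUE),
                    oe_name = x$oe_id,
                    N = format(x$n_reads, scientific = FALSE, trim = TRUE),
                    score = sprintf("%.6g", x$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a chinput-style pair table
#'
#' @param x Interaction table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chinput <- function(x, path) {
  out <- data.frame(baitID = x$bait_id, otherEndID = x$oe_id,
                    N = format(x$n_reads, scientific = FALSE, trim = TRUE),
                    score = sprintf("%.6g", x$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Keep significant, sufficiently distal interactions
#'
#' Retains interactions with `score >= score_min` (promoter-interacting
#' regions at the conventional score-5 cutoff) that are either
#' trans-chromosomal or separated by at least `min_distance` between
#' fragment midpoints.  Order is preserved and the filter is idempotent.
#' Records with `NA` scores are dropped (they cannot attest significance).
#'
#' @param interactions Interaction table.
#' @param score_min Minimum significance score (default 5).
#' @param min_distance Minimum bait to other-end distance in bp (default
#'   10000).
#' @return Filtered interaction table.
#' @export
filter_significant <- function(interactions, score_min = 5,
                               min_distance = 10000) {
  if (nrow(interactions) == 0L) return(interactions)
  d <- interaction_distance(interactions)
  keep <- !is.na(interactions$score) & interactions$score >= score_min &
    (is.na(d) | d >= min_distance)
  interactions[keep, , drop = FALSE]
}

#' Interaction counts per bait fragment
#'
#' @param interactions Interaction table.
#' @return Named integer vector (names are bait ids); sums to `nrow`.
#' @export
per_bait_counts <- function(interactions) {
  if (nrow(interactions) == 0L)
    return(stats::setNames(integer(0), character(0)))
  tab <- table(interactions$bait_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Interaction counts per bait chromosome
#'
#' @param interactions Interaction table.
#' @return Named integer vector keyed by chromosome; sums to `nrow`.
#' @export
per_chromosome_counts <- function(interactions) {
  if (nrow(interactions) == 0L)
    return(stats::setNames(integer(0), character(0)))
  tab <- table(interactions$bait_chrom)
  stats::setNames(as.integer(tab), names(tab))
}

#' Percentage share of counts across conditions
#'
#' Divides each count by the grand total; integer percentages use
#' round-half-away-from-zero, matching how such proportions are usually
#' printed.  The unrounded shares (which sum to exactly 100) are returned
#' alongside.
#'
#' @param counts Named non-negative numeric vector, at least one positive.
#' @return List with `percent` (named integer) and `unrounded` (named
#'   numeric).
#' @export
#' @examples
#' share_proportions(c(HT29 = 1283056, LoVo = 1135609, hESC = 201356))$percent
share_proportions <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total == 0) stop("share_proportions: all counts are zero")
  unrounded <- 100 * counts / total
  percent <- stats::setNames(as.integer(floor(unrounded + 0.5)), names(counts))
  list(percent = percent, unrounded = unrounded)
}

#' Disjoint Venn-region sizes of up to three bait sets
#'
#' @param bait_sets Named list of up to 3 vectors (bait ids per condition).
#' @return Named integer vector over all non-empty membership patterns
#'   (names like `"A"`, `"A&B"`); the sizes sum to the size of the union.
#' @export
shared_bait_sets <- function(bait_sets) {
  k <- length(bait_sets)
  if (k < 1L || k > 3L)
    stop("shared_bait_sets supports 1 to 3 conditions")
  nms <- names(bait_sets)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("bait_sets must be a named list")
  sets <- lapply(bait_sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- unlist(lapply(seq_len(k), function(m)
    utils::combn(nms, m, paste, collapse = "&", simplify = FALSE)))
  out <- stats::setNames(integer(length(patterns)), patterns)
  if (length(universe)) {
    key <- apply(member, 1L, function(row) paste(nms[row], collapse = "&"))
    tab <- table(key)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

# internal: two-sided exact binomial p-value, vectorized over x with common n
# handled per row (small tables; binom.test semantics)
.binom_p2 <- function(x, n, p0) {
  mapply(function(xi, ni) {
    if (ni == 0L) return(1)
    stats::binom.test(xi, ni, p = p0)$p.value
  }, x, n)
}

#' Score differential interactions between two conditions
#'
#' A count-based stand-in differential scorer over the union of (bait,
#' other-end) pairs present in either table (a pair absent from one table
#' counts 0 there; pairs at 0/0 are excluded).  Each pair is tested with a
#' two-sided exact binomial test of `count_a` successes out of
#' `count_a + count_b` against the null proportion given by the library
#' share of condition A (or 0.5 when `library_norm = FALSE`), p-values are
#' Benjamini-Hochberg adjusted across pairs, and
#' `diff_score = -log10(adjusted p)`.  A pair is significant when
#' `diff_score > diff_threshold` (default 5, the conventional differential
#' score cutoff).
#'
#' @param table_a,table_b Interaction tables sharing a fragment namespace.
#' @param library_norm Account for library-size differences through the
#'   null proportion (default TRUE).
#' @param diff_threshold Significance cutoff on `diff_score`.
#' @return Data frame `bait_id`, `oe_id`, `count_a`, `count_b`,
#'   `log2_ratio`, `diff_score`, `significant`, plus coordinate columns of
#'   the bait/other end.
#' @export
differential_score <- function(table_a, table_b, library_norm = TRUE,
                               diff_threshold = 5) {
  key_a <- paste(table_a$bait_id, table_a$oe_id)
  key_b <- paste(table_b$bait_id, table_b$oe_id)
  if (nrow(table_a) && nrow(table_b) && !length(intersect(key_a, key_b)))
    warning("no (bait, other end) pairs shared between conditions")
  lib_a <- sum(table_a$n_reads); lib_b <- sum(table_b$n_reads)
  coords <- rbind(
    table_a[, c("bait_id", "oe_id", "bait_chrom", "bait_start", "bait_end",
                "oe_chrom", "oe_start", "oe_end")],
    table_b[, c("bait_id", "oe_id", "bait_chrom", "bait_start", "bait_end",
                "oe_chrom", "oe_start", "oe_end")])
  coords <- coords[!duplicated(paste(coords$bait_id, coords$oe_id)), ,
                   drop = FALSE]
  key <- paste(coords$bait_id, coords$oe_id)
  ca <- table_a$n_reads[match(key, key_a)]; ca[is.na(ca)] <- 0
  cb <- table_b$n_reads[match(key, key_b)]; cb[is.na(cb)] <- 0
  keep <- (ca + cb) > 0
  coords <- coords[keep, , drop = FALSE]
  ca <- ca[keep]; cb <- cb[keep]
  out <- coords
  out$count_a <- ca
  out$count_b <- cb
  out$log2_ratio <- log2((ca + 1) / (cb + 1))
  if (nrow(out) == 0L) {
    out$diff_score <- numeric(0); out$significant <- logical(0)
    rownames(out) <- NULL
    return(out)
  }
  p0 <- if (library_norm && (lib_a + lib_b) > 0) lib_a / (lib_a + lib_b) else 0.5
  p <- .binom_p2(round(ca), round(ca + cb), p0)
  padj <- stats::p.adjust(p, method = "BH")
  out$diff_score <- pmin(-log10(padj), 300)
  out$significant <- out$diff_score > diff_threshold
  rownames(out) <- NULL
  out
}

#' Differential interactions within a window around one bait
#'
#' Keeps pairs whose other-end midpoint lies within `window` bp up- or
#' downstream of the bait midpoint on the same chromosome (boundary
#' inclusive).  Trans-chromosomal pairs are dropped.
#'
#' @param differentials Output of [differential_score()].
#' @param bait_id Bait fragment id (must exist in `fragment_map`).
#' @param fragment_map Fragment map used to resolve the bait midpoint.
#' @param window Half-window in base pairs (default 500000).
#' @return Subset of `differentials` for that bait within the window.
#' @export
window_around_bait <- function(differentials, bait_id, fragment_map,
                               window = 500000) {
  i <- match(bait_id, fragment_map$frag_id)
  if (is.na(i)) stop("unknown bait_id: ", bait_id)
  mid <- .midpoint(fragment_map$start[i], fragment_map$end[i])
  sub <- differentials[differentials$bait_id == bait_id, , drop = FALSE]
  oe_mid <- .midpoint(sub$oe_start, sub$oe_end)
  keep <- sub$oe_chrom == fragment_map$chrom[i] &
    abs(oe_mid - mid) <= window
  sub[keep, , drop = FALSE]
}

#' Restrict differential pairs to a window around their own bait
#'
#' Vectorized variant of [window_around_bait()] applied to every pair.
#'
#' @param differentials Output of [differential_score()].
#' @param window Half-window in base pairs (default 500000).
#' @return Subset of `differentials`.
#' @export
window_filter <- function(differentials, window = 500000) {
  if (nrow(differentials) == 0L) return(differentials)
  d <- abs(.midpoint(differentials$oe_start, differentials$oe_end) -
             .midpoint(differentials$bait_start, differentials$bait_end))
  keep <- differentials$bait_chrom == differentials$oe_chrom & d <= window
  differentials[keep, , drop = FALSE]
}
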
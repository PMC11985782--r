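# Genomic interval algebra and readers/writers for the standard formats the
# pipeline touches.  All coordinates are 0-based half-open [start, end)
# internally (BED convention); GTF input (1-based closed) is converted on
# read.  Overlap computations are strand-agnostic; strand only affects TSS
# derivation.

#' Construct a table of genomic intervals
#'
#' The package's shared coordinate currency: a data frame with `chrom`,
#' `start`, `end` columns in 0-based half-open convention, optionally a
#' `name` column.  Validates invariants (`start < end`, non-negative start,
#' non-empty chromosome names).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @param name Optional character vector of labels.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (and `name`).
#' @export
#' @examples
#' genomic_intervals("chr1", 0, 500000, "TAD1")
genomic_intervals <- function(chrom, start, end, name = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the 0-based half-open invariants and stops with an informative
#' message naming the first offending row.  Inverted or 1-based-looking
#' coordinates are rejected loudly, never silently corrected.
#'
#' @param x Data frame with `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom))
  if (length(bad))
    stop(what, " row ", bad[1], ": empty chromosome name")
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start != floor(x$start) | x$end != floor(x$end))
  if (length(bad))
    stop(what, " row ", bad[1], ": non-integer coordinates")
  bad <- which(x$start < 0)
  if (length(bad))
    stop(what, " row ", bad[1], ": negative start")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop(what, " row ", bad[1], ": start >= end (coordinates must be 0-based half-open)")
  invisible(x)
}

#' Base pairs of overlap between two intervals
#'
#' Vectorized over rows.  Intervals on different chromosomes overlap by 0;
#' half-open abutting intervals overlap by 0.
#'
#' @param a,b Interval tables (recycled to common length) with `chrom`,
#'   `start`, `end`.
#' @return Integer vector of overlap sizes in base pairs (>= 0).
#' @export
#' @examples
#' a <- genomic_intervals("chr1", 0, 100)
#' b <- genomic_intervals("chr1", 100, 200)
#' overlap_bp(a, b)  # 0: half-open abutment
overlap_bp <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 0L || nrow(b) == 0L) return(integer(0))
  ac <- rep_len(a$chrom, n); bc <- rep_len(b$chrom, n)
  as_ <- rep_len(a$start, n); bs <- rep_len(b$start, n)
  ae <- rep_len(a$end, n); be <- rep_len(b$end, n)
  ov <- pmax(0, pmin(ae, be) - pmax(as_, bs))
  ov[ac != bc] <- 0
  as.integer(ov)
}

#' Normalize chromosome-name style
#'
#' Chromosome names are compared as exact strings throughout; this helper
#' strips or adds the `"chr"` prefix so that resources in mixed hg38 styles
#' can be brought onto one namespace before analysis.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"chr"` to ensure the prefix, `"plain"` to strip it.
#' @return Character vector of renamed chromosomes.
#' @export
normalize_chrom <- function(chrom, style = c("chr", "plain")) {
  style <- match.arg(style)
  plain <- sub("^chr", "", chrom)
  if (style == "chr") paste0("chr", plain) else plain
}

# internal: 0-based half-open data.frame -> GRanges (1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

# internal: midpoint of an interval (floor of the average endpoint)
.midpoint <- function(start, end) floor((start + end) / 2)

#' Read a BED file
#'
#' Reads 3+ column tab-separated BED into an interval table; a 4th column, if
#' present, is retained as `name`.  Malformed lines (non-integer or inverted
#' coordinates) raise an error naming the line number.  An empty file yields
#' an empty table.
#'
#' @param path File path.
#' @return Interval data frame (`chrom`, `start`, `end`[, `name`]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", which(nf < 3L)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED line ", bad[1], ": non-integer coordinates")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (any(nf >= 4L))
    df$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  ok <- try(validate_intervals(df, what = "BED line"), silent = TRUE)
  if (inherits(ok, "try-error")) {
    # re-run per row so the error names the offending input line
    for (i in seq_len(nrow(df))) {
      r <- try(validate_intervals(df[i, , drop = FALSE]), silent = TRUE)
      if (inherits(r, "try-error"))
        stop("BED line ", i, ": ",
             sub("^.*: ", "", trimws(attr(r, "condition")$message)))
    }
  }
  df
}

#' Write a BED file
#'
#' @param x Interval table (optionally with a `name` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(x)) cols <- c(cols, "name")
  out <- x[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.BIOTYPES <- c("protein_coding", "lncRNA", "snoRNA", "miRNA",
               "pseudogene", "other_noncoding")

#' Read a gene annotation table
#'
#' Supports a BED-like TSV (`chrom start end gene_id symbol strand biotype`,
#' 0-based half-open, no header) and a minimal GTF (1-based closed `gene`
#' feature lines with `gene_id`, `gene_name`, `gene_biotype` attributes,
#' converted to 0-based half-open on read).  Duplicate gene ids and unknown
#' strand or biotype tokens are rejected.
#'
#' @param path File path.
#' @param format `"bed_tsv"` or `"gtf"`.
#' @return Data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, sorted by `gene_id`.
#' @export
read_gene_table <- function(path, format = c("bed_tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "bed_tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
      return(.empty_gene_table())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 7L))
      stop("gene TSV line ", which(lengths(fields) < 7L)[1],
           ": expected 7 columns (chrom start end gene_id symbol strand biotype)")
    df <- data.frame(
      gene_id = vapply(fields, `[[`, "", 4L),
      symbol = vapply(fields, `[[`, "", 5L),
      chrom = vapply(fields, `[[`, "", 1L),
      start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
      end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
      strand = vapply(fields, `[[`, "", 6L),
      biotype = vapply(fields, `[[`, "", 7L),
      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 9L && f[[3L]] == "gene", TRUE)
    fields <- fields[keep]
    if (length(fields) == 0L) return(.empty_gene_table())
    attr1 <- function(att, key) {
      m <- regmatches(att, regexec(paste0(key, ' "([^"]*)"'), att))[[1]]
      if (length(m) < 2L) NA_character_ else m[2]
    }
    df <- data.frame(
      gene_id = vapply(fields, function(f) attr1(f[[9L]], "gene_id"), ""),
      symbol = vapply(fields, function(f) attr1(f[[9L]], "gene_name"), ""),
      chrom = vapply(fields, `[[`, "", 1L),
      start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))) - 1,
      end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))),
      strand = vapply(fields, `[[`, "", 7L),
      biotype = vapply(fields, function(f) attr1(f[[9L]], "gene_biotype"), ""),
      stringsAsFactors = FALSE)
  }
  if (anyNA(df$gene_id) || any(!nzchar(df$gene_id)))
    stop("gene table: missing gene_id")
  if (anyDuplicated(df$gene_id))
    stop("gene table: duplicate gene_id ",
         df$gene_id[duplicated(df$gene_id)][1])
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("gene table row ", bad[1], ": unknown strand token '",
         df$strand[bad[1]], "'")
  bad <- which(!df$biotype %in% .BIOTYPES)
  if (length(bad))
    stop("gene table row ", bad[1], ": unknown biotype '",
         df$biotype[bad[1]], "' (expected one of ",
         paste(.BIOTYPES, collapse = ", "), ")")
  validate_intervals(df, what = "gene table row")
  df[order(df$gene_id), , drop = FALSE]
}

.empty_gene_table <- function() {
  data.frame(gene_id = character(0), symbol = character(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), biotype = character(0),
             stringsAsFactors = FALSE)
}

#' Write a gene table (BED-like TSV)
#'
#' @param genes Gene table as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(genes$chrom,
                    format(genes$start, scientific = FALSE, trim = TRUE),
                    format(genes$end, scientific = FALSE, trim = TRUE),
                    genes$gene_id, genes$symbol, genes$strand, genes$biotype)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transcription start sites of genes
#'
#' TSS is `start` on the plus strand and `end - 1` on the minus strand
#' (0-based position of the first transcribed base).
#'
#' @param genes Gene table.
#' @return Numeric vector of TSS positions, named by `gene_id`.
#' @export
gene_tss <- function(genes) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  stats::setNames(tss, genes$gene_id)
}

#' Read a restriction-fragment map
#'
#' TSV with header `frag_id chrom start end is_bait gene_ids`; `gene_ids` is
#' a `;`-separated list of gene ids annotated to a bait (empty for non-bait
#' fragments and for baits without promoter annotation).  On load the map is
#' checked for unique fragment ids and for per-chromosome sorted,
#' non-overlapping fragments.
#'
#' @param path File path.
#' @return Data frame with columns `frag_id`, `chrom`, `start`, `end`,
#'   `is_bait` (logical), `gene_ids` (character, `;`-separated).
#' @export
read_fragment_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = c(
    frag_id = "integer", chrom = "character", start = "numeric",
    end = "numeric", is_bait = "logical", gene_ids = "character"))
  df$gene_ids[is.na(df$gene_ids)] <- ""
  validate_fragment_map(df)
}

#' Validate a fragment map
#'
#' @param df Fragment-map data frame.
#' @return `df`, invisibly (sorted by chromosome and start).
#' @export
validate_fragment_map <- function(df) {
  validate_intervals(df, what = "fragment")
  if (anyDuplicated(df$frag_id))
    stop("fragment map: duplicate frag_id ",
         df$frag_id[duplicated(df$frag_id)][1])
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("fragment map: overlapping fragments on ", ch)
  }
  invisible(df)
}

#' Write a fragment map
#'
#' @param df Fragment-map data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(df, path) {
  out <- df[, c("frag_id", "chrom", "start", "end", "is_bait", "gene_ids")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# internal: split ";"-separated gene_ids into a list of character vectors
.split_gene_ids <- function(gene_ids) {
  out <- strsplit(gene_ids, ";", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

#' Map gene ids to their bait fragments
#'
#' Returns the bait fragment ids whose promoter annotation includes any of
#' the given genes.
#'
#' @param gene_ids Character vector of gene ids.
#' @param fragment_map Fragment map data frame.
#' @return Integer vector of bait `frag_id`s.
#' @export
baits_for_genes <- function(gene_ids, fragment_map) {
  baits <- fragment_map[fragment_map$is_bait, , drop = FALSE]
  ann <- .split_gene_ids(baits$gene_ids)
  hit <- vapply(ann, function(g) any(g %in% gene_ids), TRUE)
  baits$frag_id[hit]
}
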
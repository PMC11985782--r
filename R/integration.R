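# The staged bait-filtering cascade (STAGE 1 -> 2 -> 3), cCRE annotation of
# other ends, DE-gene overlap, and final target-gene selection/reporting.

.CCRE_CLASSES <- c("PLS", "pELS", "dELS", "DNase-H3K4me3", "CTCF")
.ENHANCER_CLASSES <- c("pELS", "dELS")

#' Read a cCRE annotation track (BED4)
#'
#' SCREEN-style candidate cis-regulatory elements: the name column carries
#' the class, one of `PLS`, `pELS`, `dELS`, `DNase-H3K4me3`, `CTCF`.
#'
#' @param path BED4 file path.
#' @return Data frame `chrom`, `start`, `end`, `ccre_class`.
#' @export
read_ccre_bed <- function(path) {
  bed <- read_bed(path)
  if (nrow(bed) && !"name" %in% names(bed))
    stop("cCRE BED needs a 4th (class) column")
  cls <- if (nrow(bed)) bed$name else character(0)
  bad <- which(!cls %in% .CCRE_CLASSES)
  if (length(bad))
    stop("cCRE line ", bad[1], ": unknown class '", cls[bad[1]],
         "' (expected ", paste(.CCRE_CLASSES, collapse = ", "), ")")
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             ccre_class = cls, stringsAsFactors = FALSE)
}

#' Read a differential-expression table
#'
#' TSV with header `gene_id log2fc fdr` (case over control).  A gene is
#' significant at `fdr <= fdr_max` and upregulated when additionally
#' `log2fc > 0`.
#'
#' @param path File path.
#' @param fdr_max FDR cutoff for significance (default 0.05).
#' @return Data frame `gene_id`, `log2fc`, `fdr`, `significant`,
#'   `upregulated`.
#' @export
read_de_table <- function(path, fdr_max = 0.05) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stop("DE table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  annotate_de_table(df[, need], fdr_max = fdr_max)
}

#' Flag significance and direction in a DE table
#'
#' @param de Data frame with `gene_id`, `log2fc`, `fdr`.
#' @param fdr_max FDR cutoff (default 0.05).
#' @return `de` with logical `significant` and `upregulated` columns.
#' @export
annotate_de_table <- function(de, fdr_max = 0.05) {
  if (any(de$fdr < 0 | de$fdr > 1, na.rm = TRUE))
    stop("FDR values must lie in [0, 1]")
  de$significant <- !is.na(de$fdr) & de$fdr <= fdr_max
  de$upregulated <- de$significant & de$log2fc > 0
  de
}

# internal: build a stage result structure
.stage_result <- function(stage, bait_ids, interactions_case,
                          interactions_control, params) {
  structure(list(stage = stage,
                 bait_ids = sort(unique(bait_ids)),
                 interactions_case = interactions_case,
                 interactions_control = interactions_control,
                 params = params),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("%s: %d baits, %d case / %d control interactions\n",
              x$stage, length(x$bait_ids), nrow(x$interactions_case),
              nrow(x$interactions_control)))
  invisible(x)
}

#' STAGE 1: baits with a non-zero count and a large count difference
#'
#' Retains a bait iff its interaction count is non-zero in at least one
#' condition and the absolute case-control count difference is at least
#' `min_diff` (a bait absent from one condition counts 0 there).  With
#' `nonzero = "both"` the stricter reading (non-zero in both conditions) is
#' applied instead.
#'
#' @param counts_case,counts_control Named count vectors from
#'   [per_bait_counts()] on the significance-filtered interactions.
#' @param interactions_case,interactions_control The filtered interaction
#'   tables; the retained per-condition subsets are carried in the result.
#' @param min_diff Minimum absolute count difference (default 10).
#' @param nonzero `"either"` (default) or `"both"`.
#' @return A `stage_result` with `stage = "STAGE1"`.
#' @export
stage1_filter <- function(counts_case, counts_control,
                          interactions_case = .empty_interactions(),
                          interactions_control = .empty_interactions(),
                          min_diff = 10, nonzero = c("either", "both")) {
  nonzero <- match.arg(nonzero)
  baits <- union(names(counts_case), names(counts_control))
  cc <- ifelse(baits %in% names(counts_case), counts_case[baits], 0)
  ct <- ifelse(baits %in% names(counts_control), counts_control[baits], 0)
  nz <- if (nonzero == "either") pmax(cc, ct) > 0 else cc > 0 & ct > 0
  keep <- baits[nz & abs(cc - ct) >= min_diff]
  .stage_result("STAGE1", keep,
                interactions_case[as.character(interactions_case$bait_id)
                                  %in% keep, , drop = FALSE],
                interactions_control[as.character(interactions_control$bait_id)
                                     %in% keep, , drop = FALSE],
                list(min_diff = min_diff, nonzero = nonzero))
}

#' STAGE 2: intersect STAGE 1 baits with differential baits
#'
#' @param stage1 A `stage_result` from [stage1_filter()].
#' @param differential_bait_ids Bait ids carrying at least one significant
#'   differential interaction.
#' @return A `stage_result` with `stage = "STAGE2"`.
#' @export
stage2_filter <- function(stage1, differential_bait_ids) {
  keep <- intersect(stage1$bait_ids, as.character(differential_bait_ids))
  .stage_result("STAGE2", keep,
                stage1$interactions_case[
                  as.character(stage1$interactions_case$bait_id) %in% keep, ,
                  drop = FALSE],
                stage1$interactions_control[
                  as.character(stage1$interactions_control$bait_id) %in% keep, ,
                  drop = FALSE],
                stage1$params)
}

#' STAGE 3: intersect STAGE 2 baits with baits of TAD-affected genes
#'
#' @param stage2 A `stage_result` from [stage2_filter()].
#' @param affected_gene_bait_ids Bait ids annotated to genes affected by
#'   TAD disruption (see [baits_for_genes()]).
#' @return A `stage_result` with `stage = "STAGE3"`; the nesting
#'   STAGE3 baits within STAGE2 baits is asserted.
#' @export
stage3_filter <- function(stage2, affected_gene_bait_ids) {
  keep <- intersect(stage2$bait_ids, as.character(affected_gene_bait_ids))
  stopifnot(all(keep %in% stage2$bait_ids))
  .stage_result("STAGE3", keep,
                stage2$interactions_case[
                  as.character(stage2$interactions_case$bait_id) %in% keep, ,
                  drop = FALSE],
                stage2$interactions_control[
                  as.character(stage2$interactions_control$bait_id) %in% keep, ,
                  drop = FALSE],
                stage2$params)
}

#' Annotate interaction other ends with cCRE classes
#'
#' An interaction receives every cCRE class whose element overlaps its
#' other-end interval by at least 1 bp; interactions overlapping no element
#' are labeled `"none"`.  An interaction can count in several classes but
#' once per class.
#'
#' @param interactions Interaction table (e.g. the case interactions of a
#'   stage result).
#' @param ccres cCRE track from [read_ccre_bed()].
#' @return List with `labels` (list of character vectors, one per
#'   interaction row) and `class_counts` (named integer vector over all
#'   classes plus `"none"`).
#' @export
annotate_other_ends <- function(interactions, ccres) {
  if (inherits(interactions, "stage_result"))
    interactions <- interactions$interactions_case
  n <- nrow(interactions)
  labels <- rep(list(character(0)), n)
  if (n && nrow(ccres)) {
    oe <- data.frame(chrom = interactions$oe_chrom,
                     start = interactions$oe_start,
                     end = interactions$oe_end, stringsAsFactors = FALSE)
    hits <- GenomicRanges::findOverlaps(.as_granges(oe), .as_granges(ccres))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(qh))
      labels[[qh[k]]] <- c(labels[[qh[k]]], ccres$ccre_class[sh[k]])
    labels <- lapply(labels, function(l) sort(unique(l)))
  }
  labels <- lapply(labels, function(l) if (length(l)) l else "none")
  lv <- c(.CCRE_CLASSES, "none")
  class_counts <- stats::setNames(integer(length(lv)), lv)
  tab <- table(factor(unlist(labels), levels = lv))
  class_counts[names(tab)] <- as.integer(tab)
  list(interactions = interactions, labels = labels,
       class_counts = class_counts)
}

#' DE genes overlapping differential bait fragments
#'
#' Keeps significant DE genes whose gene interval overlaps any differential
#' bait fragment by at least 1 bp.
#'
#' @param de DE table (see [read_de_table()]); only significant genes are
#'   considered.
#' @param genes Gene table supplying gene intervals.
#' @param differential_bait_ids Differential bait fragment ids.
#' @param fragment_map Fragment map supplying bait intervals.
#' @return Subset of `de` rows for overlapping genes.
#' @export
overlap_de_with_differential_baits <- function(de, genes,
                                               differential_bait_ids,
                                               fragment_map) {
  de_sig <- de[de$significant, , drop = FALSE]
  gi <- match(de_sig$gene_id, genes$gene_id)
  de_sig <- de_sig[!is.na(gi), , drop = FALSE]
  gi <- gi[!is.na(gi)]
  baits <- fragment_map[fragment_map$frag_id %in%
                          as.integer(differential_bait_ids), , drop = FALSE]
  if (nrow(de_sig) == 0L || nrow(baits) == 0L)
    return(de_sig[integer(0), , drop = FALSE])
  hits <- GenomicRanges::findOverlaps(
    .as_granges(genes[gi, c("chrom", "start", "end")]),
    .as_granges(baits))
  de_sig[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Baits whose start lies within a TAD boundary region
#'
#' A bait is retained iff its start coordinate falls inside any boundary
#' interval (half-open); a bait merely ending inside a boundary is not.
#'
#' @param fragment_map Fragment map.
#' @param boundaries Boundary interval table.
#' @return Integer vector of bait `frag_id`s.
#' @export
baits_at_tad_boundaries <- function(fragment_map, boundaries) {
  baits <- fragment_map[fragment_map$is_bait, , drop = FALSE]
  if (nrow(baits) == 0L || nrow(boundaries) == 0L) return(integer(0))
  starts <- data.frame(chrom = baits$chrom, start = baits$start,
                       end = baits$start + 1, stringsAsFactors = FALSE)
  hits <- GenomicRanges::findOverlaps(.as_granges(starts),
                                      .as_granges(boundaries))
  baits$frag_id[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Select and rank candidate target genes
#'
#' A gene is reported iff it satisfies all four selection criteria: it lies
#' in a disrupted TAD (`affected_genes`), it is significantly upregulated,
#' its bait survives the STAGE 3 cascade (capture-count and differential
#' evidence), and at least one STAGE 3 interaction on its bait is annotated
#' with an enhancer-like class (`pELS` or `dELS`).  Reported genes are
#' ranked by descending capture count with ties broken by larger `log2fc`
#' then lexicographic gene id, and truncated to `top_k` or thresholded at
#' `capture_min`.
#'
#' The attached `"diagnostics"` attribute evaluates every gene in the DE
#' table (plus any affected gene) against each criterion independently —
#' capture evidence as STAGE1-and-STAGE2 bait survival, the enhancer loop
#' on all significant case interactions — so that an excluded gene's
#' elimination can be attributed to the criteria it violates.
#'
#' @param stage3 `stage_result` from [stage3_filter()].
#' @param annotations Output of [annotate_other_ends()] on the STAGE 3 case
#'   interactions.
#' @param affected Affected gene ids from [affected_genes()].
#' @param de DE table with `significant`/`upregulated` flags.
#' @param fragment_map Fragment map (bait to gene annotation).
#' @param capture_counts Named per-bait counts of significant case
#'   interactions (capture counts), from [per_bait_counts()].
#' @param top_k Keep at most this many top genes (default all).
#' @param capture_min Optional minimum capture count.
#' @param stage1 Optional STAGE 1 result; lets the diagnostics separate
#'   capture-count evidence from the later intersections.
#' @param differential_bait_ids Optional differential bait set; lets the
#'   diagnostics test differential evidence independently of STAGE nesting.
#' @param case_annotations Optional [annotate_other_ends()] result over all
#'   significant case interactions, for stage-independent loop evidence.
#' @return Data frame of reports: `gene_id`, `capture_count`,
#'   `has_enhancer_loop`, `in_disrupted_tad`, `log2fc`, `fdr`, `rank`; with
#'   attributes `"diagnostics"` (per-gene criterion flags) and
#'   `"elimination_summary"` (how many genes each criterion removed).
#' @export
select_target_genes <- function(stage3, annotations, affected, de,
                                fragment_map, capture_counts,
                                top_k = Inf, capture_min = NULL,
                                stage1 = NULL, differential_bait_ids = NULL,
                                case_annotations = NULL) {
  baits <- fragment_map[fragment_map$is_bait, , drop = FALSE]
  bait_genes <- .split_gene_ids(baits$gene_ids)
  gene2bait <- data.frame(
    gene_id = unlist(bait_genes),
    bait_id = rep(baits$frag_id, lengths(bait_genes)),
    stringsAsFactors = FALSE)

  # per-bait enhancer evidence within STAGE 3
  enh3 <- unique(annotations$interactions$bait_id[
    vapply(annotations$labels, function(l)
      any(l %in% .ENHANCER_CLASSES), TRUE)])

  genes_all <- unique(c(de$gene_id, affected))
  bl <- lapply(genes_all, function(g)
    gene2bait$bait_id[gene2bait$gene_id == g])
  di <- match(genes_all, de$gene_id)
  upreg <- !is.na(di) & de$upregulated[di]
  in_disrupted <- genes_all %in% affected
  in_stage3 <- vapply(bl, function(b)
    any(as.character(b) %in% stage3$bait_ids), TRUE)
  loop3 <- vapply(bl, function(b) any(b %in% enh3), TRUE)
  capture <- vapply(bl, function(b) {
    cc <- capture_counts[as.character(b)]
    if (all(is.na(cc))) 0L else as.integer(sum(cc, na.rm = TRUE))
  }, 0L)

  selected <- in_disrupted & upreg & in_stage3 & loop3
  rep_df <- data.frame(gene_id = genes_all[selected],
                       capture_count = capture[selected],
                       has_enhancer_loop = rep(TRUE, sum(selected)),
                       in_disrupted_tad = rep(TRUE, sum(selected)),
                       log2fc = de$log2fc[di[selected]],
                       fdr = de$fdr[di[selected]],
                       stringsAsFactors = FALSE)
  if (!is.null(capture_min))
    rep_df <- rep_df[rep_df$capture_count >= capture_min, , drop = FALSE]
  ord <- order(-rep_df$capture_count, -rep_df$log2fc, rep_df$gene_id)
  rep_df <- rep_df[ord, , drop = FALSE]
  if (is.finite(top_k)) rep_df <- utils::head(rep_df, top_k)
  rep_df$rank <- seq_len(nrow(rep_df))
  rownames(rep_df) <- NULL

  # independent criterion flags for elimination attribution
  capture_ok <- if (!is.null(stage1)) vapply(bl, function(b)
    any(as.character(b) %in% stage1$bait_ids), TRUE) else in_stage3
  differential_ok <- if (!is.null(differential_bait_ids)) vapply(bl,
    function(b) any(as.character(b) %in%
                      as.character(differential_bait_ids)), TRUE)
    else in_stage3
  loop_ok <- if (!is.null(case_annotations)) {
    enh_all <- unique(case_annotations$interactions$bait_id[
      vapply(case_annotations$labels, function(l)
        any(l %in% .ENHANCER_CLASSES), TRUE)])
    vapply(bl, function(b) any(b %in% enh_all), TRUE)
  } else loop3
  diag <- data.frame(gene_id = genes_all,
                     capture_ok = capture_ok,
                     differential_ok = differential_ok,
                     enhancer_loop_ok = loop_ok,
                     disrupted_tad_ok = in_disrupted,
                     upregulated_ok = upreg,
                     capture_count = capture,
                     selected = genes_all %in% rep_df$gene_id,
                     stringsAsFactors = FALSE)
  crit <- c(high_capture = "capture_ok", differential = "differential_ok",
            enhancer_loop = "enhancer_loop_ok",
            disrupted_tad = "disrupted_tad_ok",
            upregulated = "upregulated_ok")
  diag$violated <- apply(diag[, crit], 1L, function(row)
    paste(names(crit)[!row], collapse = ","))
  attr(rep_df, "diagnostics") <- diag
  attr(rep_df, "elimination_summary") <-
    vapply(crit, function(cn) sum(!diag[[cn]]), 0L)
  rep_df
}

#' Write the target-gene report and a run manifest
#'
#' Writes a TSV of target-gene reports plus a JSON manifest (parameters,
#' seed, per-stage record counts and MD5 digests of any input files)
#' sufficient to reproduce the run.
#'
#' @param report Report from [select_target_genes()].
#' @param stages Named list of `stage_result`s (e.g. STAGE1..3).
#' @param path Output TSV path; the manifest is written next to it with a
#'   `.manifest.json` suffix.
#' @param params List of parameters used for the run.
#' @param input_paths Character vector of input file paths to digest.
#' @param seed Seed used for the run (if any).
#' @return Invisibly, the manifest as a list.
#' @export
write_report <- function(report, stages = list(), path,
                         params = list(), input_paths = character(0),
                         seed = NULL) {
  cols <- c("gene_id", "capture_count", "has_enhancer_loop",
            "in_disrupted_tad", "log2fc", "fdr", "rank")
  out <- report[, cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  digests <- if (length(input_paths))
    as.list(tools::md5sum(input_paths)) else list()
  manifest <- list(
    params = params,
    seed = seed,
    n_targets = nrow(report),
    stage_counts = lapply(stages, function(s)
      list(baits = length(s$bait_ids),
           interactions_case = nrow(s$interactions_case),
           interactions_control = nrow(s$interactions_control))),
    input_md5 = digests)
  mpath <- paste0(sub("\\.tsv$", "", path), ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read back a target-gene report TSV
#'
#' @param path Report TSV path.
#' @return Data frame of target-gene reports.
#' @export
read_target_report <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character"))
}
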
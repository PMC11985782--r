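# End-to-end orchestration: significance filtering, staged bait cascade,
# TAD classification, cCRE annotation and target-gene selection, runnable
# on in-memory objects or on a directory of exported files.

#' Pipeline parameter set
#'
#' All thresholds of the integrative analysis in one list.  Defaults mirror
#' common capture Hi-C practice: significance score >= 5 and >= 10 kb
#' separation for promoter-interacting regions, differential score > 5
#' within a 500-kb window of the bait, a STAGE 1 bait-count difference of
#' at least 10, and DE significance at FDR <= 0.05.  A YAML file with any
#' subset of these names can override them, and `...` overrides both.
#'
#' @param config_path Optional YAML file of parameter overrides.
#' @param ... Named parameter overrides.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(config_path = NULL, ...) {
  params <- list(score_min = 5, min_distance = 10000,
                 diff_window = 500000, diff_threshold = 5,
                 library_norm = TRUE, min_diff = 10, nonzero = "either",
                 fdr_max = 0.05, gene_in_tad = "tss",
                 require_de_gene = FALSE, top_k = Inf, capture_min = NULL)
  if (!is.null(config_path)) {
    over <- yaml::read_yaml(config_path)
    unknown <- setdiff(names(over), names(params))
    if (length(unknown))
      stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
    params[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  params[names(dots)] <- dots
  params
}

#' Run the full target-gene pipeline
#'
#' Filters both interaction tables for significant distal interactions,
#' computes per-bait capture counts and the STAGE 1 count-difference
#' filter, scores differential interactions within the bait window, pairs
#' and classifies TADs by gene-content equality, extracts TAD-affected
#' genes and their baits, applies STAGE 2/3, annotates STAGE 3 other ends
#' with cCRE classes and selects ranked target genes.
#'
#' @param genes Gene table.
#' @param fragment_map Fragment map.
#' @param interactions_case,interactions_control Raw interaction tables.
#' @param tads_case,tads_control Per-condition TAD sets.
#' @param ccres cCRE track.
#' @param de DE table (`gene_id`, `log2fc`, `fdr`).
#' @param params List from [pipeline_params()].
#' @return List with the filtered tables, capture counts, stage results,
#'   differentials, TAD classifications, affected genes, annotations and
#'   the final `report` (see [select_target_genes()]).
#' @export
run_target_pipeline <- function(genes, fragment_map,
                                interactions_case, interactions_control,
                                tads_case, tads_control, ccres, de,
                                params = pipeline_params()) {
  de <- annotate_de_table(de, fdr_max = params$fdr_max)
  fcase <- filter_significant(interactions_case, params$score_min,
                              params$min_distance)
  fctrl <- filter_significant(interactions_control, params$score_min,
                              params$min_distance)
  counts_case <- per_bait_counts(fcase)
  counts_ctrl <- per_bait_counts(fctrl)
  stage1 <- stage1_filter(counts_case, counts_ctrl, fcase, fctrl,
                          min_diff = params$min_diff,
                          nonzero = params$nonzero)
  diffs <- differential_score(interactions_case, interactions_control,
                              library_norm = params$library_norm,
                              diff_threshold = params$diff_threshold)
  diffs <- window_filter(diffs, params$diff_window)
  differential_baits <- unique(diffs$bait_id[diffs$significant])

  pairs <- pair_tads(tads_case, tads_control)
  ga <- assign_genes_to_tads(genes, tads_case, mode = params$gene_in_tad)
  gb <- assign_genes_to_tads(genes, tads_control, mode = params$gene_in_tad)
  cls <- classify_tad_pairs(pairs, ga, gb,
                            require_de_gene = params$require_de_gene,
                            de_genes = de$gene_id[de$significant])
  affected <- affected_genes(cls, genes)
  affected_baits <- baits_for_genes(affected, fragment_map)

  stage2 <- stage2_filter(stage1, differential_baits)
  stage3 <- stage3_filter(stage2, affected_baits)
  ann3 <- annotate_other_ends(stage3$interactions_case, ccres)
  ann_case <- annotate_other_ends(fcase, ccres)
  report <- select_target_genes(stage3, ann3, affected, de, fragment_map,
                                counts_case, top_k = params$top_k,
                                capture_min = params$capture_min,
                                stage1 = stage1,
                                differential_bait_ids = differential_baits,
                                case_annotations = ann_case)
  list(filtered = list(case = fcase, control = fctrl),
       capture_counts = list(case = counts_case, control = counts_ctrl),
       stage1 = stage1, stage2 = stage2, stage3 = stage3,
       differentials = diffs, differential_baits = differential_baits,
       classifications = cls, affected = affected,
       annotations = ann3, report = report, params = params)
}

#' Run the pipeline on a synthetic world
#'
#' @param world A `synthetic_world` from [simulate_world()].
#' @param params List from [pipeline_params()].
#' @return As [run_target_pipeline()].
#' @export
run_world_pipeline <- function(world, params = pipeline_params()) {
  run_target_pipeline(world$genes, world$fragment_map,
                      world$interactions_by_condition$case,
                      world$interactions_by_condition$control,
                      world$tads_by_condition$case,
                      world$tads_by_condition$control,
                      world$ccres, world$de_table, params)
}

#' Run the pipeline on a directory of exported files
#'
#' Reads the file layout written by [export_world()] and runs
#' [run_target_pipeline()]; a fresh run on exported files reproduces the
#' in-memory results.
#'
#' @param dir Directory holding the exported world.
#' @param params List from [pipeline_params()].
#' @return As [run_target_pipeline()].
#' @export
run_pipeline_dir <- function(dir, params = pipeline_params()) {
  p <- function(...) file.path(dir, ...)
  genes <- read_gene_table(p("genes.tsv"), format = "bed_tsv")
  fragment_map <- read_fragment_map(p("fragments.tsv"))
  read_tads <- function(cond) {
    bed <- read_bed(p(sprintf("tads_%s.bed", cond)))
    data.frame(tad_id = bed$name, chrom = bed$chrom, start = bed$start,
               end = bed$end, condition = cond, stringsAsFactors = FALSE)
  }
  run_target_pipeline(genes, fragment_map,
                      read_interactions(p("interactions_case.ibed"), "ibed"),
                      read_interactions(p("interactions_control.ibed"), "ibed"),
                      read_tads("case"), read_tads("control"),
                      read_ccre_bed(p("ccres.bed")),
                      read_de_table(p("de_table.tsv")),
                      params)
}
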
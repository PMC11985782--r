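# Seeded synthetic-data generator: genomes, fragment maps, TAD sets with
# planted boundary shifts, promoter-capture interaction tables with planted
# enhancer-promoter loops, cCRE tracks, DE tables and contact matrices, all
# with recorded ground truth so every pipeline stage is testable offline.

#' Simulation configuration
#'
#' Defaults describe a two-chromosome, 10-Mb-per-chromosome desk-scale
#' genome with 10 TADs per chromosome at 20-kb bins, 10-kb restriction
#' fragments, a power-law distance decay of expected contact counts and a
#' mildly overdispersed negative-binomial count model.  Planted
#' enhancer-promoter loops multiply expected counts by `loop_fold` in the
#' case condition; planted boundary shifts move at least one gene between
#' adjacent domains.
#'
#' @param seed Integer seed; the whole world is deterministic given it.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome (bp).
#' @param bin_size Contact-matrix bin size (bp).
#' @param n_genes Total number of genes (including planted ones).
#' @param frac_protein_coding Fraction of protein-coding genes.
#' @param n_tads Total number of TADs across chromosomes.
#' @param frac_disrupted Fraction of TAD pairs given boundary shifts.
#' @param shift_bp Boundary displacement magnitude (bp, multiple of
#'   `bin_size`).
#' @param n_fragments Total restriction fragments (tiling all chromosomes).
#' @param frac_bait Target fraction of fragments flagged as baits.
#' @param mean_reads Negative-binomial mean count at the 50-kb reference
#'   distance.
#' @param nb_dispersion NB dispersion phi (variance `mu + phi mu^2`).
#' @param decay_exponent Power-law exponent of distance decay.
#' @param loop_fold Count multiplier at planted loops in the case
#'   condition (>= 1; 1 plants statistically null loops).
#' @param n_planted_targets Genes planted to satisfy all four selection
#'   criteria.
#' @param n_decoys Decoy genes, each violating exactly one criterion
#'   (types cycle through no_loop, conserved_tad, not_upregulated,
#'   low_capture).
#' @param n_loops_per_target Planted loops per target bait.
#' @param oe_per_bait Candidate other ends sampled per bait.
#' @param target_log2fc log2 fold change given to planted targets.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L,
                              chrom_length_bp = 1e7, bin_size = 2e4,
                              n_genes = 120L, frac_protein_coding = 0.5,
                              n_tads = 20L, frac_disrupted = 0.3,
                              shift_bp = 1e5, n_fragments = 2000L,
                              frac_bait = 0.15, mean_reads = 50,
                              nb_dispersion = 0.05, decay_exponent = 1,
                              loop_fold = 4, n_planted_targets = 5L,
                              n_decoys = 4L, n_loops_per_target = 15L,
                              oe_per_bait = 30L, target_log2fc = 2) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = chrom_length_bp, bin_size = bin_size,
              n_genes = as.integer(n_genes),
              frac_protein_coding = frac_protein_coding,
              n_tads = as.integer(n_tads), frac_disrupted = frac_disrupted,
              shift_bp = shift_bp, n_fragments = as.integer(n_fragments),
              frac_bait = frac_bait, mean_reads = mean_reads,
              nb_dispersion = nb_dispersion,
              decay_exponent = decay_exponent, loop_fold = loop_fold,
              n_planted_targets = as.integer(n_planted_targets),
              n_decoys = as.integer(n_decoys),
              n_loops_per_target = as.integer(n_loops_per_target),
              oe_per_bait = as.integer(oe_per_bait),
              target_log2fc = target_log2fc)
  for (f in c("frac_protein_coding", "frac_disrupted", "frac_bait"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  if (cfg$loop_fold < 1) stop("loop_fold must be >= 1")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$shift_bp %% cfg$bin_size != 0)
    stop("shift_bp must be a multiple of bin_size")
  if (cfg$chrom_length_bp %% cfg$bin_size != 0)
    stop("chrom_length_bp must be a multiple of bin_size")
  if (cfg$n_tads %% cfg$n_chroms != 0)
    stop("n_tads must be divisible by n_chroms")
  tads_per_chrom <- cfg$n_tads / cfg$n_chroms
  min_span <- max(3 * cfg$shift_bp, 8 * cfg$bin_size)
  if (tads_per_chrom * min_span > cfg$chrom_length_bp)
    stop("infeasible config: shift_bp too large for the TAD spans ",
         "(need ", tads_per_chrom, " TADs of at least ", min_span, " bp)")
  n_shifts_max <- max(0, tads_per_chrom - 1)
  cfg$min_span_bp <- min_span
  n_planted <- cfg$n_planted_targets + cfg$n_decoys + cfg$n_chroms * n_shifts_max
  if (cfg$n_genes < n_planted + 10L)
    stop("n_genes too small for the planted gene layout")
  structure(cfg, class = "simulation_config")
}

# internal: random TAD partition of one chromosome; returns boundary
# positions (bp, excluding 0 and L), all at bin multiples, min span kept
.sample_tad_cuts <- function(L, bin, n_tads, min_span) {
  if (n_tads == 1L) return(numeric(0))
  nbins <- L / bin
  min_bins <- ceiling(min_span / bin)
  extra <- nbins - n_tads * min_bins
  add <- as.vector(stats::rmultinom(1, extra, rep(1, n_tads)))
  spans <- (min_bins + add) * bin
  cumsum(spans)[seq_len(n_tads - 1L)]
}

#' Simulate a contact matrix with planted TAD boundaries
#'
#' Expected counts are `background` everywhere plus `within - background`
#' inside each TAD block defined by the boundary cut positions; optional
#' Poisson noise is applied to the upper triangle and mirrored.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length (bp).
#' @param bin_size Bin width (bp).
#' @param cuts Boundary positions in bp (multiples of `bin_size`).
#' @param within,background Expected within-TAD and background counts.
#' @param noise `"none"` or `"poisson"`.
#' @return A `contact_matrix`.
#' @export
simulate_contact_matrix <- function(chrom, chrom_length, bin_size, cuts,
                                    within = 10, background = 1,
                                    noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  n <- chrom_length / bin_size
  block <- findInterval(seq_len(n) - 0.5, cuts / bin_size)
  same <- outer(block, block, "==")
  mu <- matrix(background, n, n)
  mu[same] <- within
  if (noise == "none") return(contact_matrix(chrom, bin_size, mu))
  counts <- matrix(0, n, n)
  upper <- upper.tri(counts, diag = TRUE)
  counts[upper] <- stats::rpois(sum(upper), mu[upper])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(chrom, bin_size, counts)
}

# internal: NB-based significance score against the no-loop expectation
.nb_score <- function(count, mu0, size) {
  p <- stats::pnbinom(count - 1, mu = mu0, size = size, lower.tail = FALSE)
  pmin(-log10(pmax(p, 1e-300)), 300)
}

#' Simulate a complete synthetic world with planted ground truth
#'
#' Generates a genome annotation, a tiling fragment map with promoter
#' baits, per-condition TAD sets where a run of consecutive boundaries is
#' shifted by `shift_bp` in the control condition (moving one planted
#' "mover" gene per shifted boundary between domains), per-condition
#' interaction tables with distance-decaying negative-binomial counts and
#' planted enhancer-promoter loops (case-condition counts multiplied by
#' `loop_fold`; significance scores are the upper-tail probability of each
#' count under the no-loop expectation, so planted loops reliably score at
#' least 5 at the default fold), a cCRE track with dELS elements at planted
#' loop other ends, a DE table with planted upregulation, and per-condition
#' contact matrices (block-diagonal over each condition's TADs plus Poisson
#' noise).
#'
#' Planted targets satisfy all four selection criteria by construction;
#' each decoy violates exactly one (`no_loop`: loops without enhancer
#' elements, `conserved_tad`: placed in a conserved pair, `not_upregulated`:
#' negative fold change, `low_capture`: only 3 planted loops).
#'
#' @param config A `simulation_config`.
#' @return A `synthetic_world` list: `config`, `genes`, `fragment_map`,
#'   `tads_by_condition` (case/control), `interactions_by_condition`,
#'   `ccres`, `de_table`, `contact_matrices`, `truth`.
#' @export
simulate_world <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  L <- config$chrom_length_bp
  bin <- config$bin_size
  tads_per_chrom <- config$n_tads / config$n_chroms

  # --- TAD layout with a run of consecutive shifted boundaries ---------
  cuts_case <- lapply(chroms, function(ch)
    .sample_tad_cuts(L, bin, tads_per_chrom, config$min_span_bp))
  names(cuts_case) <- chroms
  n_disr_per_chrom <- round(config$frac_disrupted * tads_per_chrom)
  shifts <- list()  # per chrom: indices of shifted cuts
  cuts_ctrl <- cuts_case
  for (ch in chroms) {
    D <- n_disr_per_chrom
    nb <- length(cuts_case[[ch]])
    if (D <= 0 || nb == 0) { shifts[[ch]] <- integer(0); next }
    run_len <- if (D >= tads_per_chrom) nb else max(1L, D - 1L)
    s <- if (nb - run_len + 1L > 1L)
      sample.int(nb - run_len + 1L, 1L) else 1L
    idx <- s:(s + run_len - 1L)
    shifts[[ch]] <- idx
    cuts_ctrl[[ch]][idx] <- cuts_case[[ch]][idx] + config$shift_bp
  }
  mk_tads <- function(cuts, cond) do.call(rbind, lapply(chroms, function(ch)
    boundaries_to_tads(data.frame(chrom = ch, start = cuts[[ch]],
                                  end = cuts[[ch]] + bin,
                                  stringsAsFactors = FALSE),
                       ch, L, cond)))
  tads_case <- mk_tads(cuts_case, "case")
  tads_ctrl <- mk_tads(cuts_ctrl, "control")

  # disrupted pairs: TADs flanking any shifted boundary
  disrupted_idx <- list()
  for (ch in chroms) {
    idx <- shifts[[ch]]
    disrupted_idx[[ch]] <- if (length(idx))
      sort(unique(c(idx, idx + 1L))) else integer(0)
  }
  tad_id_of <- function(ch, i) sprintf("case_%s_tad%02d", ch, i)
  disrupted_tads <- unlist(lapply(chroms, function(ch)
    vapply(disrupted_idx[[ch]], function(i) tad_id_of(ch, i), "")))
  conserved_tads <- setdiff(tads_case$tad_id, disrupted_tads)

  # shift windows: [cut, cut + shift) on each shifted boundary
  shift_windows <- do.call(rbind, lapply(chroms, function(ch) {
    idx <- shifts[[ch]]
    if (!length(idx)) return(NULL)
    data.frame(chrom = ch, start = cuts_case[[ch]][idx],
               end = cuts_case[[ch]][idx] + config$shift_bp,
               stringsAsFactors = FALSE)
  }))

  # --- genes -----------------------------------------------------------
  # uniform draw from [a, b] without materializing the range
  runif_int <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L
  frags_per_chrom <- config$n_fragments %/% config$n_chroms
  frag_len <- floor(L / frags_per_chrom)
  used_frags <- character(0)  # fragments hosting a planted gene TSS
  gene_rows <- list()
  next_gene <- 1L
  add_gene <- function(chrom, tss, role) {
    id <- sprintf("G%04d", next_gene)
    next_gene <<- next_gene + 1L
    len <- sample(2000:20000, 1L)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") { start <- tss; end <- min(tss + len, L) }
    else { end <- tss + 1; start <- max(end - len, 0) }
    gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
      gene_id = id, symbol = paste0("GENE", sub("^G", "", id)),
      chrom = chrom, start = start, end = end, strand = strand,
      biotype = NA_character_, role = role, stringsAsFactors = FALSE)
    id
  }
  # movers: one gene inside each shift window
  mover_ids <- character(0)
  if (!is.null(shift_windows)) for (k in seq_len(nrow(shift_windows))) {
    tss <- runif_int(shift_windows$start[k] + 1000,
                     shift_windows$end[k] - 1000)
    mover_ids <- c(mover_ids, add_gene(shift_windows$chrom[k], tss, "mover"))
  }
  in_shift_window <- function(chrom, pos) {
    if (is.null(shift_windows)) return(FALSE)
    any(shift_windows$chrom == chrom & pos >= shift_windows$start &
          pos < shift_windows$end)
  }
  # place a gene inside a given case TAD, away from shift windows, domain
  # edges (so it stays in the paired TAD under both conditions) and on a
  # fragment not already hosting another planted gene (so planted genes
  # never share a bait)
  place_in_tad <- function(tad_id, role) {
    row <- tads_case[tads_case$tad_id == tad_id, ]
    repeat {
      tss <- runif_int(row$start + config$shift_bp + 1000,
                       row$end - config$shift_bp - 1000)
      frag_key <- paste(row$chrom, tss %/% frag_len)
      if (!in_shift_window(row$chrom, tss) &&
          !frag_key %in% used_frags) break
    }
    used_frags <<- c(used_frags, frag_key)
    add_gene(row$chrom, tss, role)
  }
  decoy_types <- rep(c("no_loop", "conserved_tad", "not_upregulated",
                       "low_capture"), length.out = config$n_decoys)
  pick_tads <- function(pool, n) {
    if (!length(pool)) pool <- tads_case$tad_id
    rep(pool, length.out = n)
  }
  target_homes <- pick_tads(disrupted_tads, config$n_planted_targets)
  target_ids <- vapply(seq_len(config$n_planted_targets), function(i)
    place_in_tad(target_homes[i], "target"), "")
  decoy_ids <- character(config$n_decoys)
  for (i in seq_len(config$n_decoys)) {
    home_pool <- if (decoy_types[i] == "conserved_tad")
      conserved_tads else disrupted_tads
    if (!length(home_pool)) home_pool <- tads_case$tad_id
    # rotate past the target homes so decoys sit in their own TADs where
    # the pool allows it
    home <- home_pool[(config$n_planted_targets + i - 1L) %%
                        length(home_pool) + 1L]
    decoy_ids[i] <- place_in_tad(home, decoy_types[i])
  }
  # background genes
  n_bg <- config$n_genes - length(gene_rows)
  for (k in seq_len(max(0L, n_bg))) {
    repeat {
      ch <- sample(chroms, 1L)
      tss <- runif_int(25000, L - 25000)
      # keep background promoters off planted-gene fragments so planted
      # baits carry exactly their planted gene
      if (!in_shift_window(ch, tss) &&
          !paste(ch, tss %/% frag_len) %in% used_frags &&
          !any(abs(tss - cuts_case[[ch]]) < 2000) &&
          !any(abs(tss - cuts_ctrl[[ch]]) < 2000)) break
    }
    add_gene(ch, tss, "background")
  }
  genes <- do.call(rbind, gene_rows)
  genes$biotype <- ifelse(
    stats::runif(nrow(genes)) < config$frac_protein_coding, "protein_coding",
    sample(c("lncRNA", "snoRNA", "miRNA", "pseudogene", "other_noncoding"),
           nrow(genes), replace = TRUE))
  roles <- stats::setNames(genes$role, genes$gene_id)
  genes$role <- NULL

  # --- fragment map ----------------------------------------------------
  fragment_map <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    starts <- (seq_len(frags_per_chrom) - 1L) * frag_len
    ends <- c(starts[-1], L)
    data.frame(frag_id = (ci - 1L) * frags_per_chrom +
                 seq_len(frags_per_chrom),
               chrom = chroms[ci], start = starts, end = ends,
               is_bait = FALSE, gene_ids = "", stringsAsFactors = FALSE)
  }))
  tss <- gene_tss(genes)
  for (g in seq_len(nrow(genes))) {
    i <- which(fragment_map$chrom == genes$chrom[g] &
                 fragment_map$start <= tss[g] & tss[g] < fragment_map$end)
    fragment_map$is_bait[i] <- TRUE
    fragment_map$gene_ids[i] <- paste(c(
      .split_gene_ids(fragment_map$gene_ids[i])[[1]], genes$gene_id[g]),
      collapse = ";")
  }
  n_bait_target <- ceiling(config$frac_bait * nrow(fragment_map))
  extra <- n_bait_target - sum(fragment_map$is_bait)
  if (extra > 0) {
    pool <- which(!fragment_map$is_bait)
    fragment_map$is_bait[sample(pool, min(extra, length(pool)))] <- TRUE
  }
  gene_bait <- stats::setNames(
    vapply(genes$gene_id, function(g)
      baits_for_genes(g, fragment_map)[1], 0L), genes$gene_id)

  # --- interactions with planted loops ---------------------------------
  size <- 1 / config$nb_dispersion
  mid <- .midpoint(fragment_map$start, fragment_map$end)
  loop_rows <- list()
  pair_rows <- list()
  loop_counts <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  loop_counts[target_ids] <- config$n_loops_per_target
  for (i in seq_len(config$n_decoys)) {
    loop_counts[decoy_ids[i]] <-
      if (decoy_types[i] == "low_capture") 3L else config$n_loops_per_target
  }
  bait_idx <- which(fragment_map$is_bait)
  for (b in bait_idx) {
    bid <- fragment_map$frag_id[b]
    ch <- fragment_map$chrom[b]
    same <- which(fragment_map$chrom == ch & fragment_map$frag_id != bid)
    d <- abs(mid[same] - mid[b])
    cand_far <- same[d >= 15000 & d <= 600000]
    cand_near <- same[d >= 15000 & d <= 120000]
    genes_here <- .split_gene_ids(fragment_map$gene_ids[b])[[1]]
    n_loops <- if (length(genes_here)) max(loop_counts[genes_here]) else 0L
    n_loops <- min(n_loops, length(cand_near))
    loop_oe <- if (n_loops > 0)
      sample(cand_near, n_loops) else integer(0)
    n_rest <- max(0L, config$oe_per_bait - length(loop_oe))
    rest_pool <- setdiff(cand_far, loop_oe)
    rest <- if (n_rest > 0 && length(rest_pool))
      sample(rest_pool, min(n_rest, length(rest_pool))) else integer(0)
    oe <- c(loop_oe, rest)
    if (!length(oe)) next
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      b = b, o = oe, is_loop = oe %in% loop_oe, stringsAsFactors = FALSE)
    if (length(loop_oe))
      loop_rows[[length(loop_rows) + 1L]] <- data.frame(
        bait_id = bid, oe_id = fragment_map$frag_id[loop_oe],
        gene_id = if (length(genes_here))
          genes_here[which.max(loop_counts[genes_here])] else NA_character_,
        stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  planted_loops <- if (length(loop_rows)) do.call(rbind, loop_rows) else
    data.frame(bait_id = integer(0), oe_id = integer(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  d <- abs(mid[pairs$o] - mid[pairs$b])
  mu0 <- config$mean_reads * (d / 5e4)^(-config$decay_exponent)
  mk_table <- function(mu) {
    counts <- stats::rnbinom(length(mu), mu = mu, size = size)
    data.frame(bait_id = fragment_map$frag_id[pairs$b],
               oe_id = fragment_map$frag_id[pairs$o],
               bait_chrom = fragment_map$chrom[pairs$b],
               bait_start = fragment_map$start[pairs$b],
               bait_end = fragment_map$end[pairs$b],
               oe_chrom = fragment_map$chrom[pairs$o],
               oe_start = fragment_map$start[pairs$o],
               oe_end = fragment_map$end[pairs$o],
               n_reads = counts,
               score = .nb_score(counts, mu0, size),
               stringsAsFactors = FALSE)
  }
  int_case <- mk_table(ifelse(pairs$is_loop, mu0 * config$loop_fold, mu0))
  int_ctrl <- mk_table(mu0)

  # --- cCRE track ------------------------------------------------------
  no_loop_genes <- decoy_ids[decoy_types == "no_loop"]
  no_loop_baits <- fragment_map$frag_id[fragment_map$is_bait &
    vapply(.split_gene_ids(fragment_map$gene_ids),
           function(g) any(g %in% no_loop_genes), TRUE)]
  no_loop_oes <- planted_loops$oe_id[planted_loops$bait_id %in% no_loop_baits]
  enhancer_loops <- planted_loops[!planted_loops$bait_id %in% no_loop_baits &
                                    !planted_loops$oe_id %in% no_loop_oes, ,
                                  drop = FALSE]
  loop_oe_idx <- match(unique(enhancer_loops$oe_id), fragment_map$frag_id)
  ccre_loop <- if (length(loop_oe_idx)) data.frame(
    chrom = fragment_map$chrom[loop_oe_idx],
    start = mid[loop_oe_idx] - 400, end = mid[loop_oe_idx] + 400,
    ccre_class = "dELS", stringsAsFactors = FALSE) else NULL
  forbidden <- fragment_map[fragment_map$frag_id %in% no_loop_oes, ,
                            drop = FALSE]
  n_bg_ccre <- 150L
  bg_rows <- list()
  while (length(bg_rows) < n_bg_ccre) {
    ch <- sample(chroms, 1L)
    s <- sample.int(L - 2000, 1L)
    w <- sample(200:1000, 1L)
    if (nrow(forbidden) && any(forbidden$chrom == ch &
                               s < forbidden$end & s + w > forbidden$start))
      next
    bg_rows[[length(bg_rows) + 1L]] <- data.frame(
      chrom = ch, start = s, end = s + w,
      ccre_class = sample(.CCRE_CLASSES, 1L), stringsAsFactors = FALSE)
  }
  ccres <- rbind(ccre_loop, do.call(rbind, bg_rows))
  ccres <- ccres[order(ccres$chrom, ccres$start), , drop = FALSE]
  rownames(ccres) <- NULL

  # --- DE table --------------------------------------------------------
  lfc <- stats::rnorm(nrow(genes), 0, 0.8)
  fdr <- ifelse(stats::runif(nrow(genes)) < 0.3,
                stats::runif(nrow(genes), 0, 0.049),
                stats::runif(nrow(genes), 0.051, 1))
  de <- data.frame(gene_id = genes$gene_id, log2fc = lfc, fdr = fdr,
                   stringsAsFactors = FALSE)
  de$log2fc[de$gene_id %in% target_ids] <- config$target_log2fc
  de$fdr[de$gene_id %in% target_ids] <- 0.001
  for (i in seq_len(config$n_decoys)) {
    de$log2fc[de$gene_id == decoy_ids[i]] <-
      if (decoy_types[i] == "not_upregulated")
        -config$target_log2fc else config$target_log2fc
    de$fdr[de$gene_id == decoy_ids[i]] <- 0.001
  }
  de <- annotate_de_table(de)

  # --- contact matrices ------------------------------------------------
  contact_matrices <- list(
    case = stats::setNames(lapply(chroms, function(ch)
      simulate_contact_matrix(ch, L, bin, cuts_case[[ch]])), chroms),
    control = stats::setNames(lapply(chroms, function(ch)
      simulate_contact_matrix(ch, L, bin, cuts_ctrl[[ch]])), chroms))

  truth <- list(
    disrupted_tad_ids = disrupted_tads,
    conserved_tad_ids = conserved_tads,
    planted_target_gene_ids = target_ids,
    decoy_gene_ids = stats::setNames(decoy_ids, decoy_types),
    mover_gene_ids = mover_ids,
    planted_loops = planted_loops,
    boundary_cuts = list(case = cuts_case, control = cuts_ctrl),
    shifted_boundaries = shifts,
    gene_roles = roles,
    gene_bait = gene_bait)

  structure(list(config = config, genes = genes,
                 fragment_map = fragment_map,
                 tads_by_condition = list(case = tads_case,
                                          control = tads_ctrl),
                 interactions_by_condition = list(case = int_case,
                                                  control = int_ctrl),
                 ccres = ccres, de_table = de,
                 contact_matrices = contact_matrices, truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_world: %d chrom(s), %d genes, %d fragments,",
                     " %d TADs/condition, %d planted targets\n"),
              x$config$n_chroms, nrow(x$genes), nrow(x$fragment_map),
              nrow(x$tads_by_condition$case),
              length(x$truth$planted_target_gene_ids)))
  invisible(x)
}

#' Export a synthetic world to disk in the pipeline's external formats
#'
#' Writes `genes.tsv`, `fragments.tsv`, per-condition TAD BED4 files and
#' interaction tables (both ibed and chinput), `ccres.bed`, `de_table.tsv`,
#' per-chromosome/condition contact matrices and `truth.json`.  A fresh
#' pipeline run on these files reproduces the in-memory results.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_gene_table(world$genes, p("genes.tsv"))
  write_fragment_map(world$fragment_map, p("fragments.tsv"))
  for (cond in names(world$tads_by_condition)) {
    tt <- world$tads_by_condition[[cond]]
    write_bed(data.frame(chrom = tt$chrom, start = tt$start, end = tt$end,
                         name = tt$tad_id, stringsAsFactors = FALSE),
              p(sprintf("tads_%s.bed", cond)))
  }
  for (cond in names(world$interactions_by_condition)) {
    write_ibed(world$interactions_by_condition[[cond]],
               p(sprintf("interactions_%s.ibed", cond)))
    write_chinput(world$interactions_by_condition[[cond]],
                  p(sprintf("interactions_%s.chinput", cond)))
  }
  write_bed(data.frame(chrom = world$ccres$chrom, start = world$ccres$start,
                       end = world$ccres$end, name = world$ccres$ccre_class,
                       stringsAsFactors = FALSE), p("ccres.bed"))
  utils::write.table(
    data.frame(gene_id = world$de_table$gene_id,
               log2fc = sprintf("%.6g", world$de_table$log2fc),
               fdr = sprintf("%.6g", world$de_table$fdr)),
    p("de_table.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in names(world$contact_matrices))
    for (ch in names(world$contact_matrices[[cond]]))
      write_contact_matrix(world$contact_matrices[[cond]][[ch]],
                           p(sprintf("matrix_%s_%s.tsv", ch, cond)))
  truth <- world$truth
  truth$gene_roles <- as.list(truth$gene_roles)
  truth$gene_bait <- as.list(truth$gene_bait)
  truth$decoy_gene_ids <- as.list(truth$decoy_gene_ids)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
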
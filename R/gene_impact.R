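#' Region RPKM recovered from a coverage track
#'
#' `n = sum(per-base coverage) / fragment_len` is exactly the fractional
#' overlap count for constant-length fragments; RPKM follows.
#'
#' @param track coverage [signal_track()].
#' @param N total filtered library size.
#' @param chrom,start,end 0-based half-open region.
#' @param fragment_len fragment length that produced the track.
#' @return RPKM of the region.
#' @export
region_rpkm <- function(track, N, chrom, start, end, fragment_len = 150) {
  n <- sum(track_values(track, chrom, start, end)) / fragment_len
  rpkm(n, end - start, N)
}

#' Genome-wide median window RPKM (background reference level)
#'
#' Median RPKM over non-overlapping tiles of every chromosome in the
#' track; the scale-free reference against which "enriched" regions are
#' judged.
#'
#' @inheritParams region_rpkm
#' @param tile tile width in bp, default 1000.
#' @return median RPKM.
#' @export
genome_median_rpkm <- function(track, N, tile = 1000, fragment_len = 150) {
  vals <- unlist(lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    n_tiles <- floor(length(v) / tile)
    if (n_tiles == 0) return(numeric(0))
    sums <- IRanges::viewSums(
      IRanges::Views(v, IRanges::successiveIRanges(rep(tile, n_tiles))))
    rpkm(sums / fragment_len, tile, N)
  }))
  .assert(length(vals) > 0, "track too short for any tile")
  median(vals)
}

#' Pair polymorphic copies with nearby transcription start sites
#'
#' Distance is the number of bases strictly between the insertion interval
#' and the TSS (0 if the TSS falls inside or adjacent to the element);
#' pairs farther than `max_dist` are dropped.  A gene may pair with
#' several copies and vice versa.
#'
#' @param insertions `te_table` data.frame (caller restricts to
#'   polymorphic copies).
#' @param genes gene data.frame (see [read_genes()]).
#' @param max_dist maximum TSS distance in bp (inclusive), default 5000.
#' @return data.frame `copy_id`, `gene_id`, `tss_distance_bp`.
#' @export
tss_proximal_copies <- function(insertions, genes, max_dist = 5000) {
  empty <- data.frame(copy_id = character(), gene_id = character(),
                      tss_distance_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(insertions) == 0 || nrow(genes) == 0) return(empty)
  ins_gr <- GRanges(insertions$chrom,
                    IRanges(insertions$start + 1L, insertions$end))
  tss_gr <- GRanges(genes$chrom, IRanges(genes$tss + 1L, genes$tss + 1L))
  hits <- findOverlaps(ins_gr, tss_gr, maxgap = max_dist)
  if (length(hits) == 0) return(empty)
  d <- distance(ins_gr[queryHits(hits)], tss_gr[subjectHits(hits)])
  keep <- !is.na(d) & d <= max_dist
  out <- data.frame(copy_id = insertions$copy_id[queryHits(hits)[keep]],
                    gene_id = genes$gene_id[subjectHits(hits)[keep]],
                    tss_distance_bp = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$copy_id), , drop = FALSE]
}

#' Heterochromatin-enrichment filter for copy/gene pairs
#'
#' A pair is kept when, relative to `min_fold` times the genome-median
#' window RPKM of each line's track: the copy body is enriched in the
#' full-site line, the gene promoter (TSS +/- `promoter_halfwidth`) is
#' enriched in the full-site line, and the promoter is NOT enriched in the
#' empty-site line.
#'
#' @param pairs output of [tss_proximal_copies()].
#' @param insertions,genes lookup tables for coordinates.
#' @param track_full,track_empty coverage tracks from quality-filtered but
#'   UNmasked reads: detecting enrichment at the copy body itself needs
#'   the element-internal signal that TE masking would remove.
#' @param N_full,N_empty filtered library sizes.
#' @param promoter_halfwidth promoter half-width in bp, default 1000.
#' @param min_fold enrichment fold over genome median, default 2.
#' @param fragment_len fragment length of the tracks.
#' @return `pairs` rows passing the filter, with columns
#'   `copy_rpkm_full`, `promoter_rpkm_full`, `promoter_rpkm_empty`,
#'   `threshold_full`, `threshold_empty` appended.
#' @export
enrichment_filter <- function(pairs, insertions, genes, track_full,
                              track_empty, N_full, N_empty,
                              promoter_halfwidth = 1000, min_fold = 2.0,
                              fragment_len = 150) {
  if (nrow(pairs) == 0) return(cbind(pairs, copy_rpkm_full = numeric(0),
                                     promoter_rpkm_full = numeric(0),
                                     promoter_rpkm_empty = numeric(0),
                                     threshold_full = numeric(0),
                                     threshold_empty = numeric(0)))
  thr_full <- min_fold * genome_median_rpkm(track_full, N_full,
                                            fragment_len = fragment_len)
  thr_empty <- min_fold * genome_median_rpkm(track_empty, N_empty,
                                             fragment_len = fragment_len)
  ins <- insertions[match(pairs$copy_id, insertions$copy_id), ]
  gen <- genes[match(pairs$gene_id, genes$gene_id), ]
  vals <- t(vapply(seq_len(nrow(pairs)), function(i) {
    prom <- c(gen$tss[i] - promoter_halfwidth,
              gen$tss[i] + promoter_halfwidth)
    c(copy = region_rpkm(track_full, N_full, ins$chrom[i], ins$start[i],
                         ins$end[i], fragment_len),
      prom_full = region_rpkm(track_full, N_full, gen$chrom[i],
                              max(prom[1], 0), prom[2], fragment_len),
      prom_empty = region_rpkm(track_empty, N_empty, gen$chrom[i],
                               max(prom[1], 0), prom[2], fragment_len))
  }, numeric(3)))
  out <- pairs
  out$copy_rpkm_full <- vals[, "copy"]
  out$promoter_rpkm_full <- vals[, "prom_full"]
  out$promoter_rpkm_empty <- vals[, "prom_empty"]
  out$threshold_full <- thr_full
  out$threshold_empty <- thr_empty
  keep <- out$copy_rpkm_full >= thr_full &
    out$promoter_rpkm_full >= thr_full &
    out$promoter_rpkm_empty < thr_empty
  out[keep, , drop = FALSE]
}

#' Compare normalized gene expression between the two lines
#'
#' Ratio of per-gene expression RPKM, empty-site line over full-site line;
#' the flag is TRUE when expression is at least `min_ratio`-fold lower in
#' the insertion-carrying line.
#'
#' @param expr_full,expr_empty data.frames `gene_id`, `length_bp`, `count`
#'   (RNA-seq read counts per gene, one per line).
#' @param gene_id gene to compare.
#' @param min_ratio fold threshold, default 2.
#' @param N_full,N_empty library sizes (default: column sums).
#' @return list `ratio` (`NA` when both counts are zero, `Inf` when only
#'   the full-site line is zero) and `differentially_lower` flag.
#' @export
expression_compare <- function(expr_full, expr_empty, gene_id,
                               min_ratio = 2.0,
                               N_full = sum(expr_full$count),
                               N_empty = sum(expr_empty$count)) {
  i_f <- match(gene_id, expr_full$gene_id)
  i_e <- match(gene_id, expr_empty$gene_id)
  .assert(!is.na(i_f) && !is.na(i_e), "gene %s missing from counts", gene_id)
  cf <- expr_full$count[i_f]; ce <- expr_empty$count[i_e]
  if (cf == 0 && ce == 0) {
    warning("gene ", gene_id, " has zero counts in both lines")
    return(list(ratio = NA_real_, differentially_lower = FALSE))
  }
  r_full <- rpkm(cf, expr_full$length_bp[i_f], N_full)
  r_empty <- rpkm(ce, expr_empty$length_bp[i_e], N_empty)
  ratio <- if (r_full == 0) Inf else r_empty / r_full
  list(ratio = ratio, differentially_lower = ratio >= min_ratio)
}

#' Identify genes plausibly silenced by insertion-induced heterochromatin
#'
#' Composes, in order: (1) TSS proximity of polymorphic copies, (2)
#' heterochromatin enrichment at the copy and at the promoter in the
#' full-site line only, (3) lower normalized expression in the full-site
#' line.  Returns one row per surviving copy/gene pair with all
#' per-filter values, ordered by `gene_id`.
#'
#' @param insertions `te_table` (all copies; polymorphic ones are selected
#'   internally).
#' @param genes gene table (see [read_genes()]).
#' @param reads_full,reads_empty raw aligned reads per line (quality
#'   filtering and TE masking are applied internally).
#' @param expr_full,expr_empty per-gene expression count tables.
#' @param chrom_sizes named chromosome sizes.
#' @param config list overriding defaults: `max_dist` (5000),
#'   `promoter_halfwidth` (1000), `min_fold` (2), `min_expr_ratio` (2),
#'   `fragment_len` (150), `min_mapq` (7).
#' @return data.frame of candidates with per-filter provenance columns.
#' @export
run_gene_impact <- function(insertions, genes, reads_full, reads_empty,
                            expr_full, expr_empty, chrom_sizes,
                            config = list()) {
  cfg <- utils::modifyList(list(max_dist = 5000, promoter_halfwidth = 1000,
                                min_fold = 2.0, min_expr_ratio = 2.0,
                                fragment_len = 150, min_mapq = 7), config)
  poly <- insertions[insertions$status == "polymorphic", , drop = FALSE]
  pairs <- tss_proximal_copies(poly, genes, cfg$max_dist)

  rf <- filter_reads(reads_full, min_mapq = cfg$min_mapq)
  re <- filter_reads(reads_empty, min_mapq = cfg$min_mapq)
  N_full <- nrow(rf); N_empty <- nrow(re)
  tr_full <- build_coverage(rf, cfg$fragment_len, chrom_sizes)
  tr_empty <- build_coverage(re, cfg$fragment_len, chrom_sizes)

  enr <- enrichment_filter(pairs, insertions, genes, tr_full, tr_empty,
                           N_full, N_empty, cfg$promoter_halfwidth,
                           cfg$min_fold, cfg$fragment_len)
  if (nrow(enr) == 0) {
    enr$expr_full <- numeric(0); enr$expr_empty <- numeric(0)
    enr$expression_ratio <- numeric(0)
    return(enr)
  }
  keep <- logical(nrow(enr))
  ratio <- numeric(nrow(enr))
  for (i in seq_len(nrow(enr))) {
    cmp <- expression_compare(expr_full, expr_empty, enr$gene_id[i],
                              cfg$min_expr_ratio)
    ratio[i] <- cmp$ratio
    keep[i] <- cmp$differentially_lower
  }
  enr$expr_full <- expr_full$count[match(enr$gene_id, expr_full$gene_id)]
  enr$expr_empty <- expr_empty$count[match(enr$gene_id, expr_empty$gene_id)]
  enr$expression_ratio <- ratio
  out <- enr[keep, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
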
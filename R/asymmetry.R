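#' Reads per kilobase per million mapped reads
#'
#' `RPKM = n / (L_kb * N_millions)` where `n` is the (possibly fractional)
#' number of reads assigned to the region, `L_kb` the region length in kb,
#' and `N_millions` the total filtered library size in millions.
#'
#' @param n fractional read count(s) assigned to the region.
#' @param length_bp region length(s) in bp.
#' @param n_total total aligned, filtered reads in the library.
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(n, length_bp, n_total) {
  .assert(all(length_bp > 0), "zero-length region")
  .assert(all(n_total > 0), "zero library size")
  .assert(all(n >= 0), "negative read count")
  n / ((length_bp / 1000) * (n_total / 1e6))
}

#' RPKM asymmetry between two samples
#'
#' `(rpkm_a - rpkm_b) / (rpkm_a + rpkm_b + eps)`: bounded in \[-1, 1\],
#' 0 for equal enrichment, +1 when only sample A (the full-site line) is
#' enriched, -1 when only sample B is.  `eps` guards division by zero.
#'
#' @param rpkm_a,rpkm_b non-negative RPKM values (vectorized).
#' @param eps small positive constant, default 1e-9.
#' @return asymmetry value(s).
#' @export
rpkm_asymmetry <- function(rpkm_a, rpkm_b, eps = 1e-9) {
  .assert(all(rpkm_a >= 0) && all(rpkm_b >= 0), "negative RPKM")
  .assert(eps > 0, "eps must be > 0")
  (rpkm_a - rpkm_b) / (rpkm_a + rpkm_b + eps)
}

.window_label <- function(w1, w2) {
  kb <- function(x) sub("\\.?0+$", "", sprintf("%.3f", x / 1000))
  if (w1 == 0) paste0("<", kb(w2), "kb") else paste0(kb(w1), "-", kb(w2), "kb")
}

# Oriented flank regions of one copy for a distance band [w1, w2) from the
# element edge.  Returns data.frame chrom/start/end/side (0-based half-open).
.flank_band_regions <- function(insertion, w1, w2) {
  start <- as.integer(insertion$start); end <- as.integer(insertion$end)
  left <- c(start - w2, start - w1)
  right <- c(end + w1, end + w2)
  minus <- identical(as.character(insertion$strand), "-")
  data.frame(
    chrom = as.character(insertion$chrom),
    start = c(left[1], right[1]),
    end = c(left[2], right[2]),
    side = if (minus) c("three_prime", "five_prime")
           else c("five_prime", "three_prime"),
    stringsAsFactors = FALSE
  )
}

# Fractional (overlap-proportion) or 5'-containment read counts per region.
.count_reads_in_regions <- function(reads, regions, fragment_len,
                                    count_mode, chrom_sizes = NULL) {
  n_out <- numeric(nrow(regions))
  if (nrow(reads) == 0 || nrow(regions) == 0) return(n_out)
  # clamp to the chromosome; fully off-chromosome regions become
  # zero-width (they are flagged truncated upstream anyway)
  s <- pmax(regions$start, 0L)
  e <- pmax(regions$end, s)
  reg <- GRanges(regions$chrom, IRanges(s + 1L, e))
  if (count_mode == "five_prime") {
    pts <- GRanges(reads$chrom, IRanges(reads$pos5 + 1L, reads$pos5 + 1L))
    hits <- findOverlaps(pts, reg)
    tab <- tabulate(subjectHits(hits), nbins = nrow(regions))
    return(as.numeric(tab))
  }
  frags <- .fragments_granges(reads, fragment_len, chrom_sizes)
  hits <- findOverlaps(frags, reg)
  if (length(hits) == 0) return(n_out)
  ov <- width(pintersect(frags[queryHits(hits)], reg[subjectHits(hits)]))
  frac <- ov / width(frags[queryHits(hits)])
  agg <- rowsum(frac, group = subjectHits(hits))
  n_out[as.integer(rownames(agg))] <- agg[, 1]
  n_out
}

#' Windowed flank RPKM asymmetry across many copies
#'
#' For every insertion and every distance band of `scheme`, builds the
#' oriented flank window(s), counts reads per line (fractionally by
#' overlap proportion of the extended fragment, or by 5'-end containment),
#' computes per-line RPKM with each line's own library size, and the RPKM
#' asymmetry.  With `combine_sides = TRUE` (as in per-copy distribution
#' figures) both flanks are pooled into one region of twice the window
#' span; otherwise one record per side is returned.
#'
#' @param reads_a,reads_b filtered (and typically TE-masked) reads for the
#'   full-site line (A) and the empty-site line (B).
#' @param insertions `te_table` data.frame.
#' @param scheme list of `c(from, to)` distance bands in bp from the
#'   element edge; must be ordered and non-overlapping.  Default
#'   `list(c(0,1000), c(1000,2500), c(2500,5000))`.
#' @param N_a,N_b total filtered library sizes (defaults: rows of the read
#'   sets; pass pre-masking totals when masking was applied).
#' @param fragment_len fragment length for extension-based counting.
#' @param chrom_sizes optional named sizes; used to flag truncated windows.
#' @param combine_sides pool 5' and 3' flanks per copy (default TRUE).
#' @param count_mode `"fractional"` (default) or `"five_prime"`.
#' @param eps asymmetry epsilon.
#' @return data.frame of class `asymmetry_records`: `copy_id`,
#'   `window_label`, `side`, `n_a`, `n_b`, `rpkm_a`, `rpkm_b`,
#'   `asymmetry`, `eps`, `truncated`.  Truncated windows (off-chromosome)
#'   are flagged and excluded from downstream summaries.
#' @export
windowed_asymmetry <- function(reads_a, reads_b, insertions,
                               scheme = list(c(0, 1000), c(1000, 2500),
                                             c(2500, 5000)),
                               N_a = nrow(reads_a), N_b = nrow(reads_b),
                               fragment_len = 150, chrom_sizes = NULL,
                               combine_sides = TRUE,
                               count_mode = c("fractional", "five_prime"),
                               eps = 1e-9) {
  count_mode <- match.arg(count_mode)
  .assert(length(scheme) >= 1, "empty scheme")
  b <- do.call(rbind, scheme)
  .assert(all(b[, 2] > b[, 1]), "scheme windows must have positive span")
  if (nrow(b) > 1)
    .assert(all(b[-1, 1] >= b[-nrow(b), 2]) && !is.unsorted(b[, 1]),
            "scheme windows overlap or are unordered")
  empty <- data.frame(copy_id = character(), window_label = character(),
                      side = character(), n_a = numeric(), n_b = numeric(),
                      rpkm_a = numeric(), rpkm_b = numeric(),
                      asymmetry = numeric(), eps = numeric(),
                      truncated = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("asymmetry_records", "data.frame")
  if (nrow(insertions) == 0) return(empty)

  # enumerate regions: copy x window x side
  regs <- do.call(rbind, lapply(seq_len(nrow(insertions)), function(i) {
    do.call(rbind, lapply(seq_along(scheme), function(w) {
      r <- .flank_band_regions(insertions[i, ], scheme[[w]][1], scheme[[w]][2])
      r$copy_idx <- i; r$window_idx <- w
      r
    }))
  }))
  size <- if (is.null(chrom_sizes)) rep(NA_integer_, nrow(regs))
          else unname(chrom_sizes[regs$chrom])
  regs$truncated <- regs$start < 0 | (!is.na(size) & regs$end > size)

  regs$n_a <- .count_reads_in_regions(reads_a, regs, fragment_len,
                                      count_mode, chrom_sizes)
  regs$n_b <- .count_reads_in_regions(reads_b, regs, fragment_len,
                                      count_mode, chrom_sizes)

  if (combine_sides) {
    key <- paste(regs$copy_idx, regs$window_idx)
    agg <- do.call(rbind, lapply(split(regs, key), function(g) {
      data.frame(copy_idx = g$copy_idx[1], window_idx = g$window_idx[1],
                 side = "both", n_a = sum(g$n_a), n_b = sum(g$n_b),
                 len = sum(g$end - g$start), truncated = any(g$truncated),
                 stringsAsFactors = FALSE)
    }))
  } else {
    agg <- data.frame(copy_idx = regs$copy_idx, window_idx = regs$window_idx,
                      side = regs$side, n_a = regs$n_a, n_b = regs$n_b,
                      len = regs$end - regs$start, truncated = regs$truncated,
                      stringsAsFactors = FALSE)
  }
  agg <- agg[order(agg$copy_idx, agg$window_idx, agg$side), , drop = FALSE]
  out <- data.frame(
    copy_id = insertions$copy_id[agg$copy_idx],
    window_label = vapply(scheme, function(w) .window_label(w[1], w[2]),
                          character(1))[agg$window_idx],
    side = agg$side, n_a = agg$n_a, n_b = agg$n_b,
    rpkm_a = rpkm(agg$n_a, agg$len, N_a),
    rpkm_b = rpkm(agg$n_b, agg$len, N_b),
    stringsAsFactors = FALSE
  )
  out$asymmetry <- rpkm_asymmetry(out$rpkm_a, out$rpkm_b, eps)
  out$eps <- eps
  out$truncated <- agg$truncated
  rownames(out) <- NULL
  class(out) <- c("asymmetry_records", "data.frame")
  out
}

#' Flank RPKM asymmetry of a single copy at one distance band
#'
#' Convenience wrapper around [windowed_asymmetry()] for one insertion and
#' one window (default the first kilobase of flank, both sides pooled).
#'
#' @inheritParams windowed_asymmetry
#' @param insertion single-row `te_table`.
#' @param window `c(from, to)` distance band in bp.
#' @return single-row `asymmetry_records` data.frame.
#' @export
copy_flank_asymmetry <- function(reads_a, reads_b, insertion,
                                 window = c(0, 1000),
                                 N_a = nrow(reads_a), N_b = nrow(reads_b),
                                 fragment_len = 150, chrom_sizes = NULL,
                                 combine_sides = TRUE,
                                 count_mode = c("fractional", "five_prime"),
                                 eps = 1e-9) {
  windowed_asymmetry(reads_a, reads_b, insertion, scheme = list(window),
                     N_a = N_a, N_b = N_b, fragment_len = fragment_len,
                     chrom_sizes = chrom_sizes, combine_sides = combine_sides,
                     count_mode = match.arg(count_mode), eps = eps)
}

#' Write asymmetry records as TSV
#'
#' @param records `asymmetry_records` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asymmetry_records <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
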
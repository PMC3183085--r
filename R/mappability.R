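#' Mean mappability of a region
#'
#' Arithmetic mean of the per-base alignability values (fraction of reads
#' covering a base that align uniquely, in \[0,1\]) over a region.  Bases
#' absent from the track count as 0.
#'
#' @param track mappability [signal_track()].
#' @param chrom chromosome.
#' @param start,end 0-based half-open region (must be non-empty).
#' @return mean score in \[0, 1\].
#' @export
mean_mappability <- function(track, chrom, start, end) {
  .assert(end > start, "empty region")
  v <- track_values(track, chrom, start, end)
  .assert(all(v <= 1 + 1e-12), "mappability values must be <= 1")
  mean(v)
}

#' Flag/filter TE copies by mappability of body or flanks
#'
#' Scores each insertion by the mean mappability of its body or of its two
#' flanks pooled, and splits the table at `min_mean`.  Meant for flagging
#' low-confidence copies in summaries, not silent removal.
#'
#' @param insertions `te_table` data.frame.
#' @param track mappability [signal_track()].
#' @param region_selector `"body"` or `"flank"`.
#' @param min_mean minimum mean score to keep, default 0.5.
#' @param flank_len flank length used by the `"flank"` selector.
#' @return list with `kept` and `dropped` data.frames, each carrying
#'   `mean_score` and `kept` columns.
#' @export
filter_by_mappability <- function(insertions, track,
                                  region_selector = c("body", "flank"),
                                  min_mean = 0.5, flank_len = 5000) {
  region_selector <- match.arg(region_selector)
  score <- vapply(seq_len(nrow(insertions)), function(i) {
    ins <- insertions[i, ]
    if (region_selector == "body") {
      mean_mappability(track, ins$chrom, ins$start, ins$end)
    } else {
      v <- c(track_values(track, ins$chrom, ins$start - flank_len, ins$start),
             track_values(track, ins$chrom, ins$end, ins$end + flank_len))
      mean(v)
    }
  }, numeric(1))
  out <- insertions
  out$mean_score <- score
  out$kept <- score >= min_mean
  list(kept = out[out$kept, , drop = FALSE],
       dropped = out[!out$kept, , drop = FALSE])
}

#' Write mappability scores as TSV
#'
#' @param scored a data.frame from [filter_by_mappability()] (`kept` and
#'   `dropped` rbound by the caller, or either one).
#' @param selector selector label recorded in the output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mappability_scores <- function(scored, selector, path) {
  write.table(data.frame(copy_id = scored$copy_id, selector = selector,
                         mean_score = scored$mean_score,
                         kept_flag = as.integer(scored$kept)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
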
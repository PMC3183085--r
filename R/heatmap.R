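#' Stack flank profiles into a per-copy coverage matrix
#'
#' One row per copy (stable input order), one column per bp offset from
#' the element edge — the tested backbone of the spreading heatmaps.
#'
#' @param profiles list of `flank_profile`s sharing side and length.
#' @param side expected side (`"five_prime"` or `"three_prime"`); all
#'   profiles must match.
#' @param line_label label of the cell line the coverage came from.
#' @return numeric matrix of class `flank_matrix` with `copy_id` rownames
#'   and attributes `side`, `line_label`.
#' @export
flank_matrix <- function(profiles, side = "five_prime", line_label = "A") {
  if (length(profiles) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = 0)
  } else {
    sides <- vapply(profiles, function(p) p$side, character(1))
    .assert(all(sides == side), "profiles mix sides (expected %s)", side)
    lens <- unique(vapply(profiles, function(p) length(p$values), integer(1)))
    .assert(length(lens) == 1, "profiles mix lengths")
    m <- do.call(rbind, lapply(profiles, function(p) p$values))
    rownames(m) <- vapply(profiles, function(p) p$copy_id, character(1))
    colnames(m) <- as.character(seq_len(ncol(m)) - 1L)
  }
  structure(m, side = side, line_label = line_label,
            class = c("flank_matrix", class(m)))
}

#' Order heatmap rows by full-site flank coverage
#'
#' Rows are sorted by total (row-sum) coverage of the full-site matrix in
#' descending order, ties broken by `copy_id`; the identical permutation
#' is applied to the empty-site matrix so rows stay paired.
#'
#' @param matrix_full,matrix_empty `flank_matrix` objects over the same
#'   copies.
#' @return list with `full` and `empty`, both reordered.
#' @export
order_rows <- function(matrix_full, matrix_empty) {
  .assert(setequal(rownames(matrix_full), rownames(matrix_empty)) &&
            nrow(matrix_full) == nrow(matrix_empty),
          "full/empty matrices disagree on copy ids")
  matrix_empty <- matrix_empty[rownames(matrix_full), , drop = FALSE]
  o <- order(-rowSums(matrix_full), rownames(matrix_full))
  list(full = matrix_full[o, , drop = FALSE],
       empty = matrix_empty[o, , drop = FALSE])
}

#' Write a flank matrix as TSV (header row = bp offsets)
#'
#' @param m a `flank_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flank_matrix <- function(m, path) {
  df <- data.frame(copy_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a flank matrix as a PNG heatmap (thin plotting adapter)
#'
#' @param m a `flank_matrix`.
#' @param path output PNG path.
#' @param max_value color-scale ceiling (default data maximum).
#' @return `path`, invisibly.
#' @export
plot_flank_matrix <- function(m, path, max_value = max(m, 1)) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("white", "orange", "red"))(64)
  graphics::image(t(pmin(unclass(m), max_value))[, rev(seq_len(nrow(m))),
                                                 drop = FALSE],
                  col = pal, axes = FALSE,
                  xlab = "distance from element edge (bp)",
                  ylab = sprintf("copies (n=%d)", nrow(m)))
  invisible(path)
}
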
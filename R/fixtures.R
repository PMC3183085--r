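#' Write a synthetic cohort as a plain-text fixture bundle
#'
#' Emits, into `directory`: the TE table (TSV, 1-based coordinates, one
#' presence column per line), gene models (BED6), reads per line
#' (BED6+uniqueness), the mappability track (bedGraph), chromosome sizes,
#' expression counts (TSV), ground truth (JSON) and a `manifest.json`
#' recording every file plus the generating config and seed.  Re-running
#' with the same config yields byte-identical files.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly (list with `files`, `config`, `seed`).
#' @export
write_fixture_bundle <- function(cohort, directory) {
  .assert(inherits(cohort, "synthetic_cohort"), "not a synthetic_cohort")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  .assert(dir.exists(directory), "cannot create directory %s", directory)
  labs <- cohort$config$line_labels
  p <- function(f) file.path(directory, f)

  files <- list(
    te_table = "te_table.tsv", genes = "genes.bed",
    reads_a = sprintf("reads_%s.bed", labs[1]),
    reads_b = sprintf("reads_%s.bed", labs[2]),
    mappability = "mappability.bedGraph",
    chrom_sizes = "chrom.sizes",
    expr_a = sprintf("expr_%s.tsv", labs[1]),
    expr_b = sprintf("expr_%s.tsv", labs[2]),
    truth = "truth.json")

  write_te_table(cohort$te_table, p(files$te_table), labs)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", cohort$genes$chrom,
                     cohort$genes$start, cohort$genes$end,
                     cohort$genes$gene_id, 0L, cohort$genes$strand),
             p(files$genes))
  write_reads(cohort$reads_a, p(files$reads_a))
  write_reads(cohort$reads_b, p(files$reads_b))
  write_signal_track(cohort$mappability, p(files$mappability))
  writeLines(sprintf("%s\t%d", names(cohort$chrom_sizes),
                     cohort$chrom_sizes), p(files$chrom_sizes))
  write.table(cohort$expr_a, p(files$expr_a), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$expr_b, p(files$expr_b), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(cohort$truth, p(files$truth), dataframe = "columns",
                       digits = NA, pretty = TRUE)

  manifest <- list(files = files,
                   seed = cohort$config$seed,
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Read a fixture bundle back through the standard readers
#'
#' @param directory bundle directory containing `manifest.json`.
#' @return list with `te_table`, `genes`, `reads_a`, `reads_b`,
#'   `mappability`, `chrom_sizes`, `expr_a`, `expr_b`, `truth`,
#'   `manifest`.
#' @export
read_fixture_bundle <- function(directory) {
  mpath <- file.path(directory, "manifest.json")
  .assert(file.exists(mpath), "no manifest.json in %s", directory)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  f <- manifest$files
  p <- function(x) file.path(directory, x)
  chrom_sizes <- read_chrom_sizes(p(f$chrom_sizes))
  list(te_table = read_te_table(p(f$te_table)),
       genes = read_genes(p(f$genes), "bed6"),
       reads_a = read_reads(p(f$reads_a), "bed6q"),
       reads_b = read_reads(p(f$reads_b), "bed6q"),
       mappability = read_signal_track(p(f$mappability),
                                       chrom_sizes = chrom_sizes),
       chrom_sizes = chrom_sizes,
       expr_a = read.delim(p(f$expr_a), stringsAsFactors = FALSE),
       expr_b = read.delim(p(f$expr_b), stringsAsFactors = FALSE),
       truth = jsonlite::read_json(p(f$truth), simplifyVector = TRUE),
       manifest = manifest)
}
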
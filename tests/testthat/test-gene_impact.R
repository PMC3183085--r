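test_that("tss_proximal_copies measures gap distance and applies the cap", {
  te <- make_insertion(start = 10000L, end = 15000L)
  genes <- data.frame(
    gene_id = c("near", "far", "inside", "edge"),
    chrom = "chr1",
    start = c(15368L, 20001L, 12000L, 20000L),
    end = c(17368L, 22001L, 14000L, 22000L),
    strand = "+", stringsAsFactors = FALSE)
  genes$tss <- genes$start
  genes$length_bp <- genes$end - genes$start
  pairs <- tss_proximal_copies(te, genes, max_dist = 5000)
  expect_equal(sort(pairs$gene_id), c("edge", "inside", "near"))
  expect_equal(pairs$tss_distance_bp[pairs$gene_id == "near"], 368L)
  expect_equal(pairs$tss_distance_bp[pairs$gene_id == "inside"], 0L)
  expect_equal(pairs$tss_distance_bp[pairs$gene_id == "edge"], 5000L)
  # 5001 bp away -> excluded; relaxing max_dist only grows the set
  expect_false("far" %in% pairs$gene_id)
  more <- tss_proximal_copies(te, genes, max_dist = 6000)
  expect_true(all(pairs$gene_id %in% more$gene_id))
})

impact_fixture <- function(promoter_empty_enriched = FALSE,
                           copy_enriched = TRUE,
                           promoter_full_enriched = TRUE) {
  # gene 3 kb downstream so the promoter window (TSS +/- 1 kb) stays
  # clear of the element body
  sizes <- c(chr1 = 100000L)
  base <- rep(1, 100000)
  vf <- base; ve <- base
  if (copy_enriched) vf[10001:15000] <- 8
  if (promoter_full_enriched) vf[17001:19000] <- 8
  if (promoter_empty_enriched) ve[17001:19000] <- 8
  te <- make_insertion(start = 10000L, end = 15000L)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 18000L,
                      end = 20000L, strand = "+", stringsAsFactors = FALSE)
  genes$tss <- genes$start
  genes$length_bp <- 2000L
  list(te = te, genes = genes,
       track_full = signal_track(list(chr1 = vf), sizes),
       track_empty = signal_track(list(chr1 = ve), sizes),
       pairs = tss_proximal_copies(te, genes, 5000))
}

test_that("enrichment_filter requires full-only promoter enrichment", {
  fx <- impact_fixture()
  kept <- enrichment_filter(fx$pairs, fx$te, fx$genes, fx$track_full,
                            fx$track_empty, 1e6, 1e6)
  expect_equal(kept$gene_id, "g1")
  expect_gt(kept$promoter_rpkm_full, kept$threshold_full)
  expect_lt(kept$promoter_rpkm_empty, kept$threshold_empty)

  both <- impact_fixture(promoter_empty_enriched = TRUE)
  expect_equal(nrow(enrichment_filter(both$pairs, both$te, both$genes,
                                      both$track_full, both$track_empty,
                                      1e6, 1e6)), 0)

  silent <- impact_fixture(promoter_full_enriched = FALSE)
  expect_equal(nrow(enrichment_filter(silent$pairs, silent$te, silent$genes,
                                      silent$track_full, silent$track_empty,
                                      1e6, 1e6)), 0)
})

test_that("expression_compare flags genes lower in the full-site line", {
  ef <- data.frame(gene_id = c("g1", "g2"), length_bp = 2000L,
                   count = c(25L, 0L))
  ee <- data.frame(gene_id = c("g1", "g2"), length_bp = 2000L,
                   count = c(100L, 0L))
  cmp <- expression_compare(ef, ee, "g1", N_full = 1000, N_empty = 1000)
  expect_equal(cmp$ratio, 4)
  expect_true(cmp$differentially_lower)
  eq <- expression_compare(ef, ef, "g1", N_full = 1000, N_empty = 1000)
  expect_equal(eq$ratio, 1)
  expect_false(eq$differentially_lower)
  inf <- expression_compare(
    data.frame(gene_id = "g", length_bp = 1000L, count = 0L),
    data.frame(gene_id = "g", length_bp = 1000L, count = 50L), "g",
    N_full = 1000, N_empty = 1000)
  expect_equal(inf$ratio, Inf)
  expect_true(inf$differentially_lower)
  expect_warning(z <- expression_compare(ef, ee, "g2",
                                         N_full = 1000, N_empty = 1000),
                 "zero counts")
  expect_false(z$differentially_lower)
})

test_that("run_gene_impact recovers exactly the planted silenced gene", {
  cfg <- sim_config(seed = 50, n_chroms = 1, chrom_len_bp = 4e6,
                    n_common_copies = 5, n_polymorphic_copies = 15,
                    flank_fold = 4, n_genes = 8,
                    planted_impact_genes = list(
                      list(tss_distance = 368, silencing_fold = 4)))
  co <- simulate_cohort(cfg)
  cand <- run_gene_impact(co$te_table, co$genes, co$reads_a, co$reads_b,
                          co$expr_a, co$expr_b, co$chrom_sizes)
  truth <- co$truth$genes
  expect_equal(cand$gene_id, truth$gene_id[truth$impacted])
  expect_equal(cand$tss_distance_bp, 368L)
  expect_true(all(cand$expression_ratio >= 2))

  # composition soundness: output is a subset of the proximity pairs
  poly <- co$te_table[co$te_table$status == "polymorphic", ]
  pairs <- tss_proximal_copies(poly, co$genes, 5000)
  expect_true(all(paste(cand$copy_id, cand$gene_id) %in%
                    paste(pairs$copy_id, pairs$gene_id)))
})

test_that("no heterochromatin at the insertion means no candidates", {
  # the promoter window (TSS +/- 1 kb at 368 bp distance) reaches into the
  # element body, so "enrichment removed" means the whole insertion is
  # chromatin-neutral: te_fold = flank_fold = 1
  cfg <- sim_config(seed = 51, n_chroms = 1, chrom_len_bp = 4e6,
                    n_common_copies = 5, n_polymorphic_copies = 15,
                    te_fold = 1, flank_fold = 1, n_genes = 8,
                    planted_impact_genes = list(
                      list(tss_distance = 368, silencing_fold = 4)))
  co <- simulate_cohort(cfg)
  cand <- run_gene_impact(co$te_table, co$genes, co$reads_a, co$reads_b,
                          co$expr_a, co$expr_b, co$chrom_sizes)
  expect_equal(nrow(cand), 0)

  # and a cohort with no gene near any polymorphic copy is empty too
  cfg2 <- sim_config(seed = 52, n_chroms = 1, chrom_len_bp = 4e6,
                     n_common_copies = 5, n_polymorphic_copies = 15,
                     flank_fold = 4, n_genes = 8)
  co2 <- simulate_cohort(cfg2)
  cand2 <- run_gene_impact(co2$te_table, co2$genes, co2$reads_a,
                           co2$reads_b, co2$expr_a, co2$expr_b,
                           co2$chrom_sizes)
  expect_equal(nrow(cand2), 0)
})
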
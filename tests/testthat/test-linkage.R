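test_that("consensus rule keeps exactly the hand-enumerated peaks", {
  kept <- consensus_responsive_peaks(proseq_fixture())
  expect_equal(kept$name, c("pk1", "pk3", "pk4"))
  expect_equal(kept$n_passing, c(3, 4, 3))
})

test_that("consensus rule treats missing condition columns as failing", {
  tbl <- proseq_fixture()
  tbl$logfc_H460_6h <- NULL
  tbl$p_H460_6h <- NULL
  kept <- consensus_responsive_peaks(tbl)
  # pk1 only failed the dropped condition; pk4 falls to 2 passing
  expect_equal(kept$name, c("pk1", "pk3"))
})

test_that("relaxing consensus thresholds never drops a retained peak", {
  set.seed(19)
  conds <- c("A549_3h", "A549_6h", "H460_3h", "H460_6h")
  tbl <- tibble::tibble(chrom = "chr1", start = 1:50 * 1000,
                        end = 1:50 * 1000 + 500,
                        name = paste0("p", 1:50))
  for (cond in conds) {
    tbl[[paste0("logfc_", cond)]] <- stats::rnorm(50)
    tbl[[paste0("p_", cond)]] <- stats::runif(50)
  }
  strict <- consensus_responsive_peaks(tbl, p_max = 0.05)$name
  loose_p <- consensus_responsive_peaks(tbl, p_max = 0.2)$name
  loose_lfc <- consensus_responsive_peaks(tbl, p_max = 0.05, logfc_max = 0.5)$name
  expect_true(all(strict %in% loose_p))
  expect_true(all(strict %in% loose_lfc))
})

test_that("link filter enforces the inclusive CCscore and both-arm rules", {
  resp <- genomic_intervals("chr1", c(1000, 20000), c(1500, 20500))
  links <- validate_links(tibble::tibble(
    chrom1 = "chr1",
    start1 = c(900, 900, 900, 50000, 900),
    end1 = c(1200, 1200, 1200, 50300, 1200),
    chrom2 = "chr1",
    start2 = c(20100, 20100, 30000, 60000, 20100),
    end2 = c(20400, 20400, 30300, 60300, 20400),
    ccscore = c(1.0, 0.99, 2.0, 3.0, 2.5),
    pvalue = 0.5))
  links$name <- paste0("L", 1:5)
  kept <- filter_links(links, resp)
  # L1: boundary ccscore 1.0 kept; L2 fails ccscore; L3 one arm only;
  # L4 no arms; L5 both arms and high score
  expect_equal(kept$name, c("L1", "L5"))
  # order invariance
  kept2 <- filter_links(links[5:1, ], resp)
  expect_setequal(kept2$name, kept$name)
})

test_that("significance boundary is strictly below alpha", {
  expect_equal(link_significance(c(0, 49, 50, 51), 1000),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("identity shuffle marks every link as expected background", {
  spec <- synthetic_spec(n_genes = 10, n_nonsig_genes = 5,
                         n_background_links = 10, seed = 5)
  reg <- simulate_regulome(spec)
  sn <- shuffle_null(reg$links, reg$genome, n_shuffles = 20, seed = 1,
                     relocate = FALSE)
  expect_true(all(sn$empirical_freq == 1))
  expect_false(any(sn$significant))
})

test_that("a planted link above the background maximum is always significant", {
  spec <- synthetic_spec(n_genes = 10, n_nonsig_genes = 5, frac_group1 = 0.5,
                         n_background_links = 15, true_link_ccscore = 50,
                         seed = 9)
  reg <- simulate_regulome(spec)
  sn <- shuffle_null(reg$links, reg$genome, n_shuffles = 100, seed = 2)
  planted <- sn[sn$truth_true, ]
  expect_true(all(planted$empirical_freq == 0))
  expect_true(all(planted$significant))
})

test_that("shuffling preserves anchor widths and inter-anchor offsets", {
  spec <- synthetic_spec(n_genes = 10, n_nonsig_genes = 5,
                         n_background_links = 12, seed = 3)
  reg <- simulate_regulome(spec)
  set.seed(4)
  shuf <- nrf2regulome:::relocate_links(reg$links, reg$genome)
  expect_equal(shuf$end1 - shuf$start1, reg$links$end1 - reg$links$start1)
  expect_equal(shuf$start2 - shuf$start1, reg$links$start2 - reg$links$start1)
  expect_true(all(shuf$start1 >= 0))
  glen <- stats::setNames(reg$genome$length, reg$genome$chrom)
  expect_true(all(shuf$end2 <= glen[shuf$chrom2]))
})

test_that("peak classification follows promoter > enhancer > linked precedence", {
  prom <- tibble::tibble(gene = "SIG1", chrom = "chr1", tss = 10000,
                         strand = "+")
  enh <- genomic_intervals("chr1", c(9500, 30000), c(10500, 31000))
  links <- tibble::tibble(chrom1 = "chr1", start1 = 10000, end1 = 10500,
                          chrom2 = "chr1", start2 = 50000, end2 = 50500,
                          ccscore = 5, pvalue = 0.01, significant = TRUE)
  peaks <- genomic_intervals("chr1",
                             c(9800, 30200, 50100, 70000),
                             c(10200, 30400, 50400, 70200))
  out <- classify_peaks(peaks, prom, enh, links, "SIG1")
  # first peak overlaps both the promoter window and an enhancer state
  expect_equal(out$class, c("promoter", "enhancer", "linked", "other"))
  # a non-significant link confers no linked status
  links$significant <- FALSE
  out2 <- classify_peaks(peaks, prom, enh, links, "SIG1")
  expect_equal(out2$class[3], "other")
})

test_that("linkage summary counts distinct enhancer bins per gene", {
  prom <- tibble::tibble(gene = c("SIG1", "SIG2", "GEN1"), chrom = "chr1",
                         tss = c(10000, 100000, 200000), strand = "+")
  mk <- function(tss_start, enh_start) {
    tibble::tibble(chrom1 = "chr1", start1 = tss_start, end1 = tss_start + 500,
                   chrom2 = "chr1", start2 = enh_start, end2 = enh_start + 500,
                   ccscore = 5, pvalue = 0.01)
  }
  links <- dplyr::bind_rows(mk(10000, 40000), mk(10000, 60000),  # SIG1: 2 bins
                            mk(100000, 140000))                  # SIG2: 1 bin
  ls <- linkage_summary(links, prom, c("SIG1", "SIG2"))
  per <- ls$per_gene
  expect_equal(per$n_linked_enhancers[per$gene == "SIG1"], 2L)
  expect_equal(per$linkage_type[per$gene == "SIG1"], "higher-order")
  expect_equal(per$linkage_type[per$gene == "SIG2"], "single-enhancer")
  expect_equal(per$linkage_type[per$gene == "GEN1"], "promoter-only")
})

test_that("planted higher-order proportions are recovered from the pipeline", {
  spec <- synthetic_spec(n_genes = 30, n_nonsig_genes = 10, frac_group1 = 0.5,
                         frac_higher_order = 0.4, n_background_links = 10,
                         true_link_ccscore = 20, seed = 14)
  reg <- simulate_regulome(spec)
  resp <- consensus_responsive_peaks(reg$proseq)
  fl <- filter_links(reg$links, resp)
  sn <- shuffle_null(fl, reg$genome, n_shuffles = 100, seed = 14)
  ls <- linkage_summary(sn, reg$promoters,
                        reg$promoters$gene[reg$promoters$signature])
  got <- ls$proportions$higher_order_prop[ls$proportions$signature]
  planted <- reg$truth_genes |>
    dplyr::filter(.data$truth_n_enhancers >= 1) |>
    dplyr::summarise(p = mean(.data$truth_n_enhancers >= 2)) |>
    dplyr::pull(p)
  expect_equal(got, planted, tolerance = 0.1)
})
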
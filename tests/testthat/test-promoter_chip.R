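test_that("promoter score averages peaks inside the half-open window", {
  prom <- tibble::tibble(gene = "GCLC", chrom = "chr1", tss = 10000,
                         strand = "+")
  peaks <- genomic_intervals(
    chrom = rep("chr1", 3),
    start = c(9200, 10500, 12000),   # two inside +/-1 kb, one outside
    end = c(9400, 10700, 12200),
    signal = c(4.0, 6.0, 50.0))
  sc <- promoter_score(prom, peaks)
  expect_equal(sc$promoter_score, 5.0)
  expect_equal(sc$n_peaks_in_window, 2L)
})

test_that("window boundaries are half-open and empty windows score zero", {
  prom <- tibble::tibble(gene = "g", chrom = "chr1", tss = 10000, strand = "+")
  # peak starting exactly at tss + window is excluded
  at_edge <- genomic_intervals("chr1", 11000, 11200, signal = 9)
  expect_equal(promoter_score(prom, at_edge)$promoter_score, 0)
  # one bp earlier overlaps
  just_in <- genomic_intervals("chr1", 10999, 11200, signal = 9)
  expect_equal(promoter_score(prom, just_in)$promoter_score, 9)
  # no peaks on the chromosome at all
  off <- genomic_intervals("chr2", 9500, 9700, signal = 9)
  expect_equal(promoter_score(prom, off)$promoter_score, 0)
})

test_that("promoter score ignores peak order and widens monotonically", {
  set.seed(3)
  prom <- tibble::tibble(gene = letters[1:5], chrom = "chr1",
                         tss = seq(20000, 100000, length.out = 5),
                         strand = "+")
  peaks <- random_intervals(100, chroms = "chr1", max_pos = 120000)
  peaks$signal <- stats::runif(100, 1, 10)
  s1 <- promoter_score(prom, peaks)
  s2 <- promoter_score(prom, peaks[sample(100), ])
  expect_equal(s1, s2)
  wide <- promoter_score(prom, peaks, window_bp = 2000)
  expect_true(all(wide$n_peaks_in_window >= s1$n_peaks_in_window))
})

test_that("two-means grouping splits scores as brute force does", {
  sc <- tibble::tibble(gene = letters[1:4], promoter_score = c(0, 0, 50, 60))
  expect_equal(classify_groups(sc)$group, c("I", "I", "II", "II"))
  expect_equal(classify_groups(sc)$group, brute_two_means(sc$promoter_score))
  set.seed(8)
  for (rep in 1:5) {
    x <- c(stats::rexp(10, 1), 20 + stats::rexp(10, 1 / 10))
    sc <- tibble::tibble(gene = paste0("g", seq_along(x)), promoter_score = x)
    expect_equal(classify_groups(sc)$group, brute_two_means(x))
  }
})

test_that("threshold grouping and degenerate input behave as documented", {
  sc <- tibble::tibble(gene = c("a", "b"), promoter_score = c(0.99, 1.0))
  out <- classify_groups(sc, method = "threshold", threshold = 1.0)
  expect_equal(out$group, c("I", "II"))
  flat <- tibble::tibble(gene = c("a", "b"), promoter_score = c(2, 2))
  expect_error(classify_groups(flat), "threshold")
})

test_that("group labels recover the planted regulome exactly", {
  spec <- synthetic_spec(n_genes = 30, n_nonsig_genes = 10,
                         n_background_links = 10, seed = 12)
  reg <- simulate_regulome(spec)
  sig <- reg$promoters[reg$promoters$signature, ]
  labels <- classify_groups(promoter_score(sig, reg$peaks$NRF2))
  truth <- reg$truth_genes$truth_group[match(labels$gene, reg$truth_genes$gene)]
  expect_equal(labels$group, truth)
})

test_that("exact Wilcoxon matches enumeration, including ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  set.seed(17)
  for (rep in 1:10) {
    x <- sample(1:6, 4, replace = TRUE)  # ties likely
    y <- sample(1:6, 5, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y), enum_wilcox(x, y))
  }
  # tie-free case agrees with the reference implementation
  x <- c(1.1, 2.3, 4.5); y <- c(0.2, 3.3, 5.1, 6.0)
  expect_equal(wilcoxon_rank_sum(x, y),
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("large-sample Wilcoxon approximation tracks the reference", {
  set.seed(23)
  x <- stats::rnorm(15); y <- stats::rnorm(20, 0.8)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value
  expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-10)
})

test_that("Fisher combination follows the chi-square closed form", {
  chi <- -2 * (log(0.1) + log(0.2))
  expect_equal(chi, 7.824, tolerance = 1e-3)
  # df = 4 tail has closed form exp(-x/2) * (1 + x/2)
  expect_equal(fisher_combine(c(0.1, 0.2)), exp(-chi / 2) * (1 + chi / 2))
  expect_equal(fisher_combine(c(0.1, 0.2)), 0.0984, tolerance = 5e-3)
  expect_equal(fisher_combine(0.37), 0.37)
})

test_that("proximal peaks are assigned to the closest signature gene", {
  prom <- tibble::tibble(
    gene = c("SIGA", "OTHB"), chrom = "chr1", tss = c(10000, 50000),
    strand = "+", gene_start = c(10000, 50000), gene_end = c(20000, 60000))
  peaks <- genomic_intervals("chr1", c(5000, 15000, 48000), c(5200, 15200, 48200),
                             signal = c(1, 1, 1))
  out <- assign_proximal_peaks(peaks, prom, "SIGA")
  expect_equal(out$closest_gene, c("SIGA", "SIGA", "OTHB"))
  # peak 2 is inside SIGA's gene body, peak 3 belongs to a non-signature gene
  expect_equal(out$proximal, c(TRUE, FALSE, FALSE))
})

test_that("factor enrichment flags planted group differences and only those", {
  set.seed(31)
  n_pk <- 24
  nrf2 <- genomic_intervals("chr1", seq(10000, by = 5000, length.out = n_pk),
                            seq(10200, by = 5000, length.out = n_pk))
  nrf2$group <- rep(c("I", "II"), each = n_pk / 2)
  make_reps <- function(shift) {
    purrr::map(1:2, function(r) {
      sig <- c(stats::rlnorm(n_pk / 2, 1), stats::rlnorm(n_pk / 2, 1 + shift))
      genomic_intervals("chr1", nrf2$start, nrf2$end, signal = sig)
    })
  }
  res <- factor_enrichment(nrf2, list(planted = make_reps(2.5),
                                      null1 = make_reps(0),
                                      null2 = make_reps(0)))
  expect_true(res$significant[res$factor == "planted"])
  expect_equal(res$mean_group2[res$factor == "planted"] >
                 res$mean_group1[res$factor == "planted"], TRUE)
  expect_true(all(res$adjusted_p >= res$combined_p))
})

test_that("null factors stay below the false-positive budget", {
  set.seed(41)
  n_pk <- 30
  nrf2 <- genomic_intervals("chr1", seq(10000, by = 5000, length.out = n_pk),
                            seq(10200, by = 5000, length.out = n_pk))
  nrf2$group <- rep(c("I", "II"), each = n_pk / 2)
  sets <- purrr::map(seq_len(60), function(f) {
    purrr::map(1:2, function(r) {
      genomic_intervals("chr1", nrf2$start, nrf2$end,
                        signal = stats::rlnorm(n_pk, 1))
    })
  })
  names(sets) <- paste0("factor", seq_along(sets))
  res <- factor_enrichment(nrf2, sets)
  expect_lte(mean(res$significant), 0.07)
})
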
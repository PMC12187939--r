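#' Promoter ChIP occupancy score
#'
#' For each promoter, the score is the arithmetic mean signal of all
#' peaks overlapping the window `[tss - window_bp, tss + window_bp)`
#' (clipped at 0), i.e. within 1 kb up- and downstream at the default.
#' Promoters with no peak in the window score 0, not `NA`, so the group
#' classification has a total order; a peak overlapping two promoter
#' windows contributes to both.
#'
#' @param promoters Tibble: `gene`, `chrom`, `tss`, `strand`.
#' @param peaks Peak tibble with `signal` (see [read_bed()]).
#' @param window_bp Half-window in bp (default 1000).
#' @return Tibble: `gene`, `promoter_score`, `n_peaks_in_window`.
#' @export
promoter_score <- function(promoters, peaks, window_bp = 1000) {
  stopifnot(window_bp > 0, all(c("gene", "chrom", "tss") %in% names(promoters)))
  win <- tibble::tibble(chrom = promoters$chrom,
                        start = pmax(promoters$tss - window_bp, 0),
                        end = promoters$tss + window_bp)
  scored <- overlap_signal(win, peaks)
  tibble::tibble(gene = promoters$gene,
                 promoter_score = scored$signal,
                 n_peaks_in_window = scored$n_overlap)
}

#' Promoter scores for several factors at once
#'
#' @param promoters Promoter tibble.
#' @param peaksets Named list of peak tibbles (one per factor).
#' @inheritParams promoter_score
#' @return Long tibble: `gene`, `factor`, `promoter_score`,
#'   `n_peaks_in_window`.
#' @export
promoter_score_table <- function(promoters, peaksets, window_bp = 1000) {
  purrr::imap_dfr(peaksets, function(pk, nm) {
    dplyr::mutate(promoter_score(promoters, pk, window_bp), factor = nm,
                  .after = "gene")
  })
}

#' Classify genes into low/high promoter-occupancy groups
#'
#' Group I = low promoter-bound signal, group II = high. The default
#' `two_means` method runs a deterministic 1-D 2-means on
#' `log1p(score)` with centers initialized at the min and max; the lower
#' cluster is group I. `threshold` mode assigns group I to
#' `score < threshold`.
#'
#' @param scores Output of [promoter_score()] (for the NRF2 factor).
#' @param method `"two_means"` (default) or `"threshold"`.
#' @param threshold Cutoff for threshold mode.
#' @return Tibble: `gene`, `promoter_score`, `group` (`"I"`/`"II"`).
#' @export
#' @examples
#' sc <- tibble::tibble(gene = letters[1:4], promoter_score = c(0, 0, 50, 60))
#' classify_groups(sc)$group
classify_groups <- function(scores, method = c("two_means", "threshold"),
                            threshold = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "promoter_score") %in% names(scores)),
            nrow(scores) >= 2)
  x <- scores$promoter_score
  if (method == "threshold") {
    stopifnot(!is.null(threshold))
    group <- ifelse(x < threshold, "I", "II")
  } else {
    lx <- log1p(x)
    if (max(lx) == min(lx))
      stop("all promoter scores identical; use method = 'threshold'",
           call. = FALSE)
    km <- stats::kmeans(lx, centers = matrix(c(min(lx), max(lx))))
    low <- which.min(km$centers)
    group <- ifelse(km$cluster == low, "I", "II")
  }
  tibble::tibble(gene = scores$gene, promoter_score = x, group = group)
}

#' Assign peaks to their closest gene and keep gene-distal ones
#'
#' "Proximal" peaks for enrichment are those whose closest gene (by TSS
#' distance from the peak, ties broken by gene name) is a signature gene
#' while the peak does not lie within that gene's body.
#'
#' @param peaks Peak tibble.
#' @param promoters Promoter tibble; `gene_start`/`gene_end` columns, if
#'   present, define gene bodies for the exclusion.
#' @param signature_genes Character vector of signature gene symbols.
#' @return `peaks` with `closest_gene` and `proximal` columns.
#' @export
assign_proximal_peaks <- function(peaks, promoters, signature_genes) {
  mid <- (peaks$start + peaks$end) / 2
  prom_split <- split(promoters, promoters$chrom)
  closest <- purrr::map_chr(seq_len(nrow(peaks)), function(i) {
    pr <- prom_split[[peaks$chrom[i]]]
    if (is.null(pr) || nrow(pr) == 0) return(NA_character_)
    d <- abs(pr$tss - mid[i])
    cand <- pr$gene[d == min(d)]
    sort(cand)[1]
  })
  in_body <- rep(FALSE, nrow(peaks))
  if (all(c("gene_start", "gene_end") %in% names(promoters))) {
    pr <- promoters[match(closest, promoters$gene), ]
    ok <- !is.na(closest)
    in_body[ok] <- interval_overlaps(peaks$chrom[ok], peaks$start[ok],
                                     peaks$end[ok], pr$chrom[ok],
                                     pr$gene_start[ok], pr$gene_end[ok])
  }
  dplyr::mutate(peaks, closest_gene = closest,
                proximal = !is.na(closest) & closest %in% signature_genes &
                  !in_body)
}

#' Wilcoxon rank-sum test (exact for small samples)
#'
#' Two-sided rank-sum p-value: exact by enumeration of all group
#' assignments when the combined sample size is at most `exact_max`
#' (correct under ties, since enumeration conditions on the observed
#' values), otherwise a normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Combined-size limit for exact enumeration (default 20).
#' @return Two-sided p-value.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # 1/3
wilcoxon_rank_sum <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    mu <- n1 * (n + 1) / 2
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
}

#' Fisher's method for combining p-values
#'
#' `chi2 = -2 * sum(log(p))` on `2k` degrees of freedom.
#'
#' @param pvalues P-values in \[0, 1\].
#' @return Combined p-value.
#' @export
#' @examples
#' fisher_combine(c(0.1, 0.2))  # ~0.0984
fisher_combine <- function(pvalues) {
  stopifnot(length(pvalues) >= 1, all(pvalues >= 0 & pvalues <= 1))
  stats::pchisq(-2 * sum(log(pvalues)), df = 2 * length(pvalues),
                lower.tail = FALSE)
}

#' Factor co-occupancy enrichment between promoter groups
#'
#' Each proximal NRF2 peak is scored with the overlapping signal of every
#' other factor (0 where no peak of that factor overlaps). Per factor
#' replicate, group I vs group II signals are compared by a two-sided
#' Wilcoxon rank-sum test; replicate p-values are combined with Fisher's
#' method; combined p-values are BH-adjusted across factors and called
#' significant below 0.05.
#'
#' @param nrf2_peaks Peak tibble with a `group` column (`"I"`/`"II"`),
#'   e.g. proximal peaks labelled by their closest gene's group.
#' @param factor_peaksets Tibble of factor peaks with columns `factor`,
#'   `replicate`, `chrom`, `start`, `end`, `signal` — or a named list of
#'   per-factor lists of peak tibbles.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return Tibble per factor: group means, per-replicate p-values
#'   (list-column), `combined_p`, `adjusted_p`, `significant`.
#' @export
factor_enrichment <- function(nrf2_peaks, factor_peaksets, alpha = 0.05) {
  stopifnot("group" %in% names(nrf2_peaks),
            all(nrf2_peaks$group %in% c("I", "II")))
  if (!all(c("I", "II") %in% nrf2_peaks$group))
    stop("both promoter groups must be represented", call. = FALSE)
  if (is.list(factor_peaksets) && !is.data.frame(factor_peaksets)) {
    factor_peaksets <- purrr::imap_dfr(factor_peaksets, function(reps, fac) {
      purrr::imap_dfr(reps, function(pk, i) {
        dplyr::mutate(pk, factor = fac, replicate = as.integer(i))
      })
    })
  }
  res <- factor_peaksets |>
    dplyr::group_by(.data$factor) |>
    dplyr::group_map(function(fac_peaks, key) {
      reps <- split(fac_peaks, fac_peaks$replicate)
      if (length(reps) == 0) return(NULL)
      vals <- purrr::map(reps, function(pk) {
        overlap_signal(nrf2_peaks, pk)$signal
      })
      pvals <- purrr::map_dbl(vals, function(v) {
        wilcoxon_rank_sum(v[nrf2_peaks$group == "I"],
                          v[nrf2_peaks$group == "II"])
      })
      all_vals <- Reduce(`+`, vals) / length(vals)
      tibble::tibble(
        factor = key$factor,
        mean_group1 = mean(all_vals[nrf2_peaks$group == "I"]),
        mean_group2 = mean(all_vals[nrf2_peaks$group == "II"]),
        replicate_p = list(unname(pvals)),
        combined_p = fisher_combine(pvals))
    }) |>
    dplyr::bind_rows()
  res$adjusted_p <- stats::p.adjust(res$combined_p, method = "BH")
  res$significant <- res$adjusted_p < alpha
  res
}
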
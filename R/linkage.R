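#' Consensus NRF2-responsive PRO-seq peaks
#'
#' A peak is retained iff `logfc < logfc_max` and `p < p_max` (both
#' strict) in at least `min_conditions` of the condition set — the
#' "logFC < 0 and p < 0.1 in at least 3 of 4 conditions" rule at the
#' defaults. Missing condition columns or `NA` entries count as failing.
#'
#' @param peaks PRO-seq differential tibble: interval columns plus
#'   `logfc_<cond>` / `p_<cond>` pairs.
#' @param conditions Condition names (default the four cell line x
#'   timepoint combinations).
#' @param logfc_max Strict upper bound on logFC (default 0).
#' @param p_max Strict upper bound on p (default 0.1).
#' @param min_conditions Minimum passing conditions (default 3).
#' @return The retained subset, with an `n_passing` column.
#' @export
consensus_responsive_peaks <- function(peaks,
                                       conditions = c("A549_3h", "A549_6h",
                                                      "H460_3h", "H460_6h"),
                                       logfc_max = 0, p_max = 0.1,
                                       min_conditions = 3) {
  pass <- purrr::map(conditions, function(cond) {
    lfc_col <- paste0("logfc_", cond); p_col <- paste0("p_", cond)
    if (!all(c(lfc_col, p_col) %in% names(peaks)))
      return(rep(FALSE, nrow(peaks)))
    ok <- peaks[[lfc_col]] < logfc_max & peaks[[p_col]] < p_max
    ok & !is.na(ok)
  })
  n_passing <- Reduce(`+`, pass)
  out <- peaks[n_passing >= min_conditions, , drop = FALSE]
  out$n_passing <- n_passing[n_passing >= min_conditions]
  tibble::as_tibble(out)
}

#' Filter contact links by CCscore and responsive-peak support
#'
#' Retains links with `ccscore >= ccscore_min` (inclusive, "at least 1")
#' whose two anchors each overlap at least one responsive PRO-seq peak.
#'
#' @param links Link tibble (see [read_bedpe()]).
#' @param responsive Responsive peak tibble (e.g. from
#'   [consensus_responsive_peaks()]); `NULL` skips the overlap condition.
#' @param ccscore_min Minimum CCscore (default 1).
#' @return The retained subset.
#' @export
filter_links <- function(links, responsive = NULL, ccscore_min = 1) {
  keep <- links$ccscore >= ccscore_min
  if (!is.null(responsive)) {
    a1 <- overlaps_any(tibble::tibble(chrom = links$chrom1, start = links$start1,
                                      end = links$end1), responsive)
    a2 <- overlaps_any(tibble::tibble(chrom = links$chrom2, start = links$start2,
                                      end = links$end2), responsive)
    keep <- keep & a1 & a2
  }
  tibble::as_tibble(links[keep, , drop = FALSE])
}

# Canonical unordered bin-pair key at the given resolution.
bin_pair_key <- function(chrom1, start1, chrom2, start2, resolution) {
  b1 <- bin_floor(start1, resolution); b2 <- bin_floor(start2, resolution)
  swap <- chrom2 < chrom1 | (chrom1 == chrom2 & b2 < b1)
  k1 <- ifelse(swap, paste0(chrom2, ":", b2), paste0(chrom1, ":", b1))
  k2 <- ifelse(swap, paste0(chrom1, ":", b1), paste0(chrom2, ":", b2))
  paste0(k1, "|", k2)
}

# Relocate each link uniformly: new chromosome drawn length-weighted, new
# anchor1 start uniform in the feasible range, anchor widths and the
# signed anchor1 -> anchor2 offset preserved.
relocate_links <- function(links, genome) {
  n <- nrow(links)
  w1 <- links$end1 - links$start1
  w2 <- links$end2 - links$start2
  offset <- links$start2 - links$start1
  chrom <- character(n); start1 <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      j <- sample.int(nrow(genome), 1, prob = genome$length)
      len <- genome$length[j]
      lo <- max(0, -offset[i])
      hi <- min(len - w1[i], len - offset[i] - w2[i])
      if (hi >= lo) {
        chrom[i] <- genome$chrom[j]
        start1[i] <- floor(stats::runif(1, lo, hi + 1))
        break
      }
      if (all(genome$length < w1[i] + abs(offset[i]) + w2[i]))
        stop("link span exceeds every chromosome", call. = FALSE)
    }
  }
  tibble::tibble(chrom1 = chrom, start1 = start1, end1 = start1 + w1,
                 chrom2 = chrom, start2 = start1 + offset,
                 end2 = start1 + offset + w2, ccscore = links$ccscore)
}

#' Empirical link significance by a binned shuffle null
#'
#' The link set is relocated `n_shuffles` times across the genome
#' (anchor widths and inter-anchor offsets preserved, so the
#' distance-dependence of contact scores survives shuffling). Original
#' and shuffled links are reduced to unordered 5 kb bin pairs; a shuffle
#' replicate scores a hit for an original link when any shuffled link
#' occupies the same bin pair with a CCscore at or above the original's.
#' Links hit in fewer than `alpha` of the replicates (strictly less than
#' 5% at the defaults) are significant.
#'
#' @param links Filtered link tibble.
#' @param genome Tibble (`chrom`, `length`).
#' @param n_shuffles Number of shuffle replicates (default 1000).
#' @param resolution Bin width in bp (default 5000).
#' @param alpha Empirical-frequency cutoff (default 0.05, strict `<`).
#' @param seed Seed; each replicate uses an indexed substream.
#' @param relocate Test hook: `FALSE` scores the identity shuffle, which
#'   marks every link non-significant.
#' @return `links` with `bin1`, `bin2`, `shuffle_hits`, `n_shuffles`,
#'   `empirical_freq` and `significant` columns.
#' @export
shuffle_null <- function(links, genome, n_shuffles = 1000, resolution = 5000,
                         alpha = 0.05, seed = 1L, relocate = TRUE) {
  stopifnot(nrow(genome) > 0, all(genome$length > 0))
  if (any(links$end1 - links$start1 > max(genome$length)) ||
      any(links$end2 - links$start2 > max(genome$length)))
    stop("anchor longer than every chromosome", call. = FALSE)
  keys <- bin_pair_key(links$chrom1, links$start1, links$chrom2, links$start2,
                       resolution)
  hits <- integer(nrow(links))
  for (s in seq_len(n_shuffles)) {
    set.seed(substream_seed(seed, paste0("shuffle_", s)))
    shuf <- if (relocate) relocate_links(links, genome) else links
    skey <- bin_pair_key(shuf$chrom1, shuf$start1, shuf$chrom2, shuf$start2,
                         resolution)
    max_cc <- tapply(shuf$ccscore, skey, max)
    m <- max_cc[keys]
    hits <- hits + as.integer(!is.na(m) & m >= links$ccscore)
  }
  dplyr::mutate(links,
                bin1 = bin_floor(.data$start1, resolution),
                bin2 = bin_floor(.data$start2, resolution),
                shuffle_hits = hits, n_shuffles = n_shuffles,
                empirical_freq = hits / n_shuffles,
                significant = link_significance(hits, n_shuffles, alpha))
}

#' Significance call from shuffle hits
#'
#' A link is significant when it reappears in strictly less than `alpha`
#' of the shuffle replicates: 50 hits out of 1000 (exactly 5%) is not
#' significant.
#'
#' @param shuffle_hits Hits per link.
#' @param n_shuffles Number of shuffle replicates.
#' @param alpha Cutoff (default 0.05).
#' @return Logical vector.
#' @export
#' @examples
#' link_significance(c(49, 50), 1000)  # TRUE, FALSE
link_significance <- function(shuffle_hits, n_shuffles, alpha = 0.05) {
  (shuffle_hits / n_shuffles) < alpha
}

# Genes a link arm is proximal to: the arm overlaps the +/-window
# promoter region, with a nearest-TSS fallback within fallback_bp.
arm_genes <- function(chrom, start, end, promoters, window_bp = 1000,
                      fallback_bp = 10000) {
  prom_split <- split(promoters, promoters$chrom)
  purrr::pmap(list(chrom, start, end), function(ch, s, e) {
    pr <- prom_split[[ch]]
    if (is.null(pr)) return(character(0))
    hit <- s < pr$tss + window_bp & pr$tss - window_bp < e
    if (any(hit)) return(pr$gene[hit])
    d <- pmax(pr$tss - e, s - pr$tss, 0)
    near <- d <= fallback_bp
    if (any(near)) pr$gene[near][which.min(d[near])] else character(0)
  })
}

#' Classify PRO-seq peaks by their regulatory context
#'
#' Precedence promoter > enhancer > linked > other: a peak overlapping
#' any promoter window is `promoter`; else `enhancer` if it overlaps an
#' annotated enhancer chromatin state; else `linked` if it overlaps
#' either arm of a significant link whose other arm is proximal to a
#' signature gene; else `other`.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, ...).
#' @param promoters Promoter tibble.
#' @param enhancer_states Interval tibble of enhancer chromatin states.
#' @param significant_links Output of [shuffle_null()] (rows with
#'   `significant` are used; a plain link tibble is taken whole).
#' @param signature_genes Character vector of signature genes.
#' @param window_bp Promoter half-window (default 1000).
#' @return `peaks` with a `class` column.
#' @export
classify_peaks <- function(peaks, promoters, enhancer_states,
                           significant_links, signature_genes,
                           window_bp = 1000) {
  if ("significant" %in% names(significant_links))
    significant_links <- significant_links[significant_links$significant, ]
  prom_win <- tibble::tibble(chrom = promoters$chrom,
                             start = pmax(promoters$tss - window_bp, 0),
                             end = promoters$tss + window_bp)
  is_prom <- overlaps_any(peaks, prom_win)
  is_enh <- overlaps_any(peaks, enhancer_states)
  linked_arms <- if (nrow(significant_links) > 0) {
    g1 <- arm_genes(significant_links$chrom1, significant_links$start1,
                    significant_links$end1, promoters, window_bp)
    g2 <- arm_genes(significant_links$chrom2, significant_links$start2,
                    significant_links$end2, promoters, window_bp)
    sig1 <- purrr::map_lgl(g1, function(g) any(g %in% signature_genes))
    sig2 <- purrr::map_lgl(g2, function(g) any(g %in% signature_genes))
    dplyr::bind_rows(
      # arm2 is "linked" when arm1 sits at a signature gene, and vice versa
      tibble::tibble(chrom = significant_links$chrom2[sig1],
                     start = significant_links$start2[sig1],
                     end = significant_links$end2[sig1]),
      tibble::tibble(chrom = significant_links$chrom1[sig2],
                     start = significant_links$start1[sig2],
                     end = significant_links$end1[sig2]))
  } else tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  is_linked <- overlaps_any(peaks, linked_arms)
  dplyr::mutate(peaks, class = dplyr::case_when(
    is_prom ~ "promoter",
    is_enh ~ "enhancer",
    is_linked ~ "linked",
    TRUE ~ "other"))
}

#' Per-gene linkage summary and higher-order proportions
#'
#' Restricted to significant links with at least one arm proximal to a
#' gene, counts for every gene the distinct non-promoter enhancer bins
#' linked to it: 0 = promoter-only, 1 = single-enhancer, >= 2 =
#' higher-order. Also reports the higher-order proportion among
#' signature vs non-signature genes (among genes with at least one
#' linked enhancer).
#'
#' @param significant_links Output of [shuffle_null()] or a link tibble.
#' @param promoters Promoter tibble.
#' @param signature_genes Character vector of signature genes.
#' @param window_bp Promoter half-window (default 1000).
#' @param resolution Bin width for distinct-enhancer counting (default
#'   5000).
#' @return List with `per_gene` (gene, n_linked_enhancers, linkage_type,
#'   signature) and `proportions` (per gene set: n genes with links,
#'   higher-order proportion).
#' @export
linkage_summary <- function(significant_links, promoters, signature_genes,
                            window_bp = 1000, resolution = 5000) {
  if ("significant" %in% names(significant_links))
    significant_links <- significant_links[significant_links$significant, ]
  counts <- stats::setNames(vector("list", nrow(promoters)), promoters$gene)
  if (nrow(significant_links) > 0) {
    g1 <- arm_genes(significant_links$chrom1, significant_links$start1,
                    significant_links$end1, promoters, window_bp)
    g2 <- arm_genes(significant_links$chrom2, significant_links$start2,
                    significant_links$end2, promoters, window_bp)
    for (i in seq_len(nrow(significant_links))) {
      b1 <- paste0(significant_links$chrom1[i], ":",
                   bin_floor(significant_links$start1[i], resolution))
      b2 <- paste0(significant_links$chrom2[i], ":",
                   bin_floor(significant_links$start2[i], resolution))
      for (g in g1[[i]]) counts[[g]] <- union(counts[[g]], b2)
      for (g in g2[[i]]) counts[[g]] <- union(counts[[g]], b1)
    }
  }
  # a gene's own promoter bin is not an enhancer of that gene
  own_bin <- paste0(promoters$chrom, ":", bin_floor(promoters$tss, resolution))
  n_linked <- purrr::imap_int(counts, function(b, g) {
    length(setdiff(b, own_bin[promoters$gene == g]))
  })
  per_gene <- tibble::tibble(
    gene = promoters$gene,
    n_linked_enhancers = unname(n_linked[promoters$gene]),
    linkage_type = dplyr::case_when(
      n_linked_enhancers >= 2 ~ "higher-order",
      n_linked_enhancers == 1 ~ "single-enhancer",
      TRUE ~ "promoter-only"),
    signature = promoters$gene %in% signature_genes)
  proportions <- per_gene |>
    dplyr::filter(.data$n_linked_enhancers >= 1) |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     higher_order_prop = mean(.data$linkage_type == "higher-order"),
                     .groups = "drop")
  list(per_gene = per_gene, proportions = proportions)
}
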
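#' Specification for the synthetic multi-omic study
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the statistical structure of the study inputs at desk scale: a
#' pan-cancer dependency screen (cell lines x multi-omic features with a
#' small informative subset), a two-chromosome toy regulome with planted
#' promoter-bound (group II) and enhancer-driven (group I) signature
#' genes, chromatin-contact links above an exponential background, a
#' rescue transcriptome with a coactivator-reliant gene subset, and
#' class-coherent metabolite/lipid shifts.
#'
#' @param n_cell_lines Cell lines in the dependency dataset.
#' @param n_features Multi-omic features (columns of X).
#' @param n_informative Features that actually drive the dependency score.
#' @param effect_size Per-informative-feature coefficient on the latent
#'   dependency (features are standard normal, so this is a standardized
#'   effect).
#' @param noise_sd SD of the Gaussian screen noise added independently to
#'   the Chronos-like and Demeter-like observations of the latent score.
#' @param n_genes Signature genes in the regulome.
#' @param n_nonsig_genes Non-signature genes carried along for contrast.
#' @param frac_group1 Fraction of signature genes in group I (no
#'   promoter-proximal NRF2 peak; a distal enhancer 5-50 kb away instead).
#' @param genome Tibble (`chrom`, `length`) of the toy genome.
#' @param n_background_links Background contact links with exponential
#'   CCscores.
#' @param n_true_links Planted promoter-enhancer links; `NULL` derives the
#'   count from `frac_group1` and `frac_higher_order`.
#' @param true_link_ccscore CCscore given to planted links.
#' @param frac_higher_order Fraction of group I genes planted with two
#'   distal enhancers (higher-order linkage).
#' @param attenuation Multiplier applied to the luciferase-normalized WT
#'   log2FC to produce the mutant response of CBP/p300-reliant genes
#'   (1 = no attenuation).
#' @param reliant_frac Fraction of NRF2-responsive rescue genes that are
#'   CBP/p300-reliant.
#' @param rescue_noise_sd Residual SD on rescue log2FC values.
#' @param n_rescue_genes Genes in the rescue transcriptome.
#' @param analyte_classes Tibble (`class`, `n`, `log2fc`) of metabolite
#'   classes and their planted WT-vs-control shifts.
#' @param lipid_classes Same for the lipidomics assay.
#' @param n_replicates Replicates per condition for analyte tables.
#' @param analyte_noise_sd Replicate SD on log2 abundances.
#' @param seed Master seed; each generator draws from an independent
#'   stage-hashed substream, so adding one generator never perturbs
#'   another.
#' @return A `synthetic_spec` list.
#' @export
#' @examples
#' spec <- synthetic_spec(n_cell_lines = 50, n_features = 40, seed = 1)
synthetic_spec <- function(n_cell_lines = 300,
                           n_features = 500,
                           n_informative = 10,
                           effect_size = 1.0,
                           noise_sd = 1.0,
                           n_genes = 60,
                           n_nonsig_genes = 60,
                           frac_group1 = 0.4,
                           genome = tibble::tibble(chrom = c("chr1", "chr2"),
                                                   length = c(1e7, 1e7)),
                           n_background_links = 40,
                           n_true_links = NULL,
                           true_link_ccscore = 8,
                           frac_higher_order = 0.4,
                           attenuation = 0.4,
                           reliant_frac = 0.3,
                           rescue_noise_sd = 0.05,
                           n_rescue_genes = 1000,
                           analyte_classes = default_analyte_classes(),
                           lipid_classes = default_lipid_classes(),
                           n_replicates = 4,
                           analyte_noise_sd = 0.25,
                           seed = 1L) {
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features", call. = FALSE)
  stopifnot(frac_group1 >= 0, frac_group1 <= 1, n_cell_lines > 0, n_features > 0,
            n_genes > 0, nrow(genome) > 0, all(genome$length > 0),
            n_replicates >= 2, attenuation >= 0)
  spec <- as.list(environment())
  class(spec) <- "synthetic_spec"
  spec
}

#' @rdname synthetic_spec
#' @export
default_analyte_classes <- function() {
  tibble::tibble(
    class = c("glutathione", "glutamate dipeptide", "nucleotide", "amino acid",
              "TCA", "sugar phosphate", "cofactor", "urea cycle"),
    n = c(8L, 10L, 12L, 15L, 10L, 9L, 8L, 8L),
    log2fc = c(-2, 0, 0, 0, 0, 0, 0, 0))
}

#' @rdname synthetic_spec
#' @export
default_lipid_classes <- function() {
  tibble::tibble(
    class = c("TAG", "DAG", "CE", "PC", "PE", "LPE", "SM", "FFA"),
    n = c(12L, 10L, 8L, 14L, 12L, 8L, 9L, 10L),
    log2fc = c(1.5, -1, 0, 0, 0, 0, 0, 0))
}

# Deterministic per-stage substream of the master seed: a multiplicative
# hash of the stage name mixed with the seed, kept inside 32-bit range.
substream_seed <- function(seed, stage) {
  ch <- utf8ToInt(stage)
  h <- sum((ch * seq_along(ch)) %% 65521) %% 65521
  as.integer((as.numeric(seed) * 65537 + h * 2654435.0) %% 2147483647)
}

#' Simulate a multi-omic dependency dataset
#'
#' Builds a cell-lines-by-features matrix of standard-normal multi-omic
#' features, of which `n_informative` drive a latent dependency; the
#' Chronos-like and Demeter-like screens observe that latent score (offset
#' to centre near the -0.5 dependency threshold) with independent
#' Gaussian noise of SD `noise_sd`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `features` (tibble, `cell_line` + feature columns),
#'   `feature_meta` (feature, omic type), `dependency` (cell_line,
#'   chronos, demeter), and `truth_features` (feature, `truth_informative`,
#'   `truth_beta`).
#' @export
simulate_dependency_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(substream_seed(spec$seed, "dependency"))
  n <- spec$n_cell_lines
  p <- spec$n_features
  k <- spec$n_informative
  X <- matrix(stats::rnorm(n * p), nrow = n)
  feat <- sprintf("feat_%04d", seq_len(p))
  colnames(X) <- feat
  informative <- sort(sample.int(p, k))
  beta <- numeric(p)
  beta[informative] <- spec$effect_size
  latent <- if (k > 0) drop(X[, informative, drop = FALSE] %*% beta[informative]) / sqrt(max(k, 1))
            else numeric(n)
  chronos <- -0.5 + latent + stats::rnorm(n, sd = spec$noise_sd)
  demeter <- -0.5 + latent + stats::rnorm(n, sd = spec$noise_sd)
  lines <- sprintf("line_%03d", seq_len(n))
  omic <- sample(c("expression", "mutation", "copy number", "pathway",
                   "metabolite", "other"), p, replace = TRUE)
  list(
    features = tibble::as_tibble(cbind(tibble::tibble(cell_line = lines),
                                       tibble::as_tibble(X))),
    feature_meta = tibble::tibble(feature = feat, omic_type = omic),
    dependency = tibble::tibble(cell_line = lines, chronos = chronos,
                                demeter = demeter),
    truth_features = tibble::tibble(feature = feat,
                                    truth_informative = seq_len(p) %in% informative,
                                    truth_beta = beta))
}

#' Simulate a toy regulome with planted promoter and enhancer structure
#'
#' Genes are laid on a jittered grid across the toy genome. Group II
#' signature genes receive an NRF2 peak inside the +/-1 kb promoter
#' window; group I signature genes receive an NRF2 peak 5-50 kb away with
#' an enhancer chromatin state and an H3K27ac peak at that site, plus a
#' planted contact link (CCscore `true_link_ccscore`) joining the
#' promoter bin to the enhancer bin; a fraction of group I genes get a
#' second enhancer (higher-order linkage). Background links connect
#' random same-chromosome bin pairs with left-truncated exponential
#' CCscores. The PRO-seq differential table is responsive (logFC < 0,
#' p < 0.1 in all four conditions) at signature promoters and planted
#' enhancers, and null elsewhere.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `promoters`, `peaks` (named list NRF2/p300/H3K4me3/
#'   H3K27ac), `chromatin_states`, `proseq`, `links`, `genome`,
#'   `truth_genes`, `truth_links`.
#' @export
simulate_regulome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(substream_seed(spec$seed, "regulome"))
  genome <- spec$genome
  n_sig <- spec$n_genes
  n_non <- spec$n_nonsig_genes
  n_all <- n_sig + n_non
  margin <- 1.5e5
  spacing <- 1.2e5
  slots <- purrr::map2_dfr(genome$chrom, genome$length, function(ch, len) {
    pos <- seq(margin, len - margin, by = spacing)
    tibble::tibble(chrom = ch, slot = pos)
  })
  if (nrow(slots) < n_all)
    stop("chromosomes too short for requested gene placements", call. = FALSE)
  slots <- slots[sort(sample.int(nrow(slots), n_all)), ]
  tss <- round(slots$slot + stats::runif(n_all, -2e4, 2e4))
  strand <- sample(c("+", "-"), n_all, replace = TRUE)
  gene <- c(sprintf("SIG%03d", seq_len(n_sig)), sprintf("GEN%03d", seq_len(n_non)))
  signature <- rep(c(TRUE, FALSE), c(n_sig, n_non))
  promoters <- tibble::tibble(
    gene = gene, chrom = slots$chrom, tss = tss, strand = strand,
    gene_start = ifelse(strand == "+", tss, tss - 1e4),
    gene_end = ifelse(strand == "+", tss + 1e4, tss + 1),
    signature = signature)

  n_g1 <- round(spec$frac_group1 * n_sig)
  group <- rep("II", n_sig)
  if (n_g1 > 0) group[sample.int(n_sig, n_g1)] <- "I"

  # enhancer allocation for group I genes
  g1_idx <- which(group == "I")
  n_enh <- integer(n_sig)
  if (length(g1_idx) > 0) {
    if (is.null(spec$n_true_links)) {
      n2 <- round(spec$frac_higher_order * length(g1_idx))
      n_enh[g1_idx] <- 1L
      if (n2 > 0) n_enh[g1_idx[seq_len(n2)]] <- 2L
    } else {
      total <- spec$n_true_links
      first <- pmin(length(g1_idx), total)
      n_enh[g1_idx[seq_len(first)]] <- 1L
      extra <- total - first
      if (extra > length(g1_idx))
        stop("n_true_links exceeds 2 links per group I gene", call. = FALSE)
      if (extra > 0) n_enh[g1_idx[seq_len(extra)]] <- 2L
    }
  }

  pw <- 150  # peak half-width
  peak_sig <- function(n) pmax(stats::rnorm(n, 30, 5), 5)
  nrf2 <- list(); h3k27 <- list(); states <- list(); true_links <- list()
  enh_rows <- list()
  res <- 5000
  offsets_grid <- seq(6000, 48000, by = 6000)
  for (i in seq_len(n_sig)) {
    ch <- promoters$chrom[i]; t0 <- promoters$tss[i]
    if (group[i] == "II") {
      centre <- t0 + round(stats::runif(1, -600, 600))
      nrf2[[length(nrf2) + 1]] <- tibble::tibble(
        chrom = ch, start = centre - pw, end = centre + pw,
        name = paste0("NRF2_prom_", gene[i]), strand = ".",
        signal = peak_sig(1), qvalue = stats::runif(1, 0, 0.01))
    }
    if (n_enh[i] > 0) {
      mags <- sample(offsets_grid, n_enh[i])
      signs <- sample(c(-1, 1), n_enh[i], replace = TRUE)
      for (e in seq_len(n_enh[i])) {
        centre <- t0 + signs[e] * mags[e]
        nrf2[[length(nrf2) + 1]] <- tibble::tibble(
          chrom = ch, start = centre - pw, end = centre + pw,
          name = paste0("NRF2_enh_", gene[i], "_", e), strand = ".",
          signal = peak_sig(1), qvalue = stats::runif(1, 0, 0.01))
        h3k27[[length(h3k27) + 1]] <- tibble::tibble(
          chrom = ch, start = centre - 800, end = centre + 800,
          name = paste0("H3K27ac_enh_", gene[i], "_", e), strand = ".",
          signal = peak_sig(1), qvalue = NA_real_)
        states[[length(states) + 1]] <- tibble::tibble(
          chrom = ch, start = centre - 1000, end = centre + 1000,
          state = "Enhancer")
        true_links[[length(true_links) + 1]] <- tibble::tibble(
          chrom1 = ch, start1 = bin_floor(t0, res), end1 = bin_floor(t0, res) + res,
          chrom2 = ch, start2 = bin_floor(centre, res), end2 = bin_floor(centre, res) + res,
          ccscore = spec$true_link_ccscore,
          pvalue = stats::runif(1, 0, 0.01),
          gene = gene[i])
        enh_rows[[length(enh_rows) + 1]] <- tibble::tibble(
          gene = gene[i], chrom = ch, centre = centre)
      }
    }
  }
  nrf2 <- dplyr::bind_rows(nrf2)
  h3k27_prom <- tibble::tibble(
    chrom = promoters$chrom, start = promoters$tss - 700,
    end = promoters$tss + 700,
    name = paste0("H3K27ac_prom_", gene), strand = ".",
    signal = peak_sig(n_all), qvalue = NA_real_)
  h3k27 <- dplyr::bind_rows(c(h3k27, list(h3k27_prom)))
  h3k4me3 <- tibble::tibble(
    chrom = promoters$chrom, start = promoters$tss - 500,
    end = promoters$tss + 500,
    name = paste0("H3K4me3_", gene), strand = ".",
    signal = peak_sig(n_all), qvalue = NA_real_)
  p300 <- dplyr::mutate(nrf2, name = sub("NRF2", "p300", .data$name),
                        signal = peak_sig(nrow(nrf2)))

  # background NRF2 peaks, rejected away from promoter windows and
  # planted enhancers so planted structure stays clean
  n_bg_pk <- 30
  bg <- list()
  avoid <- dplyr::bind_rows(
    tibble::tibble(chrom = promoters$chrom, start = promoters$tss - 2000,
                   end = promoters$tss + 2000),
    nrf2[c("chrom", "start", "end")])
  tries <- 0
  while (length(bg) < n_bg_pk && tries < 2000) {
    tries <- tries + 1
    j <- sample.int(nrow(genome), 1, prob = genome$length)
    centre <- round(stats::runif(1, 1e4, genome$length[j] - 1e4))
    cand <- tibble::tibble(chrom = genome$chrom[j], start = centre - pw,
                           end = centre + pw)
    if (!overlaps_any(cand, avoid)) {
      bg[[length(bg) + 1]] <- dplyr::mutate(
        cand, name = sprintf("NRF2_bg_%03d", length(bg) + 1), strand = ".",
        signal = pmax(stats::rnorm(1, 8, 3), 1), qvalue = stats::runif(1, 0, 0.05))
    }
  }
  nrf2 <- dplyr::bind_rows(nrf2, dplyr::bind_rows(bg))

  # PRO-seq differential table over four conditions
  conditions <- c("A549_3h", "A549_6h", "H460_3h", "H460_6h")
  enh_tbl <- dplyr::bind_rows(enh_rows)
  resp_prom <- tibble::tibble(
    chrom = promoters$chrom[signature], start = promoters$tss[signature] - 300,
    end = promoters$tss[signature] + 300,
    name = paste0("pro_prom_", gene[signature]), responsive = TRUE)
  resp_enh <- if (nrow(enh_tbl) > 0) tibble::tibble(
    chrom = enh_tbl$chrom, start = enh_tbl$centre - 300, end = enh_tbl$centre + 300,
    name = paste0("pro_enh_", enh_tbl$gene, "_", seq_len(nrow(enh_tbl))),
    responsive = TRUE) else NULL
  n_null <- 40
  null_pos <- purrr::map_dfr(seq_len(n_null), function(i) {
    j <- sample.int(nrow(genome), 1, prob = genome$length)
    centre <- round(stats::runif(1, 1e4, genome$length[j] - 1e4))
    tibble::tibble(chrom = genome$chrom[j], start = centre - 300, end = centre + 300,
                   name = sprintf("pro_null_%03d", i), responsive = FALSE)
  })
  proseq <- dplyr::bind_rows(resp_prom, resp_enh, null_pos)
  for (cond in conditions) {
    lfc <- ifelse(proseq$responsive,
                  -stats::rlnorm(nrow(proseq), meanlog = 0, sdlog = 0.4),
                  stats::rnorm(nrow(proseq), 0, 0.5))
    p <- ifelse(proseq$responsive,
                stats::runif(nrow(proseq), 0, 0.02),
                stats::runif(nrow(proseq)))
    proseq[[paste0("logfc_", cond)]] <- lfc
    proseq[[paste0("p_", cond)]] <- p
  }
  names(proseq)[names(proseq) == "responsive"] <- "truth_responsive"

  # links: planted + background
  true_links <- dplyr::bind_rows(true_links)
  n_bg <- spec$n_background_links
  bg_links <- purrr::map_dfr(seq_len(n_bg), function(i) {
    j <- sample.int(nrow(genome), 1, prob = genome$length)
    len <- genome$length[j]
    a1 <- bin_floor(stats::runif(1, 0, len - 2.1e6), res)
    gap <- bin_floor(stats::runif(1, 1e4, 2e6), res)
    tibble::tibble(chrom1 = genome$chrom[j], start1 = a1, end1 = a1 + res,
                   chrom2 = genome$chrom[j], start2 = a1 + gap, end2 = a1 + gap + res,
                   ccscore = 1.0 + stats::rexp(1, rate = 2/3),
                   pvalue = stats::runif(1), gene = NA_character_)
  })
  links <- validate_links(dplyr::bind_rows(
    dplyr::mutate(true_links, truth_true = TRUE),
    dplyr::mutate(bg_links, truth_true = FALSE)))
  links$name <- sprintf("link_%03d", seq_len(nrow(links)))

  truth_genes <- tibble::tibble(
    gene = gene, truth_signature = signature,
    truth_group = c(group, rep(NA_character_, n_non)),
    truth_n_enhancers = c(n_enh, rep(0L, n_non)))

  list(promoters = promoters,
       peaks = list(NRF2 = validate_intervals(nrf2),
                    p300 = validate_intervals(p300),
                    H3K4me3 = validate_intervals(h3k4me3),
                    H3K27ac = validate_intervals(h3k27)),
       chromatin_states = validate_intervals(
         if (length(states) > 0) dplyr::bind_rows(states)
         else tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric(), state = character())),
       proseq = proseq,
       links = links,
       genome = genome,
       truth_genes = truth_genes,
       truth_links = links[c("name", "gene", "truth_true")])
}

#' Simulate rescue transcriptomes and analyte tables
#'
#' The rescue table mimics a knockdown / re-expression experiment: an
#' NRF2-responsive gene subset gains expression under WT rescue; within
#' it, a CBP/p300-reliant subset responds under the coactivator-binding
#' mutant only by `attenuation` times the WT (luciferase-normalized)
#' response, so its true diagonal cosine is below 1. Analyte tables carry
#' log-normal abundances with the planted per-class WT-vs-control shifts
#' of `analyte_classes` / `lipid_classes`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `rescue` (gene, mean_log2_cpm, logfc_wt, logfc_mut,
#'   logfc_luc, truth columns), `metabolites` and `lipids` (long analyte
#'   tables: analyte, class, sample, condition, abundance), and
#'   `truth_classes`.
#' @export
simulate_rescue_and_omics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stopifnot(nrow(spec$analyte_classes) > 0)
  set.seed(substream_seed(spec$seed, "rescue"))
  n <- spec$n_rescue_genes
  gene <- sprintf("RG%04d", seq_len(n))
  mean_log2_cpm <- c(stats::rnorm(round(0.9 * n), 4, 2),
                     stats::rnorm(n - round(0.9 * n), -3, 1))[sample.int(n)]
  responsive <- stats::runif(n) < 0.3
  reliant <- responsive & stats::runif(n) < spec$reliant_frac
  logfc_luc <- stats::rnorm(n, 0, 0.1)
  wt_resp <- ifelse(responsive, stats::rlnorm(n, meanlog = 0.3, sdlog = 0.4),
                    stats::rnorm(n, 0, 0.15))
  logfc_wt <- logfc_luc + wt_resp + stats::rnorm(n, 0, spec$rescue_noise_sd)
  mut_resp <- ifelse(reliant, spec$attenuation * wt_resp, wt_resp)
  logfc_mut <- logfc_luc + mut_resp + stats::rnorm(n, 0, spec$rescue_noise_sd)
  rescue <- tibble::tibble(
    gene = gene, mean_log2_cpm = mean_log2_cpm,
    logfc_wt = logfc_wt, logfc_mut = logfc_mut, logfc_luc = logfc_luc,
    truth_responsive = responsive, truth_reliant = reliant)

  sim_assay <- function(classes, stage) {
    set.seed(substream_seed(spec$seed, stage))
    purrr::pmap_dfr(classes, function(class, n, log2fc) {
      analyte <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "_", class), seq_len(n))
      base <- stats::rnorm(n, 17, 2)
      purrr::map_dfr(seq_len(n), function(i) {
        reps <- spec$n_replicates
        ctrl <- base[i] + stats::rnorm(reps, 0, spec$analyte_noise_sd)
        trt <- base[i] + log2fc + stats::rnorm(reps, 0, spec$analyte_noise_sd)
        tibble::tibble(
          analyte = analyte[i], class = class,
          sample = c(paste0("WT_", seq_len(reps)), paste0("luc_", seq_len(reps))),
          condition = rep(c("WT", "luc"), each = reps),
          abundance = 2^c(trt, ctrl))
      })
    })
  }
  truth_classes <- dplyr::bind_rows(
    dplyr::mutate(spec$analyte_classes, assay = "metabolite"),
    dplyr::mutate(spec$lipid_classes, assay = "lipid"))
  names(truth_classes)[names(truth_classes) == "log2fc"] <- "truth_log2fc"

  list(rescue = rescue,
       metabolites = sim_assay(spec$analyte_classes, "metabolites"),
       lipids = sim_assay(spec$lipid_classes, "lipids"),
       truth_classes = truth_classes[c("assay", "class", "n", "truth_log2fc")])
}

#' Write a simulated regulome to standard-format files
#'
#' Emits the BED/BEDPE/TSV dialects the package readers parse: one BED
#' per ChIP factor, a chromatin-state BED, a links BEDPE, and TSVs for
#' promoters, PRO-seq differentials, genome and truth tables (truth
#' columns carry a `truth_` prefix).
#'
#' @param regulome Result of [simulate_regulome()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_synthetic_regulome <- function(regulome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (f in names(regulome$peaks)) {
    p <- file.path(dir, paste0("peaks_", f, ".bed"))
    write_bed(regulome$peaks[[f]], p)
    paths[paste0("peaks_", f)] <- p
  }
  p <- file.path(dir, "chromatin_states.bed")
  readr::write_tsv(regulome$chromatin_states, p, col_names = FALSE, progress = FALSE)
  paths["chromatin_states"] <- p
  paths["links"] <- write_bedpe(regulome$links, file.path(dir, "links.bedpe"))
  for (nm in c("promoters", "proseq", "genome", "truth_genes", "truth_links")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(regulome[[nm]], p, progress = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}
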
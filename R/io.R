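#' Read a BED / narrowPeak-style peak file
#'
#' BED3+ tab-separated, no header. Columns beyond the third follow BED6
#' (`name`, `score`, `strand`); a signal column (narrowPeak `signalValue`,
#' column 7) and an optional q-value column can be pulled by index.
#'
#' @param path File path.
#' @param with_signal Read a signal column? Default `TRUE` when the file
#'   has `signal_col` columns.
#' @param signal_col 1-based index of the signal column (default 7,
#'   narrowPeak `signalValue`).
#' @param qvalue_col Optional 1-based index of a q-value column.
#' @return Tibble of peaks (`chrom`, `start`, `end`, `name`, `strand`,
#'   `signal`, `qvalue`), input order preserved.
#' @export
read_bed <- function(path, with_signal = TRUE, signal_col = 7, qvalue_col = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          name = character(), strand = character(),
                          signal = numeric(), qvalue = numeric()))
  }
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns: ", path, call. = FALSE)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop("malformed BED line ", bad[1], " in ", path, call. = FALSE)
  out <- tibble::tibble(
    chrom = raw[[1]], start = start, end = end,
    name = if (ncol(raw) >= 4) raw[[4]] else paste0("peak_", seq_len(nrow(raw))),
    strand = if (ncol(raw) >= 6 && all(raw[[6]] %in% c("+", "-", "."))) raw[[6]] else ".")
  out$signal <- if (with_signal && ncol(raw) >= signal_col) {
    suppressWarnings(as.numeric(raw[[signal_col]]))
  } else NA_real_
  out$qvalue <- if (!is.null(qvalue_col) && ncol(raw) >= qvalue_col) {
    suppressWarnings(as.numeric(raw[[qvalue_col]]))
  } else NA_real_
  if (any(!is.na(out$signal) & out$signal < 0))
    stop("negative signal value in ", path, call. = FALSE)
  validate_intervals(out)
}

#' Write peaks as BED6 + signal
#'
#' Emits `chrom start end name score strand signal`, the dialect
#' [read_bed()] parses back losslessly (`signal_col = 7`).
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- tibble::tibble(
    chrom = peaks$chrom,
    start = format(peaks$start, scientific = FALSE, trim = TRUE),
    end = format(peaks$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(peaks)) peaks$name else ".",
    score = 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else ".",
    signal = if ("signal" %in% names(peaks)) peaks$signal else 0)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BEDPE link file
#'
#' First six columns are `chrom1 start1 end1 chrom2 start2 end2`; the
#' contact-count score (CCscore) and p-value columns are selected by
#' index. Anchors are returned canonically ordered so that
#' `(chrom1, start1) <= (chrom2, start2)`.
#'
#' @param path File path.
#' @param ccscore_col 1-based index of the CCscore column (default 8,
#'   after a name column).
#' @param pvalue_col Optional 1-based index of the p-value column
#'   (default 9).
#' @return Tibble of links (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `ccscore`, `pvalue`).
#' @export
read_bedpe <- function(path, ccscore_col = 8, pvalue_col = 9) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) return(empty_links())
  if (ncol(raw) < 6) stop("BEDPE needs >= 6 coordinate columns: ", path, call. = FALSE)
  if (ncol(raw) < ccscore_col)
    stop("BEDPE file has no CCscore column at index ", ccscore_col, call. = FALSE)
  num <- function(j) suppressWarnings(as.numeric(raw[[j]]))
  out <- tibble::tibble(
    chrom1 = raw[[1]], start1 = num(2), end1 = num(3),
    chrom2 = raw[[4]], start2 = num(5), end2 = num(6),
    ccscore = num(ccscore_col),
    pvalue = if (!is.null(pvalue_col) && ncol(raw) >= pvalue_col) num(pvalue_col) else NA_real_)
  if (any(is.na(out$start1) | is.na(out$end1) | is.na(out$start2) | is.na(out$end2)))
    stop("malformed BEDPE coordinates in ", path, call. = FALSE)
  if (any(out$start1 < 0 | out$start2 < 0))
    stop("negative BEDPE coordinate in ", path, call. = FALSE)
  validate_links(out)
}

empty_links <- function() {
  tibble::tibble(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                 chrom2 = character(), start2 = numeric(), end2 = numeric(),
                 ccscore = numeric(), pvalue = numeric())
}

#' Validate and canonically order a link table
#'
#' Anchors are swapped where needed so anchor1 sorts at or before anchor2
#' by `(chrom, start)`; CCscores must be non-negative and p-values in
#' \[0, 1\] where present.
#'
#' @param links Link tibble (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `ccscore`, optionally `pvalue`).
#' @return Canonically ordered tibble.
#' @export
validate_links <- function(links) {
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "ccscore") %in% names(links)))
  if (nrow(links) == 0) return(tibble::as_tibble(links))
  if (any(links$start1 < 0 | links$start1 >= links$end1 |
          links$start2 < 0 | links$start2 >= links$end2))
    stop("invalid link anchor coordinates (need 0 <= start < end)", call. = FALSE)
  if (any(links$ccscore < 0, na.rm = TRUE)) stop("ccscore must be >= 0", call. = FALSE)
  if ("pvalue" %in% names(links) &&
      any(links$pvalue < 0 | links$pvalue > 1, na.rm = TRUE))
    stop("link pvalue must be in [0, 1]", call. = FALSE)
  swap <- links$chrom2 < links$chrom1 |
    (links$chrom1 == links$chrom2 & links$start2 < links$start1)
  if (any(swap)) {
    tmp <- links[swap, c("chrom1", "start1", "end1")]
    links[swap, c("chrom1", "start1", "end1")] <-
      links[swap, c("chrom2", "start2", "end2")]
    links[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  tibble::as_tibble(links)
}

#' Write links as BEDPE
#'
#' Emits `chrom1 start1 end1 chrom2 start2 end2 name ccscore pvalue`
#' (plus any extra columns), the dialect [read_bedpe()] parses back with
#' its default column indices.
#'
#' @param links Link tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(links, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  df <- tibble::tibble(
    chrom1 = links$chrom1, start1 = fmt(links$start1), end1 = fmt(links$end1),
    chrom2 = links$chrom2, start2 = fmt(links$start2), end2 = fmt(links$end2),
    name = if ("name" %in% names(links)) links$name else ".",
    ccscore = links$ccscore,
    pvalue = if ("pvalue" %in% names(links)) links$pvalue else NA_real_)
  extra <- setdiff(names(links), c(names(df), "start1", "end1", "start2", "end2"))
  for (cn in extra) df[[cn]] <- links[[cn]]
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration defaults
#'
#' Collects the thresholds the pipeline applies, at their study defaults:
#' a +/-1 kb promoter window, 5 kb link binning, 1000 shuffles with a <5%
#' significance rule, CCscore >= 1 link filter, the "logFC < 0 and
#' p < 0.1 in >= 3 of 4 conditions" consensus rule, and the Chronos < -0.5
#' dependency threshold.
#'
#' @param ... Overrides for any default field.
#' @return Named list of configuration values.
#' @export
#' @examples
#' pipeline_config(n_shuffles = 200)$n_shuffles
pipeline_config <- function(...) {
  cfg <- list(
    promoter_window_bp = 1000,
    link_resolution_bp = 5000,
    n_shuffles = 1000,
    shuffle_alpha = 0.05,
    ccscore_min = 1.0,
    consensus_min_conditions = 3L,
    consensus_logfc_max = 0.0,
    consensus_p_max = 0.1,
    chronos_dependent_max = -0.5,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(promoter_window_bp > 0, link_resolution_bp > 0, n_shuffles > 0,
              shuffle_alpha > 0, shuffle_alpha < 1, ccscore_min >= 0,
              consensus_min_conditions > 0)
  })
  cfg
}
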
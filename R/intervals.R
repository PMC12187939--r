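#' Genomic interval tibbles
#'
#' Intervals throughout the package are plain tibbles in BED convention:
#' 0-based, half-open (`start` inclusive, `end` exclusive), so
#' `width = end - start`. Strand is carried (`+`, `-`, `.`) but ignored by
#' overlap and distance arithmetic; only promoter-window construction is
#' strand-aware.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions (integer bp).
#' @param end 0-based exclusive end positions (integer bp); must exceed
#'   `start`.
#' @param strand Strand, one of `"+"`, `"-"`, `"."`.
#' @param ... Further per-interval columns (e.g. `name`, `signal`).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand` and any
#'   extras, validated against the half-open invariants.
#' @export
#' @examples
#' genomic_intervals("chr1", 100, 200)
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  out <- tibble::tibble(chrom = as.character(chrom),
                        start = as.numeric(start),
                        end = as.numeric(end),
                        strand = strand, ...)
  validate_intervals(out)
}

#' @rdname genomic_intervals
#' @param x A data frame carrying `chrom`, `start`, `end`.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end", call. = FALSE)
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  tibble::as_tibble(x)
}

#' Pairwise interval overlap under half-open semantics
#'
#' Two intervals overlap iff they share a chromosome and at least 1 bp:
#' `a.start < b.end && b.start < a.end`. Touching intervals
#' (`a.end == b.start`) do not overlap, matching bedtools defaults.
#' Vectorized over both arguments (recycled).
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Interval fields.
#' @return Logical vector.
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

#' Which query intervals overlap any subject interval
#'
#' @param query,subjects Interval tibbles (see [genomic_intervals()]).
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subjects) {
  if (nrow(subjects) == 0) return(rep(FALSE, nrow(query)))
  sub_split <- split(subjects[c("start", "end")], subjects$chrom)
  purrr::pmap_lgl(query[c("chrom", "start", "end")], function(chrom, start, end) {
    s <- sub_split[[chrom]]
    !is.null(s) && any(start < s$end & s$start < end)
  })
}

#' Mean subject signal overlapping each query interval
#'
#' For each query interval, the arithmetic mean of `signal` over subject
#' intervals overlapping it, and the overlap count; queries with no
#' overlapping subject score 0 (not `NA`), so downstream rankings have a
#' total order.
#'
#' @param query Interval tibble.
#' @param subjects Interval tibble with a `signal` column.
#' @return `query` with `signal` (mean overlapping signal) and `n_overlap`
#'   columns appended.
#' @export
overlap_signal <- function(query, subjects) {
  stopifnot("signal" %in% names(subjects))
  sub_split <- split(subjects[c("start", "end", "signal")], subjects$chrom)
  res <- purrr::pmap(query[c("chrom", "start", "end")], function(chrom, start, end) {
    s <- sub_split[[chrom]]
    if (is.null(s)) return(c(0, 0))
    hit <- start < s$end & s$start < end
    n <- sum(hit)
    c(if (n > 0) mean(s$signal[hit]) else 0, n)
  })
  query$signal <- purrr::map_dbl(res, 1)
  query$n_overlap <- as.integer(purrr::map_dbl(res, 2))
  query
}

#' Distance to the nearest same-chromosome interval
#'
#' Returns 0 when any subject overlaps the query, otherwise the gap in bp
#' between closest edges (`query.start - subject.end` or
#' `subject.start - query.end`, whichever is non-negative; touching
#' intervals have gap 0). `NA` when no subject shares the chromosome.
#'
#' @param query Single-row interval tibble, or a tibble over which the
#'   computation is vectorized row-wise.
#' @param subjects Interval tibble.
#' @return Numeric vector of distances (bp), `NA` where undefined.
#' @export
nearest_distance <- function(query, subjects) {
  sub_split <- split(subjects[c("start", "end")], subjects$chrom)
  purrr::pmap_dbl(query[c("chrom", "start", "end")], function(chrom, start, end) {
    s <- sub_split[[chrom]]
    if (is.null(s) || nrow(s) == 0) return(NA_real_)
    gap_left <- start - s$end   # subject entirely left of query
    gap_right <- s$start - end  # subject entirely right of query
    d <- pmax(gap_left, gap_right, 0)
    d[start < s$end & s$start < end] <- 0
    min(d)
  })
}

#' Floor interval starts to a genomic bin grid
#'
#' @param pos Positions (bp).
#' @param resolution Bin width (bp), default 5000.
#' @return `floor(pos / resolution) * resolution`, idempotent.
#' @export
bin_floor <- function(pos, resolution = 5000) {
  floor(pos / resolution) * resolution
}
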
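#' Expression filter for rescue transcriptomes
#'
#' Keeps genes with average expression of at least `min_log2_cpm`
#' (inclusive boundary), the -1 log2 CPM floor at the default.
#'
#' @param table Rescue tibble with a `mean_log2_cpm` column.
#' @param min_log2_cpm Inclusive minimum (default -1).
#' @return The retained subset.
#' @export
expression_filter <- function(table, min_log2_cpm = -1) {
  stopifnot("mean_log2_cpm" %in% names(table))
  tibble::as_tibble(table[table$mean_log2_cpm >= min_log2_cpm, , drop = FALSE])
}

#' Normalize rescue log2 fold changes against the luciferase control
#'
#' `norm_wt = logfc_wt - logfc_luc`, `norm_mut = logfc_mut - logfc_luc`;
#' the luciferase column itself is left unchanged. Negative normalized
#' values mean decreased expression relative to the luciferase rescue.
#'
#' @param table Rescue tibble with `logfc_wt`, `logfc_mut`, `logfc_luc`.
#' @return `table` with `norm_wt` and `norm_mut` appended.
#' @export
normalize_rescue <- function(table) {
  for (col in c("logfc_wt", "logfc_mut", "logfc_luc")) {
    if (!col %in% names(table))
      stop("missing column: ", col, call. = FALSE)
  }
  dplyr::mutate(table, norm_wt = .data$logfc_wt - .data$logfc_luc,
                norm_mut = .data$logfc_mut - .data$logfc_luc)
}

#' Cosine similarity to the 1:1 diagonal
#'
#' Cosine of the angle between the point `(norm_wt, norm_mut)` and the
#' diagonal `y = x` representing identical WT and mutant responses:
#' `(norm_wt + norm_mut) / (sqrt(2) * sqrt(norm_wt^2 + norm_mut^2))`.
#' A value of 1 means equal response; divergence lowers the value, and
#' points with negative coordinates can go negative (no clipping). The
#' zero vector has no direction and returns `NA`.
#'
#' @param norm_wt,norm_mut Luciferase-normalized log2 fold changes
#'   (vectorized).
#' @return Cosine in \[-1, 1\], `NA` for the zero vector.
#' @export
#' @examples
#' cosine_to_diagonal(1, 1)  # 1
#' cosine_to_diagonal(1, 0)  # cos(45 deg) ~ 0.7071
cosine_to_diagonal <- function(norm_wt, norm_mut) {
  norm <- sqrt(norm_wt^2 + norm_mut^2)
  ifelse(norm == 0, NA_real_, (norm_wt + norm_mut) / (sqrt(2) * norm))
}

#' Rescue-divergence pipeline
#'
#' Applies the expression filter, luciferase normalization and diagonal
#' cosine in one chain; output is sorted by ascending cosine so the most
#' CBP/p300-divergent genes come first.
#'
#' @param table Rescue tibble (`gene`, `mean_log2_cpm`, `logfc_wt`,
#'   `logfc_mut`, `logfc_luc`).
#' @param min_log2_cpm Expression floor (default -1).
#' @return Filtered tibble with `norm_wt`, `norm_mut`, `cosine`.
#' @export
rescue_divergence <- function(table, min_log2_cpm = -1) {
  table |>
    expression_filter(min_log2_cpm) |>
    normalize_rescue() |>
    dplyr::mutate(cosine = cosine_to_diagonal(.data$norm_wt, .data$norm_mut)) |>
    dplyr::arrange(.data$cosine)
}
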
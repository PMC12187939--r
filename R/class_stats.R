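#' Per-analyte differential abundance
#'
#' A stand-in per-feature engine for relative-quantification assays:
#' log2 fold change is the difference of mean log2 abundances and the
#' p-value a two-sided Welch t-test on log2 abundances. Externally
#' computed per-analyte statistics (e.g. limma-voom output) can be fed
#' straight to [class_statistics()] instead. Analytes with both
#' condition vectors identical carry no evidence and get p = 1; analytes
#' with fewer than 2 replicates in either condition are skipped with a
#' warning.
#'
#' @param table Long analyte tibble: `analyte`, `class`, `sample`,
#'   `condition`, `abundance` (positive).
#' @param cond_a,cond_b Condition labels; log2fc is a minus b.
#' @return Tibble per analyte: `analyte`, `class`, `log2fc`, `p`.
#' @export
analyte_differential <- function(table, cond_a, cond_b) {
  stopifnot(all(c("analyte", "class", "condition", "abundance") %in% names(table)),
            all(table$abundance > 0))
  if (!all(c(cond_a, cond_b) %in% table$condition))
    stop("both conditions must be present", call. = FALSE)
  res <- table |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::group_by(.data$analyte, .data$class) |>
    dplyr::group_map(function(d, key) {
      a <- log2(d$abundance[d$condition == cond_a])
      b <- log2(d$abundance[d$condition == cond_b])
      if (length(a) < 2 || length(b) < 2) {
        warning("skipping analyte with <2 replicates: ", key$analyte,
                call. = FALSE)
        return(NULL)
      }
      lfc <- mean(a) - mean(b)
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        1  # degenerate variance: no evidence either way
      } else {
        stats::t.test(a, b)$p.value
      }
      tibble::tibble(analyte = key$analyte, class = key$class,
                     log2fc = lfc, p = p)
    }) |>
    dplyr::bind_rows()
  res
}

#' Tippett's method for combining p-values
#'
#' The combined p-value of `k` tests through their minimum:
#' `1 - (1 - min(p))^k`.
#'
#' @param pvalues Non-empty vector of p-values in \[0, 1\].
#' @return Combined p-value.
#' @export
#' @examples
#' tippett_combine(c(0.01, 0.5, 0.9))  # 1 - 0.99^3
tippett_combine <- function(pvalues) {
  if (length(pvalues) == 0) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  1 - (1 - min(pvalues))^length(pvalues)
}

#' Class-level statistics by direction
#'
#' Groups per-analyte results by (class, sign of log2fc), combines each
#' group's p-values with Tippett's method, and BH-adjusts the combined
#' p-values jointly across all groups of the assay. Analytes with
#' exactly zero log2fc have no direction and are excluded (with a
#' message).
#'
#' @param per_analyte Tibble: `analyte`, `class`, `log2fc`, `p` — from
#'   [analyte_differential()] or an external engine.
#' @return Tibble per (class, direction): `k`, `mean_log2fc`, `min_p`,
#'   `combined_p`, `q_value`.
#' @export
class_statistics <- function(per_analyte) {
  stopifnot(all(c("class", "log2fc", "p") %in% names(per_analyte)))
  zero <- per_analyte$log2fc == 0
  if (any(zero)) {
    message(sum(zero), " analyte(s) with log2fc exactly 0 excluded from ",
            "direction groups")
    per_analyte <- per_analyte[!zero, , drop = FALSE]
  }
  out <- per_analyte |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    dplyr::group_by(.data$class, .data$direction) |>
    dplyr::summarise(k = dplyr::n(),
                     mean_log2fc = mean(.data$log2fc),
                     min_p = min(.data$p),
                     combined_p = tippett_combine(.data$p),
                     .groups = "drop")
  out$q_value <- stats::p.adjust(out$combined_p, method = "BH")
  dplyr::arrange(out, .data$q_value, .data$combined_p)
}
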
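.norm_chrom <- function(x) {
  if_else(stringr::str_starts(x, "chr"), x, paste0("chr", x))
}

.as_granges <- function(df, what = "intervals") {
  if (any(df$start >= df$end)) {
    abort(sprintf("malformed %s: start must be < end", what))
  }
  GenomicRanges::GRanges(
    .norm_chrom(df$chrom),
    IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Flag elements overlapping a peak set
#'
#' An element overlaps when it shares at least `min_overlap` bases with at
#' least one peak on the same chromosome (coordinates 0-based half-open,
#' "chr" prefixes harmonised). Optionally require the shared bases to be at
#' least a fraction of the element length.
#'
#' @param elements Tibble with `chrom`, `start`, `end` (and usually
#'   `element_id`).
#' @param peaks Tibble with `chrom`, `start`, `end`.
#' @param min_overlap Minimum shared bases (default 1, the BedTools
#'   convention).
#' @param min_frac Optional minimum shared fraction of the element length.
#' @return The `elements` tibble with a logical `overlaps` column appended.
#' @export
intersect_peaks <- function(elements, peaks, min_overlap = 1,
                            min_frac = NULL) {
  gr_e <- .as_granges(elements, "elements")
  gr_p <- .as_granges(peaks, "peaks")
  hits <- GenomicRanges::findOverlaps(gr_e, gr_p,
                                      minoverlap = as.integer(min_overlap))
  q <- S4Vectors::queryHits(hits)
  if (!is.null(min_frac)) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_e)[q],
      IRanges::ranges(gr_p)[S4Vectors::subjectHits(hits)]
    ))
    q <- q[w / IRanges::width(IRanges::ranges(gr_e)[q]) >= min_frac]
  }
  elements$overlaps <- seq_len(nrow(elements)) %in% q
  elements
}

#' Fisher enrichment of peak overlap in active vs inactive elements
#'
#' Builds the 2x2 table (active/inactive x overlapping/non-overlapping) and
#' computes the exact hypergeometric p-value and the odds ratio (with
#' Haldane's 0.5 correction when a cell is zero). A table with an empty
#' margin is flagged degenerate with `p = 1`.
#'
#' @param overlaps Logical vector of per-element overlap flags.
#' @param active Logical vector of per-element active flags (same length).
#' @param dataset_id Label for the peak set.
#' @param alternative Sidedness of the Fisher test (default two-sided).
#' @return One-row tibble with the table cells, `odds_ratio`, `p_value`,
#'   `degenerate`.
#' @export
fisher_enrichment <- function(overlaps, active, dataset_id = "peaks",
                              alternative = "two.sided") {
  stopifnot(length(overlaps) == length(active))
  a <- sum(active & overlaps); b <- sum(active & !overlaps)
  c_ <- sum(!active & overlaps); d <- sum(!active & !overlaps)
  degenerate <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
  or <- if (min(a, b, c_, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  p <- if (degenerate) {
    1
  } else {
    fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                alternative = alternative)$p.value
  }
  tibble(dataset_id = dataset_id,
         active_overlap = a, active_no_overlap = b,
         inactive_overlap = c_, inactive_no_overlap = d,
         odds_ratio = or, p_value = p, degenerate = degenerate)
}

#' Element counts per dataset-membership pattern
#'
#' The exact counts behind an UpSet plot: for overlap flags across several
#' peak datasets, counts of elements per membership pattern (pattern counts
#' always sum to the number of elements), plus the overall fraction of
#' elements overlapping at least one dataset.
#'
#' @param flags Tibble with `element_id` and one logical column per dataset.
#' @param active Optional logical vector splitting counts into active and
#'   inactive.
#' @return Tibble (pattern, n, and n_active/n_inactive when `active` is
#'   given) with attribute `overlap_fraction`.
#' @export
upset_counts <- function(flags, active = NULL) {
  ds <- setdiff(names(flags), "element_id")
  if (length(ds) < 1) abort("input error: need at least one dataset column")
  m <- as.matrix(flags[ds])
  pattern <- apply(m, 1, function(fl) {
    if (!any(fl)) "none" else paste(ds[fl], collapse = "&")
  })
  out <- tibble(pattern = pattern)
  if (!is.null(active)) {
    stopifnot(length(active) == nrow(flags))
    out$active <- active
    res <- out |>
      group_by(.data$pattern) |>
      summarise(n = dplyr::n(), n_active = sum(.data$active),
                n_inactive = sum(!.data$active), .groups = "drop") |>
      arrange(dplyr::desc(.data$n))
  } else {
    res <- out |> count(.data$pattern, name = "n") |>
      arrange(dplyr::desc(.data$n))
  }
  attr(res, "overlap_fraction") <- mean(rowSums(m) > 0)
  res
}
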
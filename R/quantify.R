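#' Quality-control filter for barcode counts
#'
#' Drops barcodes whose DNA count falls below `min_dna` in a sample, then
#' drops elements left with fewer than `min_barcodes` surviving barcodes in
#' any sample. Elements with too little DNA representation give unstable
#' RNA/DNA ratios, so both thresholds act on the DNA side.
#'
#' @param counts Barcode-count tibble (element_id, barcode, sample_id,
#'   dna_count, rna_count).
#' @param min_barcodes Minimum surviving barcodes per element per sample.
#' @param min_dna Minimum DNA count for a barcode to survive in a sample.
#' @param n_designed Number of designed elements, used for the recovered
#'   fraction; defaults to the number of distinct elements in `counts`.
#' @return The filtered counts tibble, with attributes `qc_report` (tibble:
#'   element_id, min_barcodes_per_sample, pass, reason) and
#'   `recovered_fraction`.
#' @export
qc_filter <- function(counts, min_barcodes = 10, min_dna = 1,
                      n_designed = NULL) {
  if (is.null(counts) || nrow(counts) == 0) {
    abort("input error: `counts` is empty")
  }
  all_elements <- unique(counts$element_id)
  n_designed <- n_designed %||% length(all_elements)
  kept <- counts |> filter(.data$dna_count >= min_dna)
  per_sample <- kept |>
    count(.data$element_id, .data$sample_id, name = "n_bc")
  # an element must clear min_barcodes in every sample it was measured in;
  # samples where it vanished entirely count as zero
  n_samples <- length(unique(counts$sample_id))
  worst <- per_sample |>
    group_by(.data$element_id) |>
    summarise(min_bc = if (dplyr::n() < n_samples) 0L else min(.data$n_bc),
              .groups = "drop")
  report <- tibble(element_id = all_elements) |>
    left_join(worst, by = "element_id") |>
    mutate(
      min_barcodes_per_sample = dplyr::coalesce(.data$min_bc, 0L),
      pass = .data$min_barcodes_per_sample >= min_barcodes,
      reason = if_else(.data$pass, NA_character_, "insufficient_barcodes")
    ) |>
    select("element_id", "min_barcodes_per_sample", "pass", "reason")
  out <- kept |> filter(.data$element_id %in% report$element_id[report$pass])
  attr(out, "qc_report") <- report
  attr(out, "recovered_fraction") <- length(all_elements) / n_designed
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param counts A tibble returned by [qc_filter()].
#' @return The per-element QC report tibble.
#' @export
qc_report <- function(counts) attr(counts, "qc_report")

#' Compute per-element, per-sample enhancer activity
#'
#' Activity is the library-size-normalised ratio of summed RNA barcode counts
#' to summed DNA barcode counts (sum-then-divide, which is robust to
#' low-count barcodes): per sample, size factors `f(s) = total counts in s /
#' median total across samples` are computed separately for DNA and RNA, and
#' `a(e, s) = ((sum rna + pseudocount)/f_rna) / ((sum dna + pseudocount)/f_dna)`.
#'
#' @param counts QC-filtered barcode counts.
#' @param samples Sample sheet tibble (sample_id, line_id, time_point); every
#'   sample in `counts` must appear.
#' @param pseudocount Added to both count sums to keep zero-RNA elements
#'   finite.
#' @return Tibble (element_id, sample_id, activity, n_bc) with attribute
#'   `size_factors`.
#' @export
compute_activity <- function(counts, samples, pseudocount = 1) {
  if (nrow(counts) == 0) abort("input error: `counts` is empty")
  missing_s <- setdiff(unique(counts$sample_id), samples$sample_id)
  if (length(missing_s) > 0) {
    abort(sprintf("sample sheet is missing sample(s): %s",
                  paste(missing_s, collapse = ", ")))
  }
  totals <- counts |>
    group_by(.data$sample_id) |>
    summarise(dna_total = sum(.data$dna_count),
              rna_total = sum(.data$rna_count), .groups = "drop")
  if (any(totals$dna_total == 0) || any(totals$rna_total == 0)) {
    bad <- totals$sample_id[totals$dna_total == 0 | totals$rna_total == 0]
    abort(sprintf("degenerate-sample error: zero total counts in %s",
                  paste(bad, collapse = ", ")))
  }
  totals <- totals |>
    mutate(f_dna = .data$dna_total / median(.data$dna_total),
           f_rna = .data$rna_total / median(.data$rna_total))
  act <- counts |>
    group_by(.data$element_id, .data$sample_id) |>
    summarise(dna = sum(.data$dna_count), rna = sum(.data$rna_count),
              n_bc = dplyr::n(), .groups = "drop") |>
    left_join(select(totals, "sample_id", "f_dna", "f_rna"), by = "sample_id") |>
    mutate(activity = ((.data$rna + pseudocount) / .data$f_rna) /
             ((.data$dna + pseudocount) / .data$f_dna)) |>
    select("element_id", "sample_id", "activity", "n_bc")
  attr(act, "size_factors") <- select(totals, "sample_id", "f_dna", "f_rna")
  act
}

#' Collapse replicate samples to per-time-point activity
#'
#' Arithmetic mean of activity over the replicate samples (cell lines) of
#' each time point, on the linear activity scale. Elements missing from all
#' samples of a time point are reported as `NA`, not zero.
#'
#' @param activity Tibble from [compute_activity()].
#' @param samples Sample sheet tibble.
#' @return Tibble (element_id, time_point, activity, n_samples).
#' @export
collapse_by_timepoint <- function(activity, samples) {
  tps <- unique(samples$time_point)
  if (length(tps) == 0) abort("input error: sample sheet has no time points")
  collapsed <- activity |>
    inner_join(select(samples, "sample_id", "time_point"), by = "sample_id") |>
    group_by(.data$element_id, .data$time_point) |>
    summarise(activity = mean(.data$activity), n_samples = dplyr::n(),
              .groups = "drop")
  # elements absent from every sample of a time point -> explicit NA rows
  full <- tidyr::expand_grid(element_id = unique(activity$element_id),
                             time_point = tps)
  full |>
    left_join(collapsed, by = c("element_id", "time_point")) |>
    mutate(n_samples = dplyr::coalesce(.data$n_samples, 0L),
           time_point = factor(.data$time_point, levels = tps) |> as.character())
}
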
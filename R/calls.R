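.bg_cutoff <- function(model, threshold) {
  if (model$degenerate) {
    qnorm(1 - threshold, model$mu_pooled, model$sigma_pooled)
  } else {
    qnorm(1 - threshold, model$mu0, model$sigma0)
  }
}

#' Call MPRA-active enhancers against the background component
#'
#' The p-value of each (element, time point) activity is the upper tail of
#' the background component of the fitted mixture (one-sided: enhancers, not
#' silencers). An element is called active when `p < alpha / n_tests`
#' (Bonferroni). Elements with missing (QC-failed) activity are emitted with
#' `active = FALSE`, `p_value = NA` and `qc_missing = TRUE`.
#'
#' @param activity Tibble (element_id, time_point, activity) as produced by
#'   [collapse_by_timepoint()]; per-sample calling works the same way with a
#'   `sample_id` column renamed to `time_point`.
#' @param model A fitted [fit_mixture()] model.
#' @param alpha Family-wise error target.
#' @param n_tests Bonferroni denominator. Defaults to the number of
#'   non-missing tests performed (elements x time points), so the family is
#'   everything reported from the run; pass the number of elements to
#'   reproduce a per-element denominator.
#' @return Tibble (element_id, time_point, activity, p_value, active,
#'   qc_missing) with attribute `calling` (alpha, n_tests, threshold,
#'   cutoff).
#' @export
call_active <- function(activity, model, alpha = 0.05, n_tests = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("configuration error: `alpha` must be in (0, 1)")
  }
  n_tests <- n_tests %||% sum(!is.na(activity$activity))
  if (n_tests < 1) abort("configuration error: `n_tests` must be >= 1")
  threshold <- alpha / n_tests
  p <- background_tail(model, activity$activity)
  calls <- activity |>
    mutate(
      p_value = p,
      active = !is.na(p) & p < threshold,
      qc_missing = is.na(.data$activity)
    ) |>
    select("element_id", "time_point", "activity", "p_value", "active",
           "qc_missing")
  attr(calls, "calling") <- list(
    alpha = alpha, n_tests = n_tests, threshold = threshold,
    cutoff = .bg_cutoff(model, threshold)
  )
  calls
}

#' Classify temporal activity patterns
#'
#' Partitions elements by which time points they are active at: the 2^T
#' Venn classes for T time points. With the canonical iPSC/TD0/TD30 design
#' the 8 classes are `none`, the three `-only` classes, the three pairwise
#' intersections, and `all`. Elements missing a time point are classified
#' from the available flags and flagged `partial`.
#'
#' @param calls Tibble from [call_active()] (one call per element per time
#'   point).
#' @param time_points Optional ordering of time points; defaults to order of
#'   appearance.
#' @return Tibble (element_id, temporal_class, n_active, partial) with
#'   attribute `partition`: a tibble of counts per class.
#' @export
classify_temporal <- function(calls, time_points = NULL) {
  tps <- time_points %||% unique(calls$time_point)
  if (!"qc_missing" %in% names(calls)) calls$qc_missing <- FALSE
  dup <- calls |> count(.data$element_id, .data$time_point) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("each element must have exactly one call per time point")
  }
  wide <- calls |>
    mutate(time_point = factor(.data$time_point, levels = tps)) |>
    select("element_id", "time_point", "active", "qc_missing") |>
    tidyr::pivot_wider(names_from = "time_point",
                       values_from = c("active", "qc_missing"))
  act <- as.matrix(wide[paste0("active_", tps)])
  act[is.na(act)] <- FALSE
  missing_cols <- paste0("qc_missing_", tps)
  miss <- as.matrix(wide[intersect(missing_cols, names(wide))])
  partial <- rowSums(is.na(miss) | miss) > 0
  labels <- apply(act, 1, function(fl) .venn_label(fl, tps))
  classes <- tibble(
    element_id = wide$element_id,
    temporal_class = labels,
    n_active = rowSums(act),
    partial = partial
  )
  lvl <- .venn_levels(tps)
  partition <- classes |>
    mutate(temporal_class = factor(.data$temporal_class, levels = lvl)) |>
    count(.data$temporal_class, name = "n", .drop = FALSE) |>
    mutate(temporal_class = as.character(.data$temporal_class))
  attr(classes, "partition") <- partition
  classes
}

.venn_label <- function(flags, tps) {
  on <- tps[flags]
  if (length(on) == 0) return("none")
  if (length(on) == length(tps)) return("all")
  if (length(on) == 1) return(paste0(on, "-only"))
  paste(on, collapse = "&")
}

.venn_levels <- function(tps) {
  combos <- unlist(lapply(seq_along(tps), function(k) {
    apply(utils::combn(tps, k), 2, function(on) {
      .venn_label(tps %in% on, tps)
    })
  }))
  c("none", combos)
}

#' Fit a single Gaussian to positive-control activities
#'
#' @param positives Numeric vector of positive-control activities.
#' @param two_component Fit a two-component mixture and use the upper
#'   component (for positive-control sets where a fraction is inactive).
#' @return List with `mu_pos`, `sigma_pos` and the fit method used.
#' @export
fit_positive_gaussian <- function(positives, two_component = FALSE) {
  positives <- positives[is.finite(positives)]
  if (length(positives) < 5 || sd(positives) == 0) {
    abort("degenerate positive fit: need more positive-control activities")
  }
  if (two_component) {
    fm <- fit_mixture(positives, min_points = 5)
    if (!fm$degenerate) {
      return(list(mu_pos = fm$mu1, sigma_pos = fm$sigma1,
                  method = "mixture_upper"))
    }
  }
  list(mu_pos = mean(positives), sigma_pos = sd(positives), method = "single")
}

#' Estimate assay sensitivity from the positive-control distribution
#'
#' The activity cutoff `c` is where the background tail equals the
#' per-test Bonferroni threshold `alpha / n_tests`; sensitivity is the area
#' of the positive-control Gaussian above that cutoff divided by its total
#' area: `S = 1 - Phi((c - mu_pos) / sigma_pos)` — the probability that a
#' truly active element clears the significance cutoff.
#'
#' @param model Fitted background [fit_mixture()] model.
#' @param positives Optional numeric vector of positive-control activities;
#'   alternatively supply `mu_pos`/`sigma_pos` directly.
#' @param mu_pos,sigma_pos Positive-control Gaussian parameters.
#' @param alpha Family-wise error target.
#' @param n_tests Bonferroni denominator.
#' @param two_component Passed to [fit_positive_gaussian()].
#' @return One-row tibble (cutoff, sensitivity, alpha, n_tests, mu_pos,
#'   sigma_pos).
#' @export
estimate_sensitivity <- function(model, positives = NULL, mu_pos = NULL,
                                 sigma_pos = NULL, alpha = 0.05,
                                 n_tests = 1, two_component = FALSE) {
  if (!is.null(positives)) {
    fit <- fit_positive_gaussian(positives, two_component = two_component)
    mu_pos <- fit$mu_pos; sigma_pos <- fit$sigma_pos
  }
  if (is.null(mu_pos) || is.null(sigma_pos) || sigma_pos <= 0) {
    abort("degenerate positive fit: supply positives or valid mu_pos/sigma_pos")
  }
  threshold <- alpha / n_tests
  cutoff <- .bg_cutoff(model, threshold)
  tibble(
    cutoff = cutoff,
    sensitivity = pnorm((cutoff - mu_pos) / sigma_pos, lower.tail = FALSE),
    alpha = alpha, n_tests = n_tests, mu_pos = mu_pos, sigma_pos = sigma_pos
  )
}

#' Hierarchical clustering of enhancer activity profiles
#'
#' Ward minimum-variance clustering (on squared Euclidean distances,
#' `hclust` method `ward.D2`) of the element x sample (or element x time
#' point) activity matrix. Missing values are imputed by the row mean and
#' the affected elements flagged. The activity cap applies to display
#' (see [plot_activity_heatmap()]) only, never to the distances.
#'
#' @param activity Long tibble (element_id, sample_id or time_point,
#'   activity).
#' @param cap Display cap on activity (default 4).
#' @param calls Optional [call_active()] result used to report the fraction
#'   of active elements per top-level cluster.
#' @param k Number of top-level clusters to report.
#' @return An object of class `mpra_clustering`: list with `hclust`, `order`
#'   (element ids in dendrogram order), `clusters` (element_id, cluster),
#'   `summary` (per-cluster size and active fraction, if calls given),
#'   `imputed` (element ids with imputed entries), `cap`.
#' @export
cluster_activity <- function(activity, cap = 4, calls = NULL, k = 2) {
  unit <- if ("sample_id" %in% names(activity)) "sample_id" else "time_point"
  wide <- activity |>
    select("element_id", dplyr::all_of(unit), "activity") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(unit),
                       values_from = "activity")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$element_id
  if (nrow(mat) < 2) abort("input error: need at least 2 elements to cluster")
  imputed <- rownames(mat)[rowSums(is.na(mat)) > 0]
  if (length(imputed) > 0) {
    rm_ <- rowMeans(mat, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- rm_[idx[, 1]]
    mat[is.na(mat)] <- 0  # rows that were entirely missing
  }
  hc <- hclust(dist(mat), method = "ward.D2")
  cl <- cutree(hc, k = k)
  clusters <- tibble(element_id = rownames(mat), cluster = unname(cl))
  summary <- clusters |> count(.data$cluster, name = "n_elements")
  if (!is.null(calls)) {
    act_el <- calls |>
      group_by(.data$element_id) |>
      summarise(active_any = any(.data$active), .groups = "drop")
    summary <- clusters |>
      left_join(act_el, by = "element_id") |>
      group_by(.data$cluster) |>
      summarise(n_elements = dplyr::n(),
                n_active = sum(.data$active_any, na.rm = TRUE),
                frac_active = mean(.data$active_any, na.rm = TRUE),
                .groups = "drop")
  }
  structure(list(
    hclust = hc, order = rownames(mat)[hc$order], clusters = clusters,
    summary = summary, imputed = imputed, cap = cap, matrix = mat
  ), class = "mpra_clustering")
}

#' @export
print.mpra_clustering <- function(x, ...) {
  cat(sprintf("Ward clustering of %d elements into %d top-level clusters\n",
              nrow(x$clusters), max(x$clusters$cluster)))
  print(x$summary)
  invisible(x)
}
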
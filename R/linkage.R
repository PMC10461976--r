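#' Group linked-gene expression by enhancer activity status
#'
#' Splits per-gene mean RPKM into three groups: genes linked to at least one
#' MPRA-active enhancer, genes linked only to tested-but-inactive enhancers,
#' and an optional background set (e.g. all gene-linked enhancers genome
#' wide). Groups are compared pairwise with the two-sample KS test.
#'
#' @param links Tibble (element_id, gene_id).
#' @param expression Wide expression tibble: `gene_id` plus one RPKM column
#'   per sample.
#' @param calls [call_active()] result; an element is MPRA-active if active
#'   at any time point.
#' @param background_genes Optional character vector of background-pool gene
#'   ids present in `expression`.
#' @param alternative KS alternative passed to [compare_counts()].
#' @return List with `groups` (gene_id, group, mean_rpkm), `tests`
#'   (comparison, statistic, p_value), and `n_dropped` (linked genes absent
#'   from the expression matrix).
#' @export
expression_by_group <- function(links, expression, calls,
                                background_genes = NULL,
                                alternative = "two.sided") {
  mean_rpkm <- tibble(
    gene_id = expression$gene_id,
    mean_rpkm = rowMeans(as.matrix(expression[setdiff(names(expression), "gene_id")]))
  )
  active_el <- calls |>
    group_by(.data$element_id) |>
    summarise(active = any(.data$active), .groups = "drop")
  gene_status <- links |>
    inner_join(active_el, by = "element_id") |>
    group_by(.data$gene_id) |>
    summarise(group = if_else(any(.data$active), "active_linked",
                              "inactive_linked"),
              .groups = "drop")
  n_dropped <- sum(!gene_status$gene_id %in% mean_rpkm$gene_id)
  if (n_dropped > 0) {
    warn(sprintf("%d linked gene(s) absent from the expression matrix; dropped",
                 n_dropped))
  }
  groups <- gene_status |> inner_join(mean_rpkm, by = "gene_id")
  if (!is.null(background_genes)) {
    bg <- mean_rpkm |>
      filter(.data$gene_id %in% background_genes) |>
      mutate(group = "background")
    groups <- bind_rows(groups, bg[c("gene_id", "group", "mean_rpkm")])
  }
  gs <- unique(groups$group)
  combos <- if (length(gs) >= 2) utils::combn(gs, 2, simplify = FALSE) else list()
  tests <- purrr::map_dfr(combos, function(cc) {
    ga <- groups$mean_rpkm[groups$group == cc[1]]
    gb <- groups$mean_rpkm[groups$group == cc[2]]
    if (length(ga) == 0 || length(gb) == 0) {
      warn(sprintf("empty group in comparison %s vs %s; skipped", cc[1], cc[2]))
      return(tibble())
    }
    compare_counts(ga, gb, alternative = alternative) |>
      mutate(comparison = paste(cc[1], "vs", cc[2]), .before = 1)
  })
  list(groups = groups, tests = tests, n_dropped = n_dropped)
}

#' Per-link activity and expression log2 fold changes between two time points
#'
#' For every enhancer-gene link, `dA = log2((a(e, tp_b) + eps) / (a(e, tp_a)
#' + eps))` and `dE = log2((mean RPKM(g, tp_b) + eps) / (mean RPKM(g, tp_a)
#' + eps))`, where expression per time point is the mean over that time
#' point's samples.
#'
#' @param activity Per-time-point activity tibble from
#'   [collapse_by_timepoint()].
#' @param links Tibble (element_id, gene_id).
#' @param expression Wide expression tibble.
#' @param samples Sample sheet (sample_id, time_point).
#' @param tp_a,tp_b The two time points compared (fold change is b over a).
#' @param pseudocount Added to both ratios (default 0.01) to keep zeros
#'   finite.
#' @return Tibble (element_id, gene_id, dA, dE, tp_a, tp_b); links whose
#'   element or gene is absent are dropped, with the count in attribute
#'   `n_dropped`.
#' @export
pair_deltas <- function(activity, links, expression, samples, tp_a, tp_b,
                        pseudocount = 0.01) {
  if (!all(c(tp_a, tp_b) %in% activity$time_point)) {
    abort("both time points must be present in `activity`")
  }
  if (!all(c(tp_a, tp_b) %in% samples$time_point)) {
    abort("both time points must be present in `samples`")
  }
  act_w <- activity |>
    filter(.data$time_point %in% c(tp_a, tp_b)) |>
    select("element_id", "time_point", "activity") |>
    tidyr::pivot_wider(names_from = "time_point", values_from = "activity")
  expr_tp <- expression |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "rpkm") |>
    inner_join(select(samples, "sample_id", "time_point"), by = "sample_id") |>
    filter(.data$time_point %in% c(tp_a, tp_b)) |>
    group_by(.data$gene_id, .data$time_point) |>
    summarise(rpkm = mean(.data$rpkm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time_point", values_from = "rpkm")
  out <- links |>
    inner_join(act_w, by = "element_id") |>
    inner_join(expr_tp, by = "gene_id", suffix = c("_act", "_exp"))
  a_a <- out[[paste0(tp_a, "_act")]]; a_b <- out[[paste0(tp_b, "_act")]]
  e_a <- out[[paste0(tp_a, "_exp")]]; e_b <- out[[paste0(tp_b, "_exp")]]
  keep <- complete.cases(a_a, a_b, e_a, e_b)
  res <- tibble(
    element_id = out$element_id[keep], gene_id = out$gene_id[keep],
    dA = log2((a_b[keep] + pseudocount) / (a_a[keep] + pseudocount)),
    dE = log2((e_b[keep] + pseudocount) / (e_a[keep] + pseudocount)),
    tp_a = tp_a, tp_b = tp_b
  )
  attr(res, "n_dropped") <- nrow(links) - nrow(res)
  res
}

#' Activity-expression concordance curve
#'
#' For each cutoff `c` of a grid, the fraction of enhancer-gene pairs with
#' both `|dA| >= c` and `|dE| >= c`, computed separately for MPRA-active and
#' inactive elements. Joint exceedance without a sign-agreement requirement
#' is the default because both concordant and anticorrelated pairs count as
#' coupled; `require_sign_match = TRUE` restricts to pairs where dA and dE
#' share a sign.
#'
#' @param pairs [pair_deltas()] result.
#' @param calls Optional [call_active()] result used to split pairs into
#'   `active` / `inactive` element groups; without it a single `all` group
#'   is reported.
#' @param cutoffs Cutoff grid; must include 0 (where the fraction is 1).
#' @param require_sign_match Require `sign(dA) == sign(dE)`.
#' @return Tibble (cutoff, group, fraction, n); `fraction` is `NA` for an
#'   empty group.
#' @export
concordance_curve <- function(pairs, calls = NULL,
                              cutoffs = seq(0, 2, by = 0.1),
                              require_sign_match = FALSE) {
  if (nrow(pairs) == 0) abort("input error: empty pair list")
  if (!any(cutoffs == 0)) abort("cutoff grid must include 0")
  if (!is.null(calls)) {
    active_el <- calls |>
      group_by(.data$element_id) |>
      summarise(active = any(.data$active), .groups = "drop")
    pairs <- pairs |>
      left_join(active_el, by = "element_id") |>
      mutate(group = if_else(dplyr::coalesce(.data$active, FALSE),
                             "active", "inactive"))
  } else {
    pairs$group <- "all"
  }
  groups <- unique(pairs$group)
  purrr::map_dfr(groups, function(g) {
    pg <- pairs |> filter(.data$group == g)
    ok_sign <- if (require_sign_match) sign(pg$dA) == sign(pg$dE) else TRUE
    purrr::map_dfr(cutoffs, function(cc) {
      pass <- abs(pg$dA) >= cc & abs(pg$dE) >= cc & (cc == 0 | ok_sign)
      tibble(cutoff = cc, group = g,
             fraction = if (nrow(pg) == 0) NA_real_ else mean(pass),
             n = nrow(pg))
    })
  })
}
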
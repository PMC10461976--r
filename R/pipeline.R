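#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates simulate -> quantify -> fit background -> call -> sensitivity
#' -> temporal classification -> linkage -> overlap on one synthetic
#' experiment, writing every intermediate as plain text plus a JSON run
#' manifest. Identical configuration and seed give byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param min_barcodes,min_dna QC thresholds, see [qc_filter()].
#' @param pseudocount Activity pseudocount, see [compute_activity()].
#' @param n_bins Histogram bins for [fit_mixture()].
#' @param alpha,n_tests Calling parameters, see [call_active()].
#' @param gof_B Bootstrap replicates for [goodness_of_fit()]; 0 skips it.
#' @param tp_pair Time-point pair for the concordance analysis; defaults to
#'   the first two time points.
#' @param cutoffs Concordance cutoff grid.
#' @param do_cluster Run [cluster_activity()] (quadratic in elements; skip
#'   for very large libraries).
#' @return Invisibly, a list of all in-memory results plus `manifest`.
#' @export
run_pipeline <- function(config, outdir, min_barcodes = 10, min_dna = 1,
                         pseudocount = 1, n_bins = 30, alpha = 0.05,
                         n_tests = NULL, gof_B = 0,
                         tp_pair = NULL, cutoffs = seq(0, 2, by = 0.1),
                         do_cluster = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }

  lib <- stage("simulate", {
    lb <- simulate_library(config)
    cn <- simulate_counts(lb$elements, lb$truth, config)
    ex <- simulate_expression(lb$elements, lb$truth, config)
    pk <- simulate_peaks(lb$elements, lb$truth, seed = config$seed)
    write_bed(lb$elements |> mutate(name = .data$element_id),
              file.path(outdir, "elements.bed"))
    write_fasta(lb$elements, file.path(outdir, "elements.fa"))
    readr::write_tsv(cn$counts, file.path(outdir, "counts.tsv"))
    readr::write_tsv(cn$samples, file.path(outdir, "samples.tsv"))
    readr::write_tsv(ex$expression, file.path(outdir, "expression.tsv"))
    readr::write_tsv(ex$links, file.path(outdir, "links.tsv"))
    readr::write_tsv(lb$truth, file.path(outdir, "truth.tsv"))
    write_bed(pk, file.path(outdir, "peaks.bed"))
    list(lib = lb, counts = cn, expr = ex, peaks = pk)
  })

  quant <- stage("quantify", {
    filtered <- qc_filter(lib$counts$counts, min_barcodes = min_barcodes,
                          min_dna = min_dna,
                          n_designed = nrow(lib$lib$elements))
    act <- compute_activity(filtered, lib$counts$samples,
                            pseudocount = pseudocount)
    act_tp <- collapse_by_timepoint(act, lib$counts$samples)
    readr::write_tsv(qc_report(filtered), file.path(outdir, "qc_report.tsv"))
    readr::write_tsv(act, file.path(outdir, "activity_by_sample.tsv"))
    readr::write_tsv(act_tp, file.path(outdir, "activity_by_timepoint.tsv"))
    list(activity = act, activity_tp = act_tp)
  })

  model <- stage("fit-background", {
    neg_ids <- lib$lib$elements$element_id[
      lib$lib$elements$control_class == "negative"]
    negs <- quant$activity$activity[quant$activity$element_id %in% neg_ids]
    m <- fit_mixture(negs, n_bins = n_bins)
    if (gof_B > 0) m <- goodness_of_fit(m, negs, B = gof_B,
                                        seed = config$seed)
    write_model_json(m, file.path(outdir, "background_model.json"))
    m
  })

  calls <- stage("call", {
    cand_tp <- quant$activity_tp |>
      filter(.data$element_id %in% lib$lib$elements$element_id[
        lib$lib$elements$control_class == "candidate"])
    cl <- call_active(cand_tp, model, alpha = alpha, n_tests = n_tests)
    readr::write_tsv(cl, file.path(outdir, "calls.tsv"))
    cl
  })

  temporal <- stage("classify", {
    tc <- classify_temporal(calls, time_points = config$time_points)
    readr::write_tsv(tc, file.path(outdir, "temporal_classes.tsv"))
    readr::write_tsv(attr(tc, "partition"),
                     file.path(outdir, "temporal_partition.tsv"))
    tc
  })

  sens <- stage("sensitivity", {
    pos_ids <- lib$lib$elements$element_id[
      lib$lib$elements$control_class == "positive"]
    pos <- quant$activity$activity[quant$activity$element_id %in% pos_ids]
    cal <- attr(calls, "calling")
    s <- estimate_sensitivity(model, positives = pos, alpha = cal$alpha,
                              n_tests = cal$n_tests)
    jsonlite::write_json(as.list(s), file.path(outdir, "sensitivity.json"),
                         auto_unbox = TRUE, digits = NA)
    s
  })

  clust <- NULL
  if (do_cluster) {
    clust <- stage("cluster", {
      cc <- cluster_activity(quant$activity, calls = calls)
      merge_tab <- cbind(cc$hclust$merge, height = cc$hclust$height)
      readr::write_tsv(as_tibble(as.data.frame(merge_tab)),
                       file.path(outdir, "cluster_merges.tsv"))
      readr::write_tsv(cc$clusters, file.path(outdir, "clusters.tsv"))
      cc
    })
  }

  link <- stage("linkage", {
    tp_pair <- tp_pair %||% config$time_points[1:2]
    grp <- expression_by_group(lib$expr$links, lib$expr$expression, calls,
                               background_genes = lib$expr$background_genes)
    pd <- pair_deltas(quant$activity_tp, lib$expr$links,
                      lib$expr$expression, lib$counts$samples,
                      tp_a = tp_pair[1], tp_b = tp_pair[2])
    curve <- concordance_curve(pd, calls = calls, cutoffs = cutoffs)
    readr::write_tsv(pd, file.path(outdir, "pair_deltas.tsv"))
    readr::write_tsv(curve, file.path(outdir, "concordance_curve.tsv"))
    readr::write_tsv(grp$groups, file.path(outdir, "expression_groups.tsv"))
    list(groups = grp, deltas = pd, curve = curve)
  })

  enr <- stage("overlap", {
    cand <- lib$lib$elements |>
      filter(.data$control_class == "candidate")
    ov <- intersect_peaks(cand, lib$peaks)
    act_el <- calls |>
      group_by(.data$element_id) |>
      summarise(active = any(.data$active), .groups = "drop")
    ov <- ov |> left_join(act_el, by = "element_id") |>
      mutate(active = dplyr::coalesce(.data$active, FALSE))
    fe <- fisher_enrichment(ov$overlaps, ov$active, dataset_id = "peaks")
    readr::write_tsv(fe, file.path(outdir, "enrichment.tsv"))
    up <- upset_counts(ov |> select("element_id", peaks = "overlaps"),
                       active = ov$active)
    readr::write_tsv(up, file.path(outdir, "upset_counts.tsv"))
    list(enrichment = fe, upset = up)
  })

  manifest <- list(
    package = "lentimpra",
    version = as.character(utils::packageVersion("lentimpra")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    parameters = list(min_barcodes = min_barcodes, min_dna = min_dna,
                      pseudocount = pseudocount, n_bins = n_bins,
                      alpha = alpha, gof_B = gof_B),
    outputs = sort(list.files(outdir))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(library = lib$lib, counts = lib$counts,
                 expression = lib$expr, activity = quant$activity,
                 activity_tp = quant$activity_tp, model = model,
                 calls = calls, temporal = temporal, sensitivity = sens,
                 clustering = clust, linkage = link, overlap = enr,
                 manifest = manifest))
}
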
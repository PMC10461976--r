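#' Simulation configuration for a synthetic lentiMPRA experiment
#'
#' Builds the parameter set for the synthetic-data generator. Defaults mirror
#' the design of a lentiMPRA screen of forebrain-organoid enhancers: 6,989
#' candidate elements plus 150 shuffled negative controls and 122 positive
#' controls (7,261 designed sequences), ~40 barcodes per element, and 9
#' samples (3 iPSC lines at each of the iPSC, TD0 and TD30 stages). True
#' activity on the linear RNA/DNA scale is drawn from a background Gaussian
#' N(mu0, sigma0) for inactive elements and a signal Gaussian N(mu1, sigma1)
#' for active ones, with the signal mean 55% above background.
#'
#' @param n_elements Number of candidate enhancer elements.
#' @param n_negative Number of shuffled-sequence negative controls.
#' @param n_positive Number of positive-control elements.
#' @param barcodes_per_element Mean number of barcodes per element (Poisson).
#' @param n_lines Number of cell lines (replicates per time point).
#' @param time_points Ordered character vector of time-point labels.
#' @param mu0,sigma0 Background Gaussian mean and sd (activity units).
#' @param mu1,sigma1 Signal Gaussian mean and sd.
#' @param pi_active Fraction of candidate elements truly active per time point.
#' @param pi_negative Probability a shuffled negative control is genuinely
#'   active (shuffling can create functional motifs by chance).
#' @param p_positive_active Probability a positive control is active; below 1
#'   because not all externally validated enhancers replicate in the assay.
#' @param depth_dna,depth_rna Mean reads per barcode for DNA and RNA counts.
#' @param dispersion Negative-binomial overdispersion alpha with variance
#'   `mean + alpha * mean^2`; 0 degenerates to Poisson.
#' @param coupling Signed activity-to-expression effect size (log2 units per
#'   standardised activity unit).
#' @param expr_baseline_mean,expr_baseline_sd Per-gene baseline log2 RPKM.
#' @param expr_noise_sd Gaussian noise sd on log2 RPKM.
#' @param p_positive_link Probability an enhancer-gene link couples with
#'   positive sign (enhancers predominantly activate; the remainder couple
#'   negatively).
#' @param pi_background_pool Active fraction among the unselected background
#'   pool of gene-linked enhancers (lower than `pi_active` because tested
#'   elements are selected for high chromatin activity).
#' @param n_background_genes Number of background-pool genes to simulate.
#' @param seed Master RNG seed; each generator stage derives its own stream.
#' @return A list of validated parameters with class `"sim_config"`.
#' @export
sim_config <- function(n_elements = 6989, n_negative = 150, n_positive = 122,
                       barcodes_per_element = 40, n_lines = 3,
                       time_points = c("iPSC", "TD0", "TD30"),
                       mu0 = 1, sigma0 = 0.2, mu1 = 1.55, sigma1 = 0.3,
                       pi_active = 0.35, pi_negative = 0.3,
                       p_positive_active = 0.6,
                       depth_dna = 50, depth_rna = 50, dispersion = 0.1,
                       coupling = 1,
                       expr_baseline_mean = 5, expr_baseline_sd = 1,
                       expr_noise_sd = 0.5, p_positive_link = 0.75,
                       pi_background_pool = 0.1, n_background_genes = 500,
                       seed = 1L) {
  .check_count(n_elements, "n_elements")
  .check_count(n_negative, "n_negative")
  .check_count(n_positive, "n_positive")
  .check_positive(barcodes_per_element, "barcodes_per_element")
  .check_count(n_lines, "n_lines")
  if (length(time_points) == 0 || anyDuplicated(time_points) ||
      any(is.na(time_points))) {
    abort("configuration error: `time_points` must be non-empty and unique")
  }
  .check_positive(sigma0, "sigma0")
  .check_positive(sigma1, "sigma1")
  .check_fraction(pi_active, "pi_active")
  .check_fraction(pi_negative, "pi_negative")
  .check_fraction(p_positive_active, "p_positive_active")
  .check_positive(depth_dna, "depth_dna")
  .check_positive(depth_rna, "depth_rna")
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort("configuration error: `dispersion` must be >= 0")
  }
  .check_fraction(pi_background_pool, "pi_background_pool")
  .check_fraction(p_positive_link, "p_positive_link")
  cfg <- list(
    n_elements = as.integer(n_elements), n_negative = as.integer(n_negative),
    n_positive = as.integer(n_positive),
    barcodes_per_element = barcodes_per_element,
    n_lines = as.integer(n_lines), time_points = as.character(time_points),
    mu0 = mu0, sigma0 = sigma0, mu1 = mu1, sigma1 = sigma1,
    pi_active = pi_active, pi_negative = pi_negative,
    p_positive_active = p_positive_active,
    depth_dna = depth_dna, depth_rna = depth_rna, dispersion = dispersion,
    coupling = coupling,
    expr_baseline_mean = expr_baseline_mean,
    expr_baseline_sd = expr_baseline_sd, expr_noise_sd = expr_noise_sd,
    p_positive_link = p_positive_link,
    pi_background_pool = pi_background_pool,
    n_background_genes = as.integer(n_background_genes),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Sample sheet for a simulated experiment
#'
#' One row per sample: each of `n_lines` cell lines measured at each time
#' point.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `sample_id`, `line_id`, `time_point`.
#' @export
sim_sample_sheet <- function(config) {
  grid <- tidyr::expand_grid(
    line_id = paste0("L", seq_len(config$n_lines)),
    time_point = config$time_points
  )
  grid |>
    mutate(sample_id = paste(.data$line_id, .data$time_point, sep = "_")) |>
    select("sample_id", "line_id", "time_point")
}

#' Simulate a designed MPRA element library with ground truth
#'
#' Generates candidate enhancers, shuffled negative controls and positive
#' controls, each with a 270-bp sequence, genomic coordinates, and (for
#' candidates) at least one linked gene. True per-time-point activity is
#' drawn from the background Gaussian for inactive elements and the signal
#' Gaussian for active ones, truncated at zero (activity lives on the linear
#' RNA/DNA scale).
#'
#' Optionally plants exact matches of a motif consensus into sequences so
#' that motif-density comparisons have a known signal: positives receive
#' `positive_boost` times the candidate planting rate.
#'
#' @param config A [sim_config()].
#' @param element_length Designed element length in bp (synthesis constraint).
#' @param plant_pwm Optional PWM (see [read_jaspar()]) whose consensus is
#'   planted into sequences.
#' @param plant_rate Mean planted copies per candidate element (Poisson).
#' @param positive_boost Multiplier on `plant_rate` for positive controls.
#' @return List with `elements` (tibble: element_id, chrom, start, end,
#'   strand, control_class, sequence, linked_genes list-column), `truth`
#'   (tibble: element_id, time_point, true_activity, true_active), and
#'   `links` (tibble: element_id, gene_id, link_source).
#' @export
simulate_library <- function(config, element_length = 270L,
                             plant_pwm = NULL, plant_rate = 1,
                             positive_boost = 3) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream_seed(config$seed, "library")
  n_c <- config$n_elements; n_n <- config$n_negative; n_p <- config$n_positive
  ids <- c(
    sprintf("E%05d", seq_len(n_c)),
    sprintf("NEG%04d", seq_len(n_n)),
    sprintf("POS%04d", seq_len(n_p))
  )
  cls <- rep(c("candidate", "negative", "positive"), c(n_c, n_n, n_p))
  seqs <- .random_dna(n_c + n_p, element_length)
  cand_seq <- seqs[seq_len(n_c)]
  pos_seq <- seqs[n_c + seq_len(n_p)]
  # negatives: nucleotide-shuffled copies of randomly chosen candidates
  neg_seq <- .shuffle_dna(cand_seq[sample.int(n_c, n_n, replace = n_n > n_c)])
  sequence <- c(cand_seq, neg_seq, pos_seq)

  if (!is.null(plant_pwm)) {
    consensus <- pwm_consensus(plant_pwm)
    rate <- ifelse(cls == "positive", plant_rate * positive_boost, plant_rate)
    copies <- rpois(length(sequence), rate)
    sequence <- .plant_motif(sequence, consensus, copies)
  }

  n_all <- length(ids)
  start <- sample.int(1e8L, n_all) + 1e4L
  elements <- tibble(
    element_id = ids,
    chrom = sample(paste0("chr", 1:22), n_all, replace = TRUE),
    start = start,
    end = start + element_length,
    strand = "+",
    control_class = cls,
    sequence = sequence
  )

  # candidate elements carry 1-2 dedicated linked genes
  n_genes_per <- 1L + stats::rbinom(n_c, 1L, 0.3)
  gene_ids <- sprintf("G%05d", seq_len(sum(n_genes_per)))
  links <- tibble(
    element_id = rep(ids[seq_len(n_c)], n_genes_per),
    gene_id = gene_ids,
    link_source = sample(c("proximity", "conformation", "both"),
                         length(gene_ids), replace = TRUE,
                         prob = c(0.5, 0.3, 0.2))
  )
  linked <- split(links$gene_id, factor(links$element_id, levels = ids))
  elements$linked_genes <- unname(lapply(linked, function(x) x %||% character(0)))

  p_active <- c(rep(config$pi_active, n_c), rep(config$pi_negative, n_n),
                rep(config$p_positive_active, n_p))
  truth <- tidyr::expand_grid(element_id = ids,
                              time_point = config$time_points) |>
    mutate(
      true_active = runif(dplyr::n()) < rep(p_active, each = length(config$time_points)),
      true_activity = pmax(0, if_else(
        .data$true_active,
        rnorm(dplyr::n(), config$mu1, config$sigma1),
        rnorm(dplyr::n(), config$mu0, config$sigma0)
      ))
    ) |>
    select("element_id", "time_point", "true_activity", "true_active")

  list(elements = elements, truth = truth, links = links)
}

.plant_motif <- function(sequence, consensus, copies) {
  w <- nchar(consensus)
  for (i in which(copies > 0)) {
    s <- sequence[i]
    L <- nchar(s)
    if (L < w) next
    for (k in seq_len(copies[i])) {
      at <- sample.int(L - w + 1L, 1L)
      substr(s, at, at + w - 1L) <- consensus
    }
    sequence[i] <- s
  }
  sequence
}

#' Extract the enhancer-gene link table from a simulated library
#'
#' @param elements Element tibble with a `linked_genes` list-column.
#' @return Tibble with columns `element_id`, `gene_id`.
#' @export
element_links <- function(elements) {
  tibble(
    element_id = rep(elements$element_id, lengths(elements$linked_genes)),
    gene_id = unlist(elements$linked_genes, use.names = FALSE)
  )
}

#' Simulate barcode-level DNA and RNA counts
#'
#' Each element receives a Poisson number of barcodes (minimum 1). For each
#' (barcode, sample) pair the DNA count is negative-binomial with mean
#' `depth_dna`, and the RNA count is negative-binomial with mean
#' `depth_rna * true_activity` of the element at that sample's time point.
#' Variance is `mean + dispersion * mean^2`; `dispersion = 0` gives Poisson
#' counts.
#'
#' @param elements Element tibble from [simulate_library()].
#' @param truth Ground-truth tibble from [simulate_library()].
#' @param config The [sim_config()] used to generate the library.
#' @return List with `counts` (tibble: element_id, barcode, sample_id,
#'   dna_count, rna_count) and `samples` (the sample sheet).
#' @export
simulate_counts <- function(elements, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  key <- paste(truth$element_id, truth$time_point)
  need <- tidyr::expand_grid(element_id = elements$element_id,
                             time_point = config$time_points)
  miss <- setdiff(paste(need$element_id, need$time_point), key)
  if (length(miss) > 0) {
    abort(sprintf("consistency error: truth is missing %d (element, time point) entries, e.g. %s",
                  length(miss), miss[[1]]))
  }
  .set_stream_seed(config$seed, "counts")
  samples <- sim_sample_sheet(config)
  n_el <- nrow(elements)
  n_bc <- pmax(1L, rpois(n_el, config$barcodes_per_element))
  total_bc <- sum(n_bc)
  barcode <- .random_dna(total_bc, 15L)
  el_of_bc <- rep(elements$element_id, n_bc)

  n_s <- nrow(samples)
  counts <- tibble(
    element_id = rep(el_of_bc, each = n_s),
    barcode = rep(barcode, each = n_s),
    sample_id = rep(samples$sample_id, times = total_bc),
    time_point = rep(samples$time_point, times = total_bc)
  )
  act <- setNames(truth$true_activity, key)
  mu_rna <- config$depth_rna * unname(act[paste(counts$element_id, counts$time_point)])
  nr <- nrow(counts)
  counts$dna_count <- .rcounts(nr, config$depth_dna, config$dispersion)
  counts$rna_count <- .rcounts(nr, mu_rna, config$dispersion)
  counts$time_point <- NULL
  list(counts = counts, samples = samples)
}

.rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a linked-gene expression matrix
#'
#' Expression of a linked gene tracks its enhancer's standardised true
#' activity: `log2 RPKM = baseline + coupling * (activity - mu0)/sigma0 *
#' sign + noise`, with a random sign per link so both positive and negative
#' activity-expression coupling occur. A background pool of genes linked to
#' unselected enhancers (drawn with a lower active fraction,
#' `pi_background_pool`) emulates the genome-wide set from which tested
#' elements were chosen for high activity.
#'
#' @inheritParams simulate_counts
#' @return List with `expression` (wide tibble: gene_id plus one RPKM column
#'   per sample), `links` (element_id, gene_id, link_source, sign), and
#'   `background_genes` (character vector of background-pool gene ids).
#' @export
simulate_expression <- function(elements, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream_seed(config$seed, "expression")
  samples <- sim_sample_sheet(config)
  links <- element_links(elements)
  links$link_source <- "proximity"
  links$sign <- sample(c(-1, 1), nrow(links), replace = TRUE,
                       prob = c(1 - config$p_positive_link,
                                config$p_positive_link))

  # standardized true activity per (element, time point)
  z <- (truth$true_activity - config$mu0) / config$sigma0
  zkey <- setNames(z, paste(truth$element_id, truth$time_point))

  grid <- tidyr::expand_grid(li = seq_len(nrow(links)),
                             si = seq_len(nrow(samples)))
  g_base <- rnorm(nrow(links), config$expr_baseline_mean, config$expr_baseline_sd)
  zval <- unname(zkey[paste(links$element_id[grid$li],
                            samples$time_point[grid$si])])
  log2e <- g_base[grid$li] +
    config$coupling * zval * links$sign[grid$li] +
    rnorm(nrow(grid), 0, config$expr_noise_sd)
  tested <- tibble(
    gene_id = links$gene_id[grid$li],
    sample_id = samples$sample_id[grid$si],
    rpkm = 2^log2e
  )

  # background pool: genes linked to unselected enhancers with a lower
  # chance of activity
  nb <- config$n_background_genes
  bg <- NULL
  if (nb > 0) {
    bg_ids <- sprintf("BG%05d", seq_len(nb))
    bg_sign <- sample(c(-1, 1), nb, replace = TRUE,
                      prob = c(1 - config$p_positive_link,
                               config$p_positive_link))
    bg_base <- rnorm(nb, config$expr_baseline_mean, config$expr_baseline_sd)
    bgrid <- tidyr::expand_grid(gi = seq_len(nb), si = seq_len(nrow(samples)))
    bg_active <- matrix(runif(nb * length(config$time_points)) <
                          config$pi_background_pool,
                        nrow = nb)
    colnames(bg_active) <- config$time_points
    act <- ifelse(
      bg_active[cbind(bgrid$gi, match(samples$time_point[bgrid$si],
                                      config$time_points))],
      rnorm(nrow(bgrid), config$mu1, config$sigma1),
      rnorm(nrow(bgrid), config$mu0, config$sigma0)
    )
    zb <- (pmax(0, act) - config$mu0) / config$sigma0
    bg <- tibble(
      gene_id = bg_ids[bgrid$gi],
      sample_id = samples$sample_id[bgrid$si],
      rpkm = 2^(bg_base[bgrid$gi] + config$coupling * zb * bg_sign[bgrid$gi] +
                  rnorm(nrow(bgrid), 0, config$expr_noise_sd))
    )
  }

  expr <- bind_rows(tested, bg) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpkm")
  list(expression = expr, links = links,
       background_genes = if (is.null(bg)) character(0) else unique(bg$gene_id))
}

#' Simulate external peak sets overlapping the library
#'
#' Builds a BED-like peak set that covers a chosen fraction of truth-active
#' and truth-inactive elements, for testing overlap-enrichment calls with
#' known ground truth.
#'
#' @param elements Element tibble.
#' @param truth Ground-truth tibble; an element counts as active if active at
#'   any time point.
#' @param frac_active,frac_inactive Fractions of active / inactive elements
#'   the peak set should cover.
#' @param pad Bases of padding added on each side of a covered element.
#' @param seed RNG seed.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
simulate_peaks <- function(elements, truth, frac_active = 0.8,
                           frac_inactive = 0.4, pad = 50L, seed = 1L) {
  .set_stream_seed(seed, "peaks")
  any_active <- truth |>
    group_by(.data$element_id) |>
    summarise(active = any(.data$true_active), .groups = "drop")
  el <- left_join(elements, any_active, by = "element_id")
  keep_p <- runif(nrow(el)) < if_else(el$active, frac_active, frac_inactive)
  pk <- el[keep_p, c("chrom", "start", "end")]
  pk$start <- pmax(0L, pk$start - pad)
  pk$end <- pk$end + pad
  pk$name <- sprintf("peak%05d", seq_len(nrow(pk)))
  as_tibble(pk)
}
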
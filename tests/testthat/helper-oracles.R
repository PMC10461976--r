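# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive algorithms.

# quadratic all-pairs interval overlap
brute_force_overlap <- function(elements, peaks, min_overlap = 1) {
  vapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    any(peaks$chrom == e$chrom &
          pmin(peaks$end, e$end) - pmax(peaks$start, e$start) >= min_overlap)
  }, logical(1))
}

# two-sided Fisher p by enumeration of all tables with fixed margins
fisher_enum_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact PWM score tail by exhaustive enumeration of all 4^L sequences
enum_score_tail <- function(w, bg, scores) {
  L <- nrow(w)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  seq_scores <- numeric(nrow(grid))
  seq_probs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    idx <- grid[i, ]
    seq_scores[i] <- sum(w[cbind(seq_len(L), idx)])
    seq_probs[i] <- prod(bg[idx])
  }
  vapply(scores, function(s) sum(seq_probs[seq_scores >= s - 1e-9]), 0)
}

# Ward (ward.D2) agglomeration by direct Lance-Williams recursion on
# squared distances; returns sorted merge heights
ward_heights <- function(mat) {
  n <- nrow(mat)
  D2 <- as.matrix(dist(mat))^2
  diag(D2) <- Inf
  sizes <- rep(1, n)
  alive <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(alive)
    sub <- D2[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[best[1]]; j <- idx[best[2]]
    heights[step] <- sqrt(D2[i, j])
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(alive)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D2[i, k] <- D2[k, i] <-
        ((ni + nk) * D2[i, k] + (nj + nk) * D2[j, k] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    alive[j] <- FALSE
  }
  sort(heights)
}

# exhaustive search for the length-L window with the most fully contained
# hits; ties leftmost. region and hit spans are 0-based half-open.
exhaustive_core_window <- function(region, hit_starts, hit_ends, L) {
  wins <- region[1]:(region[2] - L)
  counts <- vapply(wins, function(w) {
    sum(hit_starts >= w & hit_ends <= w + L)
  }, 0L)
  w <- wins[which.max(counts)]
  c(w, w + L)
}

# small simulation config used across tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_elements = 120, n_negative = 30, n_positive = 15,
                   barcodes_per_element = 10, n_background_genes = 50)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# a fixed, non-degenerate mixture model for arithmetic tests
fixed_model <- function(mu0 = 1, sigma0 = 0.2, mu1 = 1.55, sigma1 = 0.3,
                        pi = 0.7) {
  structure(list(mu0 = mu0, sigma0 = sigma0, mu1 = mu1, sigma1 = sigma1,
                 pi = pi, degenerate = FALSE, mu_pooled = mu0,
                 sigma_pooled = sigma0, n_points = 0L, n_bins = 30,
                 log2 = FALSE, ks_pvalue = NA_real_, ad_pvalue = NA_real_),
            class = "mpra_mixture")
}

# run the quantification front half of the pipeline on a config
quantify_sim <- function(cfg, min_barcodes = 10, min_dna = 1) {
  lib <- simulate_library(cfg)
  cn <- simulate_counts(lib$elements, lib$truth, cfg)
  fl <- qc_filter(cn$counts, min_barcodes = min_barcodes, min_dna = min_dna)
  act <- compute_activity(fl, cn$samples)
  atp <- collapse_by_timepoint(act, cn$samples)
  list(lib = lib, counts = cn, activity = act, activity_tp = atp)
}

negative_activities <- function(q) {
  neg <- q$lib$elements$element_id[q$lib$elements$control_class == "negative"]
  q$activity$activity[q$activity$element_id %in% neg]
}
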
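#' Construct a position weight matrix object
#'
#' @param matrix Numeric matrix, positions x bases, with columns A, C, G, T
#'   of per-position probabilities (each row sums to 1 within 1e-6).
#' @param motif_id Motif identifier.
#' @param background Length-4 base frequencies of the 0-order background
#'   model (default uniform).
#' @param pseudocount Pseudocount mixed into probabilities before log-odds.
#' @return An object of class `pwm`.
#' @export
pwm <- function(matrix, motif_id = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  colnames(matrix) <- .dna_alphabet
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    abort(sprintf("PWM `%s`: position probabilities must sum to 1", motif_id))
  }
  if (abs(sum(background) - 1) > 1e-6 || any(background < 0)) {
    abort("PWM background frequencies must be a probability vector")
  }
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%d positions), consensus %s\n", x$motif_id,
              nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (per-position argmax base)
#' @param x A [pwm()] object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste0(.dna_alphabet[apply(x$matrix, 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param x A [pwm()] object.
#' @return A [pwm()] with positions reversed and bases complemented.
#' @export
revcomp_pwm <- function(x) {
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), c("T", "G", "C", "A"),
                drop = FALSE]
  colnames(m) <- .dna_alphabet
  pwm(m, motif_id = x$motif_id, background = x$background[c(4, 3, 2, 1)],
      pseudocount = x$pseudocount)
}

# log2-odds score matrix; pseudocount is mixed with the background before
# the ratio so zero-probability cells stay finite
.logodds <- function(p, background, pseudocount) {
  pp <- sweep(p, 2, background * pseudocount, `+`) / (1 + pseudocount)
  w <- log2(sweep(pp, 2, background, `/`))
  # zero-probability cells at pseudocount 0: clamp to a finite sentinel so
  # the score distribution stays well ordered
  pmax(w, -1e9)
}

# Exact distribution of the total log-odds score under the 0-order
# background, by dynamic-programming convolution of the per-position score
# distributions. Distinct score sums are merged at 1e-9 resolution; if the
# support exceeds `max_support` values it is re-binned at `granularity`.
.score_distribution <- function(w, background, max_support = 2e5,
                                granularity = 1e-4) {
  s <- 0; p <- 1
  for (j in seq_len(nrow(w))) {
    snew <- as.vector(outer(w[j, ], s, `+`))
    pnew <- as.vector(outer(background, p, `*`))
    o <- order(snew)
    snew <- snew[o]; pnew <- pnew[o]
    tol <- if (length(snew) > max_support) granularity else 1e-9
    grp <- cumsum(c(TRUE, diff(snew) > tol))
    p <- as.vector(rowsum(pnew, grp))
    s <- snew[!duplicated(grp)]
  }
  list(score = s, tail = rev(cumsum(rev(p))))
}

# p-value of observed score(s): P(S >= q) with a 1e-9 tolerance on equality
.score_pvalue <- function(dist, q) {
  i <- findInterval(q - 1e-9, dist$score, left.open = TRUE) + 1
  out <- numeric(length(q))
  ok <- i <= length(dist$score)
  out[ok] <- dist$tail[i[ok]]
  out
}

#' Scan a sequence with a PWM
#'
#' Computes the log2-odds score of the motif at every offset on both
#' strands, with an exact p-value per score obtained by dynamic-programming
#' convolution of the per-position score distribution under the 0-order
#' background model. Positions with base `N` contribute a score of 0
#' (background odds).
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pwm_obj A [pwm()] object.
#' @param background Base frequencies for scoring and the null distribution;
#'   defaults to the PWM's own background.
#' @param pseudocount Overrides the PWM's pseudocount.
#' @param both_strands Scan the minus strand too.
#' @return Tibble (motif_id, offset, strand, score, p_value); `offset` is
#'   0-based within the sequence. Empty if the sequence is shorter than the
#'   motif.
#' @export
scan_pwm <- function(sequence, pwm_obj, background = NULL,
                     pseudocount = NULL, both_strands = TRUE) {
  stopifnot(inherits(pwm_obj, "pwm"))
  background <- background %||% pwm_obj$background
  pseudocount <- pseudocount %||% pwm_obj$pseudocount
  Lm <- nrow(pwm_obj$matrix)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  empty <- tibble(motif_id = character(0), offset = integer(0),
                  strand = character(0), score = numeric(0),
                  p_value = numeric(0))
  if (n < Lm) return(empty)
  idx <- match(chars, .dna_alphabet)
  idx[is.na(idx)] <- 5L

  strands <- if (both_strands) c("+", "-") else "+"
  out <- lapply(strands, function(st) {
    pw <- if (st == "+") pwm_obj else revcomp_pwm(pwm_obj)
    bg <- if (st == "+") background else background[c(4, 3, 2, 1)]
    w <- .logodds(pw$matrix, bg, pseudocount)
    w5 <- cbind(w, 0)  # N column
    sc <- numeric(n - Lm + 1)
    for (j in seq_len(Lm)) sc <- sc + unname(w5[j, idx[j:(j + n - Lm)]])
    dist <- .score_distribution(w, bg)
    tibble(motif_id = pwm_obj$motif_id, offset = 0:(n - Lm), strand = st,
           score = sc, p_value = .score_pvalue(dist, sc))
  })
  bind_rows(out)
}

#' Scan a set of elements with a set of PWMs
#'
#' @param elements Element tibble with `element_id` and `sequence` columns.
#' @param pwms A single [pwm()] or a list of them.
#' @param ... Passed to [scan_pwm()].
#' @return Tibble of hits with an `element_id` column.
#' @export
scan_elements <- function(elements, pwms, ...) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    purrr::map_dfr(pwms, function(pw) {
      h <- scan_pwm(elements$sequence[i], pw, ...)
      if (nrow(h) > 0) h$element_id <- elements$element_id[i]
      h
    })
  })
}

#' Count TFBSs per element at an FDR threshold
#'
#' Benjamini-Hochberg correction is applied over all hits of the scan batch
#' (every scored offset on both strands across all elements and motifs);
#' hits with `q <= q_threshold` are counted per element.
#'
#' @param hits Hit tibble from [scan_elements()].
#' @param elements Element tibble (elements with no hit get a count of 0).
#' @param q_threshold FDR threshold.
#' @return Tibble (element_id, n_tfbs).
#' @export
count_tfbs <- function(hits, elements, q_threshold = 0.05) {
  if (nrow(hits) > 0) {
    hits$q_value <- p.adjust(hits$p_value, method = "BH")
    cnt <- hits |>
      filter(.data$q_value <= q_threshold) |>
      count(.data$element_id, name = "n_tfbs")
  } else {
    cnt <- tibble(element_id = character(0), n_tfbs = integer(0))
  }
  tibble(element_id = elements$element_id) |>
    left_join(cnt, by = "element_id") |>
    mutate(n_tfbs = dplyr::coalesce(.data$n_tfbs, 0L))
}

#' Two-sample Kolmogorov-Smirnov comparison of count distributions
#'
#' @param group_a,group_b Numeric vectors (e.g. per-element TFBS counts in
#'   two element classes).
#' @param alternative Passed to [stats::ks.test()].
#' @return One-row tibble (statistic, p_value, n_a, n_b, small_sample flag
#'   set when either group has fewer than 5 values).
#' @export
compare_counts <- function(group_a, group_b, alternative = "two.sided") {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("input error: both groups must be non-empty")
  }
  small <- length(group_a) < 5 || length(group_b) < 5
  if (small) warn("group size < 5; KS p-value unreliable")
  kt <- suppressWarnings(ks.test(group_a, group_b, alternative = alternative))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(group_a), n_b = length(group_b),
         small_sample = small)
}

#' Select the core region of an enhancer
#'
#' Reduces an element to a core of at most `L` bases in two stages, the way
#' synthesis-length cores are chosen for MPRA libraries. Stage 1: per-base
#' evidence depth is the number of evidence tracks (p300 ChIP, DNase, CAGE,
#' ...) covering each base; the candidate region is the longest maximal run
#' of bases at maximal depth, extended symmetrically to `L` when shorter
#' (the odd extra base goes to the 5' side). Stage 2: if the stage-1 region
#' still exceeds `L`, or no track overlaps the element, a window of length
#' `L` is slid base by base (over the stage-1 region, or the whole element
#' when there was no overlap) and the window containing the most TFBS hits
#' at `q <= q_threshold`, fully contained, wins; ties go to the leftmost
#' window.
#'
#' @param element One-row tibble with `element_id`, `chrom`, `start`, `end`,
#'   `sequence` (0-based half-open coordinates; `end - start` must equal the
#'   sequence length).
#' @param tracks List of evidence-track tibbles (`chrom`, `start`, `end`).
#' @param pwms PWM list for the stage-2 motif count (may be `NULL`).
#' @param L Core length in bp.
#' @param q_threshold FDR threshold for counted hits.
#' @return One-row tibble (element_id, chrom, core_start, core_end,
#'   rel_start, rel_end, stage).
#' @export
select_core <- function(element, tracks = list(), pwms = NULL, L = 270,
                        q_threshold = 0.05) {
  stopifnot(nrow(element) == 1, L >= 1)
  len <- element$end - element$start
  if (nchar(element$sequence) != len) {
    abort("element sequence length must equal end - start")
  }
  if (len <= L) {
    return(tibble(element_id = element$element_id, chrom = element$chrom,
                  core_start = element$start, core_end = element$end,
                  rel_start = 0L, rel_end = as.integer(len),
                  stage = "unchanged"))
  }
  depth <- .track_depth(element, tracks)
  region <- c(0L, len)  # element-relative half-open
  stage <- "tracks"
  if (max(depth) > 0) {
    run <- .longest_max_run(depth)
    if (run[2] - run[1] <= L) {
      core <- .extend_to(run, L, len)
      return(tibble(element_id = element$element_id, chrom = element$chrom,
                    core_start = element$start + core[1],
                    core_end = element$start + core[2],
                    rel_start = core[1], rel_end = core[2], stage = "tracks"))
    }
    region <- run
    stage <- "tracks+motifs"
  } else {
    stage <- "motifs"
  }
  core <- .best_motif_window(element, region, pwms, L, q_threshold)
  tibble(element_id = element$element_id, chrom = element$chrom,
         core_start = element$start + core[1],
         core_end = element$start + core[2],
         rel_start = core[1], rel_end = core[2], stage = stage)
}

.track_depth <- function(element, tracks) {
  len <- element$end - element$start
  depth <- integer(len)
  for (tr in tracks) {
    tr <- tr[.norm_chrom(tr$chrom) == .norm_chrom(element$chrom) &
               tr$end > element$start & tr$start < element$end, , drop = FALSE]
    if (nrow(tr) == 0) next
    # collapse the track to per-base coverage (a track covers a base once)
    cov <- logical(len)
    for (i in seq_len(nrow(tr))) {
      a <- max(0L, tr$start[i] - element$start)
      b <- min(len, tr$end[i] - element$start)
      if (b > a) cov[(a + 1):b] <- TRUE
    }
    depth <- depth + cov
  }
  depth
}

# longest maximal-depth run, ties leftmost; returns 0-based half-open c(a, b)
.longest_max_run <- function(depth) {
  is_max <- depth == max(depth)
  r <- rle(is_max)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  c(starts[best], ends[best])
}

# extend half-open run to length L inside [0, len); extra base goes 5'
.extend_to <- function(run, L, len) {
  extra <- L - (run[2] - run[1])
  if (extra <= 0) return(as.integer(run))
  a <- run[1] - ceiling(extra / 2)
  b <- run[2] + floor(extra / 2)
  if (a < 0) { b <- b - a; a <- 0 }
  if (b > len) { a <- a - (b - len); b <- len }
  as.integer(c(max(0, a), b))
}

.best_motif_window <- function(element, region, pwms, L, q_threshold) {
  a <- region[1]; b <- region[2]
  wins <- a:(b - L)  # candidate window starts
  counts <- integer(length(wins))
  if (!is.null(pwms)) {
    hits <- scan_elements(element, pwms)
    if (nrow(hits) > 0) {
      hits$q_value <- p.adjust(hits$p_value, method = "BH")
      hits <- hits[hits$q_value <= q_threshold, , drop = FALSE]
      if (nrow(hits) > 0) {
        Lm <- hits$offset + vapply(
          hits$motif_id, function(id) {
            if (inherits(pwms, "pwm")) nrow(pwms$matrix)
            else nrow(pwms[[which(vapply(pwms, function(p) p$motif_id, "") == id)[1]]]$matrix)
          }, 0L)
        h0 <- hits$offset; h1 <- Lm  # hit span [h0, h1)
        for (i in seq_along(h0)) {
          lo <- max(a, h1[i] - L); hi <- min(b - L, h0[i])
          if (hi >= lo) {
            sel <- which(wins >= lo & wins <= hi)
            counts[sel] <- counts[sel] + 1L
          }
        }
      }
    }
  }
  w <- wins[which.max(counts)]  # ties: leftmost (which.max takes first)
  as.integer(c(w, w + L))
}
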
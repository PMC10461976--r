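det_pwm <- function(bases, id = "det") {
  m <- matrix(0, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- 1
  pwm(m, motif_id = id)
}

random_pwm <- function(L, id = "rnd", concentration = 0.5) {
  m <- matrix(rgamma(L * 4, concentration), nrow = L)
  pwm(m / rowSums(m), motif_id = id)
}

test_that("sequences shorter than the motif give no hits", {
  pw <- det_pwm(c("A", "C", "G", "T"))
  expect_equal(nrow(scan_pwm("ACG", pw)), 0)
})

test_that("a deterministic 2-mer scores 4 bits with exact p = 1/16", {
  pw <- det_pwm(c("A", "C"))
  hits <- scan_pwm("AC", pw, pseudocount = 0)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$score, 2 * log2(1 / 0.25), tolerance = 1e-12)
  expect_equal(plus$p_value, 1 / 16, tolerance = 1e-12)
  # oracle: enumerate all 16 dinucleotides
  dinucs <- as.matrix(expand.grid(1:4, 1:4))
  w <- log2((pw$matrix) / 0.25)  # no pseudocount
  w[!is.finite(w)] <- -Inf
  scores <- w[1, dinucs[, 1]] + w[2, dinucs[, 2]]
  expect_equal(mean(scores >= plus$score - 1e-9), 1 / 16)
})

test_that("N bases score as background", {
  pw <- det_pwm(c("A", "C"))
  hits <- scan_pwm("NC", pw, pseudocount = 0, both_strands = FALSE)
  expect_equal(hits$score, log2(1 / 0.25), tolerance = 1e-12)
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(3)
  pw <- random_pwm(5)
  seq <- paste0(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  h1 <- scan_pwm(seq, pw)
  h2 <- scan_pwm(revcomp(seq), pw)
  # a + hit at offset o corresponds to a - hit at offset n - L - o
  n <- nchar(seq); L <- 5
  h1p <- h1[h1$strand == "+", ]
  h2m <- h2[h2$strand == "-", ]
  mirror <- match(n - L - h1p$offset, h2m$offset)
  expect_false(anyNA(mirror))
  expect_equal(h1p$score, h2m$score[mirror], tolerance = 1e-9)
  expect_equal(h1p$p_value, h2m$p_value[mirror], tolerance = 1e-9)
})

test_that("DP p-values equal exhaustive enumeration for lengths 4-8", {
  set.seed(4)
  for (L in 4:8) {
    pw <- random_pwm(L)
    w <- lentimpra:::.logodds(pw$matrix, rep(0.25, 4), 0.01)
    seq <- paste0(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    hits <- scan_pwm(seq, pw, both_strands = FALSE)
    oracle <- enum_score_tail(w, rep(0.25, 4), hits$score)
    expect_equal(hits$p_value, unname(oracle), tolerance = 1e-12)
  }
})

test_that("TFBS counting applies BH over the whole batch", {
  set.seed(5)
  # non-palindromic motif so only one strand can match
  pw <- det_pwm(strsplit("AACCGGTA", "")[[1]])
  bgseq <- function() paste0(sample(c("A", "G"), 40, TRUE), collapse = "")
  elements <- tibble::tibble(
    element_id = c("with_hit", "without"),
    sequence = c(paste0(substr(bgseq(), 1, 16), "AACCGGTA",
                        substr(bgseq(), 25, 40)),
                 gsub("C", "G", bgseq()))
  )
  hits <- scan_elements(elements, pw)
  counts <- count_tfbs(hits, elements, q_threshold = 0.05)
  expect_equal(counts$n_tfbs[counts$element_id == "with_hit"], 1L)
  expect_equal(counts$n_tfbs[counts$element_id == "without"], 0L)
})

test_that("elements with planted motifs show a count-distribution shift", {
  pw <- det_pwm(strsplit("ACGTACGTAC", "")[[1]])
  cfg <- sim_config(n_elements = 60, n_negative = 5, n_positive = 60,
                    seed = 19)
  lib <- simulate_library(cfg, plant_pwm = pw, plant_rate = 1,
                          positive_boost = 3)
  counts <- count_tfbs(scan_elements(lib$elements, pw), lib$elements)
  joined <- dplyr::inner_join(counts,
                              lib$elements[c("element_id", "control_class")],
                              by = "element_id")
  ks <- compare_counts(joined$n_tfbs[joined$control_class == "positive"],
                       joined$n_tfbs[joined$control_class == "candidate"])
  expect_lt(ks$p_value, 0.01)
  expect_gt(mean(joined$n_tfbs[joined$control_class == "positive"]),
            mean(joined$n_tfbs[joined$control_class == "candidate"]))
})

test_that("two-sample KS edge cases and brute-force equivalence", {
  x <- c(1, 2, 3, 4, 5)
  id <- compare_counts(x, x)
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  expect_warning(dj <- compare_counts(c(1, 2, 3), c(4, 5, 6)), "group size")
  expect_equal(dj$statistic, 1)
  expect_true(dj$small_sample)

  set.seed(6)
  a <- rpois(50, 4); b <- rpois(50, 6)
  ks <- compare_counts(a, b)
  grid <- sort(unique(c(a, b)))
  d_oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(ks$statistic, d_oracle, tolerance = 1e-12)
})

test_that("short elements pass through core selection unchanged", {
  el <- tibble::tibble(element_id = "e1", chrom = "chr1", start = 1000,
                       end = 1200,
                       sequence = paste0(rep("A", 200), collapse = ""))
  core <- select_core(el, tracks = list(), pwms = NULL, L = 270)
  expect_equal(core$core_start, 1000)
  expect_equal(core$core_end, 1200)
  expect_equal(core$stage, "unchanged")
})

test_that("track depth then motif density select the core window", {
  set.seed(8)
  seq600 <- paste0(sample(c("A", "G"), 600, TRUE), collapse = "")
  # plant one exact motif at relative position 150
  pw <- det_pwm(strsplit("ACGTACGTAC", "")[[1]])
  substr(seq600, 151, 160) <- "ACGTACGTAC"
  el <- tibble::tibble(element_id = "e1", chrom = "chr1", start = 10000,
                       end = 10600, sequence = seq600)
  tracks <- lapply(1:3, function(i) {
    tibble::tibble(chrom = "chr1", start = 10100, end = 10400)
  })
  core <- select_core(el, tracks, pwms = list(pw), L = 270)
  # stage 1 restricts to [100, 400) (depth 3), stage 2 slides inside it
  expect_gte(core$rel_start, 100)
  expect_lte(core$rel_end, 400)
  expect_equal(core$rel_end - core$rel_start, 270)
  # oracle: exhaustive window search over all 31 candidate starts
  hits <- scan_elements(el, list(pw))
  hits$q_value <- p.adjust(hits$p_value, "BH")
  hits <- hits[hits$q_value <= 0.05, ]
  oracle <- exhaustive_core_window(c(100, 400), hits$offset,
                                   hits$offset + 10, 270)
  expect_equal(c(core$rel_start, core$rel_end), oracle)
  expect_equal(core$stage, "tracks+motifs")
})

test_that("without tracks the densest motif window wins (3' planted)", {
  set.seed(9)
  seqv <- sample(c("A", "G"), 500, TRUE)
  seq500 <- paste0(seqv, collapse = "")
  pw <- det_pwm(strsplit("ACGTACGTAC", "")[[1]])
  for (at in c(401, 431, 461)) substr(seq500, at, at + 9) <- "ACGTACGTAC"
  el <- tibble::tibble(element_id = "e1", chrom = "chr1", start = 0,
                       end = 500, sequence = seq500)
  core <- select_core(el, tracks = list(), pwms = list(pw), L = 270)
  hits <- scan_elements(el, list(pw))
  hits$q_value <- p.adjust(hits$p_value, "BH")
  hits <- hits[hits$q_value <= 0.05, ]
  oracle <- exhaustive_core_window(c(0, 500), hits$offset,
                                   hits$offset + 10, 270)
  expect_equal(c(core$rel_start, core$rel_end), oracle)
  expect_equal(core$stage, "motifs")
})

test_that("core selection always returns a contained, deterministic window", {
  set.seed(10)
  pw <- det_pwm(strsplit("ACGTAC", "")[[1]])
  for (r in 1:10) {
    len <- sample(300:800, 1)
    seqr <- paste0(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    el <- tibble::tibble(element_id = "e", chrom = "chr1", start = 0,
                         end = len, sequence = seqr)
    n_tr <- sample(0:3, 1)
    tracks <- lapply(seq_len(n_tr), function(i) {
      a <- sample(0:(len - 50), 1)
      tibble::tibble(chrom = "chr1", start = a, end = a + sample(50:300, 1))
    })
    c1 <- select_core(el, tracks, list(pw), L = 270)
    c2 <- select_core(el, tracks, list(pw), L = 270)
    expect_identical(c1, c2)
    expect_gte(c1$rel_start, 0)
    expect_lte(c1$rel_end, len)
    expect_equal(c1$rel_end - c1$rel_start, min(270, len))
  }
})

test_that("BH q-values are monotone in p-values within a batch", {
  set.seed(11)
  pw <- random_pwm(6)
  elements <- tibble::tibble(
    element_id = c("a", "b"),
    sequence = replicate(2, paste0(sample(c("A", "C", "G", "T"), 50, TRUE),
                                   collapse = ""))
  )
  hits <- scan_elements(elements, pw)
  hits$q_value <- p.adjust(hits$p_value, "BH")
  o <- order(hits$p_value)
  expect_true(all(diff(hits$q_value[o]) >= -1e-12))
  expect_true(all(hits$q_value >= hits$p_value - 1e-12))
})
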
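test_that("activity at the background mean is never called active", {
  m <- fixed_model()
  act <- tibble::tibble(element_id = "e1", time_point = "iPSC", activity = 1)
  calls <- call_active(act, m, alpha = 0.05, n_tests = 7261)
  expect_equal(calls$p_value, 0.5)
  expect_false(calls$active)
})

test_that("the Bonferroni cutoff matches inverse-normal arithmetic", {
  m <- fixed_model()
  act <- tibble::tibble(element_id = c("hi", "lo"), time_point = "iPSC",
                        activity = c(1.9, 1.8))
  calls <- call_active(act, m, alpha = 0.05, n_tests = 7261)
  cal <- attr(calls, "calling")
  expect_equal(cal$threshold, 0.05 / 7261, tolerance = 1e-12)
  expect_equal(cal$threshold, 6.886e-6, tolerance = 1e-3)
  expect_equal(cal$cutoff, 1 + 0.2 * qnorm(1 - 0.05 / 7261),
               tolerance = 1e-12)
  expect_equal(cal$cutoff, 1.86949, tolerance = 1e-5)
  expect_true(calls$active[calls$element_id == "hi"])
  expect_false(calls$active[calls$element_id == "lo"])
})

test_that("missing activities yield flagged inactive calls", {
  m <- fixed_model()
  act <- tibble::tibble(element_id = c("e1", "e2"), time_point = "iPSC",
                        activity = c(2.5, NA))
  calls <- call_active(act, m, n_tests = 100)
  expect_true(calls$qc_missing[2])
  expect_false(calls$active[2])
  expect_true(is.na(calls$p_value[2]))
  expect_true(calls$active[1])
})

test_that("p-values and calls are monotone in activity", {
  m <- fixed_model()
  act <- tibble::tibble(element_id = sprintf("e%03d", 1:200),
                        time_point = "iPSC",
                        activity = seq(0.5, 3, length.out = 200))
  calls <- call_active(act, m, n_tests = 1000)
  expect_true(all(diff(calls$p_value) <= 0))
  expect_true(all(diff(as.integer(calls$active)) >= 0))
})

test_that("temporal classes follow the flag patterns exactly", {
  mk_calls <- function(flags) {
    tibble::tibble(
      element_id = rep(sprintf("e%d", seq_len(nrow(flags))), each = 3),
      time_point = rep(c("iPSC", "TD0", "TD30"), nrow(flags)),
      activity = 1, p_value = 0.5,
      active = as.vector(t(flags)), qc_missing = FALSE
    )
  }
  cls <- classify_temporal(mk_calls(matrix(c(TRUE, FALSE, FALSE), 1)))
  expect_equal(cls$temporal_class, "iPSC-only")
  cls <- classify_temporal(mk_calls(matrix(c(FALSE, TRUE, TRUE), 1)))
  expect_equal(cls$temporal_class, "TD0&TD30")

  # all 8 patterns at once: the enumerated partition
  flags <- as.matrix(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE),
                                 c(FALSE, TRUE)))
  cls <- classify_temporal(mk_calls(flags))
  part <- attr(cls, "partition")
  expect_equal(sum(part$n), 8)
  expect_true(all(part$n == 1))
  expect_setequal(part$temporal_class,
                  c("none", "iPSC-only", "TD0-only", "TD30-only",
                    "iPSC&TD0", "iPSC&TD30", "TD0&TD30", "all"))
})

test_that("random truth tables partition by brute-force enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    flags <- matrix(runif(15) < 0.5, ncol = 3)
    calls <- tibble::tibble(
      element_id = rep(sprintf("e%d", 1:5), each = 3),
      time_point = rep(c("iPSC", "TD0", "TD30"), 5),
      activity = 1, p_value = 0.5,
      active = as.vector(t(flags)), qc_missing = FALSE
    )
    cls <- classify_temporal(calls)
    # oracle: direct enumeration over the 2^3 patterns
    oracle <- apply(flags, 1, function(fl) {
      on <- c("iPSC", "TD0", "TD30")[fl]
      if (length(on) == 0) "none"
      else if (length(on) == 3) "all"
      else if (length(on) == 1) paste0(on, "-only")
      else paste(on, collapse = "&")
    })
    expect_equal(cls$temporal_class, oracle)
    part <- attr(cls, "partition")
    expect_equal(sum(part$n), 5)  # conservation
  }
})

test_that("partial elements classify from available flags and are flagged", {
  calls <- tibble::tibble(
    element_id = "e1", time_point = c("iPSC", "TD0", "TD30"),
    activity = c(2.5, NA, 1), p_value = c(1e-9, NA, 0.5),
    active = c(TRUE, FALSE, FALSE), qc_missing = c(FALSE, TRUE, FALSE)
  )
  cls <- classify_temporal(calls)
  expect_equal(cls$temporal_class, "iPSC-only")
  expect_true(cls$partial)
})

test_that("sensitivity equals alpha/N when positives match the background", {
  m <- fixed_model()
  s <- estimate_sensitivity(m, mu_pos = 1, sigma_pos = 0.2, alpha = 0.05,
                            n_tests = 7261)
  expect_equal(s$sensitivity, 0.05 / 7261, tolerance = 1e-9)
})

test_that("analytic sensitivity matches Monte-Carlo integration", {
  m <- fixed_model()
  s <- estimate_sensitivity(m, mu_pos = 1.55, sigma_pos = 0.3,
                            alpha = 0.05, n_tests = 7261)
  expect_equal(s$cutoff, 1.86949, tolerance = 1e-5)
  expect_equal(s$sensitivity, 1 - pnorm((s$cutoff - 1.55) / 0.3),
               tolerance = 1e-12)
  expect_equal(s$sensitivity, 0.1434, tolerance = 1e-3)
  set.seed(1)
  mc <- mean(rnorm(1e6, 1.55, 0.3) > s$cutoff)
  expect_lt(abs(s$sensitivity - mc), 0.005)
})

test_that("sensitivity is monotone in mu_pos, alpha and N", {
  m <- fixed_model()
  s_mu <- vapply(c(1.2, 1.5, 1.8), function(mu) {
    estimate_sensitivity(m, mu_pos = mu, sigma_pos = 0.3,
                         n_tests = 7261)$sensitivity
  }, 0)
  expect_true(all(diff(s_mu) > 0))
  s_alpha <- vapply(c(0.01, 0.05, 0.1), function(a) {
    estimate_sensitivity(m, mu_pos = 1.55, sigma_pos = 0.3, alpha = a,
                         n_tests = 7261)$sensitivity
  }, 0)
  expect_true(all(diff(s_alpha) > 0))
  s_n <- vapply(c(100, 7261, 1e5), function(n) {
    estimate_sensitivity(m, mu_pos = 1.55, sigma_pos = 0.3,
                         n_tests = n)$sensitivity
  }, 0)
  expect_true(all(diff(s_n) < 0))
})

test_that("degenerate positive sets are rejected with advice", {
  m <- fixed_model()
  expect_error(estimate_sensitivity(m, positives = rep(1.5, 10)),
               "positive")
  expect_error(estimate_sensitivity(m, positives = c(1.2, 1.4)), "positive")
})

test_that("the two-component positive fit uses the upper component", {
  set.seed(5)
  pos <- ifelse(runif(2000) < 0.4, rnorm(2000, 1, 0.2), rnorm(2000, 1.8, 0.25))
  fit <- fit_positive_gaussian(pos, two_component = TRUE)
  expect_equal(fit$method, "mixture_upper")
  expect_lt(abs(fit$mu_pos - 1.8), 0.1)
})

test_that("identical rows merge first at distance zero", {
  act <- tidyr::expand_grid(element_id = c("a", "b", "c"),
                            sample_id = c("s1", "s2")) |>
    dplyr::mutate(activity = c(1, 2, 1, 2, 4, 0))
  cl <- cluster_activity(act, k = 2)
  expect_equal(cl$hclust$height[1], 0)
  first <- sort(-cl$hclust$merge[1, ])
  expect_setequal(cl$hclust$labels[first], c("a", "b"))
})

test_that("Ward clustering recovers two well-separated blobs", {
  set.seed(7)
  mat <- rbind(matrix(rnorm(9, 0, 0.1), 3), matrix(rnorm(9, 5, 0.1), 3))
  act <- tibble::tibble(
    element_id = rep(sprintf("e%d", 1:6), each = 3),
    sample_id = rep(c("s1", "s2", "s3"), 6),
    activity = as.vector(t(mat))
  )
  cl <- cluster_activity(act, k = 2)
  grp <- cl$clusters$cluster[match(sprintf("e%d", 1:6), cl$clusters$element_id)]
  expect_equal(length(unique(grp[1:3])), 1)
  expect_equal(length(unique(grp[4:6])), 1)
  expect_true(grp[1] != grp[4])
  # merge heights match the Lance-Williams ward recursion oracle
  expect_equal(sort(cl$hclust$height), ward_heights(mat), tolerance = 1e-8)
})

test_that("active elements concentrate in one top-level cluster", {
  cfg <- sim_config(n_elements = 400, n_negative = 30, n_positive = 10,
                    pi_active = 0.3, seed = 17)
  q <- quantify_sim(cfg)
  m <- fit_mixture(negative_activities(q))
  calls <- call_active(q$activity_tp, m)
  cl <- cluster_activity(q$activity, calls = calls)
  s <- cl$summary
  truth_any <- q$lib$truth |>
    dplyr::group_by(.data$element_id) |>
    dplyr::summarise(active = any(.data$true_active))
  joined <- cl$clusters |> dplyr::inner_join(truth_any, by = "element_id")
  tab <- table(joined$cluster, joined$active)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_true(max(or, 1 / or) > 3)
})

test_that("clustering rejects degenerate inputs and imputes missing values", {
  act <- tibble::tibble(element_id = "only", sample_id = "s1", activity = 1)
  expect_error(cluster_activity(act), "input error")
  act2 <- tidyr::expand_grid(element_id = c("a", "b", "c"),
                             sample_id = c("s1", "s2")) |>
    dplyr::mutate(activity = c(1, NA, 2, 2, 3, 3))
  cl <- cluster_activity(act2)
  expect_equal(cl$imputed, "a")
})
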
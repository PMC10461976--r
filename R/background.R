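#' Fit a two-component Gaussian mixture to negative-control activities
#'
#' Shuffled negative controls show a bimodal activity distribution: a true
#' background component plus a component of sequences that gained activity
#' by chance. The density `pi * N(mu0, sigma0) + (1 - pi) * N(mu1, sigma1)`
#' is fitted by least squares to the density-normalised histogram of the
#' pooled values (the curve-fitting approach), with multi-start
#' initialisation. Components are relabelled so `mu0 <= mu1`; the lower
#' component is the calling null.
#'
#' The two-component model is accepted only when it is supported by the
#' data: if the component means nearly coincide, or a single Gaussian fits
#' the histogram as well by BIC, the model is flagged `degenerate` and
#' downstream calling falls back to the pooled single Gaussian. Without this
#' guard a spurious split of a unimodal null would underestimate `sigma0`
#' and break family-wise error control.
#'
#' @param x Numeric vector of pooled activity values (finite, >= 0, at least
#'   `min_points` of them).
#' @param n_bins Number of equal-width histogram bins.
#' @param log2 Fit on `log2(x + 0.01)` instead of the linear activity scale.
#' @param n_starts Number of jittered restarts beyond the quantile-based
#'   start.
#' @param min_points Minimum number of values required.
#' @return An object of class `mpra_mixture` with elements `mu0`, `sigma0`,
#'   `mu1`, `sigma1`, `pi` (background mixing weight), `degenerate`,
#'   `mu_pooled`, `sigma_pooled`, `ssr`, `n_points`, `n_bins`.
#' @export
fit_mixture <- function(x, n_bins = 30, log2 = FALSE, n_starts = 4,
                        min_points = 50) {
  x <- x[!is.na(x)]
  if (length(x) < min_points) {
    abort(sprintf("input error: need >= %d finite values, got %d",
                  min_points, length(x)))
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("input error: activities must be finite and >= 0")
  }
  if (log2) x <- base::log2(x + 0.01)
  h <- .density_histogram(x, n_bins)
  s_all <- sd(x)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)

  starts <- list(c(mu0 = q[1], s0 = s_all / 2, mu1 = q[2], s1 = s_all / 2,
                   pi = 0.5))
  for (j in seq_len(n_starts)) {
    jit <- starts[[1]] * exp(rnorm(5, 0, 0.15) * c(0.2, 1, 0.2, 1, 0)) +
      c(rnorm(1, 0, 0.3 * s_all), 0, rnorm(1, 0, 0.3 * s_all), 0,
        runif(1, -0.3, 0.3))
    jit["pi"] <- min(max(jit["pi"], 0.05), 0.95)
    jit["s0"] <- max(jit["s0"], s_all / 20)
    jit["s1"] <- max(jit["s1"], s_all / 20)
    starts[[j + 1]] <- jit
  }
  lower <- c(min(x) - s_all, s_all / 100, min(x) - s_all, s_all / 100, 0)
  upper <- c(max(x) + s_all, 4 * s_all, max(x) + s_all, 4 * s_all, 1)

  fits <- lapply(starts, function(st) .try_mix_fit(h, st, lower, upper))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    abort("fit error: mixture fit failed to converge from every start")
  }
  ssrs <- vapply(fits, function(f) f$ssr, 0)
  mu1s <- vapply(fits, function(f) max(f$par[c("mu0", "mu1")]), 0)
  best <- fits[[order(ssrs, mu1s)[1]]]
  p <- best$par
  # relabel so mu0 <= mu1 (pi stays the weight of the lower component)
  if (p[["mu0"]] > p[["mu1"]]) {
    p <- c(mu0 = p[["mu1"]], s0 = p[["s1"]], mu1 = p[["mu0"]],
           s1 = p[["s0"]], pi = 1 - p[["pi"]])
  }

  single <- .try_single_fit(h, mean(x), s_all)
  # identifiability guards: the two-component reading is kept only when
  # (i) the data prefer it over one Gaussian by BIC on the actual
  # log-likelihood, (ii) both components carry non-trivial weight, and
  # (iii) neither component is a sub-histogram-resolution spike
  n <- length(x)
  ll_mix <- sum(log(pmax(.mix_dens(x, p[["mu0"]], p[["s0"]], p[["mu1"]],
                                   p[["s1"]], p[["pi"]]), 1e-300)))
  ll_one <- sum(dnorm(x, mean(x), s_all, log = TRUE))
  bin_width <- diff(range(x)) / n_bins
  degenerate <- abs(p[["mu1"]] - p[["mu0"]]) < 1e-3 * s_all ||
    2 * (ll_mix - ll_one) <= 3 * log(n) ||
    p[["pi"]] < 0.1 || p[["pi"]] > 0.9 ||
    min(p[["s0"]], p[["s1"]]) < bin_width

  structure(list(
    mu0 = p[["mu0"]], sigma0 = p[["s0"]], mu1 = p[["mu1"]],
    sigma1 = p[["s1"]], pi = p[["pi"]],
    degenerate = degenerate,
    mu_pooled = mean(x), sigma_pooled = s_all,
    ssr = best$ssr, ssr_single = if (is.null(single)) NA_real_ else single$ssr,
    n_points = length(x), n_bins = n_bins, log2 = log2,
    ks_pvalue = NA_real_, ad_pvalue = NA_real_
  ), class = "mpra_mixture")
}

.density_histogram <- function(x, n_bins) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density)
}

.mix_dens <- function(xx, mu0, s0, mu1, s1, pi) {
  pi * dnorm(xx, mu0, s0) + (1 - pi) * dnorm(xx, mu1, s1)
}

.try_mix_fit <- function(h, start, lower, upper) {
  df <- data.frame(xx = h$mids, d = h$density)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ .mix_dens(xx, mu0, s0, mu1, s1, pi),
      data = df, start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(par = coef(fit), ssr = sum(resid(fit)^2))
}

.try_single_fit <- function(h, m, s) {
  df <- data.frame(xx = h$mids, d = h$density)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ dnorm(xx, mu, sg), data = df,
                      start = list(mu = m, sg = s),
                      lower = c(-Inf, s / 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(par = coef(fit), ssr = sum(resid(fit)^2))
}

#' @export
print.mpra_mixture <- function(x, ...) {
  cat("Two-component Gaussian background model\n")
  cat(sprintf("  background: N(%.4f, %.4f)  weight %.3f\n",
              x$mu0, x$sigma0, x$pi))
  cat(sprintf("  signal:     N(%.4f, %.4f)  weight %.3f\n",
              x$mu1, x$sigma1, 1 - x$pi))
  cat(sprintf("  n = %d, bins = %d, SSR = %.4g%s\n", x$n_points, x$n_bins,
              x$ssr, if (x$degenerate) "  [degenerate: pooled Gaussian used]" else ""))
  if (!is.na(x$ks_pvalue)) {
    cat(sprintf("  goodness of fit: KS p = %.3f, AD p = %.3f\n",
                x$ks_pvalue, x$ad_pvalue))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted background mixture
#' @param x An `mpra_mixture` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter.
#' @export
tidy.mpra_mixture <- function(x, ...) {
  tibble(
    term = c("mu0", "sigma0", "mu1", "sigma1", "pi"),
    estimate = c(x$mu0, x$sigma0, x$mu1, x$sigma1, x$pi)
  )
}

#' One-row fit summary of a background mixture
#' @param x An `mpra_mixture` object.
#' @param ... Unused.
#' @return One-row tibble of fit diagnostics.
#' @export
glance.mpra_mixture <- function(x, ...) {
  tibble(
    n_points = x$n_points, n_bins = x$n_bins, ssr = x$ssr,
    degenerate = x$degenerate,
    signal_to_background = x$mu1 / x$mu0,
    ks_pvalue = x$ks_pvalue, ad_pvalue = x$ad_pvalue
  )
}

#' Mixture density, CDF, and background tail probability
#'
#' `mixture_density()` and `mixture_cdf()` evaluate the full fitted
#' two-component model. `background_tail()` evaluates the upper tail of the
#' background component alone, `1 - Phi((x - mu0)/sigma0)` — the calling
#' null. For a degenerate fit all three fall back to the pooled single
#' Gaussian.
#'
#' @param model An `mpra_mixture` object.
#' @param x Numeric vector of activity values.
#' @return Numeric vector of densities / probabilities.
#' @export
mixture_density <- function(model, x) {
  if (model$degenerate) return(dnorm(x, model$mu_pooled, model$sigma_pooled))
  .mix_dens(x, model$mu0, model$sigma0, model$mu1, model$sigma1, model$pi)
}

#' @rdname mixture_density
#' @export
mixture_cdf <- function(model, x) {
  if (model$degenerate) return(pnorm(x, model$mu_pooled, model$sigma_pooled))
  model$pi * pnorm(x, model$mu0, model$sigma0) +
    (1 - model$pi) * pnorm(x, model$mu1, model$sigma1)
}

#' @rdname mixture_density
#' @export
background_tail <- function(model, x) {
  if (model$degenerate) {
    return(pnorm(x, model$mu_pooled, model$sigma_pooled, lower.tail = FALSE))
  }
  pnorm(x, model$mu0, model$sigma0, lower.tail = FALSE)
}

#' Draw random activities from a fitted mixture
#' @param model An `mpra_mixture` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
rmixture <- function(model, n) {
  if (model$degenerate) return(rnorm(n, model$mu_pooled, model$sigma_pooled))
  comp <- runif(n) < model$pi
  ifelse(comp, rnorm(n, model$mu0, model$sigma0),
         rnorm(n, model$mu1, model$sigma1))
}

#' Goodness of fit of the background mixture
#'
#' One-sample Kolmogorov-Smirnov and Anderson-Darling statistics of the data
#' against the fitted mixture CDF. Because the null is composite (parameters
#' were estimated from the same data), p-values come from a parametric
#' bootstrap that refits the model on each replicate drawn from the fitted
#' mixture.
#'
#' @param model A fitted `mpra_mixture`.
#' @param x The data the model was fitted to.
#' @param B Number of bootstrap replicates (a warning is issued below 100).
#' @param seed RNG seed for the bootstrap.
#' @return The model with `ks_statistic`, `ks_pvalue`, `ad_statistic`,
#'   `ad_pvalue` and `gof_B` filled in.
#' @export
goodness_of_fit <- function(model, x, B = 500, seed = 1L) {
  if (B < 100) warn("fewer than 100 bootstrap replicates; p-values are coarse")
  x <- sort(x[!is.na(x)])
  if (model$log2) x <- base::log2(x + 0.01)
  obs <- .gof_stats(model, x)
  .set_stream_seed(seed, "bootstrap")
  n <- length(x)
  ks_b <- ad_b <- numeric(B)
  for (b in seq_len(B)) {
    xb <- rmixture(model, n)
    mb <- tryCatch(
      suppressWarnings(fit_mixture(pmax(xb, 0), n_bins = model$n_bins,
                                   n_starts = 1, min_points = 10)),
      error = function(e) NULL
    )
    if (is.null(mb)) { ks_b[b] <- NA; ad_b[b] <- NA; next }
    st <- .gof_stats(mb, sort(xb))
    ks_b[b] <- st$ks; ad_b[b] <- st$ad
  }
  ks_b <- ks_b[!is.na(ks_b)]; ad_b <- ad_b[!is.na(ad_b)]
  model$ks_statistic <- obs$ks
  model$ad_statistic <- obs$ad
  model$ks_pvalue <- (1 + sum(ks_b >= obs$ks)) / (length(ks_b) + 1)
  model$ad_pvalue <- (1 + sum(ad_b >= obs$ad)) / (length(ad_b) + 1)
  model$gof_B <- B
  model
}

# KS and AD statistics of sorted data against the fitted mixture CDF
.gof_stats <- function(model, x_sorted) {
  n <- length(x_sorted)
  Fx <- mixture_cdf(model, x_sorted)
  i <- seq_len(n)
  ks <- max(i / n - Fx, Fx - (i - 1) / n)
  eps <- 1e-12
  Fc <- pmin(pmax(Fx, eps), 1 - eps)
  ad <- -n - mean((2 * i - 1) * (log(Fc) + log(1 - rev(Fc))))
  list(ks = ks, ad = ad)
}

#' Expectation-maximisation cross-check for the mixture fit
#'
#' Standard EM for a two-component univariate Gaussian mixture, provided as
#' an independent route to the histogram least-squares estimate of
#' [fit_mixture()].
#'
#' @param x Numeric data vector.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @return A list with `mu0`, `sigma0`, `mu1`, `sigma1`, `pi` (weight of the
#'   lower-mean component), `loglik`, `iterations`.
#' @export
em_mixture <- function(x, max_iter = 500, tol = 1e-8) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- q; sg <- rep(sd(x) / 2, 2); w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    w <- c(mean(g), 1 - mean(g))
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sg <- c(sqrt(sum(g * (x - mu[1])^2) / sum(g)),
            sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    sg <- pmax(sg, 1e-8)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mu0 = mu[ord[1]], sigma0 = sg[ord[1]], mu1 = mu[ord[2]],
       sigma1 = sg[ord[2]], pi = w[ord[1]], loglik = ll, iterations = it)
}
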
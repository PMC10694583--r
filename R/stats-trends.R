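#' Gaussian-mixture clustering of phasor data
#'
#' Phasor clouds carry an intrinsic normal component from photon noise,
#' which makes Gaussian mixtures the natural clustering model. The fit
#' uses EM with full covariances via mclust, whose model-based
#' agglomerative initialisation is deterministic for a given data set,
#' so repeated runs are bitwise reproducible. Degenerate inputs (e.g.
#' all points identical) fall back to a variance-floored model instead
#' of erroring.
#'
#' @param x An `n x d` matrix (`(g, s)` points) or a numeric vector
#'   (lifetimes).
#' @param k Number of clusters (>= 1). Default 2.
#' @param seed Integer seed, recorded in the result (initialisation is
#'   deterministic, the seed guards any stochastic mclust options).
#' @param var_floor Variance floor applied in the degenerate fallback.
#' @return An object of class `phasor_gmm`: `k`, `means` (`d x k`),
#'   `covariances` (`d x d x k`), `weights`, `labels`, `loglik`, `seed`.
#' @export
fit_gmm <- function(x, k = 2L, seed = 0L, var_floor = 1e-8) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  k <- as.integer(k)
  n <- nrow(x); d <- ncol(x)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (n < k) stop("need at least k points (n = ", n, ", k = ", k, ")",
                  call. = FALSE)
  set.seed(as.integer(seed))
  model_name <- if (d == 1L) "V" else "VVV"
  fit <- tryCatch(
    suppressWarnings(Mclust(x, G = k, modelNames = model_name,
                            verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # degenerate data (zero spread): one floored component at the mean
    mu <- matrix(colMeans(x), d, k)
    cv <- array(diag(var_floor, d), dim = c(d, d, k))
    return(structure(
      list(k = k, means = mu, covariances = cv,
           weights = rep(1 / k, k), labels = rep(1L, n),
           loglik = NA_real_, seed = as.integer(seed)),
      class = "phasor_gmm"
    ))
  }
  mu <- matrix(fit$parameters$mean, d, k)
  cv <- fit$parameters$variance$sigma
  if (is.null(cv)) {
    cv <- array(0, dim = c(d, d, k))
    sig2 <- fit$parameters$variance$sigmasq
    if (length(sig2) == 1L) sig2 <- rep(sig2, k)
    for (i in seq_len(k)) cv[, , i] <- diag(sig2[i], d)
  }
  cv <- array(cv, dim = c(d, d, k))
  for (i in seq_len(k)) {
    cv[, , i] <- cv[, , i] + diag(var_floor, d)
  }
  structure(
    list(k = k, means = mu, covariances = cv,
         weights = as.numeric(fit$parameters$pro %||% 1),
         labels = as.integer(fit$classification),
         loglik = fit$loglik, seed = as.integer(seed)),
    class = "phasor_gmm"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phasor_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d, n = %d, weights %s\n",
              x$k, length(x$labels),
              paste(sprintf("%.3f", x$weights), collapse = "/")))
  invisible(x)
}

#' Compare two lifetime distributions
#'
#' Runs the two nonparametric two-sample tests used for phasor-FLIM
#' lifetime populations — Kolmogorov-Smirnov and Mann-Whitney U, both
#' two-sided — with Bonferroni correction, and evaluates Gaussian kernel
#' density estimates of both groups on a common grid (default bandwidth
#' 0.01 ns) together with percentile, skewness and spread summaries.
#'
#' @param a,b Numeric samples (e.g. per-pixel modulation lifetimes),
#'   each with at least 5 points.
#' @param bandwidth KDE bandwidth in the data's units. Default 0.01.
#' @param n_tests Bonferroni multiplicity. Defaults to 2 (the two test
#'   statistics computed here); raise it when comparing several sample
#'   pairs in one study.
#' @param grid_n KDE grid size. Default 512.
#' @return An object of class `dist_comparison`: `ks_stat`, `ks_p`,
#'   `mwu_stat`, `mwu_p`, `corrected_ps` (named), `kde_grid`,
#'   `kde_density` (two-column matrix), and `summary` (per-group
#'   percentiles, mean, skewness, IQR).
#' @export
compare_distributions <- function(a, b, bandwidth = 0.01, n_tests = 2L,
                                  grid_n = 512L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 5L || length(b) < 5L) {
    stop("each group needs at least 5 finite values", call. = FALSE)
  }
  ks <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  # exact Mann-Whitney for small tie-free samples, normal approximation
  # with continuity correction otherwise (the stats::wilcox.test default)
  mwu <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  ps <- c(ks = unname(ks$p.value), mwu = unname(mwu$p.value))
  lo <- min(a, b) - 3 * bandwidth
  hi <- max(a, b) + 3 * bandwidth
  kde_a <- density(a, bw = bandwidth, kernel = "gaussian",
                   from = lo, to = hi, n = grid_n)
  kde_b <- density(b, bw = bandwidth, kernel = "gaussian",
                   from = lo, to = hi, n = grid_n)
  summarise_group <- function(x) {
    m <- mean(x); s <- sd(x)
    c(quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95)),
      mean = m,
      skewness = if (s > 0) mean(((x - m) / s)^3) else 0,
      iqr = unname(diff(quantile(x, c(0.25, 0.75)))))
  }
  structure(
    list(
      ks_stat = unname(ks$statistic), ks_p = ps[["ks"]],
      mwu_stat = unname(mwu$statistic), mwu_p = ps[["mwu"]],
      corrected_ps = setNames(pmin(1, n_tests * ps), names(ps)),
      n_tests = as.integer(n_tests),
      kde_grid = kde_a$x,
      kde_density = cbind(a = kde_a$y, b = kde_b$y),
      summary = rbind(a = summarise_group(a), b = summarise_group(b))
    ),
    class = "dist_comparison"
  )
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat(sprintf(
    "distribution comparison: KS D = %.4f (p = %.3g), MWU W = %.4g (p = %.3g)\n",
    x$ks_stat, x$ks_p, x$mwu_stat, x$mwu_p))
  cat(sprintf("Bonferroni-corrected (m = %d): KS p = %.3g, MWU p = %.3g\n",
              x$n_tests, x$corrected_ps[["ks"]], x$corrected_ps[["mwu"]]))
  invisible(x)
}

#' Fit a trend model to summary data
#'
#' Three models cover the trends that arise in lifetime studies:
#' \describe{
#'   \item{linear}{ordinary least squares `y = a + b x`;}
#'   \item{power_law}{`y = a x^b`, fitted by least squares on the
#'     log-log scale (both `x` and `y` must be positive);}
#'   \item{exponential_rate}{`y = c + a exp(-x / tau_decay)`, fitted by
#'     nonlinear least squares — the model for inverse-lifetime decay
#'     over storage time, with `tau_decay` reported in the units of `x`
#'     (days).}
#' }
#' `r2` is computed as `1 - SS_res/SS_tot` on the model's fitted scale
#' (the log-log scale for the power law).
#'
#' @param x,y Numeric vectors, at least 3 points.
#' @param model One of `"linear"`, `"power_law"`, `"exponential_rate"`.
#' @return An object of class `trend_fit`: `model`, named `params`,
#'   `r2`, `fitted`, and `decay_time` for the exponential model.
#' @export
fit_trend <- function(x, y, model = c("linear", "power_law",
                                      "exponential_rate")) {
  model <- match.arg(model)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  r2_of <- function(obs, fit) {
    ss_res <- sum((obs - fit)^2)
    ss_tot <- sum((obs - mean(obs))^2)
    if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
    1 - ss_res / ss_tot
  }
  if (model == "linear") {
    fit <- lm(y ~ x)
    cf <- coef(fit)
    out <- list(params = c(intercept = unname(cf[1]), slope = unname(cf[2])),
                fitted = unname(fitted(fit)),
                r2 = r2_of(y, fitted(fit)))
  } else if (model == "power_law") {
    if (any(x <= 0) || any(y <= 0)) {
      stop("power-law fit needs strictly positive x and y", call. = FALSE)
    }
    fit <- lm(log(y) ~ log(x))
    cf <- coef(fit)
    out <- list(params = c(a = unname(exp(cf[1])), b = unname(cf[2])),
                fitted = unname(exp(fitted(fit))),
                r2 = r2_of(log(y), fitted(fit)))
  } else {
    c0 <- y[which.max(x)]
    a0 <- y[which.min(x)] - c0
    if (abs(a0) < 1e-12) a0 <- diff(range(y)) + 1e-12
    t0 <- max(diff(range(x)) / 3, 1e-6)
    fit <- minpack.lm::nlsLM(
      y ~ c0 + a * exp(-x / tau_d),
      start = list(c0 = c0, a = a0, tau_d = t0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- coef(fit)
    out <- list(params = c(c0 = unname(cf["c0"]), a = unname(cf["a"]),
                           tau_decay = unname(cf["tau_d"])),
                fitted = unname(fitted(fit)),
                r2 = r2_of(y, fitted(fit)),
                decay_time = unname(cf["tau_d"]))
  }
  structure(c(list(model = model, x = x, y = y), out), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend fit (%s): R^2 = %.4f\n", x$model, x$r2))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  invisible(x)
}
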
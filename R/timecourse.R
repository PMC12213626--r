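#' Exponential decay fit with floor
#'
#' Least-squares fit of \code{T(t) = C + A * exp(-k t)}: a bounded grid over
#' the rate \code{k} with closed-form linear least squares for \code{(C, A)}
#' at each grid point, refined by golden-section search around the grid
#' optimum.  Deterministic and derivative-free.  A constant series is
#' flagged not-identifiable (the rate has no information).
#'
#' @param times numeric times (days); at least 4 points, 3 distinct times.
#' @param values measurements (um).
#' @param k_range search bounds for the rate (1/day).
#' @param n_grid grid size.
#' @return an \code{exp_decay_fit}: \code{floor_C}, \code{amplitude_A},
#'   \code{rate_k}, \code{half_decay_days = ln(2)/k}, \code{rss}, \code{n},
#'   \code{not_identifiable}.
#' @export
fit_exp_decay <- function(times, values, k_range = c(0.01, 2), n_grid = 150) {
  stopifnot(length(times) == length(values), length(times) >= 4,
            length(unique(times)) >= 3, all(is.finite(times)),
            all(is.finite(values)))
  if (sd(values) == 0) {
    return(structure(list(floor_C = values[1], amplitude_A = 0,
                          rate_k = NA_real_, half_decay_days = NA_real_,
                          rss = 0, n = length(values),
                          not_identifiable = TRUE), class = "exp_decay_fit"))
  }
  lsq <- function(k) {
    x <- exp(-k * times)
    X <- cbind(1, x)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, values)),
                   error = function(e) NULL)
    if (is.null(cf)) return(list(rss = Inf, C = NA, A = NA))
    r <- values - X %*% cf
    list(rss = sum(r^2), C = cf[1], A = cf[2])
  }
  ks <- seq(k_range[1], k_range[2], length.out = n_grid)
  rss <- vapply(ks, function(k) lsq(k)$rss, numeric(1))
  i <- which.min(rss)
  lo <- ks[max(1, i - 1)]
  hi <- ks[min(n_grid, i + 1)]
  # golden-section refinement
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- lsq(x1)$rss; f2 <- lsq(x2)$rss
  while (b - a > 1e-10) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- lsq(x1)$rss
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- lsq(x2)$rss
    }
  }
  k <- (a + b) / 2
  fit <- lsq(k)
  not_id <- abs(fit$A) < 1e-8 * max(abs(values))
  structure(list(floor_C = unname(fit$C), amplitude_A = unname(fit$A),
                 rate_k = k,
                 half_decay_days = if (not_id) NA_real_ else log(2) / k,
                 rss = fit$rss, n = length(values),
                 not_identifiable = not_id), class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  if (x$not_identifiable) {
    cat("<exp_decay_fit> not identifiable (constant series)\n")
  } else {
    cat(sprintf("<exp_decay_fit> T(t) = %.3f + %.3f exp(-%.4f t); half-decay %.2f days (n=%d)\n",
                x$floor_C, x$amplitude_A, x$rate_k, x$half_decay_days, x$n))
  }
  invisible(x)
}

#' Linear fit with R-squared and bootstrap confidence interval
#'
#' Ordinary least squares of \code{y} on \code{x}; \code{R^2 = 1 - RSS/TSS}
#' (0 by convention if \code{y} is constant).  The 95% CI for R-squared is a
#' case-resampling percentile bootstrap (seeded, deterministic).
#'
#' @param x,y numeric vectors, length >= 3; \code{x} must not be constant.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return a \code{correlation_result}: slope, intercept, r_squared,
#'   ci95_low, ci95_high, n.
#' @export
linfit_r2 <- function(x, y, n_boot = 2000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("x is constant; no linear fit possible")
  r2_of <- function(xi, yi) {
    if (sd(yi) == 0) return(list(slope = 0, intercept = mean(yi), r2 = 0))
    sl <- sum((xi - mean(xi)) * (yi - mean(yi))) / sum((xi - mean(xi))^2)
    ic <- mean(yi) - sl * mean(xi)
    rss <- sum((yi - ic - sl * xi)^2)
    tss <- sum((yi - mean(yi))^2)
    list(slope = sl, intercept = ic, r2 = 1 - rss / tss)
  }
  fit <- r2_of(x, y)
  set.seed(seed)
  n <- length(x)
  r2b <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sd(x[idx]) == 0) next
    r2b[b] <- r2_of(x[idx], y[idx])$r2
  }
  ci <- unname(quantile(r2b, c(0.025, 0.975), na.rm = TRUE))
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r2, ci95_low = ci[1], ci95_high = ci[2],
                 n = n, n_boot = n_boot), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> y = %.3f + %.3f x; R^2 = %.3f (95%% CI %.3f-%.3f, n=%d)\n",
              x$intercept, x$slope, x$r_squared, x$ci95_low, x$ci95_high, x$n))
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test of \code{after - before}:
#' \code{t = mean(d) / (sd(d)/sqrt(n))}, df = n - 1.  All-zero differences
#' are flagged \code{"zero_difference"} with p = 1; zero-variance nonzero
#' differences are flagged \code{"zero_variance"} with p below the machine
#' floor.
#'
#' @param before,after paired measurements, equal length n >= 2.
#' @return list: \code{t_stat}, \code{df}, \code{p_two_sided}, \code{flag}
#'   ("ok", "zero_difference" or "zero_variance").
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- after - before
  n <- length(d)
  if (all(d == 0))
    return(list(t_stat = NA_real_, df = n - 1L, p_two_sided = 1,
                flag = "zero_difference"))
  if (sd(d) == 0)
    return(list(t_stat = sign(mean(d)) * Inf, df = n - 1L,
                p_two_sided = .Machine$double.xmin, flag = "zero_variance"))
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t_stat = t_stat, df = n - 1L,
       p_two_sided = 2 * pt(-abs(t_stat), df = n - 1), flag = "ok")
}
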
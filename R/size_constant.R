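#' Defect-size probability histogram
#'
#' Bins defect areas (in Angstrom^2; 1 nm^2 = 100 A^2) into fixed-width
#' bins and normalises counts to probabilities summing to 1 over occupied
#' bins.
#'
#' @param areas numeric defect areas in A^2, or a `defect_set` (areas taken
#'   from its `area_nm2` column and converted).
#' @param bin_width bin width in A^2 (default 1).
#' @return A `defect_histogram` data.frame with columns `mid` (bin center,
#'   A^2), `count` and `prob`.
#' @export
defect_area_histogram <- function(areas, bin_width = 1) {
  if (inherits(areas, "defect_set")) areas <- areas$area_nm2 * 100
  areas <- as.numeric(areas)
  if (!length(areas)) stop_mem("no defect areas to histogram")
  if (bin_width <= 0) stop_mem("bin_width must be positive")
  bin <- floor(areas / bin_width)
  tab <- table(bin)
  out <- data.frame(mid = (as.numeric(names(tab)) + 0.5) * bin_width,
                    count = as.integer(tab))
  out$prob <- out$count / sum(out$count)
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- length(areas)
  class(out) <- c("defect_histogram", "data.frame")
  out
}

#' Fit the defect size constant A0
#'
#' Fits the exponential decay `A * exp(-x / A0)` to the defect-size
#' probability distribution by count-weighted least squares on
#' `ln P(x) = ln A - x / A0` over occupied bins in `[fit_min, fit_max]`
#' (counts are the inverse-variance weights for log counts).  `fit_max`
#' defaults to the largest bin still holding at least 5 counts, restricting
#' the fit to the well-sampled small-defect regime.  A0 is reported in
#' A^2; larger A0 means relatively more large defects.
#'
#' @param x a `defect_histogram`, a numeric vector of areas in A^2, or a
#'   `defect_set`.
#' @param fit_min lower edge of the fit range, A^2 (default 5).
#' @param fit_max upper edge of the fit range, A^2; `NULL` for automatic.
#' @param bin_width bin width used when `x` is not already a histogram.
#' @param n_min minimum number of samples required inside the fit range
#'   (default 50).
#' @return A `size_constant_fit` with components `A`, `A0`, `fit_min`,
#'   `fit_max`, `r_squared`, `n_samples`.
#' @export
fit_size_constant <- function(x, fit_min = 5, fit_max = NULL, bin_width = 1,
                              n_min = 50) {
  hist <- if (inherits(x, "defect_histogram")) x
          else defect_area_histogram(x, bin_width)
  bw <- attr(hist, "bin_width")
  if (is.null(fit_max)) {
    heavy <- hist$mid[hist$count >= 5 & hist$mid >= fit_min]
    if (!length(heavy))
      stop_mem("no bin at or above fit_min holds >= 5 counts; cannot set fit_max")
    fit_max <- max(heavy)
  }
  if (fit_min >= fit_max)
    stop_mem("degenerate fit range [%g, %g] A^2", fit_min, fit_max)
  sel <- hist$mid >= fit_min & hist$mid <= fit_max & hist$count >= 1
  n_samples <- sum(hist$count[sel])
  if (sum(sel) < 3)
    stop_mem("only %d occupied bins in fit range; need >= 3 (degenerate distribution)",
             sum(sel))
  if (n_samples < n_min)
    stop_mem("only %d samples in fit range [%g, %g]; need >= %d",
             n_samples, fit_min, fit_max, n_min)
  dat <- data.frame(mid = hist$mid[sel],
                    logp = log(hist$prob[sel]),
                    w = hist$count[sel])
  fit <- stats::lm(logp ~ mid, data = dat, weights = w)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop_mem("distribution does not decay over the fit range; A0 undefined")
  structure(list(A = exp(unname(stats::coef(fit)[1])),
                 A0 = -1 / slope,
                 fit_min = fit_min, fit_max = fit_max,
                 r_squared = summary(fit)$r.squared,
                 n_samples = n_samples,
                 lm_fit = fit, histogram = hist),
            class = "size_constant_fit")
}

#' @export
print.size_constant_fit <- function(x, ...) {
  cat(sprintf("Defect size constant fit: A0 = %.3f A^2 (A = %.4g)\n",
              x$A0, x$A))
  cat(sprintf("  fit range [%g, %g] A^2, %d samples, R^2 = %.4f\n",
              x$fit_min, x$fit_max, x$n_samples, x$r_squared))
  invisible(x)
}

#' @export
summary.size_constant_fit <- function(object, ...) {
  print(object)
  cat("\nWeighted log-linear regression:\n")
  print(summary(object$lm_fit)$coefficients)
  invisible(object)
}

#' @export
coef.size_constant_fit <- function(object, ...) {
  c(A = object$A, A0 = object$A0)
}

#' @export
predict.size_constant_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$histogram$mid
       else if (is.data.frame(newdata)) newdata$mid
       else as.numeric(newdata)
  object$A * exp(-x / object$A0)
}

#' @export
residuals.size_constant_fit <- function(object, ...) {
  stats::residuals(object$lm_fit)
}

#' @export
simulate.size_constant_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_local_seed(seed, {
    replicate(nsim,
              object$fit_min + stats::rexp(1000, rate = 1 / object$A0),
              simplify = FALSE)
  })
}

#' @export
plot.size_constant_fit <- function(x, ...) {
  h <- x$histogram
  graphics::plot(h$mid, log(h$prob), pch = 16, cex = 0.6,
                 xlab = expression(paste("defect area (", ring(A)^2, ")")),
                 ylab = "ln P", ...)
  xs <- seq(x$fit_min, x$fit_max, length.out = 100)
  graphics::lines(xs, log(x$A) - xs / x$A0, col = "red3", lwd = 2)
  graphics::abline(v = c(x$fit_min, x$fit_max), lty = 3, col = "grey50")
  invisible(x)
}
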
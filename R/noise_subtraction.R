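#' Adjusted Rayleigh noise model
#'
#' Background noise in magnitude MR images follows a Rayleigh distribution.
#' The model used here augments the standard Rayleigh curve with an intensity
#' scaling `alpha` and a horizontal shift `delta`:
#' \deqn{r(f) = \frac{(\alpha f + \delta)\, e^{-(\alpha f + \delta)^2 / 2\sigma^2}}{\sigma^2}}
#' Values where `alpha * f + delta < 0` are clipped to zero (the curve is only
#' meaningful on the non-negative part of its support).
#'
#' Note the model family is scale-degenerate: multiplying all three
#' parameters by the same constant rescales the curve's amplitude, so when
#' fitted to a normalized histogram only the ratios `sigma/alpha` and
#' `delta/alpha` (plus the amplitude) are identifiable. At `alpha = 1`,
#' `delta = 0` the curve is the plain Rayleigh density and `sigma` itself is
#' identifiable.
#'
#' @param f intensity level(s).
#' @param sigma Rayleigh scale, > 0.
#' @param alpha intensity scaling, > 0.
#' @param delta horizontal shift (intensity units).
#' @return the curve evaluated at `f`.
#' @export
adjusted_rayleigh <- function(f, sigma, alpha = 1, delta = 0) {
  t <- alpha * f + delta
  out <- (t / sigma^2) * exp(-t^2 / (2 * sigma^2))
  out[t < 0] <- 0
  out
}

#' Sample inverse-transform draws from the adjusted Rayleigh model
#'
#' Draws `f = (sigma * sqrt(-2 log U) - delta) / alpha` with `U ~ Uniform(0,1)`,
#' clipped at zero. Used by the phantom background generator and by the
#' parameter-recovery tests.
#'
#' @param n number of draws.
#' @param sigma,alpha,delta model parameters.
#' @param clip clip draws at zero (default TRUE, matching image intensities).
#' @return numeric vector of length `n`.
#' @export
rayleigh_noise <- function(n, sigma, alpha = 1, delta = 0, clip = TRUE) {
  u <- runif(n)
  f <- (sigma * sqrt(-2 * log(u)) - delta) / alpha
  if (clip) f <- pmax(0, f)
  f
}

#' Sample background noise from a slice
#'
#' Builds the background-noise intensity histogram from an automated
#' `box_rows x box_cols` pixel box (default 25 x 50) whose bottom edge is the
#' last image row and whose columns are centred horizontally (when the
#' remaining width is odd, the box shifts left by one pixel). For a 256 x 256
#' slice this is rows 232..256 and columns 104..153 (1-based), 1250 pixels.
#'
#' Intensities are rounded to unit-width integer bins and normalized to a
#' probability mass function so that the fitted curve and the histogram are
#' commensurate.
#'
#' @param slice a numeric matrix (one coronal slice).
#' @param box_rows,box_cols sampling-box dimensions in pixels.
#' @return an object of class `noise_histogram`: list with `f` (integer bin
#'   values `0..max`), `h` (observed densities, summing to 1), `counts`,
#'   `n_samples`, and `box` (`c(row_min, col_min, row_max, col_max)`, 1-based).
#' @export
sample_background <- function(slice, box_rows = 25, box_cols = 50) {
  stopifnot(is.matrix(slice))
  nr <- nrow(slice)
  nc <- ncol(slice)
  if (nr < box_rows || nc < box_cols) {
    stop(sprintf("slice (%d x %d) smaller than the %d x %d sampling box",
                 nr, nc, box_rows, box_cols), call. = FALSE)
  }
  row_min <- nr - box_rows + 1L
  col_min <- floor((nc - box_cols) / 2) + 1L  # odd remainder -> shift left
  box <- c(row_min, col_min, nr, col_min + box_cols - 1L)
  vals <- as.integer(round(slice[row_min:nr, col_min:box[4L]]))
  counts <- tabulate(vals + 1L, nbins = max(vals) + 1L)
  structure(
    list(
      f = 0:max(vals),
      h = counts / length(vals),
      counts = counts,
      n_samples = length(vals),
      box = box
    ),
    class = "noise_histogram"
  )
}

#' Build a noise histogram from raw values
#'
#' Convenience constructor used when the noise sample does not come from the
#' standard box (e.g. simulation studies). Same binning/normalization rules as
#' [sample_background()].
#'
#' @param values numeric vector of sampled noise intensities (>= 0).
#' @return a `noise_histogram`.
#' @export
noise_histogram <- function(values) {
  stopifnot(length(values) > 0L, all(is.finite(values)), all(values >= 0))
  vals <- as.integer(round(values))
  counts <- tabulate(vals + 1L, nbins = max(vals) + 1L)
  structure(
    list(f = 0:max(vals), h = counts / length(vals), counts = counts,
         n_samples = length(vals), box = NULL),
    class = "noise_histogram"
  )
}

#' Fit the adjusted Rayleigh curve to a noise histogram
#'
#' Least-squares fit of [adjusted_rayleigh()] to the histogram densities over
#' its support: `(sigma, alpha, delta)` minimize
#' `sum_f (r(f) - h(f))^2`. The optimizer is Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with bounds `sigma, alpha > 1e-6` and `delta`
#' unbounded, initialized at `sigma0 =` the histogram mode, `alpha0 = 1`,
#' `delta0 = 0` unless `init` overrides; a bounded quasi-Newton refit is used
#' as fallback if Levenberg-Marquardt fails to converge. The fit is
#' deterministic given the initialization.
#'
#' @param hist a `noise_histogram` with at least 3 distinct populated bins.
#' @param init optional named list/vector with starting `sigma`, `alpha`,
#'   `delta`.
#' @param max_iter maximum optimizer iterations.
#' @return an object of class `noise_fit`: list with `sigma`, `alpha`,
#'   `delta`, `rss`, and `tau` (`NA` until [compute_threshold()] is run).
#' @export
fit_adjusted_rayleigh <- function(hist, init = NULL, max_iter = 200) {
  stopifnot(inherits(hist, "noise_histogram"))
  if (sum(hist$h > 0) < 3L) {
    stop("degenerate histogram: need at least 3 distinct populated bins",
         call. = FALSE)
  }
  f <- hist$f
  h <- hist$h
  start <- list(sigma = as.numeric(f[which.max(h)]), alpha = 1, delta = 0)
  if (start$sigma <= 0) start$sigma <- max(1, mean(f * h) * sqrt(2 / pi) + 1)
  if (!is.null(init)) start <- modifyList(start, as.list(init))
  lower <- c(sigma = 1e-6, alpha = 1e-6, delta = -Inf)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      h ~ adjusted_rayleigh(f, sigma, alpha, delta),
      data = data.frame(f = f, h = h),
      start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = max_iter, maxfev = 10L * max_iter)
    ),
    error = function(e) e
  )
  if (!inherits(fit, "error")) {
    par <- coef(fit)
    rss <- sum(residuals(fit)^2)
  } else {
    obj <- function(p) sum((adjusted_rayleigh(f, p[1L], p[2L], p[3L]) - h)^2)
    opt <- optim(unlist(start), obj, method = "L-BFGS-B",
                 lower = lower, control = list(maxit = max_iter))
    if (opt$convergence != 0L) {
      stop(sprintf("adjusted-Rayleigh fit did not converge (last iterate sigma=%.4g alpha=%.4g delta=%.4g)",
                   opt$par[1L], opt$par[2L], opt$par[3L]), call. = FALSE)
    }
    par <- setNames(opt$par, c("sigma", "alpha", "delta"))
    rss <- opt$value
  }
  structure(
    list(sigma = unname(par["sigma"]), alpha = unname(par["alpha"]),
         delta = unname(par["delta"]), rss = rss, tau = NA_integer_),
    class = "noise_fit"
  )
}

#' Optimal noise threshold from a fitted curve
#'
#' Returns the integer threshold `tau` minimizing the misclassification error
#' \deqn{\epsilon_\tau = \sum_{f=0}^{\tau-1} g(f) + \sum_{f=\tau}^{F} r(f),
#'   \qquad g(f) = r(f) - h(f),}
#' enumerated over every integer `tau` in `[0, F + 1]`. The nominally infinite
#' upper sum is truncated at `F`, the larger of the histogram support maximum
#' and the point where the cumulative fitted curve exceeds `1 - tail_tol`.
#' Ties are broken toward the smallest `tau`.
#'
#' `g(f)` is used signed, exactly as defined; `clamp_g = TRUE` clamps it at
#' zero (off by default). A consequence of the signed definition is that
#' \eqn{\epsilon_{\tau+1} - \epsilon_\tau = -h(\tau) \le 0}, so the optimum
#' sits one intensity level above the largest sampled background value: the
#' threshold adapts to the full extent of the observed noise.
#'
#' @param fit a `noise_fit`.
#' @param hist the `noise_histogram` the fit was computed from.
#' @param tail_tol truncation tolerance for the upper sum.
#' @param clamp_g clamp `g(f)` at zero before summing.
#' @return the optimal integer threshold `tau`.
#' @export
compute_threshold <- function(fit, hist, tail_tol = 1e-6, clamp_g = FALSE) {
  stopifnot(inherits(fit, "noise_fit"), inherits(hist, "noise_histogram"))
  if (length(hist$f) == 0L) stop("empty histogram support", call. = FALSE)
  f_max <- max(hist$f)
  # extend the grid until the cumulative fitted curve passes 1 - tail_tol
  # (or a generous multiple of the fitted scale, if it never does)
  f_hi <- max(f_max, ceiling((6 * fit$sigma - fit$delta) / fit$alpha), f_max + 1L)
  f_ext <- 0:f_hi
  r <- adjusted_rayleigh(f_ext, fit$sigma, fit$alpha, fit$delta)
  cum_r <- cumsum(r)
  hit <- which(cum_r >= 1 - tail_tol)
  f_big <- if (length(hit)) f_ext[hit[1L]] else f_hi
  bigF <- max(f_max, f_big)
  f_ext <- 0:bigF
  r <- r[seq_len(bigF + 1L)]
  h <- numeric(bigF + 1L)
  h[hist$f + 1L] <- hist$h
  g <- r - h
  if (clamp_g) g <- pmax(g, 0)
  # eps(tau) for tau = 0..bigF+1; cumulative forms of the two sums
  eps <- c(0, cumsum(g)) + (sum(r) - c(0, cumsum(r)))
  # smallest argmin; analytic ties (flat tail beyond the histogram support)
  # must not be broken by floating-point noise in the cumulative sums
  as.integer(which(eps <= min(eps) + 1e-12)[1L] - 1L)
}

#' Fit noise and threshold for every slice
#'
#' Convenience wrapper running [sample_background()],
#' [fit_adjusted_rayleigh()] and [compute_threshold()] per slice (each slice
#' has its own box, fit and threshold).
#'
#' @param stack an `image_stack`.
#' @param box_rows,box_cols sampling-box size.
#' @param clamp_g,tail_tol passed to [compute_threshold()].
#' @param max_iter passed to [fit_adjusted_rayleigh()].
#' @return a list of `noise_fit` objects, one per slice, each with `tau` set.
#' @export
fit_noise <- function(stack, box_rows = 25, box_cols = 50, clamp_g = FALSE,
                      tail_tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(stack, "image_stack"))
  lapply(stack$slices, function(s) {
    hist <- sample_background(s, box_rows = box_rows, box_cols = box_cols)
    fit <- fit_adjusted_rayleigh(hist, max_iter = max_iter)
    fit$tau <- compute_threshold(fit, hist, tail_tol = tail_tol,
                                 clamp_g = clamp_g)
    fit
  })
}

#' Apply per-slice thresholds to build the initial binary mask
#'
#' A mask pixel is 1 iff its intensity is at least the threshold of its slice.
#'
#' @param stack an `image_stack`.
#' @param fits a list of `noise_fit` objects (one per slice, `tau` set), or a
#'   numeric vector of thresholds of length `n_slices(stack)` (a single value
#'   is recycled).
#' @return a `mask_stack` with the geometry of `stack`.
#' @export
apply_threshold <- function(stack, fits) {
  stopifnot(inherits(stack, "image_stack"))
  ns <- n_slices(stack)
  if (is.list(fits)) {
    if (length(fits) != ns) {
      stop(sprintf("got %d fits for %d slices", length(fits), ns), call. = FALSE)
    }
    taus <- vapply(fits, function(f) {
      if (!inherits(f, "noise_fit") || is.na(f$tau)) {
        stop("each fit must be a noise_fit with tau set", call. = FALSE)
      }
      as.numeric(f$tau)
    }, numeric(1L))
  } else {
    taus <- as.numeric(fits)
    if (length(taus) == 1L) taus <- rep(taus, ns)
    if (length(taus) != ns) {
      stop(sprintf("got %d thresholds for %d slices", length(taus), ns),
           call. = FALSE)
    }
  }
  masks <- lapply(seq_len(ns), function(k) {
    m <- (stack$slices[[k]] >= taus[k]) * 1L
    matrix(as.integer(m), stack$n_rows, stack$n_cols)
  })
  mask_stack(masks, like = stack)
}

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf("<noise_fit> sigma=%.4g alpha=%.4g delta=%.4g rss=%.3g tau=%s\n",
              x$sigma, x$alpha, x$delta, x$rss,
              if (is.na(x$tau)) "<unset>" else x$tau))
  invisible(x)
}
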
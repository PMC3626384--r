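#' Ventilated lung volume
#'
#' VLV is the number of mask pixels classified as ventilated times the voxel
#' volume. Per-slice volumes are reported in mL and the total in litres
#' (`total_l = sum(per_slice_ml) / 1000` exactly).
#'
#' @param mask a `mask_stack` with valid geometry.
#' @param subject_id optional identifier carried through to reports.
#' @return an object of class `vlv_result`: list with `subject_id`,
#'   `per_slice_ml`, `total_l`, `voxel_volume_mm3`.
#' @examples
#' m <- mask_stack(matrix(rep(c(0L, 1L), 500), 25, 40))  # 500 pixels on
#' compute_vlv(m)$per_slice_ml  # 500 * 42.12 / 1000
#' @export
compute_vlv <- function(mask, subject_id = NULL) {
  stopifnot(inherits(mask, "mask_stack"))
  validate_image_stack(mask)
  vox <- voxel_volume_mm3(mask)
  per_slice_ml <- vapply(mask$slices, function(s) sum(s) * vox / 1000,
                         numeric(1L))
  structure(
    list(subject_id = subject_id, per_slice_ml = per_slice_ml,
         total_l = sum(per_slice_ml) / 1000, voxel_volume_mm3 = vox),
    class = "vlv_result"
  )
}

#' @export
print.vlv_result <- function(x, ...) {
  cat(sprintf("<vlv_result>%s total %.3f L over %d slice(s) (voxel %.4g mm^3)\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              x$total_l, length(x$per_slice_ml), x$voxel_volume_mm3))
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between two binary mask stacks of
#' identical geometry; 1 means perfect agreement, 0 no overlap. When both
#' masks are empty the coefficient is defined as 1 (vacuous perfect
#' agreement; the formula itself is 0/0 there) and a message is emitted.
#'
#' @param a,b `mask_stack` objects with identical geometry.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "mask_stack"), inherits(b, "mask_stack"))
  if (!same_geometry(a, b)) stop("mask geometries differ", call. = FALSE)
  inter <- 0
  na <- 0
  nb <- 0
  for (k in seq_len(n_slices(a))) {
    inter <- inter + sum(a$slices[[k]] == 1L & b$slices[[k]] == 1L)
    na <- na + sum(a$slices[[k]])
    nb <- nb + sum(b$slices[[k]])
  }
  if (na + nb == 0) {
    message("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * inter / (na + nb)
}

#' Bland-Altman limits of agreement
#'
#' Differences `a - b`; the 95% limits of agreement are the mean difference
#' plus/minus 1.96 sample standard deviations (n-1 denominator).
#'
#' @param a,b paired numeric vectors (same units), length >= 2.
#' @return list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = length(d))
}

#' Correlation and regression of y on x
#'
#' Pearson correlation with its two-sided p-value (t distribution, n-2
#' degrees of freedom) and the ordinary least-squares slope and intercept of
#' `y` regressed on `x`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `slope`, `intercept`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in x or y: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y)
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]), p = ct$p.value, n = length(x))
}

#' Paired and unpaired t tests
#'
#' Two-sided Student t tests: paired on the differences, or classical pooled
#' two-sample (`var.equal = TRUE`) when unpaired. A paired comparison of
#' vectors whose differences have zero standard deviation is degenerate
#' (the t statistic is undefined); it is reported with `degenerate = TRUE`
#' and, for identical vectors, the convention `p = 1`.
#'
#' @param a,b numeric vectors (equal lengths when `paired`).
#' @param paired logical.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
group_tests <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (paired) {
    stopifnot(length(a) == length(b))
    d <- a - b
    if (sd(d) == 0) {
      return(list(t = NaN, p = if (all(d == 0)) 1 else NA_real_,
                  df = length(d) - 1L, degenerate = TRUE))
    }
    tt <- t.test(a, b, paired = TRUE)
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector (n >= 1; the SD uses the n-1 denominator and
#'   is `NA` for n = 1).
#' @return named vector `c(mean, sd)`.
#' @export
summarize_values <- function(values) {
  if (!length(values)) stop("empty input", call. = FALSE)
  c(mean = mean(values), sd = sd(values))
}

#' Agreement report between two segmentation methods
#'
#' Bundles the subject-level agreement analyses between a semiautomatic and a
#' reference (manual) segmentation: Bland-Altman limits of agreement on the
#' VLVs, regression/correlation of one method on the other, a paired t test,
#' and (when given) the per-subject Dice coefficients.
#'
#' @param vlv_a,vlv_b paired per-subject VLVs (litres or mL; units carried
#'   through unchanged).
#' @param dice optional per-subject Dice coefficients.
#' @return an object of class `agreement_report`: list with `bland_altman`,
#'   `regression` (of `vlv_a` on `vlv_b`), `paired_t`, `dice`
#'   (`c(mean, sd)` or `NULL`), `n`.
#' @export
agreement_report <- function(vlv_a, vlv_b, dice = NULL) {
  structure(
    list(
      bland_altman = bland_altman(vlv_a, vlv_b),
      regression = correlate(vlv_b, vlv_a),
      paired_t = group_tests(vlv_a, vlv_b, paired = TRUE),
      dice = if (is.null(dice)) NULL else summarize_values(dice),
      n = length(vlv_a)
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf("<agreement_report> n=%d\n", x$n))
  cat(sprintf("  Bland-Altman: mean diff %.3g +/- %.3g, LoA [%.3g, %.3g]\n",
              ba$mean_diff, ba$sd_diff, ba$loa_low, ba$loa_high))
  cat(sprintf("  regression: r=%.3f slope=%.3f p=%.3g\n",
              x$regression$r, x$regression$slope, x$regression$p))
  cat(sprintf("  paired t: t=%.3g p=%.3g%s\n", x$paired_t$t, x$paired_t$p,
              if (x$paired_t$degenerate) " (degenerate)" else ""))
  if (!is.null(x$dice)) {
    cat(sprintf("  Dice: %.3f +/- %.3f\n", x$dice["mean"], x$dice["sd"]))
  }
  invisible(x)
}
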
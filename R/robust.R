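#' Robust centre and scale of a value vector
#'
#' Median and MAD scaled by 1.4826, the constant that makes the MAD a
#' consistent estimator of the standard deviation under normality.
#'
#' @param values numeric vector; `NA`s (missing cells) are dropped.
#' @return list with `med` and `mad` (`mad` already carries the 1.4826
#'   scaling).
#' @examples
#' robust_center_scale(c(1, 2, 3, 4, 5))  # med 3, mad 1.4826
#' @export
robust_center_scale <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("robust_center_scale: no non-missing values", call. = FALSE)
  med <- stats::median(v)
  list(med = med, mad = MAD_CONSTANT * stats::median(abs(v - med)))
}

# 1.4826 ~ 1/qnorm(3/4): MAD-to-sigma scaling under normality
MAD_CONSTANT <- 1.4826

#' Boxplot-rule outlier cut-off (q75 + IQR)
#'
#' The standard upper outlier fence: the 75th percentile plus the
#' interquartile range of the defining sample set. Quantiles use linear
#' interpolation between order statistics (R's type 7), the convention
#' pinned for every quantile in this package.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @param source which samples defined the cut-off, recorded for
#'   provenance: `"all"` (GTI, OS) or `"normal"` (ORT).
#' @return list of class `OutlierCutoff` with fields `b` and `source`.
#' @examples
#' outlier_cutoff(1:8)$b  # 6.25 + (6.25 - 2.75) = 9.75
#' @export
outlier_cutoff <- function(values, source = c("all", "normal")) {
  source <- match.arg(source)
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("outlier_cutoff: no non-missing values", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  structure(list(b = q[2L] + (q[2L] - q[1L]), source = source),
            class = "OutlierCutoff")
}

# Row-wise helpers over a genes x samples matrix with NA = missing.
# apply() is fast enough at the scales this package targets (thousands of
# genes); quantile type 7 everywhere.

row_median <- function(x) apply(x, 1L, stats::median, na.rm = TRUE)

row_mad <- function(x, center = row_median(x)) {
  MAD_CONSTANT * row_median(abs(x - center))
}

row_quantile <- function(x, p) {
  apply(x, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    stats::quantile(v, p, names = FALSE, type = 7)
  })
}

# q75 + IQR per row
row_cutoff <- function(x) {
  apply(x, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q[2L] + (q[2L] - q[1L])
  })
}
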
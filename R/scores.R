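#' @name outlier-statistics
#' @title Per-gene cancer outlier statistics
#'
#' @description
#' Five per-gene scores for detecting genes over-expressed in a subset of
#' disease samples, computed on a genes x samples matrix with group 1 the
#' normal/reference samples and group 2 the disease samples. Missing cells
#' (`NA`) are excluded per gene, so each gene is scored over its own
#' informative-sample set — the regime of integrated multi-platform data
#' where sample counts vary gene by gene.
#'
#' * `t_statistic`: pooled-variance two-sample t, positive when the disease
#'   mean exceeds the normal mean.
#' * `copa_score`: r-th percentile (default 90) of the disease samples after
#'   centring by the all-sample median and scaling by the all-sample
#'   1.4826-MAD.
#' * `os_score` (Outlier Sum): sum of the standardized disease values that
#'   exceed the q75 + IQR cut-off computed from all samples.
#' * `ort_score` (Outlier Robust t): sum of normal-median-centred disease
#'   values above the q75 + IQR cut-off of the *normal* samples only,
#'   scaled by a pooled MAD of group-median-centred values.
#' * `gti_score` (Gene Tissue Index): per group, 100 x (proportion of
#'   samples above the all-sample cut-off B) x (mean exceedance above B,
#'   relative to B); the gene's index is the disease-group score minus the
#'   normal-group score.
#'
#' Degenerate genes (zero scale estimate; for GTI a non-positive cut-off;
#' fewer informative samples than the statistic needs) get `NA` rather than
#' an infinite score, so they cannot occupy spurious top ranks.
#'
#' @param x numeric genes x samples matrix (or `ExpressionMatrix`), `NA` =
#'   missing cell.
#' @param groups a [group_assignment()] covering the matrix samples.
#' @return named numeric vector, one score per gene; `NA` where undefined.
NULL

# Split the matrix by group and count informative samples per gene.
split_groups <- function(x, groups) {
  x <- as_expression_matrix(x)
  lab <- align_groups(x, groups)
  x1 <- x[, lab == 1L, drop = FALSE]
  x2 <- x[, lab == 2L, drop = FALSE]
  list(x = unclass(x), x1 = unclass(x1), x2 = unclass(x2),
       k1 = rowSums(!is.na(x1)), k2 = rowSums(!is.na(x2)),
       genes = rownames(x))
}

#' @rdname outlier-statistics
#' @export
t_statistic <- function(x, groups) {
  g <- split_groups(x, groups)
  m1 <- rowMeans(g$x1, na.rm = TRUE)
  m2 <- rowMeans(g$x2, na.rm = TRUE)
  ss1 <- rowSums((g$x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((g$x2 - m2)^2, na.rm = TRUE)
  s <- sqrt((ss1 + ss2) / (g$k1 + g$k2 - 2))
  tt <- (m2 - m1) / (s * sqrt(1 / g$k1 + 1 / g$k2))
  tt[g$k1 < 2L | g$k2 < 2L | s == 0] <- NA_real_
  stats::setNames(tt, g$genes)
}

#' @rdname outlier-statistics
#' @param r percentile (one of 75, 90, 95) of the standardized disease
#'   values reported by COPA; default 90.
#' @export
copa_score <- function(x, groups, r = 90) {
  if (!r %in% c(75, 90, 95))
    stop("COPA percentile r must be 75, 90 or 95", call. = FALSE)
  g <- split_groups(x, groups)
  med <- row_median(g$x)
  mad <- row_mad(g$x, med)
  z2 <- (g$x2 - med) / mad
  sc <- row_quantile(z2, r / 100)
  sc[mad == 0 | g$k1 < 1L | g$k2 < 1L] <- NA_real_
  stats::setNames(sc, g$genes)
}

#' @rdname outlier-statistics
#' @export
os_score <- function(x, groups) {
  g <- split_groups(x, groups)
  med <- row_median(g$x)
  mad <- row_mad(g$x, med)
  b <- row_cutoff(g$x)
  w <- !is.na(g$x2) & g$x2 > b          # strict: values equal to b excluded
  z2 <- (g$x2 - med) / mad
  z2[!w] <- 0
  sc <- rowSums(z2)
  sc[mad == 0 | g$k1 < 1L | g$k2 < 1L] <- NA_real_
  stats::setNames(sc, g$genes)
}

#' @rdname outlier-statistics
#' @export
ort_score <- function(x, groups) {
  g <- split_groups(x, groups)
  med1 <- row_median(g$x1)
  med2 <- row_median(g$x2)
  # pooled MAD of group-median-centred values
  madstar <- MAD_CONSTANT *
    row_median(cbind(abs(g$x1 - med1), abs(g$x2 - med2)))
  b1 <- row_cutoff(g$x1)                # outliers judged against normals only
  w <- !is.na(g$x2) & g$x2 > b1
  num <- g$x2 - med1
  num[!w] <- 0
  sc <- rowSums(num) / madstar
  sc[madstar == 0 | g$k1 < 2L | g$k2 < 1L] <- NA_real_
  stats::setNames(sc, g$genes)
}

#' Single-group Gene Tissue Index
#'
#' The GTI building block for one group of one gene: the proportion of
#' values above the cut-off `b`, weighted by how far above `b` those values
#' sit on average, relative to `b` (a headcount ratio times a relative gap,
#' in the style of the Sen poverty index), scaled by 100 for readability.
#'
#' @param group_values numeric vector of one group's expression values for a
#'   gene; `NA`s dropped.
#' @param cutoff an [outlier_cutoff()] result, or a single number `b`.
#' @return `100 * (|A| / n) * (mean(A) - b) / b` where
#'   `A = {v : v > b}` (strictly above); 0 when `A` is empty; `NA` when
#'   `b <= 0` (the relative gap needs a positive, e.g. log-intensity, scale).
#' @examples
#' gti_group_score(c(1, 1, 1, 1, 9), 2)  # 100 * (1/5) * (9-2)/2 = 70
#' @export
gti_group_score <- function(group_values, cutoff) {
  b <- if (inherits(cutoff, "OutlierCutoff")) cutoff$b else as.numeric(cutoff)
  v <- group_values[!is.na(group_values)]
  if (length(v) == 0L)
    stop("gti_group_score: no non-missing values in group", call. = FALSE)
  if (is.na(b) || b <= 0) {
    warning("GTI cut-off b <= 0: shift data to a positive (log-intensity) ",
            "scale", call. = FALSE)
    return(NA_real_)
  }
  a <- v[v > b]
  if (length(a) == 0L) return(0)
  100 * (length(a) / length(v)) * (mean(a) - b) / b
}

# vectorized per-row group part of the GTI
gti_group_part <- function(xg, kg, b) {
  w <- !is.na(xg) & xg > b
  cnt <- rowSums(w)
  xw <- xg
  xw[!w] <- 0
  mean_a <- rowSums(xw) / cnt          # NaN where cnt == 0, masked below
  out <- 100 * (cnt / kg) * (mean_a - b) / b
  out[cnt == 0L] <- 0
  out
}

#' @rdname outlier-statistics
#' @export
gti_score <- function(x, groups) {
  g <- split_groups(x, groups)
  b <- row_cutoff(g$x)                  # cut-off from ALL informative samples
  sc <- gti_group_part(g$x2, g$k2, b) - gti_group_part(g$x1, g$k1, b)
  undef_b <- !is.na(b) & b <= 0
  sc[undef_b | g$k1 < 1L | g$k2 < 1L] <- NA_real_
  sc <- stats::setNames(sc, g$genes)
  if (any(undef_b))
    attr(sc, "reason") <- stats::setNames(
      ifelse(undef_b, "b<=0: non-positive cut-off, use a positive scale", ""),
      g$genes)
  sc
}

SCORE_METHODS <- c("gti", "copa", "os", "ort", "t")

score_fun <- function(method) {
  switch(method,
         gti = gti_score, copa = copa_score, os = os_score,
         ort = ort_score, t = t_statistic,
         stop("unknown method: ", method, call. = FALSE))
}

#' Score a matrix with several outlier statistics and rank the genes
#'
#' Applies the requested statistics gene by gene and ranks each column in
#' descending order (rank 1 = strongest outlier evidence). Undefined genes
#' receive `NA` ranks and sort after all defined genes; score ties are
#' broken by gene identifier so output is deterministic.
#'
#' @inheritParams outlier-statistics
#' @param methods subset of `c("gti", "copa", "os", "ort", "t")`.
#' @param copa_r COPA percentile, one of 75/90/95.
#' @return data.frame of class `ScoreTable` with columns `gene`,
#'   `score_<method>` and `rank_<method>` per method, and `flags` listing
#'   the methods undefined for that gene. Attributes `copa_r`,
#'   `quantile_type` (always 7) and `methods` echo the configuration.
#' @examples
#' x <- expression_matrix(matrix(rnorm(50), 5, 10))
#' g <- group_assignment(rep(c(1, 2), each = 5),
#'                       sample_ids = colnames(x))
#' score_all(x, g, methods = c("gti", "t"))
#' @export
score_all <- function(x, groups, methods = SCORE_METHODS, copa_r = 90) {
  methods <- unique(methods)
  if (length(methods) == 0L)
    stop("no methods requested", call. = FALSE)
  bad <- setdiff(methods, SCORE_METHODS)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x <- as_expression_matrix(x)
  genes <- rownames(x)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  flags <- rep("", length(genes))
  for (m in methods) {
    sc <- if (m == "copa") copa_score(x, groups, r = copa_r)
          else score_fun(m)(x, groups)
    sc <- as.numeric(sc)
    out[[paste0("score_", m)]] <- sc
    out[[paste0("rank_", m)]] <- descending_rank(sc, genes)
    undef <- is.na(sc)
    flags[undef] <- ifelse(flags[undef] == "", m,
                           paste(flags[undef], m, sep = ","))
  }
  out$flags <- flags
  attr(out, "copa_r") <- copa_r
  attr(out, "quantile_type") <- 7L
  attr(out, "methods") <- methods
  class(out) <- c("ScoreTable", class(out))
  out
}

# descending ranks over defined scores, ties broken by gene id; NA -> NA
descending_rank <- function(score, gene) {
  r <- rep(NA_integer_, length(score))
  def <- which(!is.na(score))
  if (length(def))
    r[def[order(-score[def], gene[def])]] <- seq_along(def)
  r
}
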
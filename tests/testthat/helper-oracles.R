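# Independent per-gene oracles: literal, loop-based transcriptions of the
# five statistics using base-R primitives. Deliberately naive; they exist
# to cross-check the vectorized implementations, never to share code with
# them.

oracle_q <- function(v, p) stats::quantile(v, p, names = FALSE, type = 7)

oracle_cutoff <- function(v) {
  v <- v[!is.na(v)]
  oracle_q(v, 0.75) + (oracle_q(v, 0.75) - oracle_q(v, 0.25))
}

oracle_t <- function(v1, v2) {
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  n1 <- length(v1); n2 <- length(v2)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  s <- sqrt((sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)) /
              (n1 + n2 - 2))
  if (s == 0) return(NA_real_)
  (mean(v2) - mean(v1)) / (s * sqrt(1 / n1 + 1 / n2))
}

oracle_copa <- function(v1, v2, r = 90) {
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 1 || length(v2) < 1) return(NA_real_)
  v <- c(v1, v2)
  med <- stats::median(v)
  madv <- stats::mad(v, constant = 1.4826)
  if (madv == 0) return(NA_real_)
  oracle_q((v2 - med) / madv, r / 100)
}

oracle_os <- function(v1, v2) {
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 1 || length(v2) < 1) return(NA_real_)
  v <- c(v1, v2)
  med <- stats::median(v)
  madv <- stats::mad(v, constant = 1.4826)
  if (madv == 0) return(NA_real_)
  b <- oracle_cutoff(v)
  out <- v2[v2 > b]
  if (length(out) == 0) return(0)
  sum((out - med) / madv)
}

oracle_ort <- function(v1, v2) {
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 2 || length(v2) < 1) return(NA_real_)
  med1 <- stats::median(v1)
  med2 <- stats::median(v2)
  madstar <- 1.4826 * stats::median(c(abs(v1 - med1), abs(v2 - med2)))
  if (madstar == 0) return(NA_real_)
  b1 <- oracle_cutoff(v1)
  out <- v2[v2 > b1]
  if (length(out) == 0) return(0)
  sum(out - med1) / madstar
}

oracle_gti_part <- function(v, b) {
  a <- v[v > b]
  if (length(a) == 0) return(0)
  100 * (length(a) / length(v)) * (mean(a) - b) / b
}

oracle_gti <- function(v1, v2) {
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) < 1 || length(v2) < 1) return(NA_real_)
  b <- oracle_cutoff(c(v1, v2))
  if (b <= 0) return(NA_real_)
  oracle_gti_part(v2, b) - oracle_gti_part(v1, b)
}

oracle_score <- function(method, v1, v2, r = 90) {
  switch(method,
         t = oracle_t(v1, v2), copa = oracle_copa(v1, v2, r),
         os = oracle_os(v1, v2), ort = oracle_ort(v1, v2),
         gti = oracle_gti(v1, v2))
}

# Build a two-group ExpressionMatrix from per-group matrices (genes x
# samples); normals first, as everywhere in this package.
make_xg <- function(x1, x2, gene_ids = NULL) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  n1 <- ncol(x1); n2 <- ncol(x2)
  ids <- c(paste0("N", seq_len(n1)), paste0("C", seq_len(n2)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(x1)))
  x <- expression_matrix(cbind(x1, x2), gene_ids = gene_ids,
                         sample_ids = ids)
  g <- group_assignment(rep(c(1L, 2L), c(n1, n2)), sample_ids = ids)
  list(x = x, groups = g, n1 = n1, n2 = n2)
}

# One random small test matrix (optionally with missing cells); used by
# the property and oracle-equivalence suites.
random_fixture <- function(n_genes = sample(2:10, 1),
                           n1 = sample(2:8, 1), n2 = sample(2:8, 1),
                           shift = 5, missing_frac = 0) {
  x1 <- matrix(stats::rnorm(n_genes * n1, mean = shift), n_genes, n1)
  x2 <- matrix(stats::rnorm(n_genes * n2, mean = shift), n_genes, n2)
  f <- make_xg(x1, x2)
  if (missing_frac > 0) {
    x <- unclass(f$x)
    # knock out cells but keep >= 2 informative per group per gene
    for (j in seq_len(n_genes)) {
      drop1 <- which(stats::runif(n1) < missing_frac)
      drop2 <- which(stats::runif(n2) < missing_frac)
      drop1 <- head(drop1, n1 - 2)
      drop2 <- head(drop2, n2 - 2)
      x[j, drop1] <- NA
      x[j, n1 + drop2] <- NA
    }
    f$x <- expression_matrix(x)
  }
  f
}

expect_oracle_equal <- function(f, methods = c("gti", "copa", "os", "ort",
                                               "t"), tol = 1e-10) {
  lab <- unname(f$groups$labels)
  for (m in methods) {
    got <- switch(m, gti = gti_score(f$x, f$groups),
                  copa = copa_score(f$x, f$groups, 90),
                  os = os_score(f$x, f$groups),
                  ort = ort_score(f$x, f$groups),
                  t = t_statistic(f$x, f$groups))
    want <- vapply(seq_len(nrow(f$x)), function(j)
      oracle_score(m, f$x[j, lab == 1L], f$x[j, lab == 2L]), 0)
    expect_equal(as.numeric(got), want, tolerance = tol,
                 label = paste0(m, " vectorized"),
                 expected.label = paste0(m, " oracle"))
  }
}
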
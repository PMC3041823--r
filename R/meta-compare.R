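#' Overlap of the top-N gene lists of several methods
#'
#' Takes the top `n_top` genes per method (by descending score, i.e. ranks
#' 1..n_top of the [score_all()] table) and decomposes their union into the
#' full intersection lattice — the Venn-diagram regions. For three methods
#' that is 7 regions; the region counts always sum to the size of the
#' union, and the per-method "unique" lists are the singleton regions.
#'
#' @param score_table a [score_all()] result.
#' @param methods methods to compare (must be columns of the table).
#' @param n_top list length per method (default 100).
#' @return list of class `OverlapReport`: `methods`, `n_top`, `top`
#'   (per-method top gene lists), `regions` (named counts, names like
#'   `"gti&copa"` for the exclusive region in both gti and copa top lists
#'   but no other), `region_genes` (the gene lists behind the counts) and
#'   `unique` (per-method genes found by that method only).
#' @export
top_n_overlap <- function(score_table, methods = c("gti", "copa", "os"),
                          n_top = 100L) {
  stopifnot(inherits(score_table, "ScoreTable") ||
              is.data.frame(score_table))
  n_top <- as.integer(n_top)
  top <- lapply(methods, function(m) {
    rcol <- paste0("rank_", m)
    if (!rcol %in% names(score_table))
      stop("method not present in score table: ", m, call. = FALSE)
    r <- score_table[[rcol]]
    if (sum(!is.na(r)) < n_top)
      stop("fewer than ", n_top, " defined genes for method ", m,
           call. = FALSE)
    score_table$gene[!is.na(r) & r <= n_top]
  })
  names(top) <- methods
  universe <- sort(unique(unlist(top)))
  member <- vapply(top, function(g) universe %in% g,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(universe))
  # every non-empty subset of methods = one exclusive Venn region
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(methods)))[-1L, ,
                                                                     drop = FALSE]
  region_genes <- apply(subsets, 1L, function(s) {
    universe[apply(member, 1L, function(row) all(row == s))]
  }, simplify = FALSE)
  names(region_genes) <- apply(subsets, 1L, function(s)
    paste(methods[as.logical(s)], collapse = "&"))
  structure(list(methods = methods, n_top = n_top, top = top,
                 regions = vapply(region_genes, length, 0L),
                 region_genes = region_genes,
                 unique = stats::setNames(region_genes[methods], methods)),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("OverlapReport: top", x$n_top, "genes of",
      paste(x$methods, collapse = ", "), "\n")
  for (r in names(x$regions))
    cat(sprintf("  %-30s %d\n", r, x$regions[[r]]))
  invisible(x)
}

#' Spearman correlation of method scores with per-gene sample counts
#'
#' In integrated multi-study matrices the number of informative samples
#' varies per gene; a statistic whose magnitude grows with the sample
#' count (as sums of exceedances do) will rank well-measured genes above
#' genuinely outlying ones. This diagnostic computes, per method, the
#' Spearman rank correlation (average ranks for ties) between the scores
#' and a per-gene sample count; values near zero mean the score does not
#' track how often a gene was measured.
#'
#' @param score_table a [score_all()] result.
#' @param counts per-gene sample counts, aligned with (or named by) the
#'   table's genes; see [informative_counts()].
#' @param methods methods to report; default every `score_` column present.
#' @return named numeric vector of Spearman rho per method, in `[-1, 1]`.
#' @export
score_vs_samplecount_correlation <- function(score_table, counts,
                                             methods = NULL) {
  stopifnot(is.data.frame(score_table))
  if (is.null(methods))
    methods <- sub("^score_", "",
                   grep("^score_", names(score_table), value = TRUE))
  if (!is.null(names(counts)))
    counts <- counts[score_table$gene]
  if (length(counts) != nrow(score_table))
    stop("counts do not align with the score table genes", call. = FALSE)
  vapply(stats::setNames(methods, methods), function(m) {
    s <- score_table[[paste0("score_", m)]]
    ok <- !is.na(s) & !is.na(counts)
    if (sum(ok) < 3L)
      stop("need >= 3 genes with defined score and count for ", m,
           call. = FALSE)
    if (length(unique(counts[ok])) == 1L) {
      warning("constant sample-count vector: correlation undefined",
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(rank(s[ok]), rank(counts[ok]))  # Spearman via average ranks
  }, 0)
}

#' Per-gene informative sample counts
#'
#' @inheritParams outlier-statistics
#' @param which count `"all"` informative samples, or only the `"normal"`
#'   (group 1) or `"disease"` (group 2) ones.
#' @return named integer vector, one count per gene.
#' @export
informative_counts <- function(x, groups,
                               which = c("all", "normal", "disease")) {
  which <- match.arg(which)
  g <- split_groups(x, groups)
  n <- switch(which, all = g$k1 + g$k2, normal = g$k1, disease = g$k2)
  stats::setNames(as.integer(n), g$genes)
}
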
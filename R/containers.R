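#' Construct an expression matrix
#'
#' Wraps a numeric genes x samples matrix of log-scale expression values.
#' Missing cells (e.g. genes absent from some platforms of an integrated
#' multi-study dataset) are encoded as `NA`; all statistics in this package
#' are computed per gene over the non-missing ("informative") samples only.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Non-`NA`
#'   entries must be finite.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return a numeric matrix of class `ExpressionMatrix` with row and column
#'   names set.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4),
#'                        gene_ids = paste0("g", 1:3),
#'                        sample_ids = paste0("s", 1:4))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids))
    gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match row count", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.na(values) & !is.finite(values)))
    stop("non-missing expression values must be finite", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' Construct a two-group sample assignment
#'
#' Samples belong to group 1 (normal / reference) or group 2
#' (cancer / disease). Tokens `"normal"`, `"control"`, `"reference"` and
#' `"1"` map to group 1; `"cancer"`, `"disease"`, `"tumor"`, `"tumour"` and
#' `"2"` map to group 2.
#'
#' @param labels vector of group labels, one per sample, optionally named by
#'   sample identifier.
#' @param sample_ids sample identifiers; defaults to `names(labels)`.
#' @return object of class `GroupAssignment`: a list with integer `labels`
#'   (named, values in 1:2), `n1` and `n2`.
#' @examples
#' g <- group_assignment(c(s1 = "normal", s2 = "cancer", s3 = "cancer"))
#' g$n2
#' @export
group_assignment <- function(labels, sample_ids = names(labels)) {
  tok <- tolower(trimws(as.character(labels)))
  map <- c("1" = 1L, "normal" = 1L, "control" = 1L, "reference" = 1L,
           "2" = 2L, "cancer" = 2L, "disease" = 2L, "tumor" = 2L,
           "tumour" = 2L)
  bad <- !(tok %in% names(map))
  if (any(bad))
    stop("unrecognized group label(s): ",
         paste(unique(tok[bad]), collapse = ", "), call. = FALSE)
  lab <- unname(map[tok])
  if (is.null(sample_ids))
    sample_ids <- paste0("sample", seq_along(lab))
  names(lab) <- as.character(sample_ids)
  n1 <- sum(lab == 1L)
  n2 <- sum(lab == 2L)
  if (n1 < 1L || n2 < 1L)
    stop("both groups must contain at least one sample", call. = FALSE)
  structure(list(labels = lab, n1 = n1, n2 = n2),
            class = "GroupAssignment")
}

#' @export
print.GroupAssignment <- function(x, ...) {
  cat("GroupAssignment:", x$n1, "normal (group 1),",
      x$n2, "disease (group 2) samples\n")
  invisible(x)
}

# Align a GroupAssignment with the columns of an expression matrix and
# return the integer label vector in column order.
align_groups <- function(x, groups) {
  if (!inherits(groups, "GroupAssignment"))
    stop("'groups' must be a GroupAssignment", call. = FALSE)
  lab <- groups$labels
  ids <- colnames(x)
  if (!is.null(ids) && !is.null(names(lab)) &&
      all(ids %in% names(lab))) {
    lab <- lab[ids]
  } else if (length(lab) != ncol(x)) {
    stop("group assignment does not cover the matrix samples",
         call. = FALSE)
  }
  if (length(lab) != ncol(x))
    stop("group assignment does not cover the matrix samples",
         call. = FALSE)
  unname(lab)
}

as_expression_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) return(x)
  expression_matrix(as.matrix(x))
}
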
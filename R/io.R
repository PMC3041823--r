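#' Read a tab-separated expression matrix
#'
#' Expected layout: a header row of sample identifiers, then one row per
#' gene with the gene identifier in the first column. Empty fields or
#' `NA` mark missing cells. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("expression file needs a header row and at least one gene row",
         call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  sample_ids <- header[-1L]
  ncol_expect <- length(header)
  body <- cells[-1L]
  nfield <- lengths(body)
  if (any(nfield != ncol_expect))
    stop("ragged row(s) at line ",
         paste(which(nfield != ncol_expect) + 1L, collapse = ", "),
         call. = FALSE)
  gene_ids <- vapply(body, `[[`, "", 1L)
  raw <- t(vapply(body, function(r) r[-1L], character(ncol_expect - 1L)))
  raw[raw == "" | raw == "NA"] <- NA
  suppressWarnings(vals <- matrix(as.numeric(raw), nrow = length(gene_ids)))
  bad <- !is.na(raw) & is.na(vals)
  if (any(bad))
    stop("non-numeric cell(s), e.g. '", raw[which(bad)[1L]], "'",
         call. = FALSE)
  m <- expression_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids)
  if (any(vals > 50, na.rm = TRUE))
    warning("values above 50 detected: input looks like raw intensities, ",
            "but this tool expects log-scale data", call. = FALSE)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param x matrix or `ExpressionMatrix`; `NA` cells are written as `NA`.
#' @param path output path.
#' @param header optional character vector of comment lines (written with a
#'   leading `#`).
#' @export
write_expression <- function(x, path, header = NULL) {
  x <- as_expression_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- apply(format(unclass(x), trim = TRUE, digits = 15), 1L,
                paste, collapse = "\t")
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read a sample-to-group assignment file
#'
#' Two tab-separated columns: sample identifier and group label (`1`/`2`,
#' or tokens such as `normal`/`cancer`). A header line is detected and
#' skipped; `#` comment lines are ignored. When `sample_ids` is given,
#' every matrix sample must appear exactly once.
#'
#' @param path file path.
#' @param sample_ids optional sample identifiers to validate against (the
#'   matrix columns).
#' @return a [group_assignment()], ordered like `sample_ids` when given.
#' @export
read_groups <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) != 2L))
    stop("group file must have exactly two tab-separated columns",
         call. = FALSE)
  ids <- vapply(cells, `[[`, "", 1L)
  lab <- vapply(cells, `[[`, "", 2L)
  if (length(ids) && tolower(ids[1L]) %in% c("sample", "sample_id", "id")) {
    ids <- ids[-1L]; lab <- lab[-1L]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample(s) in group file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing))
      stop("sample(s) missing from group file: ",
           paste(missing, collapse = ", "), call. = FALSE)
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown))
      stop("unknown sample(s) in group file: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    ord <- match(sample_ids, ids)
    ids <- ids[ord]; lab <- lab[ord]
  }
  group_assignment(lab, sample_ids = ids)
}

#' Write a group assignment file
#' @param groups a [group_assignment()].
#' @param path output path.
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "GroupAssignment"))
  writeLines(c("sample\tgroup",
               paste(names(groups$labels), groups$labels, sep = "\t")),
             path)
  invisible(path)
}

#' Write a score table as tab-separated text
#'
#' A `#` comment header records the package version, the quantile
#' convention (type 7 — it materially changes the q75 + IQR cut-off on
#' small sample sets) and the configuration, so results are interpretable
#' without the session that made them.
#'
#' @param score_table a [score_all()] result.
#' @param path output path.
#' @param extra optional named character vector appended to the header
#'   (e.g. seed).
#' @export
write_score_table <- function(score_table, path, extra = NULL) {
  hdr <- c(paste0("gtindex ", as.character(utils::packageVersion("gtindex"))),
           "quantile_convention=type7",
           paste0("copa_r=", attr(score_table, "copa_r")),
           paste0("methods=", paste(attr(score_table, "methods"),
                                    collapse = ",")))
  if (length(extra))
    hdr <- c(hdr, paste0(names(extra), "=", unname(extra)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.table(score_table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path file path.
#' @return data.frame of class `ScoreTable`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$gene <- as.character(df$gene)
  class(df) <- c("ScoreTable", class(df))
  df
}

#' Generate a deterministic on-disk test fixture
#'
#' Writes `matrix.tsv`, `groups.tsv` and a `truth.tsv` sidecar into `dir`.
#' Three kinds:
#' * `"null"` — i.i.d. N(0, 1), no signal, no missing cells;
#' * `"spiked"` — the single-study benchmark world: a constant `m` added to
#'   the first `k` disease samples of gene 1 (named in the sidecar);
#' * `"multistudy"` — null data where each gene keeps only `count_j`
#'   informative samples, `count_j` drawn uniformly from
#'   `[count_min, count_max]` (default 20..400), emulating integrated
#'   multi-platform data; at least one sample per group is always kept.
#'
#' @param kind `"null"`, `"spiked"` or `"multistudy"`.
#' @param dir output directory (created if needed).
#' @param params named list overriding defaults: `n_genes`, `n1`, `n2`,
#'   and for `"spiked"` `k`, `m`; for `"multistudy"` `count_min`,
#'   `count_max`.
#' @param seed integer seed; identical seed gives byte-identical files.
#' @return invisibly, a list with the paths and the generated objects.
#' @export
make_fixture <- function(kind = c("null", "spiked", "multistudy"),
                         dir, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    null = list(n_genes = 1000L, n1 = 30L, n2 = 30L),
    spiked = list(n_genes = 1000L, n1 = 30L, n2 = 30L, k = 10L, m = 2),
    multistudy = list(n_genes = 2000L, n1 = 200L, n2 = 200L,
                      count_min = 20L, count_max = 400L))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown fixture parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p <- utils::modifyList(defaults, params)
  if (p$n_genes < 2L || p$n1 < 1L || p$n2 < 1L)
    stop("invalid fixture dimensions", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n <- p$n1 + p$n2
  truth <- c(kind = kind, seed = seed,
             n_genes = p$n_genes, n1 = p$n1, n2 = p$n2)
  if (kind == "spiked") {
    if (p$k > p$n2) stop("k must not exceed n2", call. = FALSE)
    cfg <- simulation_config(p$n_genes, p$n1, p$n2, k = p$k, m = p$m,
                             seed = seed)
    sim <- simulate_single_study(cfg)
    x <- sim$x; groups <- sim$groups
    truth <- c(truth, tp_gene = rownames(x)[sim$tp_gene], k = p$k, m = p$m)
  } else {
    x <- matrix(stats::rnorm(p$n_genes * n), p$n_genes, n)
    sample_ids <- c(paste0("N", seq_len(p$n1)), paste0("C", seq_len(p$n2)))
    if (kind == "multistudy") {
      if (p$count_max > n)
        stop("count_max exceeds the total sample count", call. = FALSE)
      counts <- sample(p$count_min:p$count_max, p$n_genes, replace = TRUE)
      for (j in seq_len(p$n_genes)) {
        # keep one sample per group, fill the rest at random
        keep <- c(sample.int(p$n1, 1L),
                  p$n1 + sample.int(p$n2, 1L))
        pool <- setdiff(seq_len(n), keep)
        keep <- c(keep, sample(pool, counts[j] - 2L))
        x[j, setdiff(seq_len(n), keep)] <- NA
      }
      truth <- c(truth, count_min = p$count_min, count_max = p$count_max)
    }
    x <- expression_matrix(x, gene_ids = paste0("g", seq_len(p$n_genes)),
                           sample_ids = sample_ids)
    groups <- group_assignment(rep(c(1L, 2L), c(p$n1, p$n2)),
                               sample_ids = sample_ids)
  }
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                groups = file.path(dir, "groups.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_expression(x, paths$matrix,
                   header = paste0("fixture kind=", kind, " seed=", seed))
  write_groups(groups, paths$groups)
  writeLines(c("key\tvalue", paste(names(truth), truth, sep = "\t")),
             paths$truth)
  invisible(list(paths = paths, x = x, groups = groups, truth = truth))
}

RUN_CONFIG_KEYS <- c("methods", "copa_r", "n_perm", "seed", "pooling",
                     "tail", "n_genes", "n1", "n2", "k", "m", "n_reps",
                     "n_top", "matrix", "groups", "out", "verbose")

#' Read / write a flat key=value run configuration
#'
#' One `key=value` pair per line; `#` comments allowed. Unknown keys are
#' rejected so typos fail loudly instead of silently using defaults.
#'
#' @param path file path.
#' @return named character vector (keys as names).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0))
    stop("malformed config line (expected key=value): ",
         lines[which(eq < 0)[1L]], call. = FALSE)
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substring(lines, eq + 1L))
  unknown <- setdiff(keys, RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicate config key(s)", call. = FALSE)
  stats::setNames(vals, keys)
}

#' @rdname read_run_config
#' @param config named character vector of settings.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  writeLines(paste0(names(config), "=", unname(config)), path)
  invisible(path)
}
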
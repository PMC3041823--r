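#' Randomly relabel samples, preserving group sizes
#'
#' Draws a uniformly random permutation of the group labels; the numbers of
#' normal and disease samples are unchanged. Uses the current RNG state, so
#' callers control reproducibility with `set.seed()`.
#'
#' @param groups a [group_assignment()].
#' @return a `GroupAssignment` with permuted labels over the same samples.
#' @export
permute_labels <- function(groups) {
  if (!inherits(groups, "GroupAssignment"))
    stop("'groups' must be a GroupAssignment", call. = FALSE)
  lab <- groups$labels
  new <- sample(unname(lab))
  names(new) <- names(lab)
  structure(list(labels = new, n1 = groups$n1, n2 = groups$n2),
            class = "GroupAssignment")
}

#' Permutation p-values for an outlier statistic
#'
#' Estimates per-gene empirical p-values by recomputing the chosen statistic
#' under random relabellings of the samples (group sizes preserved). The
#' default is the one-sided upper tail — outlier *over*-expression in the
#' disease group — matching the sign convention of all five statistics;
#' `tail = "two-sided"` compares absolute scores. The add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` keeps p-values strictly
#' positive.
#'
#' With `pooling = "per-gene"` (default) each gene is compared against its
#' own permutation nulls. `pooling = "pooled"` pools null scores across all
#' genes for extra resolution; this assumes genes are exchangeable under the
#' null, which fails for multi-study matrices whose informative-sample
#' counts vary per gene — use per-gene nulls there.
#'
#' @inheritParams outlier-statistics
#' @param method one of `"gti"`, `"copa"`, `"os"`, `"ort"`, `"t"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; identical seed and inputs give identical
#'   output.
#' @param pooling `"per-gene"` or `"pooled"`.
#' @param tail `"upper"` or `"two-sided"`.
#' @param copa_r COPA percentile when `method = "copa"`.
#' @return list of class `PermutationResult`: `method`, `n_perm`, `seed`,
#'   `pooling`, `tail`, named vectors `observed` and `p`.
#' @export
permutation_pvalues <- function(x, groups, method = "gti", n_perm = 1000L,
                                seed = 1L, pooling = c("per-gene", "pooled"),
                                tail = c("upper", "two-sided"),
                                copa_r = 90) {
  pooling <- match.arg(pooling)
  tail <- match.arg(tail)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L)
    stop("n_perm must be a positive integer", call. = FALSE)
  x <- as_expression_matrix(x)
  fn <- if (method == "copa")
    function(m, g) copa_score(m, g, r = copa_r)
  else score_fun(method)

  obs <- as.numeric(fn(x, groups))
  names(obs) <- rownames(x)
  stat <- if (tail == "two-sided") abs else identity

  set.seed(seed)
  ge_count <- numeric(length(obs))     # #{null >= obs} per gene
  null_n <- numeric(length(obs))       # defined null draws per gene
  pooled_null <- if (pooling == "pooled") vector("list", n_perm) else NULL
  for (b in seq_len(n_perm)) {
    nl <- as.numeric(fn(x, permute_labels(groups)))
    ok <- !is.na(nl)
    if (pooling == "per-gene") {
      ge_count <- ge_count + (ok & stat(nl) >= stat(obs))
      null_n <- null_n + ok
    } else {
      pooled_null[[b]] <- stat(nl[ok])
    }
  }
  if (pooling == "per-gene") {
    p <- (1 + ge_count) / (1 + null_n)
    p[null_n == 0L] <- NA_real_
  } else {
    pooled <- sort(unlist(pooled_null))
    n_null <- length(pooled)
    if (n_null == 0L) {
      p <- rep(NA_real_, length(obs))
    } else {
      # #{pooled >= obs} via binary search on the sorted null
      below <- findInterval(stat(obs), pooled, left.open = TRUE)
      p <- (1 + (n_null - below)) / (1 + n_null)
    }
  }
  p[is.na(obs)] <- NA_real_
  if (all(is.na(p)))
    warning("all permutation p-values undefined (degenerate statistic?)",
            call. = FALSE)
  structure(list(method = method, n_perm = n_perm, seed = seed,
                 pooling = pooling, tail = tail,
                 observed = obs, p = stats::setNames(p, names(obs))),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat("PermutationResult:", x$method, "statistic,", x$n_perm,
      "permutations (seed", paste0(x$seed, ","), x$pooling, "null,",
      x$tail, "tail)\n")
  def <- sum(!is.na(x$p))
  cat(" ", def, "genes with defined p-values;",
      sum(x$p <= 0.05, na.rm = TRUE), "at p <= 0.05\n")
  invisible(x)
}
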
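#' Log2-transform an expression matrix
#'
#' Replaces every value by `log2(value + pseudocount)`. FPKM-like values
#' are strongly right-skewed; all two-group tests and correlations in this
#' package operate on this stabilized scale by default.
#'
#' @param x an [expression_matrix()].
#' @param pseudocount positive offset (default 1, so zero expression maps
#'   to zero).
#' @return an `ExpressionMatrix` on the log2 scale. Note the log2 values
#'   bypass the nonnegativity check (they may be negative for
#'   `pseudocount < 1`); the object is marked with attribute
#'   `log2 = TRUE`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("`pseudocount` must be a positive number", call. = FALSE)
  out <- x
  out$values <- log2(x$values + pseudocount)
  attr(out, "log2") <- TRUE
  out
}

is_log2 <- function(x) isTRUE(attr(x, "log2"))

#' Per-gene two-group differential expression test
#'
#' Computes, for every gene, the two group means, the log2 fold change
#' (`mean_b - mean_a`, i.e. second group relative to the first — the
#' direction convention used throughout the package) and a two-sided
#' p-value from either Welch's t-test (default; expects log2-transformed
#' input, see [log_transform()]) or the Mann-Whitney U test (exact when
#' sample sizes permit and there are no ties, normal approximation with tie
#' correction otherwise).
#'
#' Genes with zero variance in both groups get p = 1 when the means are
#' equal (no evidence of change, notably all-zero genes) and p = 0 when
#' they differ deterministically.
#'
#' @param x an `ExpressionMatrix`.
#' @param group_a,group_b group labels; the comparison is "a vs b" with
#'   direction b relative to a.
#' @param method `"welch_t"` or `"mann_whitney"`.
#' @return data.frame of class `ComparisonResult`: gene, mean_a, mean_b,
#'   log2fc, p (q and call are added by [call_degs()]), with attributes
#'   `group_a`, `group_b`, `method`.
#' @export
compare_groups <- function(x, group_a, group_b,
                           method = c("welch_t", "mann_whitney")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  method <- match.arg(method)
  sa <- group_samples(x, group_a)
  sb <- group_samples(x, group_b)
  if (length(sa) < 2 || length(sb) < 2)
    stop("fewer than 2 samples in a group", call. = FALSE)
  va <- x$values[, sa, drop = FALSE]
  vb <- x$values[, sb, drop = FALSE]
  ma <- rowMeans(va)
  mb <- rowMeans(vb)
  p <- vapply(seq_len(nrow(va)), function(i) {
    a <- va[i, ]; b <- vb[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    if (method == "welch_t")
      stats::t.test(b, a, var.equal = FALSE)$p.value
    else
      suppressWarnings(stats::wilcox.test(b, a, exact = NULL)$p.value)
  }, numeric(1))
  res <- data.frame(gene = rownames(x$values), mean_a = ma, mean_b = mb,
                    log2fc = mb - ma, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "group_a") <- group_a
  attr(res, "group_b") <- group_b
  attr(res, "method") <- method
  class(res) <- c("ComparisonResult", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("p-values must be numeric", call. = FALSE)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Apply the DEG calling criterion to a comparison result
#'
#' Adds BH q-values (computed across all genes of this one comparison) and
#' a directional call: `up` if `p < alpha_p` and `q < alpha_q` and
#' `log2fc > 0`, `down` analogously, `ns` otherwise. Setting `alpha_q = 1`
#' reproduces p-only DEG counting.
#'
#' @param res a `ComparisonResult` from [compare_groups()].
#' @param alpha_p,alpha_q thresholds in (0, 1] (defaults 0.05 and 0.05,
#'   the joint criterion used for the published DEG lists).
#' @return the result with columns `q` and `call` filled.
#' @export
call_degs <- function(res, alpha_p = 0.05, alpha_q = 0.05) {
  stopifnot(inherits(res, "ComparisonResult"), "p" %in% names(res))
  if (alpha_p <= 0 || alpha_p > 1 || alpha_q <= 0 || alpha_q > 1)
    stop("alpha thresholds must lie in (0, 1]", call. = FALSE)
  res$q <- bh_adjust(res$p)
  sig <- res$p < alpha_p & res$q < alpha_q & res$log2fc != 0
  res$call <- ifelse(sig, ifelse(res$log2fc > 0, "up", "down"), "ns")
  res
}

#' Run the three ordered comparisons of the stimulus-deprivation design
#'
#' Log-transforms the input (unless already transformed), tests every
#' ordered pair in `comparisons`, and applies the calling criterion per
#' comparison.
#'
#' @param x an `ExpressionMatrix` (raw or log2 scale).
#' @param comparisons list of ordered group pairs; default
#'   `list(c("C","A20"), c("C","AD"), c("A20","AD"))`.
#' @param method,alpha_p,alpha_q see [compare_groups()] and [call_degs()].
#' @param pseudocount passed to [log_transform()] when needed.
#' @return named list of called `ComparisonResult` frames, names like
#'   `"C_vs_A20"`.
#' @export
run_comparisons <- function(x,
                            comparisons = list(c("C", "A20"), c("C", "AD"),
                                               c("A20", "AD")),
                            method = "welch_t", alpha_p = 0.05,
                            alpha_q = 0.05, pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  lv <- group_levels(x)
  for (cmp in comparisons)
    if (!all(cmp %in% lv))
      stop("comparison refers to unknown group: ",
           paste(cmp, collapse = " vs "), call. = FALSE)
  # rank-based testing is invariant to the monotone transform, but means and
  # log2fc are reported on the log2 scale for either method
  xl <- if (is_log2(x)) x else log_transform(x, pseudocount)
  out <- lapply(comparisons, function(cmp) {
    call_degs(compare_groups(xl, cmp[1], cmp[2], method = method),
              alpha_p = alpha_p, alpha_q = alpha_q)
  })
  names(out) <- vapply(comparisons, function(cmp) paste0(cmp[1], "_vs_", cmp[2]),
                       character(1))
  out
}

#' Collapse the three comparison results into a call table
#'
#' @param results named list of exactly three called `ComparisonResult`
#'   frames in design order (c1, c2, c3), as returned by
#'   [run_comparisons()].
#' @param systems optional named character vector gene -> system.
#' @return a [call_table()].
#' @export
calls_from_results <- function(results, systems = NULL) {
  stopifnot(length(results) == 3)
  genes <- results[[1]]$gene
  for (r in results)
    if (!identical(r$gene, genes))
      stop("comparison results cover different gene sets", call. = FALSE)
  sys <- if (is.null(systems)) rep(NA_character_, length(genes))
         else unname(systems[genes])
  call_table(data.frame(gene = genes, system = sys,
                        call_c1 = results[[1]]$call,
                        call_c2 = results[[2]]$call,
                        call_c3 = results[[3]]$call,
                        stringsAsFactors = FALSE))
}

#' Write one comparison result as TSV
#' @param res a called `ComparisonResult`.
#' @param path output path.
#' @export
write_comparison_result <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(res)
}
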
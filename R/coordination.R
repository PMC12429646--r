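#' Per-group Pearson correlation over a gene set
#'
#' Computes the pairwise Pearson correlation matrix for the given genes
#' over the samples of one group, on the log2(x + pseudocount) scale by
#' default (small-n Pearson on raw, skewed FPKM is dominated by outliers;
#' set `log_scale = FALSE` for the raw-scale variant). Genes with zero
#' variance within the group have undefined correlations; they are recorded
#' in `$degenerate` and excluded from pair counting.
#'
#' Correlation significance at these small sample sizes (the design has
#' n = 6 per group) is assessed downstream by [significant_pairs()].
#'
#' @param x an [expression_matrix()].
#' @param genes gene symbols to correlate (matched case-insensitively;
#'   unknown symbols are dropped with a warning).
#' @param group group label; must have at least 4 samples.
#' @param log_scale correlate log2-transformed values (default TRUE; a
#'   matrix already produced by [log_transform()] is never re-transformed).
#' @param pseudocount offset for the log transform.
#' @return object of class `CoordinationSummary`: list with `group`,
#'   `genes`, `r` (correlation matrix), `n` (samples used), `degenerate`
#'   (zero-variance genes); [significant_pairs()] fills `pairs`,
#'   `per_gene_count`, `total_count`.
#' @export
correlation_matrix <- function(x, genes, group, log_scale = TRUE,
                               pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  smp <- group_samples(x, group)
  if (length(smp) < 4)
    stop("group '", group, "' has fewer than 4 samples; correlation ",
         "significance is not assessable", call. = FALSE)
  resolved <- match_genes(genes, rownames(x$values))
  if (anyNA(resolved)) {
    warning("dropping genes absent from the matrix: ",
            paste(genes[is.na(resolved)], collapse = ", "), call. = FALSE)
    resolved <- resolved[!is.na(resolved)]
  }
  resolved <- unique(resolved)
  if (length(resolved) < 2)
    stop("need at least 2 resolvable genes", call. = FALSE)
  v <- x$values[resolved, smp, drop = FALSE]
  if (log_scale && !is_log2(x)) v <- log2(v + pseudocount)
  sds <- apply(v, 1, stats::sd)
  degenerate <- rownames(v)[sds == 0]
  r <- suppressWarnings(stats::cor(t(v), method = "pearson"))
  diag(r) <- 1
  structure(list(group = group, genes = rownames(v), r = r,
                 n = length(smp), degenerate = degenerate,
                 pairs = NULL, per_gene_count = NULL, total_count = NULL,
                 alpha = NULL, sign_filter = NULL),
            class = "CoordinationSummary")
}

#' Wrap a pre-computed correlation matrix as a coordination summary
#'
#' For published correlation matrices where the underlying expression is
#' unavailable: supply the symmetric r matrix and the per-group sample
#' size, then count significant pairs with [significant_pairs()].
#'
#' @param r symmetric correlation matrix with unit diagonal and gene
#'   dimnames.
#' @param n number of samples the correlations were computed from.
#' @param group group label (annotation only).
#' @return a `CoordinationSummary` with `r` filled.
#' @export
coordination_from_matrix <- function(r, n, group = "unknown") {
  stopifnot(is.matrix(r), nrow(r) == ncol(r), nrow(r) >= 2, n >= 4)
  if (is.null(rownames(r)))
    stop("matrix must carry gene dimnames", call. = FALSE)
  if (max(abs(r - t(r))) > 1e-8 || any(abs(r) > 1 + 1e-8))
    stop("not a valid correlation matrix", call. = FALSE)
  structure(list(group = group, genes = rownames(r), r = r, n = as.integer(n),
                 degenerate = character(),
                 pairs = NULL, per_gene_count = NULL, total_count = NULL,
                 alpha = NULL, sign_filter = NULL),
            class = "CoordinationSummary")
}

# two-sided p for Pearson r at sample size n via the t-transform, df = n - 2
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  p
}

#' Detect significantly correlated gene pairs
#'
#' A pair is significant when the two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) with df = n - 2 is below `alpha`, and
#' the sign of r passes `sign_filter`. No multiple-testing correction is
#' applied by default (pair counts at n = 6 are only attainable
#' uncorrected); `adjust = "BH"` applies Benjamini-Hochberg across all
#' counted pairs. Zero-variance genes never contribute pairs.
#'
#' @param summary a `CoordinationSummary` with `r` filled.
#' @param alpha significance level in (0, 1).
#' @param sign_filter count `"positive"`, `"negative"` or `"both"` (default)
#'   correlations.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return the summary with `pairs` (data.frame gene_i, gene_j, r, p,
#'   significant), `per_gene_count` and `total_count` filled.
#' @export
significant_pairs <- function(summary, alpha = 0.05,
                              sign_filter = c("both", "positive", "negative"),
                              adjust = c("none", "BH")) {
  stopifnot(inherits(summary, "CoordinationSummary"))
  sign_filter <- match.arg(sign_filter)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  genes <- summary$genes
  ok <- !(genes %in% summary$degenerate)
  idx <- which(upper.tri(summary$r), arr.ind = TRUE)
  keep <- ok[idx[, 1]] & ok[idx[, 2]]
  idx <- idx[keep, , drop = FALSE]
  r <- summary$r[idx]
  p <- cor_pvalue(r, summary$n)
  if (adjust == "BH") p <- bh_adjust(p)
  pass_sign <- switch(sign_filter,
                      both = rep(TRUE, length(r)),
                      positive = r > 0,
                      negative = r < 0)
  sig <- p < alpha & pass_sign
  pairs <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                      r = r, p = p, significant = sig,
                      stringsAsFactors = FALSE, row.names = NULL)
  cnt <- setNames(integer(length(genes)), genes)
  if (any(sig)) {
    tb <- table(c(pairs$gene_i[sig], pairs$gene_j[sig]))
    cnt[names(tb)] <- as.integer(tb)
  }
  summary$pairs <- pairs
  summary$per_gene_count <- cnt
  summary$total_count <- sum(sig)
  summary$alpha <- alpha
  summary$sign_filter <- sign_filter
  summary
}

#' @export
print.CoordinationSummary <- function(x, ...) {
  cat(sprintf("CoordinationSummary [%s]: %d genes, n = %d samples\n",
              x$group, length(x$genes), x$n))
  if (!is.null(x$total_count))
    cat(sprintf("significant pairs (alpha = %g, %s): %d\n",
                x$alpha, x$sign_filter, x$total_count))
  invisible(x)
}

#' Compare transcriptional coordination between groups
#'
#' Runs [correlation_matrix()] + [significant_pairs()] for the identical
#' gene list in every requested group, and tabulates per-gene
#' significant-partner counts side by side. The per-group total pair count
#' is the group's transcriptional-coordination measure.
#'
#' @inheritParams correlation_matrix
#' @inheritParams significant_pairs
#' @param groups group labels to compare.
#' @return list with `summaries` (named list of `CoordinationSummary`),
#'   `totals` (named integer vector), and `delta` (data.frame of per-gene
#'   counts per group).
#' @export
compare_coordination <- function(x, genes, groups, alpha = 0.05,
                                 sign_filter = "both", log_scale = TRUE,
                                 pseudocount = 1, adjust = "none") {
  resolved <- match_genes(genes, rownames(x$values))
  resolved <- unique(resolved[!is.na(resolved)])
  if (length(resolved) < 2) {
    # fewer than two genes: no pairs exist in any group
    summaries <- lapply(groups, function(g) {
      structure(list(group = g, genes = resolved,
                     r = diag(1, length(resolved)),
                     n = length(group_samples(x, g)),
                     degenerate = character(),
                     pairs = data.frame(gene_i = character(),
                                        gene_j = character(), r = numeric(),
                                        p = numeric(), significant = logical()),
                     per_gene_count = setNames(integer(length(resolved)),
                                               resolved),
                     total_count = 0L, alpha = alpha,
                     sign_filter = sign_filter),
                class = "CoordinationSummary")
    })
    names(summaries) <- groups
    totals <- setNames(rep(0L, length(groups)), groups)
    delta <- data.frame(gene = resolved, stringsAsFactors = FALSE)
    return(list(summaries = summaries, totals = totals, delta = delta))
  }
  summaries <- lapply(groups, function(g) {
    significant_pairs(
      correlation_matrix(x, genes, g, log_scale = log_scale,
                         pseudocount = pseudocount),
      alpha = alpha, sign_filter = sign_filter, adjust = adjust)
  })
  names(summaries) <- groups
  totals <- vapply(summaries, function(s) s$total_count, integer(1))
  counts <- do.call(cbind, lapply(summaries, function(s) s$per_gene_count))
  delta <- data.frame(gene = rownames(counts), counts,
                      stringsAsFactors = FALSE, row.names = NULL,
                      check.names = FALSE)
  list(summaries = summaries, totals = totals, delta = delta)
}

#' Write a coordination summary's matrix and pair list as TSV
#'
#' @param summary a `CoordinationSummary` after [significant_pairs()].
#' @param matrix_path,pairs_path output paths (either may be `NULL` to
#'   skip).
#' @export
write_coordination <- function(summary, matrix_path = NULL, pairs_path = NULL) {
  if (!is.null(matrix_path)) {
    df <- data.frame(gene = rownames(summary$r), summary$r,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(pairs_path) && !is.null(summary$pairs))
    utils::write.table(summary$pairs, pairs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(summary)
}
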
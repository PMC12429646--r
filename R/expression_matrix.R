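#' Construct a validated expression matrix
#'
#' An `ExpressionMatrix` bundles a genes-by-samples matrix of nonnegative,
#' FPKM-like expression values with a sample-to-group assignment. It is the
#' substrate of every statistical stage: differential expression testing,
#' trajectory classification of the resulting calls, and per-group
#' correlation (coordination) analysis.
#'
#' Gene symbols must be unique after case normalization (mouse symbol
#' capitalization varies between sources, so `Th` and `th` are treated as the
#' same gene and rejected as duplicates). Every sample must be assigned to
#' exactly one group and every group must contain at least two samples;
#' correlation analysis additionally requires four (enforced in
#' [correlation_matrix()]).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). All values must be finite
#'   and `>= 0`.
#' @param groups named character vector mapping each sample id (names) to a
#'   group label, e.g. `c(s1 = "C", s2 = "A20", ...)`. Must cover exactly the
#'   columns of `values`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `groups` (named character vector, aligned to
#'   the columns of `values`).
#' @examples
#' vals <- matrix(abs(rnorm(12, 5)), nrow = 3,
#'                dimnames = list(c("Th", "Drd1", "Penk"), paste0("s", 1:4)))
#' grp <- setNames(rep(c("C", "A20"), each = 2), paste0("s", 1:4))
#' em <- expression_matrix(vals, grp)
#' n_genes(em)
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("negative expression value found; FPKM-like input must be >= 0",
         call. = FALSE)
  genes <- rownames(values)
  if (anyDuplicated(tolower(genes)))
    stop("duplicate gene symbol (case-insensitive): ",
         paste(unique(genes[duplicated(tolower(genes))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id", call. = FALSE)

  if (is.factor(groups)) groups <- setNames(as.character(groups), names(groups))
  if (!is.character(groups) || is.null(names(groups)))
    stop("`groups` must be a named character vector (sample -> group)",
         call. = FALSE)
  missing_grp <- setdiff(colnames(values), names(groups))
  if (length(missing_grp))
    stop("samples without a group assignment: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(groups), colnames(values))
  if (length(unknown))
    stop("group map refers to unknown samples: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  groups <- groups[colnames(values)]
  tab <- table(groups)
  if (any(tab < 2))
    stop("fewer than 2 samples in group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)

  structure(list(values = values, groups = groups), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
n_genes <- function(x) nrow(x$values)

#' @rdname expression_matrix
#' @export
n_samples <- function(x) ncol(x$values)

#' @rdname expression_matrix
#' @export
group_levels <- function(x) unique(unname(x$groups))

#' Samples belonging to one group
#' @param x an `ExpressionMatrix`.
#' @param group group label.
#' @return character vector of sample ids.
#' @keywords internal
group_samples <- function(x, group) {
  if (!group %in% x$groups)
    stop("unknown group: ", group, call. = FALSE)
  names(x$groups)[x$groups == group]
}

# Detect tab vs comma delimiter from the header line of a text table.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab == 0 && n_com == 0 )
    return("\t")   # single-column table; delimiter irrelevant
  if (n_tab >= n_com) "\t" else ","
}

#' Read an expression table and its group map from delimited text
#'
#' The expression table has gene symbols in the first column and one column
#' per sample; the group map is a two-column table `sample<TAB>group`. The
#' delimiter (tab or comma) is auto-detected from the header line of each
#' file. Samples present in the table but absent from the group map are
#' dropped with a warning; samples named in the group map but absent from
#' the table are an error.
#'
#' @param path path to the expression table.
#' @param group_map_path path to the sample-to-group map.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, group_map_path) {
  delim <- detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2)
    stop("malformed expression table: need a gene column plus >= 1 sample",
         call. = FALSE)
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric expression in column(s): ",
         paste(names(vals)[non_num], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- genes

  gm_delim <- detect_delim(group_map_path)
  gm <- utils::read.table(group_map_path, header = TRUE, sep = gm_delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(gm) < 2)
    stop("malformed group map: need columns sample, group", call. = FALSE)
  groups <- setNames(as.character(gm[[2]]), as.character(gm[[1]]))

  unknown <- setdiff(names(groups), colnames(m))
  if (length(unknown))
    stop("group map refers to unknown samples: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  unmapped <- setdiff(colnames(m), names(groups))
  if (length(unmapped)) {
    warning("dropping samples absent from the group map: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
    m <- m[, setdiff(colnames(m), unmapped), drop = FALSE]
  }
  expression_matrix(m, groups)
}

#' Write an expression matrix (and its group map) as tab-separated text
#'
#' Inverse of [read_expression_table()]: `read` after `write` reproduces the
#' object exactly (up to numeric print precision, controlled by `digits`).
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path for the expression table.
#' @param group_map_path output path for the sample-to-group map.
#' @param digits significant digits for expression values.
#' @return `x`, invisibly.
#' @export
write_expression_table <- function(x, path, group_map_path, digits = 15) {
  df <- data.frame(gene = rownames(x$values),
                   signif(x$values, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- data.frame(sample = names(x$groups), group = unname(x$groups),
                   stringsAsFactors = FALSE)
  utils::write.table(gm, group_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
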
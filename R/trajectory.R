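PATHOLOGY_RULES <- c("cvsad_or_a20vsad", "cvsad_only", "non_normalized")

check_call_tokens <- function(...) {
  for (v in list(...)) {
    bad <- setdiff(unique(v), CALL_TOKENS)
    if (length(bad))
      stop("invalid call token(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
}

#' Classify a gene's expression trajectory from its comparison calls
#'
#' Maps the call triplet (c1 = C vs A20, c2 = C vs AD, c3 = A20 vs AD) to
#' one of the six trajectory categories of [TRAJECTORY_CLASSES], by
#' precedence:
#' \itemize{
#'   \item c1 significant, c2 not: `transient` (altered under the stimulus,
#'     back to baseline after deprivation);
#'   \item c1 and c2 both significant: `persistent_same_sign` if they agree
#'     in direction, `persistent_reversed` if they disagree;
#'   \item only c2 significant: `deprivation_emergent`;
#'   \item only c3 significant: `deprivation_shifted`;
#'   \item nothing significant: `unchanged`.
#' }
#' The mapping is total and single-valued over all 27 token triplets.
#' All arguments are vectorized and recycled to a common length.
#'
#' @param c1,c2,c3 call tokens (`up` / `down` / `ns`).
#' @return character vector of categories.
#' @examples
#' classify_gene("up", "down", "down")  # persistent_reversed (the Th pattern)
#' classify_gene("up", "ns", "down")    # transient
#' @export
classify_gene <- function(c1, c2, c3) {
  n <- max(length(c1), length(c2), length(c3))
  c1 <- rep_len(as.character(c1), n)
  c2 <- rep_len(as.character(c2), n)
  c3 <- rep_len(as.character(c3), n)
  check_call_tokens(c1, c2, c3)
  out <- rep("unchanged", n)
  out[c1 != "ns" & c2 == "ns"] <- "transient"
  out[c1 != "ns" & c2 != "ns" & c1 == c2] <- "persistent_same_sign"
  out[c1 != "ns" & c2 != "ns" & c1 != c2] <- "persistent_reversed"
  out[c1 == "ns" & c2 != "ns"] <- "deprivation_emergent"
  out[c1 == "ns" & c2 == "ns" & c3 != "ns"] <- "deprivation_shifted"
  out
}

#' Flag a gene as pathology-associated
#'
#' The persistence criterion: a gene is associated with the lasting
#' (post-deprivation) pathology when its expression at the AD time point
#' still differs from control and/or from the stimulated group. Three rule
#' variants are provided because published gene lists built on this
#' criterion are not perfectly internally consistent:
#' \describe{
#'   \item{`cvsad_or_a20vsad` (default)}{c2 or c3 significant — the literal
#'     "differs from C and/or from A20 at AD" reading.}
#'   \item{`cvsad_only`}{c2 significant — strictly "still differs from
#'     control".}
#'   \item{`non_normalized`}{c2 significant, or (c1 ns and c3 significant) —
#'     like the default but never flags a transient gene on the strength of
#'     its c3 rebound alone.}
#' }
#' Vectorized over the call triplet.
#'
#' @param c1,c2,c3 call tokens.
#' @param rule one of `PATHOLOGY_RULES`.
#' @return logical vector.
#' @export
pathology_flag <- function(c1, c2, c3, rule = PATHOLOGY_RULES) {
  rule <- match.arg(rule)
  n <- max(length(c1), length(c2), length(c3))
  c1 <- rep_len(as.character(c1), n)
  c2 <- rep_len(as.character(c2), n)
  c3 <- rep_len(as.character(c3), n)
  check_call_tokens(c1, c2, c3)
  switch(rule,
         cvsad_or_a20vsad = c2 != "ns" | c3 != "ns",
         cvsad_only = c2 != "ns",
         non_normalized = c2 != "ns" | (c1 == "ns" & c3 != "ns"))
}

#' Classify every gene of a call table
#'
#' @param calls a [call_table()].
#' @param rule pathology rule, see [pathology_flag()].
#' @return data.frame: the call table plus `category`, `pathology`,
#'   `rule_id`.
#' @export
classify_trajectories <- function(calls, rule = "cvsad_or_a20vsad") {
  stopifnot(inherits(calls, "CallTable"))
  out <- as.data.frame(calls)
  out$category <- classify_gene(calls$call_c1, calls$call_c2, calls$call_c3)
  out$pathology <- pathology_flag(calls$call_c1, calls$call_c2,
                                  calls$call_c3, rule)
  out$rule_id <- rule
  out
}

#' Summarize trajectory calls over one gene panel
#'
#' Resolves the panel members against the call table (case-insensitively;
#' members absent from the table are reported as untested) and tabulates:
#' trajectory-category counts, up/down counts per comparison, the DEG set
#' (members with at least one non-ns call), the pathology set under the
#' chosen rule, and subclass counts within the DEG set.
#'
#' @param calls a [call_table()].
#' @param panel a [gene_panel()].
#' @param rule pathology rule, see [pathology_flag()].
#' @return object of class `PanelSummary` (a list).
#' @examples
#' \donttest{
#' s <- summarize_panel(nacc_call_fixture(), load_default_panels()$GABAergic)
#' s$deg_set       # 6 genes
#' s$category_counts[["transient"]]  # 5
#' }
#' @export
summarize_panel <- function(calls, panel, rule = "cvsad_or_a20vsad") {
  stopifnot(inherits(calls, "CallTable"), inherits(panel, "GenePanel"))
  if (!length(panel$members)) stop("empty panel", call. = FALSE)
  idx <- match(tolower(panel$members), tolower(calls$gene))
  tested <- panel$members[!is.na(idx)]
  untested <- panel$members[is.na(idx)]
  sub <- calls[stats::na.omit(idx), , drop = FALSE]

  cls <- classify_gene(sub$call_c1, sub$call_c2, sub$call_c3)
  path <- pathology_flag(sub$call_c1, sub$call_c2, sub$call_c3, rule)
  category_counts <- setNames(integer(length(TRAJECTORY_CLASSES)),
                              TRAJECTORY_CLASSES)
  tb <- table(factor(cls, levels = TRAJECTORY_CLASSES))
  category_counts[names(tb)] <- as.integer(tb)

  updown <- sapply(c(c1 = "call_c1", c2 = "call_c2", c3 = "call_c3"),
                   function(col) c(up = sum(sub[[col]] == "up"),
                                   down = sum(sub[[col]] == "down")))
  is_deg <- sub$call_c1 != "ns" | sub$call_c2 != "ns" | sub$call_c3 != "ns"
  deg_set <- sort(tested[is_deg])
  pathology_set <- sort(tested[path])

  tags <- panel$subclass_of[match(tolower(tested[is_deg]),
                                  tolower(names(panel$subclass_of)))]
  subclass_counts <- if (length(tags)) table(tags[!is.na(tags)]) else table(character())

  structure(list(system = panel$name,
                 n_members = length(panel$members),
                 tested = sort(tested), untested = sort(untested),
                 category_counts = category_counts,
                 updown_counts = updown,
                 deg_set = deg_set,
                 pathology_set = pathology_set,
                 subclass_counts = subclass_counts,
                 rule_id = rule),
            class = "PanelSummary")
}

#' @export
print.PanelSummary <- function(x, ...) {
  cat(sprintf("PanelSummary '%s' (rule %s): %d members, %d tested, %d DEGs, %d pathology-associated\n",
              x$system, x$rule_id, x$n_members, length(x$tested),
              length(x$deg_set), length(x$pathology_set)))
  nz <- x$category_counts[x$category_counts > 0]
  if (length(nz))
    cat("categories:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize every panel of a list
#'
#' @inheritParams summarize_panel
#' @param panels named list of [gene_panel()] objects.
#' @return named list of `PanelSummary` objects, in panel order.
#' @export
summarize_panels <- function(calls, panels, rule = "cvsad_or_a20vsad") {
  lapply(panels, summarize_panel, calls = calls, rule = rule)
}

#' Tabular form of panel summaries
#'
#' One row per system with member/tested/DEG/pathology counts and the six
#' category counts; convenient for TSV export.
#'
#' @param summaries list of `PanelSummary` objects.
#' @return data.frame.
#' @export
panel_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(system = s$system, n_members = s$n_members,
               n_tested = length(s$tested), n_deg = length(s$deg_set),
               n_pathology = length(s$pathology_set),
               t(as.matrix(s$category_counts)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
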
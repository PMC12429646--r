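#' Gene panels for the five neurotransmitter systems
#'
#' A `GenePanel` is a named set of gene symbols belonging to one
#' neurotransmitter system (catecholaminergic, opioidergic/cannabinoidergic,
#' serotonergic, GABAergic, glutamatergic), optionally annotated with a
#' functional subclass per gene (receptor subtype, enzyme, transporter,
#' peptide precursor, ...). The default panels bundled with the package
#' cover the genes profiled in the nucleus accumbens study design this
#' package implements; some genes (e.g. `Maoa`, `Slc18a2`, `Ddc`) belong to
#' more than one system and appear in both panels.
#'
#' @param name system label.
#' @param members character vector of unique gene symbols.
#' @param subclass_of named character vector mapping a subset of `members`
#'   to subclass tags (e.g. `ionotropic_receptor`, `metabotropic_receptor`,
#'   `decarboxylase`, `transporter`, `enzyme`, `peptide_precursor`).
#' @return an object of class `GenePanel`.
#' @export
gene_panel <- function(name, members, subclass_of = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- as.character(members)
  if (anyDuplicated(tolower(members)))
    stop("panel '", name, "' has duplicate members", call. = FALSE)
  if (length(subclass_of)) {
    if (is.null(names(subclass_of)))
      stop("`subclass_of` must be named by gene symbol", call. = FALSE)
    stray <- setdiff(names(subclass_of), members)
    if (length(stray))
      stop("subclass tags for non-members: ", paste(stray, collapse = ", "),
           call. = FALSE)
  }
  structure(list(name = name, members = members,
                 subclass_of = subclass_of),
            class = "GenePanel")
}

#' @export
print.GenePanel <- function(x, ...) {
  cat(sprintf("GenePanel '%s': %d genes (%d subclass-tagged)\n",
              x$name, length(x$members), length(x$subclass_of)))
  invisible(x)
}

#' Read gene panels from a three-column TSV (gene, system, subclass)
#'
#' An empty subclass field leaves the gene untagged. Systems appear in the
#' returned list in order of first appearance in the file.
#'
#' @param path panel file path.
#' @return named list of [gene_panel()] objects.
#' @export
read_panel_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = NULL, colClasses = "character")
  need <- c("gene", "system", "subclass")
  if (!all(need %in% names(df)))
    stop("panel file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (sys in unique(df$system)) {
    sub <- df[df$system == sys, , drop = FALSE]
    tags <- setNames(sub$subclass, sub$gene)
    tags <- tags[nzchar(tags)]
    out[[sys]] <- gene_panel(sys, sub$gene, tags)
  }
  out
}

#' Load the bundled neurotransmitter panels
#'
#' Returns the five default panels (catecholaminergic,
#' opioidergic_cannabinoidergic, serotonergic, GABAergic, glutamatergic) in
#' that canonical order.
#'
#' @return named list of [gene_panel()] objects.
#' @examples
#' panels <- load_default_panels()
#' length(panels$catecholaminergic$members)  # 29
#' @export
load_default_panels <- function() {
  path <- system.file("extdata", "neuro_panels.tsv", package = "trajdeg",
                      mustWork = TRUE)
  read_panel_file(path)
}

#' Case-insensitive gene symbol matching
#'
#' Resolves `query` symbols against `reference` symbols ignoring case, and
#' returns the matching reference spellings (NA where unmatched).
#'
#' @param query,reference character vectors of gene symbols.
#' @return character vector, same length as `query`.
#' @keywords internal
match_genes <- function(query, reference) {
  idx <- match(tolower(query), tolower(reference))
  reference[idx]
}
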
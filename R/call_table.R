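CALL_TOKENS <- c("up", "down", "ns")

#' Per-gene comparison-call table
#'
#' A `CallTable` records, for each gene, the directional outcome of the
#' three ordered group comparisons of the stimulus-deprivation design:
#' `call_c1` = control vs stimulated (C vs A20), `call_c2` = control vs
#' deprived (C vs AD), `call_c3` = stimulated vs deprived (A20 vs AD).
#' A call's sign is that of the second-listed group relative to the first
#' (so `up` in c1 means higher in A20 than in C). Tokens are `up`, `down`,
#' or `ns` (not significant).
#'
#' Call tables are either derived from expression data via
#' [run_comparisons()] + [calls_from_results()], or transcribed from
#' published per-gene statements when raw expression is unavailable (see
#' [nacc_call_fixture()]).
#'
#' @param df data.frame with columns `gene`, `system`, `call_c1`,
#'   `call_c2`, `call_c3`. `system` may be `NA` for unannotated genes.
#' @return a validated data.frame of class `CallTable`.
#' @export
call_table <- function(df) {
  need <- c("gene", "system", "call_c1", "call_c2", "call_c3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("call table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[need]
  df$gene <- as.character(df$gene)
  df$system <- as.character(df$system)
  if (anyDuplicated(tolower(df$gene)))
    stop("duplicate gene symbol in call table", call. = FALSE)
  for (col in c("call_c1", "call_c2", "call_c3")) {
    df[[col]] <- as.character(df[[col]])
    bad <- setdiff(unique(df[[col]]), CALL_TOKENS)
    if (length(bad))
      stop("invalid call token(s) in ", col, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("CallTable", "data.frame")
  df
}

#' Read a comparison-call table from tab/comma-separated text
#'
#' @param path file with columns gene, system, call_c1, call_c2, call_c3;
#'   call tokens must be `up`, `down` or `ns`.
#' @param known_systems optional character vector; if given, every non-`NA`
#'   system must be one of these.
#' @return a [call_table()].
#' @export
read_call_table <- function(path, known_systems = NULL) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = "NA")
  ct <- call_table(df)
  if (!is.null(known_systems)) {
    bad <- setdiff(stats::na.omit(unique(ct$system)), known_systems)
    if (length(bad))
      stop("unknown system(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ct
}

#' @rdname read_call_table
#' @param x a `CallTable`.
#' @export
write_call_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' The bundled nucleus-accumbens comparison-call fixture
#'
#' Per-gene calls for the three comparisons (C vs A20, C vs AD, A20 vs AD)
#' transcribed from the published per-system results narrative: a call is
#' `ns` unless the text asserts a significant difference for that gene and
#' comparison. 54 genes across the five neurotransmitter systems. Two
#' transcription notes: the A20-vs-AD direction for `Grm7` is stated only
#' as "differed" and is encoded `up` by analogy with the same-pattern genes
#' `Drd3`/`Adrb1`/`Oprk1`/`Pdyn`; `Gabra5`'s C-vs-AD call continues its
#' C-vs-A20 upregulation ("did not return to control").
#'
#' @return a [call_table()].
#' @examples
#' calls <- nacc_call_fixture()
#' calls[calls$gene == "Th", ]
#' @export
nacc_call_fixture <- function() {
  path <- system.file("extdata", "nacc_calls.tsv", package = "trajdeg",
                      mustWork = TRUE)
  read_call_table(path, known_systems = names(load_default_panels()))
}
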
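#' Configure an end-to-end pipeline run
#'
#' One of three input modes: `"expression"` (a gene-by-sample table plus a
#' group map), `"calls"` (a pre-computed comparison-call table, used when
#' raw expression is unavailable), or `"synthetic"` (simulate a dataset
#' from a [simulation_spec()]). The pipeline then runs differential
#' expression (expression/synthetic modes), trajectory classification and
#' per-panel summaries, and — when expression is available — per-group
#' coordination analysis over the pathology-associated gene set.
#'
#' @param mode input mode.
#' @param expression_path,group_map_path input paths (expression mode).
#' @param calls_path input path (calls mode).
#' @param sim a [simulation_spec()] (synthetic mode; default spec with
#'   `seed` if omitted).
#' @param comparisons ordered group pairs (c1, c2, c3 of the design).
#' @param method,alpha_p,alpha_q differential expression settings, see
#'   [run_comparisons()].
#' @param pathology_rule see [pathology_flag()].
#' @param coordination_alpha,sign_filter coordination settings, see
#'   [significant_pairs()].
#' @param coordination_genes `"pathology"` (default: correlate the
#'   pathology-associated set) or an explicit character vector of genes.
#' @param out_dir output directory for result TSVs, `summary.md` and
#'   `run.log`.
#' @param seed integer seed (drives synthetic mode; recorded in the log).
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(mode = c("expression", "calls", "synthetic"),
                            expression_path = NULL, group_map_path = NULL,
                            calls_path = NULL, sim = NULL,
                            comparisons = list(c("C", "A20"), c("C", "AD"),
                                               c("A20", "AD")),
                            method = "welch_t",
                            alpha_p = 0.05, alpha_q = 0.05,
                            pathology_rule = "cvsad_or_a20vsad",
                            coordination_alpha = 0.05,
                            sign_filter = "both",
                            coordination_genes = "pathology",
                            out_dir = "trajdeg_results", seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "expression" &&
      (is.null(expression_path) || is.null(group_map_path)))
    stop("expression mode needs `expression_path` and `group_map_path`",
         call. = FALSE)
  if (mode == "calls" && is.null(calls_path))
    stop("calls mode needs `calls_path`", call. = FALSE)
  if (mode == "synthetic" && is.null(sim))
    sim <- simulation_spec(seed = seed)
  if (!(alpha_p > 0 && alpha_p <= 1 && alpha_q > 0 && alpha_q <= 1))
    stop("alpha thresholds must lie in (0, 1]", call. = FALSE)
  if (!pathology_rule %in% PATHOLOGY_RULES)
    stop("unknown pathology rule: ", pathology_rule, call. = FALSE)
  structure(list(mode = mode, expression_path = expression_path,
                 group_map_path = group_map_path, calls_path = calls_path,
                 sim = sim, comparisons = comparisons, method = method,
                 alpha_p = alpha_p, alpha_q = alpha_q,
                 pathology_rule = pathology_rule,
                 coordination_alpha = coordination_alpha,
                 sign_filter = sign_filter,
                 coordination_genes = coordination_genes,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Serialize / restore a pipeline config as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  if (!is.null(obj$sim)) {
    obj$sim <- unclass(obj$sim)
    obj$sim$class_counts <- as.list(obj$sim$class_counts)
  }
  yaml::write_yaml(obj, path)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sim <- if (!is.null(obj$sim))
    simulation_spec(n_per_group = obj$sim$n_per_group,
                    class_counts = unlist(obj$sim$class_counts),
                    effect_size = obj$sim$effect_size, sigma = obj$sim$sigma,
                    baseline_range = unlist(obj$sim$baseline_range),
                    coordination = obj$sim$coordination,
                    groups = unlist(obj$sim$groups), seed = obj$sim$seed)
  pipeline_config(mode = obj$mode, expression_path = obj$expression_path,
                  group_map_path = obj$group_map_path,
                  calls_path = obj$calls_path, sim = sim,
                  comparisons = lapply(obj$comparisons, unlist),
                  method = obj$method, alpha_p = obj$alpha_p,
                  alpha_q = obj$alpha_q, pathology_rule = obj$pathology_rule,
                  coordination_alpha = obj$coordination_alpha,
                  sign_filter = obj$sign_filter,
                  coordination_genes = unlist(obj$coordination_genes),
                  out_dir = obj$out_dir, seed = obj$seed)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the configured stages, writes every stage output as TSV plus a
#' markdown summary (`summary.md`) and a plain-text run log (`run.log`)
#' under `config$out_dir`, and returns the in-memory artifacts. Outputs
#' contain no timestamps, so identical configs (and seeds) give
#' byte-identical result files.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `calls`, `trajectories`, `summaries`,
#'   `results` (per-comparison frames or NULL), `coordination` (or NULL)
#'   and `summary_lines`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  em <- NULL
  truth <- NULL
  results <- NULL

  if (config$mode == "synthetic") {
    sim <- with_stage("simulate", generate_dataset(config$sim))
    em <- sim$expression
    truth <- sim$truth
    write_expression_table(em, out("expression.tsv"), out("groups.tsv"))
    utils::write.table(truth, out("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (config$mode == "expression") {
    em <- with_stage("read_expression",
                     read_expression_table(config$expression_path,
                                           config$group_map_path))
  }

  if (!is.null(em)) {
    results <- with_stage("diffexpr",
      run_comparisons(em, comparisons = config$comparisons,
                      method = config$method, alpha_p = config$alpha_p,
                      alpha_q = config$alpha_q))
    for (nm in names(results))
      write_comparison_result(results[[nm]], out(paste0("deg_", nm, ".tsv")))
    calls <- calls_from_results(results)
  } else {
    calls <- with_stage("read_calls", read_call_table(config$calls_path))
  }

  traj <- with_stage("trajectory",
                     classify_trajectories(calls, config$pathology_rule))
  utils::write.table(traj, out("trajectories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panels <- load_default_panels()
  summaries <- with_stage("trajectory",
                          summarize_panels(calls, panels,
                                           config$pathology_rule))
  utils::write.table(panel_summary_table(summaries),
                     out("panel_summaries.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  coordination <- NULL
  if (!is.null(em)) {
    genes <- if (identical(config$coordination_genes, "pathology"))
      traj$gene[traj$pathology] else config$coordination_genes
    genes <- genes[!is.na(match_genes(genes, rownames(em$values)))]
    if (length(genes) >= 2) {
      coordination <- with_stage("coordination",
        compare_coordination(em, genes, groups = group_levels(em),
                             alpha = config$coordination_alpha,
                             sign_filter = config$sign_filter))
      utils::write.table(coordination$delta, out("coordination_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (g in names(coordination$summaries))
        write_coordination(coordination$summaries[[g]],
                           matrix_path = out(paste0("cor_", g, ".tsv")),
                           pairs_path = out(paste0("pairs_", g, ".tsv")))
    }
  }

  summary_lines <- render_summary(list(config = config, summaries = summaries,
                                       trajectories = traj,
                                       coordination = coordination))
  writeLines(summary_lines, out("summary.md"))

  log_lines <- c("trajdeg pipeline run",
                 paste0("package_version: ",
                        as.character(utils::packageVersion("trajdeg"))),
                 paste0("mode: ", config$mode),
                 paste0("seed: ", config$seed),
                 paste0("alpha_p: ", config$alpha_p),
                 paste0("alpha_q: ", config$alpha_q),
                 paste0("pathology_rule: ", config$pathology_rule),
                 paste0("coordination_alpha: ", config$coordination_alpha),
                 paste0("sign_filter: ", config$sign_filter))
  writeLines(log_lines, out("run.log"))

  invisible(list(calls = calls, trajectories = traj, summaries = summaries,
                 results = results, coordination = coordination,
                 truth = truth, summary_lines = summary_lines))
}

#' Render a markdown summary of pipeline stage outputs
#'
#' Per-system sections with category counts, up/down counts per
#' comparison, and the pathology gene list; a coordination section with
#' per-group totals when expression was available. Deterministic ordering:
#' systems in panel order, genes alphabetical. Missing stages are marked
#' unavailable, never fabricated.
#'
#' @param stages list with `config`, `summaries`, `trajectories`, and
#'   optionally `coordination`.
#' @return character vector of markdown lines.
#' @export
render_summary <- function(stages) {
  cfg <- stages$config
  lines <- c("# Trajectory classification summary", "",
             paste0("Pathology rule: `", cfg$pathology_rule, "`; ",
                    "DEG thresholds p < ", cfg$alpha_p, ", q < ", cfg$alpha_q,
                    "."), "")
  for (s in stages$summaries) {
    lines <- c(lines, paste0("## ", s$system), "",
               sprintf("- members: %d (tested: %d, untested: %d)",
                       s$n_members, length(s$tested), length(s$untested)),
               sprintf("- DEGs (any significant comparison): %d",
                       length(s$deg_set)))
    nz <- s$category_counts[s$category_counts > 0]
    if (length(nz))
      lines <- c(lines, paste0("- categories: ",
                               paste(sprintf("%s = %d", names(nz), nz),
                                     collapse = ", ")))
    ud <- s$updown_counts
    lines <- c(lines,
               sprintf("- up/down per comparison: c1 %d/%d, c2 %d/%d, c3 %d/%d",
                       ud["up", "c1"], ud["down", "c1"], ud["up", "c2"],
                       ud["down", "c2"], ud["up", "c3"], ud["down", "c3"]),
               sprintf("- pathology-associated (%d): %s",
                       length(s$pathology_set),
                       if (length(s$pathology_set))
                         paste(s$pathology_set, collapse = ", ")
                       else "none"),
               "")
  }
  lines <- c(lines, "## Coordination", "")
  if (is.null(stages$coordination)) {
    msg <- if (is.null(stages$trajectories) ||
               !any(stages$trajectories$pathology))
      "no genes to correlate" else "unavailable (no expression data)"
    lines <- c(lines, paste0("Coordination section: ", msg, "."), "")
  } else {
    tot <- stages$coordination$totals
    lines <- c(lines,
               "Significant correlated pairs among the analyzed gene set:",
               "",
               sprintf("- %s: %d pairs", names(tot), tot), "")
  }
  lines
}
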
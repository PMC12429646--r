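#' Trajectory classes recognized throughout the package
#'
#' Canonical ordering of the six per-gene trajectory archetypes over the
#' (C, A20, AD) design: `unchanged`, `transient` (altered under the
#' stimulus, back to baseline after deprivation), `persistent_same_sign`
#' (altered and still altered in the same direction), `persistent_reversed`
#' (altered, then overshoots past baseline in the opposite direction),
#' `deprivation_emergent` (unaltered under the stimulus, altered after
#' deprivation), and `deprivation_shifted` (only the A20-vs-AD contrast is
#' significant).
#'
#' @export
TRAJECTORY_CLASSES <- c("unchanged", "transient", "persistent_same_sign",
                        "persistent_reversed", "deprivation_emergent",
                        "deprivation_shifted")

#' Default planted-class composition for a simulated gene set
#'
#' Majority-unchanged mix (60% unchanged, 10% each transient /
#' persistent-same-sign / deprivation-emergent, 5% each of the rarer
#' reversed and shifted archetypes), mirroring the observation that only a
#' handful of profiled genes show reversal or deprivation-only shifts.
#'
#' @param n_genes total number of genes.
#' @return named integer vector over [TRAJECTORY_CLASSES].
#' @export
default_class_counts <- function(n_genes = 500) {
  prop <- c(unchanged = 0.60, transient = 0.10, persistent_same_sign = 0.10,
            persistent_reversed = 0.05, deprivation_emergent = 0.10,
            deprivation_shifted = 0.05)
  counts <- floor(prop * n_genes)
  counts["unchanged"] <- counts["unchanged"] + (n_genes - sum(counts))
  counts
}

#' Specify a synthetic three-group expression simulation
#'
#' The generative model, per gene g and sample s in group k, is
#' \deqn{log2(x_{gs} + 1) = \mu_g + \delta_{g,k} + \lambda f_s [g \in
#' cluster(k)] + \epsilon_{gs}, \quad \epsilon_{gs} \sim N(0, \sigma^2)}
#' with one latent factor score \eqn{f_s \sim N(0,1)} per sample of a
#' cluster's group, and expression back-transformed as
#' \eqn{\max(2^x - 1, 0)}. The planted log2 shift triplets
#' \eqn{(\delta_C, \delta_{A20}, \delta_{AD})} per class are: unchanged
#' (0,0,0); transient (0,d,0); persistent_same_sign (0,d,d);
#' persistent_reversed (0,d,-d); deprivation_emergent (0,0,d);
#' deprivation_shifted (0,-d/2,+d/2). The sign of d is randomized per gene
#' and recorded in the truth table.
#'
#' @param n_per_group replicates per group (design default 6).
#' @param class_counts named vector over [TRAJECTORY_CLASSES] (missing
#'   classes count 0).
#' @param effect_size log2-scale shift magnitude d (default 1.5).
#' @param sigma per-gene log2 noise standard deviation (default 0.5).
#' @param baseline_range interval for per-gene baseline log2 expression.
#' @param coordination list of planted co-expression clusters, each a list
#'   with elements `group`, `size`, `lambda` (factor loading). Cluster
#'   members are drawn from unchanged-class genes so planted correlation is
#'   not confounded with planted shifts.
#' @param groups group labels, ordered (baseline group first).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec including the seed.
#' @return object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_per_group = 6,
                            class_counts = default_class_counts(500),
                            effect_size = 1.5,
                            sigma = 0.5,
                            baseline_range = c(2, 8),
                            coordination = list(),
                            groups = c("C", "A20", "AD"),
                            seed = 1L) {
  stopifnot(length(n_per_group) == 1, n_per_group >= 2,
            n_per_group == round(n_per_group))
  bad <- setdiff(names(class_counts), TRAJECTORY_CLASSES)
  if (length(bad))
    stop("unknown trajectory class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  full <- setNames(rep(0L, length(TRAJECTORY_CLASSES)), TRAJECTORY_CLASSES)
  full[names(class_counts)] <- as.integer(class_counts)
  if (any(full < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (sum(full) < 1) stop("need at least one gene", call. = FALSE)
  stopifnot(sigma > 0, effect_size >= 0,
            length(baseline_range) == 2, baseline_range[1] <= baseline_range[2],
            length(groups) == 3, !anyDuplicated(groups))
  for (cl in coordination) {
    if (!all(c("group", "size", "lambda") %in% names(cl)))
      stop("each coordination entry needs group, size, lambda", call. = FALSE)
    if (!cl$group %in% groups) stop("cluster group not in design", call. = FALSE)
    if (cl$lambda < 0) stop("lambda must be >= 0", call. = FALSE)
    if (cl$size < 2) stop("cluster size must be >= 2", call. = FALSE)
  }
  tot_cluster <- sum(vapply(coordination, function(cl) cl$size, numeric(1)))
  if (tot_cluster > full["unchanged"])
    stop("coordination clusters need ", tot_cluster,
         " unchanged-class genes but only ", full["unchanged"],
         " are planted", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), class_counts = full,
                 effect_size = effect_size, sigma = sigma,
                 baseline_range = as.numeric(baseline_range),
                 coordination = coordination, groups = groups,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

# shift pattern (C, A20, AD) in units of d for a positive-sign gene
class_shift_pattern <- function(class) {
  switch(class,
         unchanged            = c(0, 0, 0),
         transient            = c(0, 1, 0),
         persistent_same_sign = c(0, 1, 1),
         persistent_reversed  = c(0, 1, -1),
         deprivation_emergent = c(0, 0, 1),
         deprivation_shifted  = c(0, -0.5, 0.5),
         stop("unknown class: ", class, call. = FALSE))
}

# Evaluate fn with a private RNG stream; caller's stream is untouched.
with_private_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic dataset with planted truth
#'
#' Draws an expression matrix under the generative model documented in
#' [simulation_spec()] and returns it together with the per-gene truth
#' table (planted class, shift sign, log2 shift triplet, cluster
#' membership). Bit-identical output for identical spec + seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `expression` (an [expression_matrix()]) and
#'   `truth` (data.frame: gene, class, sign, delta_c, delta_a20, delta_ad,
#'   cluster, cluster_group).
#' @examples
#' sim <- generate_dataset(simulation_spec(
#'   class_counts = c(unchanged = 10, transient = 5), seed = 7))
#' dim(sim$expression$values)  # 15 x 18
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "SimulationSpec"))
    stop("`spec` must be a SimulationSpec", call. = FALSE)
  with_private_seed(spec$seed, function() {
    counts <- spec$class_counts
    G <- sum(counts)
    classes <- rep(names(counts), counts)
    gene_ids <- sprintf("g%04d", seq_len(G))
    n <- spec$n_per_group
    sample_ids <- unlist(lapply(spec$groups, function(g) paste0(g, "_", seq_len(n))))
    grp_of <- setNames(rep(spec$groups, each = n), sample_ids)

    mu <- stats::runif(G, spec$baseline_range[1], spec$baseline_range[2])
    sign <- sample(c(1, -1), G, replace = TRUE)
    delta <- t(vapply(seq_len(G), function(i) {
      class_shift_pattern(classes[i]) * spec$effect_size * sign[i]
    }, numeric(3)))
    colnames(delta) <- spec$groups

    # assign cluster members among unchanged-class genes
    cluster_id <- rep(NA_character_, G)
    cluster_group <- rep(NA_character_, G)
    pool <- which(classes == "unchanged")
    for (i in seq_along(spec$coordination)) {
      cl <- spec$coordination[[i]]
      pick <- if (length(pool) == 1) pool else sample(pool, cl$size)
      pick <- pick[seq_len(cl$size)]
      id <- paste0(cl$group, "_cl", i)
      cluster_id[pick] <- id
      cluster_group[pick] <- cl$group
      pool <- setdiff(pool, pick)
    }

    logx <- matrix(mu, nrow = G, ncol = length(sample_ids)) +
      delta[, grp_of[sample_ids], drop = FALSE]
    for (i in seq_along(spec$coordination)) {
      cl <- spec$coordination[[i]]
      id <- paste0(cl$group, "_cl", i)
      members <- which(cluster_id == id)
      in_grp <- grp_of[sample_ids] == cl$group
      f <- stats::rnorm(sum(in_grp))
      logx[members, in_grp] <- logx[members, in_grp] +
        cl$lambda * matrix(f, nrow = length(members), ncol = sum(in_grp),
                           byrow = TRUE)
    }
    logx <- logx + matrix(stats::rnorm(G * length(sample_ids), 0, spec$sigma),
                          nrow = G)
    expr <- pmax(2 ^ logx - 1, 0)
    dimnames(expr) <- list(gene_ids, sample_ids)

    truth <- data.frame(gene = gene_ids, class = classes, sign = sign,
                        delta_c = delta[, 1], delta_a20 = delta[, 2],
                        delta_ad = delta[, 3], cluster = cluster_id,
                        cluster_group = cluster_group,
                        stringsAsFactors = FALSE, row.names = NULL)
    list(expression = expression_matrix(expr, grp_of), truth = truth)
  })
}

#' Noise-free expected comparison calls for planted truth
#'
#' Maps each planted class (and shift sign) to the call triplet that a
#' perfectly powered, perfectly calibrated test would produce: e.g. a
#' positive-sign transient gene gives (up, ns, down); a positive-sign
#' persistent_reversed gene gives (up, down, down). Used as the reference
#' in pipeline-recovery tests. Note the deprivation_shifted half-shifts
#' against C are treated as sub-threshold by construction, giving
#' (ns, ns, up/down).
#'
#' @param truth truth data.frame from [generate_dataset()].
#' @return a [call_table()] (system = NA).
#' @export
truth_to_expected_calls <- function(truth) {
  dir <- ifelse(truth$sign > 0, "up", "down")
  opp <- ifelse(truth$sign > 0, "down", "up")
  c1 <- c2 <- c3 <- rep("ns", nrow(truth))
  cl <- truth$class
  c1[cl %in% c("transient", "persistent_same_sign", "persistent_reversed")] <-
    dir[cl %in% c("transient", "persistent_same_sign", "persistent_reversed")]
  c2[cl == "persistent_same_sign"] <- dir[cl == "persistent_same_sign"]
  c2[cl %in% c("persistent_reversed")] <- opp[cl %in% c("persistent_reversed")]
  c2[cl == "deprivation_emergent"] <- dir[cl == "deprivation_emergent"]
  c3[cl == "transient"] <- opp[cl == "transient"]
  c3[cl == "persistent_reversed"] <- opp[cl == "persistent_reversed"]
  c3[cl == "deprivation_emergent"] <- dir[cl == "deprivation_emergent"]
  c3[cl == "deprivation_shifted"] <- dir[cl == "deprivation_shifted"]
  call_table(data.frame(gene = truth$gene, system = NA_character_,
                        call_c1 = c1, call_c2 = c2, call_c3 = c3,
                        stringsAsFactors = FALSE))
}

#' Serialize / restore a simulation spec as a YAML config
#'
#' @param spec a [simulation_spec()].
#' @param path file path.
#' @return `read_simulation_spec` returns a `SimulationSpec` equal to the
#'   one written.
#' @export
write_simulation_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$class_counts <- as.list(obj$class_counts)
  yaml::write_yaml(obj, path)
  invisible(spec)
}

#' @rdname write_simulation_spec
#' @export
read_simulation_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  simulation_spec(n_per_group = obj$n_per_group,
                  class_counts = unlist(obj$class_counts),
                  effect_size = obj$effect_size,
                  sigma = obj$sigma,
                  baseline_range = unlist(obj$baseline_range),
                  coordination = obj$coordination,
                  groups = unlist(obj$groups),
                  seed = obj$seed)
}
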
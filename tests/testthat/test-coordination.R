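test_that("correlation matrices reproduce hand-computed Pearson values", {
  base <- c(1, 2, 3, 4, 5, 6)
  em <- make_em(list(A = c(base, rep(1, 6), rep(1, 6)),
                     B = c(base, rep(1, 6), rep(2, 6)),
                     C = c(7 - base, rep(1, 6), rep(3, 6)),
                     D = c(2, 1, 4, 3, 6, 5, rep(1, 6), rep(4, 6))),
                n = 6)
  cm <- correlation_matrix(em, c("A", "B", "C", "D"), "C", log_scale = FALSE)
  expect_equal(cm$n, 6)
  expect_equal(cm$r["A", "B"], 1)
  expect_equal(cm$r["A", "C"], -1)
  expect_equal(cm$r["A", "D"], 29 / 35, tolerance = 1e-12)
  # symmetry + unit diagonal + bounds
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_true(all(abs(cm$r) <= 1 + 1e-12))
})

test_that("pair significance follows the t-transform with df = n - 2", {
  # r = 29/35 at n = 6: t = 2.96, p ~ 0.0415 -> significant at 0.05
  r <- 29 / 35
  n <- 6
  p <- 2 * pt(r * sqrt((n - 2) / (1 - r^2)), df = 4, lower.tail = FALSE)
  expect_equal(p, 0.041563, tolerance = 1e-4)
  expect_lt(p, 0.05)
  # critical r at alpha = 0.05, n = 6 is ~0.811: r = 0.5 is not significant
  tcrit <- qt(0.975, df = 4)
  rcrit <- sqrt(tcrit^2 / (tcrit^2 + 4))
  expect_equal(rcrit, 0.811, tolerance = 1e-3)

  m <- matrix(c(1, r, 0.5,
                r, 1, 0.2,
                0.5, 0.2, 1), 3, dimnames = list(letters[1:3], letters[1:3]))
  s <- significant_pairs(coordination_from_matrix(m, n = 6), alpha = 0.05)
  pr <- s$pairs
  expect_true(pr$significant[pr$gene_i == "a" & pr$gene_j == "b"])
  expect_false(pr$significant[pr$gene_i == "a" & pr$gene_j == "c"])
  expect_equal(s$total_count, 1L)
  expect_equal(sum(s$per_gene_count), 2L * s$total_count)
  expect_error(significant_pairs(s, alpha = 0), "alpha")
})

test_that("t-transform p-values agree with cor.test exactly", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(6)
    y <- rnorm(6)
    p_pkg <- trajdeg:::cor_pvalue(cor(x, y), 6)
    expect_equal(p_pkg, cor.test(x, y)$p.value, tolerance = 1e-10)
  }
})

test_that("the published 8-gene AD correlation matrix yields 28 significant pairs", {
  path <- system.file("extdata", "ad_coordination_matrix.tsv",
                      package = "trajdeg", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  r <- as.matrix(df)
  expect_equal(rownames(r), colnames(r))
  expect_gte(min(r[upper.tri(r)]), 0.851)
  s <- significant_pairs(coordination_from_matrix(r, n = 6, group = "AD"),
                         alpha = 0.05, sign_filter = "positive")
  expect_equal(s$total_count, 28L)
  expect_equal(unname(s$per_gene_count), rep(7L, 8))
})

test_that("sign filters and zero-variance genes are honored", {
  m <- matrix(c(1, 0.9, -0.9,
                0.9, 1, -0.85,
                -0.9, -0.85, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  s_both <- significant_pairs(coordination_from_matrix(m, 6), sign_filter = "both")
  s_pos <- significant_pairs(coordination_from_matrix(m, 6), sign_filter = "positive")
  s_neg <- significant_pairs(coordination_from_matrix(m, 6), sign_filter = "negative")
  expect_equal(s_both$total_count, 3L)
  expect_equal(s_pos$total_count, 1L)
  expect_equal(s_neg$total_count, 2L)

  set.seed(12)
  em <- make_em(list(flat = rep(2, 18),
                     v1 = abs(rnorm(18, 4)),
                     v2 = abs(rnorm(18, 4))), n = 6)
  em$values["v2", 1:6] <- em$values["v1", 1:6] * 1.5   # strong C-group link
  cm <- correlation_matrix(em, c("flat", "v1", "v2"), "C")
  expect_equal(cm$degenerate, "flat")
  s <- significant_pairs(cm)
  expect_false(any(grepl("flat", paste(s$pairs$gene_i, s$pairs$gene_j))))
  expect_equal(nrow(s$pairs), 1L)
})

test_that("preconditions: small groups and unresolvable genes error", {
  em <- make_em(list(a = rep(1:3, 3), b = rep(3:1, 3)))  # n = 3 per group
  expect_error(correlation_matrix(em, c("a", "b"), "C"), "fewer than 4")
  em6 <- make_em(list(a = rnorm(18, 5), b = rnorm(18, 5)), n = 6)
  expect_error(suppressWarnings(correlation_matrix(em6, c("zz", "yy"), "C")),
               "at least 2 resolvable")
  expect_warning(correlation_matrix(em6, c("a", "b", "zz"), "C"), "dropping genes")
})

test_that("pair-significance rate is calibrated to alpha for independent genes", {
  # ~2000 independent-gene pairs at n = 6: the significant fraction should
  # sit near alpha = 0.05 (checked across 3 seeds)
  rates <- sapply(1:3, function(s) {
    sim <- generate_dataset(simulation_spec(
      class_counts = c(unchanged = 130), seed = 300 + s))
    cm <- significant_pairs(correlation_matrix(
      sim$expression, sim$truth$gene[1:65], "C"))
    mean(cm$pairs$significant)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("group comparison detects a planted condition-specific cluster", {
  spec <- simulation_spec(
    class_counts = c(unchanged = 40),
    coordination = list(list(group = "A20", size = 10, lambda = 1)),
    seed = 55)
  sim <- generate_dataset(spec)
  members <- sim$truth$gene[!is.na(sim$truth$cluster)]
  cc <- compare_coordination(sim$expression, members,
                             groups = c("C", "A20", "AD"))
  expect_gt(cc$totals[["A20"]], cc$totals[["C"]])
  expect_equal(sum(cc$summaries$A20$per_gene_count),
               2L * cc$summaries$A20$total_count)
  expect_setequal(cc$delta$gene, members)
  expect_named(cc$summaries, c("C", "A20", "AD"))

  # identical expression in two groups -> identical totals
  v <- sim$expression$values
  v[, 7:12] <- v[, 13:18]   # copy AD block over A20 block
  em2 <- expression_matrix(v, sim$expression$groups)
  cc2 <- compare_coordination(em2, members, groups = c("A20", "AD"))
  expect_equal(cc2$totals[["A20"]], cc2$totals[["AD"]])

  # single-gene list: zero pairs in every group
  cc1 <- compare_coordination(sim$expression, members[1],
                              groups = c("C", "A20", "AD"))
  expect_equal(unname(cc1$totals), c(0L, 0L, 0L))
})
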
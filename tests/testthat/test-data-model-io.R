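test_that("expression tables round-trip through TSV and validate on read", {
  em <- make_em(list(Th = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                     Drd1 = c(0, 0.5, 1, 2, 2.5, 3, 0, 1, 2),
                     Penk = rep(2.25, 9)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  map <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, tsv, map)
  back <- read_expression_table(tsv, map)
  expect_equal(back$values, em$values)
  expect_equal(back$groups, em$groups)
  expect_equal(n_genes(back), 3)
  expect_equal(unname(table(back$groups)[group_levels(back)]), rep(3L, 3),
               ignore_attr = TRUE)
})

test_that("malformed expression input is rejected with a specific error", {
  vals <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  grp2 <- c(s1 = "C", s2 = "C")
  bad <- vals; bad[1, 1] <- -1
  expect_error(expression_matrix(bad, grp2), "negative expression")
  dup <- rbind(vals, vals[1, , drop = FALSE])
  rownames(dup) <- c("Th", "b", "th")   # duplicate after case normalization
  expect_error(expression_matrix(dup, grp2), "duplicate gene symbol")
  expect_error(expression_matrix(vals, c(s1 = "C", s2 = "A20")),
               "fewer than 2 samples")
  expect_error(expression_matrix(vals, c(s1 = "C")), "without a group")
})

test_that("group-map mismatches follow the drop/error contract", {
  em <- make_em(list(g1 = 1:6 / 2, g2 = 6:1 / 2), n = 2, groups = c("C", "A20", "AD"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  map <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, tsv, map)

  # group map naming a sample missing from the table is an error
  gm <- utils::read.table(map, header = TRUE, sep = "\t")
  gm2 <- rbind(gm, data.frame(sample = "ghost", group = "C"))
  utils::write.table(gm2, map, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_table(tsv, map), "unknown samples")

  # samples absent from the group map are dropped with a warning
  utils::write.table(gm[gm$group != "AD", ], map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_warning(sub <- read_expression_table(tsv, map), "dropping samples")
  expect_equal(sort(group_levels(sub)), c("A20", "C"))
})

test_that("comma-delimited tables are auto-detected", {
  csv <- withr::local_tempfile(fileext = ".csv")
  map <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2,s3,s4", "Th,1,2,3,4", "Drd1,4,3,2,1"), csv)
  writeLines(c("sample,group", "s1,C", "s2,C", "s3,A20", "s4,A20"), map)
  em <- read_expression_table(csv, map)
  expect_equal(dim(em$values), c(2L, 4L))
  expect_equal(em$values["Th", "s3"], 3)
})

test_that("bundled panels match the published system lists", {
  panels <- load_default_panels()
  expect_named(panels, c("catecholaminergic", "opioidergic_cannabinoidergic",
                         "serotonergic", "GABAergic", "glutamatergic"))
  expect_equal(vapply(panels, function(p) length(p$members), integer(1)),
               c(catecholaminergic = 29L, opioidergic_cannabinoidergic = 13L,
                 serotonergic = 20L, GABAergic = 23L, glutamatergic = 32L))
  # no duplicate members within a panel
  for (p in panels)
    expect_equal(anyDuplicated(tolower(p$members)), 0L)
  glu <- panels$glutamatergic
  grm <- paste0("Grm", 1:8)
  expect_true(all(grm %in% glu$members))
  expect_equal(unname(glu$subclass_of[grm]), rep("metabotropic_receptor", 8))
  expect_equal(unname(glu$subclass_of[c("Gad1", "Gad2")]),
               rep("decarboxylase", 2))
  expect_equal(unname(glu$subclass_of[c("Slc17a6", "Slc17a7", "Slc17a8")]),
               rep("transporter", 3))
  expect_equal(unname(glu$subclass_of["Grik4"]), "ionotropic_receptor")
  # shared monoamine genes appear in both relevant panels
  for (g in c("Maoa", "Maob", "Slc18a2", "Ddc")) {
    expect_true(g %in% panels$catecholaminergic$members)
    expect_true(g %in% panels$serotonergic$members)
  }
})

test_that("gene panels validate membership and subclass tags", {
  expect_error(gene_panel("x", c("Th", "th")), "duplicate")
  expect_error(gene_panel("x", "Th", c(Drd1 = "receptor")), "non-members")
  p <- gene_panel("x", c("Th", "Drd1"), c(Th = "enzyme"))
  expect_s3_class(p, "GenePanel")
})

test_that("gene symbols resolve case-insensitively without collisions", {
  expect_equal(match_genes(c("th", "TH", "drd1", "nope"),
                           c("Th", "Drd1")),
               c("Th", "Th", "Drd1", NA))
})

test_that("the call-table fixture encodes the published per-gene statements", {
  calls <- nacc_call_fixture()
  expect_equal(nrow(calls), 54)
  get <- function(g) unlist(calls[calls$gene == g,
                                  c("call_c1", "call_c2", "call_c3")],
                            use.names = FALSE)
  expect_equal(get("Th"), c("up", "down", "down"))
  expect_equal(get("Oprk1"), c("ns", "ns", "up"))
  expect_equal(get("Slc18a2"), c("up", "ns", "ns"))
  expect_equal(get("Penk"), c("ns", "up", "ns"))
  expect_equal(get("Gabra5"), c("up", "up", "ns"))
  expect_equal(get("Grm7"), c("ns", "ns", "up"))
  # the typo'd ionotropic symbol is stored under its real name
  expect_true("Gria3" %in% calls$gene)
  expect_false("Gria3a" %in% calls$gene)
})

test_that("call tables validate tokens and round-trip through TSV", {
  df <- data.frame(gene = c("Th", "Drd1"), system = "catecholaminergic",
                   call_c1 = c("up", "sideways"), call_c2 = "ns",
                   call_c3 = "ns")
  expect_error(call_table(df), "invalid call token")
  df$call_c1 <- c("up", "down")
  ct <- call_table(df)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_call_table(ct, path)
  expect_equal(as.data.frame(read_call_table(path)), as.data.frame(ct))
  expect_error(read_call_table(path, known_systems = "serotonergic"),
               "unknown system")
  df$gene <- c("Th", "tH")
  expect_error(call_table(df), "duplicate gene")
})
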
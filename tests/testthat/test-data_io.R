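test_that("expression matrices round-trip through TSV and reject bad input", {
  vals <- matrix(c(1.5, 2, 3, 4.25), 2, 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  x <- make_expr(vals, phenotype = c("M1", "M2"))
  expect_equal(dim(x), c(2L, 2L))
  mf <- tempfile(); sf <- tempfile()
  write_expression(x, mf, sf)
  y <- read_expression(mf, sf)
  expect_equal(y$values, x$values)
  expect_equal(y$meta, x$meta)

  # metadata missing one sample names the sample
  meta2 <- x$meta[1, , drop = FALSE]
  write.table(meta2, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mf, sf), "s2")

  # non-numeric cell names the coordinates
  writeLines(c("gene\ts1\ts2", "gA\t1\toops", "gB\t2\t3"), mf)
  write.table(x$meta, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mf, sf), "gA.*s2")

  # duplicate gene identifiers
  writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gA\t2\t3"), mf)
  expect_error(read_expression(mf, sf), "duplicate gene")
})

test_that("z-transformation standardizes, handles constants, and is idempotent", {
  vals <- matrix(c(0, 2, 5, 5, 1, 7), 3, 2, byrow = TRUE,
                 dimnames = list(c("g1", "gconst", "g3"), c("s1", "s2")))
  z <- z_transform(make_expr(vals))
  expect_equal(unname(z$values["g1", ]), c(-1, 1) / sqrt(2),
               tolerance = 1e-7)
  expect_equal(unname(z$values["gconst", ]), c(0, 0))
  expect_true(all(abs(rowMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values[c("g1", "g3"), ], 1, sd) - 1) < 1e-9))
  z2 <- z_transform(z)
  expect_equal(z2$values, z$values, tolerance = 1e-9)
  expect_error(z_transform(make_expr(vals[, 1, drop = FALSE])),
               "at least 2 samples")
})

test_that("technical replicates are averaged into one column per biological replicate", {
  vals <- matrix(c(1, 3, 5, 7, 2, 2, 8, 8), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  x <- make_expr(vals, phenotype = c("M1", "M1", "M2", "M2"),
                 bio = c(1, 1, 1, 1), tech = c(1, 2, 1, 2))
  z <- z_transform(x, collapse_technical = TRUE)
  expect_equal(ncol(z$values), 2L)
  # collapsed means are (2, 6) and (2, 8): both z to (-1, 1)/sqrt(2)
  expect_equal(unname(z$values[, 2] - z$values[, 1]),
               rep(sqrt(2), 2), tolerance = 1e-9)
})

test_that("metabolic models round-trip through JSON and validate structure", {
  m <- chain_model()
  expect_equal(nrow(m$reactions), 3)
  expect_equal(sum(!m$reactions$exchange), 1) # R1 touches two metabolites
  f <- tempfile(fileext = ".json")
  write_metabolic_model(m, f)
  m2 <- read_metabolic_model(f, "json")
  expect_equal(as.matrix(m2$S), as.matrix(m$S))
  expect_equal(m2$reactions, m$reactions)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$biomass, m$biomass)

  expect_error(metabolic_model(
    metabolites = "A",
    reactions = data.frame(id = c("r1", "bio"), lb = 0, ub = 1),
    stoich = list(c(A = 1, GHOST = -1), c(A = -1)),
    genes = list(character(), character()), biomass = "bio"),
    "undeclared metabolite.*GHOST")
  expect_error(metabolic_model(
    metabolites = "A",
    reactions = data.frame(id = "r1", lb = 0, ub = 1),
    stoich = list(c(A = 1)), genes = list(character()), biomass = "nope"),
    "biomass")
})

test_that("SBML FBC import recovers species, bounds, stoichiometry and genes", {
  f <- tempfile(fileext = ".xml")
  writeLines(sbml_chain_doc(), f)
  m <- read_metabolic_model(f, "sbml_fbc")
  expect_equal(m$metabolites, c("A", "B"))
  expect_equal(m$reactions$id, c("EX_in", "R1", "biomass_c"))
  expect_equal(m$reactions$lb, c(1, 0, 0))
  expect_equal(m$reactions$ub, c(1, 10, 10))
  expect_equal(unname(as.matrix(m$S)[, "R1"]), c(-1, 1))
  expect_equal(m$genes$R1, "g1")
  expect_equal(m$biomass, "biomass_c")
})

test_that("the ornithine carbamoyltransferase reaction can be added and removed", {
  base <- metabolic_model(
    metabolites = c("ornithine", "carbamoyl_p", "h", "pi", "citrulline"),
    reactions = data.frame(id = "bio", lb = 0, ub = 1),
    stoich = list(c(citrulline = -1)),
    genes = list(character()), biomass = "bio")
  m <- add_reaction(base, "OCT",
                    c(ornithine = -1, carbamoyl_p = -1, h = 1, pi = 1,
                      citrulline = 1),
                    lb = -1000, ub = 1000, genes = "Otc")
  expect_equal(nrow(m$reactions), nrow(base$reactions) + 1)
  expect_equal(unname(m$genes$OCT), "Otc")
  expect_false(m$reactions$exchange[m$reactions$id == "OCT"])
  # add then remove restores the original model
  m2 <- remove_reaction(m, "OCT")
  expect_equal(as.matrix(m2$S), as.matrix(base$S))
  expect_equal(m2$reactions, base$reactions)
  expect_error(add_reaction(m, "OCT", c(h = 1), 0, 1), "already in use")
  # original untouched by add_reaction
  expect_equal(nrow(base$reactions), 1)
})

test_that("gene sets load from GMT with p-values and invalid records are rejected", {
  gmt <- tempfile(); pv <- tempfile()
  writeLines(c("s1\tfirst set\tg1\tg2\tg3", "s2\tsecond set\tg3\tg4"), gmt)
  write.table(data.frame(id = c("s1", "s2"), pvalue = c(1e-5, 0.01)),
              pv, sep = "\t", quote = FALSE, row.names = FALSE)
  coll <- read_gene_sets(gmt, pv)
  expect_equal(length(coll), 2L)
  expect_equal(coll$sets$s2, c("g3", "g4"))
  expect_equal(unname(coll$pvalues["s1"]), 1e-5)

  write.table(data.frame(id = c("s1", "s2"), pvalue = c(0, 0.01)),
              pv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_sets(gmt, pv), "\\(0, 1\\]")
  expect_error(gene_set_collection(list(a = character()),
                                   c(a = 0.5)), "non-empty")
})

test_that("evidence tables enforce the six tiers and reject duplicates", {
  ev <- evidence_table(c("T1", "T1"), c("g1", "g2"), c("chea", "encode"))
  f <- tempfile()
  write_evidence(ev, f)
  ev2 <- read_evidence(f)
  expect_equal(as.data.frame(ev2), as.data.frame(ev))
  expect_error(evidence_table("T1", "g1", "encodeX"),
               "metacore_direct.*tfacts")
  expect_error(evidence_table(c("T1", "T1"), c("g1", "g1"),
                              c("chea", "chea")), "duplicate")
})
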
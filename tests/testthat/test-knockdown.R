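test_that("isozyme-buffered and effective genes are told apart", {
  toy <- makeToyNetwork(1, 3, 0, 0, seed = 1)
  g <- geneIds(toy$model)[1]
  cls <- classifyGene(toy$model, g)
  expect_identical(cls$status, "effective")
  expect_length(cls$falsified, 1)

  # pure isozyme pair: buffered, nothing falsified
  mets <- data.frame(id = c("A_c", "B_c"), compartment = "c",
                     boundary = FALSE)
  rxns <- data.frame(id = c("E_A", "R1", "E_B"), lb = 0, ub = 10,
                     gpr = c("", "(gx or gy)", ""))
  S <- matrix(c(1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rxns$id))
  m <- MetabolicModel(S, mets, rxns)
  expect_identical(classifyGene(m, "gx")$status, "buffered")
  expect_length(classifyGene(m, "gx")$falsified, 0)
  expect_error(classifyGene(m, "gz"), "unknown gene")
})

test_that("classification matches the truth-table oracle on random GPRs", {
  genes <- c("g1", "g2", "g3", "g4")
  set.seed(1234)
  for (i in 1:50) {
    rules <- vapply(1:3, function(k) randomGPRText(genes), character(1))
    mets <- data.frame(id = "x1", compartment = "c", boundary = FALSE)
    rxns <- data.frame(id = paste0("r", 1:3), lb = 0, ub = 1, gpr = rules)
    m <- MetabolicModel(matrix(0, 1, 3), mets, rxns)
    for (g in geneIds(m)) {
      cls <- classifyGene(m, g)
      falsifiedOracle <- paste0("r", 1:3)[vapply(rules, function(rl)
        grepl(g, rl, fixed = TRUE) &&
          !gprEvalOracle(rl, setdiff(genes, g), genes),
        logical(1))]
      expect_setequal(cls$falsified, falsifiedOracle)
      expect_identical(cls$status,
                       if (length(falsifiedOracle)) "effective"
                       else "buffered")
    }
  }
})

test_that("knockdown caps falsified reactions at envelope over fold", {
  m <- chainModel()
  po <- addProductionObjective(m, "C_c")
  env <- fva(po$model, po$reaction)
  cfg <- knockdownConfig(foldReduction = 70)
  kd <- applyKnockdown(po$model, "g_ab", env, cfg)
  ri <- reactions(kd)
  expect_equal(ri["R_AB", "lb"], 0)
  expect_equal(ri["R_AB", "ub"], 10 / 70, tolerance = 1e-9)
  # untouched elsewhere
  expect_equal(ri["R_BC", "ub"], 1000)
  expect_equal(fba(kd, po$reaction)$objective, 10 / 70, tolerance = 1e-9)

  # fold 1 is the identity up to envelope intersection: optima unchanged
  kd1 <- applyKnockdown(po$model, "g_ab", env, knockdownConfig(1))
  expect_equal(fba(kd1, po$reaction)$objective, 10, tolerance = 1e-9)

  # a missing envelope entry is an error
  envBad <- new("FluxEnvelope",
                ranges = matrix(c(0, 10), 1, 2,
                                dimnames = list("E_C", c("min", "max"))),
                objective = po$reaction, optimum = 10,
                optimalityFraction = 0)
  expect_error(applyKnockdown(po$model, "g_ab", envBad, cfg),
               "missing falsified reaction")
})

test_that("gene impact finds downstream metabolites and respects buffering", {
  m <- chainModel()
  cfg <- knockdownConfig(foldReduction = 70)
  imp <- geneImpact(m, "g_ab", cfg)
  expect_setequal(imp$metabolite, c("B_c", "C_c"))
  expect_equal(imp$baseline, c(10, 10), tolerance = 1e-9)
  expect_equal(imp$perturbed, c(10 / 70, 10 / 70), tolerance = 1e-9)
  expect_true(all(imp$perturbed <= imp$baseline))
  expect_true(all(imp$relative_drop > cfg$dropThreshold))

  # g_bc sits downstream: only C is affected
  imp2 <- geneImpact(m, "g_bc", cfg)
  expect_identical(imp2$metabolite, "C_c")

  # an equal-capacity gene-free alternate route absorbs the knockdown
  expect_equal(nrow(geneImpact(compensatedModel(), "g1", cfg)), 0)
})

test_that("affected sets grow with the fold reduction", {
  toy <- makeToyNetwork(2, 4, 0.3, 0.2, seed = 17)
  g <- toy$truth$effectiveGenes[1]
  sets <- lapply(c(2, 10, 70), function(f)
    geneImpact(toy$model, g, knockdownConfig(foldReduction = f))$key)
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("insertion scans recover planted truth and keep count partitions", {
  toy <- makeToyNetwork(3, 3, 0.4, 0.2, seed = 23)
  ins <- makeInsertions(toy$truth, c("A", "B"), 6, 0.5, seed = 4)
  scan <- suppressMessages(scanInsertions(toy$model, ins))
  ct <- scanCounts(scan)
  expect_equal(ct$genes_hit, ct$buffered_genes + ct$effective_genes)
  expect_equal(ct$effective_genes, ct$no_impact_genes + ct$impact_genes)

  hit <- unique(ins$gene)
  expect_setequal(geneStatus(scan)$gene[geneStatus(scan)$status == "impact"],
                  intersect(hit, toy$truth$effectiveGenes))
  for (g in intersect(hit, toy$truth$effectiveGenes)) {
    expect_setequal(unique(impactTable(scan)$key[impactTable(scan)$gene == g]),
                    toy$truth$impacts[[g]])
  }
  # donor overlap can never exceed a donor's own count
  dc <- scan@donorCounts
  for (i in seq_len(nrow(scan@overlaps)))
    expect_lte(scan@overlaps$overlap[i], min(dc$affected_metabolites))
})

test_that("identical donors give identical counts and full overlap", {
  toy <- makeToyNetwork(2, 3, 0.3, 0, seed = 29)
  g <- toy$truth$effectiveGenes
  ins <- rbind(data.frame(donor = "A", gene = g),
               data.frame(donor = "B", gene = g))
  scan <- scanInsertions(toy$model, ins)
  dc <- scan@donorCounts
  expect_equal(dc$affected_metabolites[1], dc$affected_metabolites[2])
  expect_equal(scan@overlaps$overlap[1], dc$affected_metabolites[1])
})

test_that("unmappable genes are counted, empty tables refused", {
  toy <- makeToyNetwork(1, 3, 0, 0, seed = 31)
  ins <- data.frame(donor = "A",
                    gene = c(geneIds(toy$model)[1], "not_a_gene"))
  scan <- suppressMessages(scanInsertions(toy$model, ins))
  expect_identical(scan@unmapped, "not_a_gene")
  expect_equal(scanCounts(scan)$insertions_in_model, 1)
  expect_error(scanInsertions(toy$model, ins[0, ]), "empty insertion")
})
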
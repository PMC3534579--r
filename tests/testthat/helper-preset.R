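# The "toy" preset: a small end-to-end study with planted truth —
# two 3-metabolite chains, biased insertions from two donors, planted
# target sites and a disease map seeded from the truly affected pool.
toyPresetInputs <- function(seed = 71) {
  toy <- makeToyNetwork(2, 3, 0.3, 0.2, seed = seed)
  ins <- makeInsertions(toy$truth, c("A", "B"), 5, 1, seed = seed + 1)
  gs <- makeGeneSequences(geneIds(toy$model), length = 120,
                          plantedSitesPerGene = 2, seed = seed + 2)
  pool <- sort(unique(unlist(toy$truth$impacts)))
  keys <- unique(stripCompartment(
    metabolites(toy$model)$id[!metabolites(toy$model)$boundary],
    c("c", "b")))
  dm <- makeDiseaseMap(keys, 3, 3, plantedKeys = pool, seed = seed + 3)
  list(toy = toy, ins = ins, seqs = gs$sequences, dm = dm)
}
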
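makeIndex <- function(counts) {
  sites <- lapply(counts, function(k)
    data.frame(position = seq_len(k), strand = rep("+", k),
               mismatches = rep(0L, k)))
  new("TargetSiteIndex", sites = sites, maxMismatch = 1L)
}

test_that("sampling follows site weights and is seed-reproducible", {
  idx <- makeIndex(c(gOnly = 5L))
  s <- sampleInsertionSets(idx, m = 3, N = 4, seed = 1)
  expect_true(all(s == "gOnly"))
  expect_equal(dim(s), c(3, 4))

  idx2 <- makeIndex(c(g1 = 900L, g2 = 100L))
  s2 <- sampleInsertionSets(idx2, m = 1, N = 20000, seed = 2)
  freq <- mean(s2 == "g1")
  se <- sqrt(0.9 * 0.1 / 20000)
  expect_lt(abs(freq - 0.9), 3 * se)

  expect_identical(sampleInsertionSets(idx2, 5, 50, seed = 7),
                   sampleInsertionSets(idx2, 5, 50, seed = 7))
  expect_error(sampleInsertionSets(idx2, 0, 10), "m must be")
  expect_error(sampleInsertionSets(idx2, 5, 0), "N must be")
  expect_error(sampleInsertionSets(makeIndex(c(g = 0L)), 1, 1),
               "no target sites")
  expect_error(sampleInsertionSets(idx2, 2000, 1, replace = FALSE),
               "without replacement")
})

test_that("empirical p follows (n+1)/(N+1) with its exact bounds", {
  idx <- makeIndex(c(g1 = 10L))
  lookup <- list(g1 = "met1")
  # observed statistic equals every sample's statistic: n = N, p = 1
  et <- enrichmentTest("g1", lookup, list(d1 = "met1"), idx,
                       m = 1, N = 100, seed = 3)
  expect_equal(et$n, 100)
  expect_equal(et$p, 1)

  # unreachable observed statistic: n = 0; with N = 9, p = 0.1
  idx2 <- makeIndex(c(g1 = 5L, g2 = 5L))
  lookup2 <- list(g1 = c("met1", "met2"), g2 = character())
  et2 <- enrichmentTest(c("g1", "g1"),
                        lookup2, list(d1 = c("met1", "met2")),
                        idx2, m = 2, N = 9, seed = 4)
  # force n = 0 by restricting the null to the empty-impact gene
  idx3 <- makeIndex(c(g2 = 5L))
  et3 <- enrichmentTest("g1", lookup2, list(d1 = c("met1", "met2")),
                        idx3, m = 1, N = 9, seed = 5)
  expect_equal(et3$n, 0)
  expect_equal(et3$p, 0.1)
  # p can never be zero and never exceeds 1
  expect_gte(min(et2$p, et3$p), 1 / 10)
  expect_lte(max(et2$p, et3$p), 1)
})

test_that("null mean and SD are the sample stream's own moments", {
  toy <- makeToyNetwork(3, 3, 0.3, 0.2, seed = 41)
  lookup <- toy$truth$impacts
  for (g in toy$truth$genes)
    if (is.null(lookup[[g]])) lookup[[g]] <- character()
  idx <- makeIndex(stats::setNames(rep(2L, length(toy$truth$genes)),
                                   toy$truth$genes))
  keys <- sort(unique(unlist(lookup)))
  dmap <- list(dA = keys[seq_len(min(3, length(keys)))], dB = keys)
  obs <- toy$truth$effectiveGenes[1]
  et <- enrichmentTest(obs, lookup, dmap, idx, m = 4, N = 300, seed = 6)

  # recompute the moments independently from the same seeded stream
  samples <- sampleInsertionSets(idx, 4, 300, seed = 6)
  lk <- lapply(lookup, normalizeMetKey)
  for (d in names(dmap)) {
    stats <- apply(samples, 2, function(gv) {
      aff <- unique(unlist(lk[intersect(unique(gv), names(lk))]))
      length(intersect(aff, normalizeMetKey(dmap[[d]])))
    })
    row <- et[et$disease == d, ]
    expect_equal(row$expected, mean(stats), tolerance = 1e-12)
    expect_equal(row$sd, stats::sd(stats), tolerance = 1e-12)
    obsStat <- length(intersect(
      normalizeMetKey(unique(unlist(lk[obs]))),
      normalizeMetKey(dmap[[d]])))
    expect_equal(row$n, sum(stats >= obsStat))
    expect_equal(row$p, (row$n + 1) / (300 + 1))
  }
})

test_that("p is non-increasing in the observed statistic", {
  toy <- makeToyNetwork(3, 4, 0.2, 0.2, seed = 43)
  lookup <- toy$truth$impacts
  for (g in toy$truth$genes)
    if (is.null(lookup[[g]])) lookup[[g]] <- character()
  idx <- makeIndex(stats::setNames(rep(2L, length(toy$truth$genes)),
                                   toy$truth$genes))
  keys <- sort(unique(unlist(lookup)))
  dmap <- list(d = keys)
  eff <- toy$truth$effectiveGenes
  small <- eff[1]
  large <- eff
  etS <- enrichmentTest(small, lookup, dmap, idx, m = 5, N = 200, seed = 8)
  etL <- enrichmentTest(large, lookup, dmap, idx, m = 5, N = 200, seed = 8)
  expect_gte(etL$observed, etS$observed)
  expect_lte(etL$n, etS$n)
  expect_lte(etL$p, etS$p)
})

test_that("diseases without metabolites are dropped with a warning", {
  idx <- makeIndex(c(g1 = 3L))
  expect_warning(
    et <- enrichmentTest("g1", list(g1 = "m1"),
                         list(good = "m1", empty = character()),
                         idx, m = 1, N = 10, seed = 9),
    "no metabolites")
  expect_identical(et$disease, "good")
})
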
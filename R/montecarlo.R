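# Monte Carlo null model: TE insertions are redistributed uniformly
# across the endonuclease target sites of the model genes; each random
# sample yields a gene multiset whose joint metabolic impact is scored
# exactly like the observed insertion set.

#' Randomly redistribute insertions across target sites
#'
#' Draws \code{N} random samples; in each, \code{m} insertions land
#' independently and uniformly on the target sites of the index
#' (with replacement by default, so a site can be hit twice), and the
#' sample is recorded as the multiset of hit genes. A gene's sampling
#' weight is therefore proportional to its number of target sites.
#'
#' @param index a [TargetSiteIndex-class] with at least one site.
#' @param m insertions per sample (>= 1).
#' @param N number of samples (>= 1).
#' @param seed optional integer; identical seeds give identical
#'   streams.
#' @param replace sample sites with replacement (default TRUE).
#' @return character matrix, \code{m} rows x \code{N} columns, of gene
#'   ids.
#' @examples
#' idx <- buildSiteIndex(c(g1 = "TTAAAA", g2 = "GGGGGG"), c("g1", "g2"))
#' sampleInsertionSets(idx, m = 2, N = 3, seed = 1)
#' @seealso [enrichmentTest()]
#' @export
sampleInsertionSets <- function(index, m, N, seed = NULL, replace = TRUE) {
  if (m < 1) stop("m must be >= 1")
  if (N < 1) stop("N must be >= 1")
  counts <- vapply(index@sites, nrow, integer(1))
  total <- sum(counts)
  if (total == 0) stop("index has no target sites")
  if (!replace && m > total)
    stop("cannot draw ", m, " sites without replacement from ", total)
  geneOfSite <- rep(names(counts), counts)
  draw <- function() {
    if (replace) {
      geneOfSite[sample.int(total, m * N, replace = TRUE)]
    } else {
      unlist(lapply(seq_len(N), function(i)
        geneOfSite[sample.int(total, m, replace = FALSE)]))
    }
  }
  picks <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  matrix(picks, nrow = m, ncol = N)
}

#' Monte Carlo disease-enrichment test of affected metabolites
#'
#' Tests, per disease, whether the observed insertion set perturbs
#' more disease-linked metabolites than random insertions would. The
#' observed statistic is the number of distinct disease-linked
#' metabolite keys in the union of affected-metabolite sets over the
#' observed genes (a gene hit several times contributes its set once).
#' The same statistic is computed for each of \code{N} random samples
#' drawn by [sampleInsertionSets()]; all diseases are scored on the
#' same samples. The one-sided empirical p-value is
#' \eqn{p = (n+1)/(N+1)} with \eqn{n} the number of samples whose
#' statistic is at least the observed one, so \eqn{p} is never zero
#' and its minimum is \eqn{1/(N+1)}.
#'
#' @param observedGenes character vector of observed insertion genes,
#'   one entry per insertion record (duplicates allowed).
#' @param impactLookup named list mapping gene id to its
#'   affected-metabolite key set (see [impactLookup()]); genes sampled
#'   or observed but absent from the lookup contribute nothing.
#' @param diseaseMap a disease map from [loadDiseaseMap()] (named list
#'   of metabolite key sets).
#' @param index a [TargetSiteIndex-class].
#' @param m insertions per random sample; defaults to
#'   \code{length(observedGenes)}.
#' @param N number of random samples (default 100000).
#' @param seed optional integer seed.
#' @param replace passed to [sampleInsertionSets()].
#' @return data.frame sorted by disease name with columns
#'   \code{disease}, \code{expected}, \code{sd}, \code{observed},
#'   \code{n}, \code{N}, \code{p}.
#' @seealso [sampleInsertionSets()], [countLinked()]
#' @export
enrichmentTest <- function(observedGenes, impactLookup, diseaseMap, index,
                           m = NULL, N = 100000, seed = NULL,
                           replace = TRUE) {
  if (!length(observedGenes)) stop("no observed genes")
  if (is.null(m)) m <- length(observedGenes)
  keep <- lengths(diseaseMap) > 0
  if (any(!keep)) {
    warning("excluding disease(s) with no metabolites: ",
            paste(names(diseaseMap)[!keep], collapse = ", "))
    diseaseMap <- diseaseMap[keep]
  }
  if (!length(diseaseMap)) stop("empty disease map")
  diseases <- sort(names(diseaseMap))
  diseaseMap <- diseaseMap[diseases]

  impactLookup <- lapply(impactLookup, normalizeMetKey)
  affectedOf <- function(genes) {
    unique(unlist(impactLookup[intersect(unique(genes),
                                         names(impactLookup))],
                  use.names = FALSE))
  }
  obsKeys <- affectedOf(observedGenes)
  observed <- vapply(diseaseMap, function(s)
    length(intersect(obsKeys, s)), integer(1))

  samples <- sampleInsertionSets(index, m, N, seed = seed,
                                 replace = replace)
  stat <- matrix(0L, nrow = length(diseases), ncol = N,
                 dimnames = list(diseases, NULL))
  for (j in seq_len(N)) {
    keys <- affectedOf(samples[, j])
    if (length(keys)) {
      stat[, j] <- vapply(diseaseMap, function(s)
        length(intersect(keys, s)), integer(1))
    }
  }
  n <- rowSums(stat >= observed[diseases])
  data.frame(
    disease = diseases,
    expected = rowMeans(stat),
    sd = apply(stat, 1, stats::sd),
    observed = unname(observed[diseases]),
    n = unname(n),
    N = N,
    p = unname((n + 1) / (N + 1)),
    row.names = NULL,
    stringsAsFactors = FALSE)
}
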
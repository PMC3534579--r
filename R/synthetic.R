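# Synthetic inputs with known ground truth: toy chain networks with
# isozyme/complex GPRs (hand-computable production optima), gene
# sequences with planted endonuclease target sites, multi-donor
# insertion tables, and disease maps with optional planted enrichment.

#' Generate a toy chain metabolic network with known knockdown truth
#'
#' Builds \code{nChains} independent linear pathways. Chain \eqn{i}
#' takes up a boundary species, converts it through
#' \code{chainLength} internal metabolites with unit stoichiometry and
#' capacity 10 on every reaction, and exports the terminal metabolite.
#' Each internal conversion is assigned a GPR drawn per the given
#' fractions: an isozyme OR-pair (knockdown buffered), a complex
#' AND-pair (either gene falsifies the reaction) or a sole gene. Every
#' gene catalyses exactly one reaction, so the metabolites truly
#' affected by a gene's knockdown are exactly the metabolites
#' downstream of its reaction in the chain — recorded in the returned
#' truth.
#'
#' @param nChains number of independent chains (>= 1).
#' @param chainLength internal metabolites per chain (>= 2).
#' @param isozymeFraction fraction of conversions with an OR-pair GPR.
#' @param complexFraction fraction with an AND-pair GPR.
#' @param seed integer seed; same seed, same model and truth.
#' @return list with \code{model} (a [MetabolicModel-class]) and
#'   \code{truth}: \code{effectiveGenes}, \code{bufferedGenes},
#'   \code{impacts} (named list gene -> truly affected
#'   compartment-stripped metabolite keys), \code{genes} (all model
#'   genes), \code{capacity}.
#' @examples
#' toy <- makeToyNetwork(2, 3, 0.3, 0.2, seed = 42)
#' toy$model
#' toy$truth$effectiveGenes
#' @seealso [scanInsertions()], [makeInsertions()]
#' @export
makeToyNetwork <- function(nChains, chainLength, isozymeFraction,
                           complexFraction, seed) {
  stopifnot(nChains >= 1, chainLength >= 2,
            isozymeFraction >= 0, complexFraction >= 0,
            isozymeFraction + complexFraction <= 1)
  withr::with_seed(seed, {
    metId <- character(); metComp <- character(); metBnd <- logical()
    rxnId <- character(); lb <- numeric(); ub <- numeric()
    gpr <- character()
    ii <- integer(); jj <- integer(); xx <- numeric()
    effective <- character(); buffered <- character()
    impacts <- list()
    cap <- 10

    addMet <- function(id, comp, bnd) {
      metId <<- c(metId, id); metComp <<- c(metComp, comp)
      metBnd <<- c(metBnd, bnd)
      length(metId)
    }
    addRxn <- function(id, stoich, l, u, rule = "") {
      rxnId <<- c(rxnId, id); lb <<- c(lb, l); ub <<- c(ub, u)
      gpr <<- c(gpr, rule)
      j <- length(rxnId)
      for (k in seq_along(stoich)) {
        ii <<- c(ii, stoich[[k]][1]); jj <<- c(jj, j)
        xx <<- c(xx, stoich[[k]][2])
      }
    }

    for (i in seq_len(nChains)) {
      ext <- addMet(sprintf("ext%d_b", i), "b", TRUE)
      rows <- vapply(seq_len(chainLength), function(j)
        addMet(sprintf("m%d_%d_c", i, j), "c", FALSE), numeric(1))
      addRxn(sprintf("U%d", i), list(c(ext, -1), c(rows[1], 1)), 0, cap)
      for (j in seq_len(chainLength - 1)) {
        u <- stats::runif(1)
        ga <- sprintf("g%d_%da", i, j)
        if (u < isozymeFraction) {
          gb <- sprintf("g%d_%db", i, j)
          rule <- sprintf("(%s or %s)", ga, gb)
          buffered <- c(buffered, ga, gb)
          downstream <- NULL
        } else if (u < isozymeFraction + complexFraction) {
          gb <- sprintf("g%d_%db", i, j)
          rule <- sprintf("(%s and %s)", ga, gb)
          effective <- c(effective, ga, gb)
          downstream <- c(ga, gb)
        } else {
          rule <- ga
          effective <- c(effective, ga)
          downstream <- ga
        }
        if (!is.null(downstream)) {
          keys <- sprintf("m%d_%d", i, (j + 1):chainLength)
          for (g in downstream) impacts[[g]] <- keys
        }
        addRxn(sprintf("R%d_%d", i, j),
               list(c(rows[j], -1), c(rows[j + 1], 1)), 0, cap, rule)
      }
      addRxn(sprintf("E%d", i), list(c(rows[chainLength], -1)), 0, cap)
    }

    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(length(metId), length(rxnId)))
    model <- MetabolicModel(
      S,
      metInfo = data.frame(id = metId, name = metId,
                           compartment = metComp, boundary = metBnd,
                           stringsAsFactors = FALSE),
      rxnInfo = data.frame(id = rxnId, lb = lb, ub = ub, gpr = gpr,
                           stringsAsFactors = FALSE))
    list(model = model,
         truth = list(effectiveGenes = sort(effective),
                      bufferedGenes = sort(buffered),
                      impacts = impacts,
                      genes = geneIds(model),
                      capacity = cap))
  })
}

#' Generate gene sequences with planted endonuclease target sites
#'
#' Background sequence is sampled at the requested GC content and then
#' iteratively repaired until it contains no window within the allowed
#' mismatch distance of the target hexamer on either strand; exact
#' target sites (TTAAAA forward or TTTTAA, a minus-strand site) are
#' then planted at recorded non-overlapping positions. Scanning the
#' output therefore finds exactly the planted sites, which makes
#' per-gene site counts deterministic.
#'
#' @param genes character vector of gene ids.
#' @param length sequence length per gene (>= \code{6 * (planted+1)}).
#' @param plantedSitesPerGene integer scalar or named vector (per
#'   gene): number of sites to plant.
#' @param gcContent background GC fraction (default 0.4, in the range
#'   of human genic sequence).
#' @param seed integer seed.
#' @param maxMismatch scan stringency the background is cleaned
#'   against (default 1).
#' @return list with \code{sequences} (named
#'   [Biostrings::DNAStringSet]) and \code{sites} (data.frame
#'   \code{gene}, \code{position}, \code{strand}).
#' @seealso [scanTargetSites()], [buildSiteIndex()]
#' @export
makeGeneSequences <- function(genes, length = 1000, plantedSitesPerGene = 1,
                              gcContent = 0.4, seed = 1, maxMismatch = 1) {
  nPlant <- if (is.null(names(plantedSitesPerGene)))
    stats::setNames(rep(plantedSitesPerGene[1], base::length(genes)), genes)
  else plantedSitesPerGene[genes]
  stopifnot(!anyNA(nPlant), all(length >= 6 * (nPlant + 1)))
  probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
             G = gcContent / 2, T = (1 - gcContent) / 2)
  bases <- names(probs)
  withr::with_seed(seed, {
    seqs <- character(base::length(genes))
    siteRows <- list()
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      k <- nPlant[[g]]
      x <- sample(bases, length, replace = TRUE, prob = probs)
      # plant first so repair can protect the planted windows
      if (k > 0) {
        slots <- seq(1L, length - 5L, by = 11L)
        if (base::length(slots) < k)
          stop("cannot place ", k, " non-overlapping sites in length ",
               length)
        pos <- sort(sample(slots, k))
        strands <- sample(c("+", "-"), k, replace = TRUE)
        for (s in seq_len(k)) {
          motif <- if (strands[s] == "+") L1_TARGET else L1_TARGET_RC
          x[pos[s]:(pos[s] + 5L)] <- strsplit(motif, "")[[1]]
        }
        siteRows[[gi]] <- data.frame(gene = g, position = pos,
                                     strand = strands,
                                     stringsAsFactors = FALSE)
        protected <- unlist(lapply(pos, function(p) p:(p + 5L)))
      } else {
        siteRows[[gi]] <- data.frame(gene = character(),
                                     position = integer(),
                                     strand = character(),
                                     stringsAsFactors = FALSE)
        protected <- integer()
      }
      plantedKey <- if (k > 0)
        paste(siteRows[[gi]]$position, siteRows[[gi]]$strand) else character()
      for (iter in seq_len(200L)) {
        hits <- scanTargetSites(paste(x, collapse = ""), maxMismatch)
        spurious <- hits[!(paste(hits$position, hits$strand) %in%
                             plantedKey), , drop = FALSE]
        if (!nrow(spurious)) break
        for (p in unique(spurious$position)) {
          win <- setdiff(p:(p + 5L), protected)
          if (base::length(win))
            x[win] <- sample(bases, base::length(win), replace = TRUE,
                             prob = probs)
        }
        if (iter == 200L)
          stop("could not clean background around planted sites for ", g)
      }
      seqs[gi] <- paste(x, collapse = "")
    }
    names(seqs) <- genes
    list(sequences = Biostrings::DNAStringSet(seqs),
         sites = do.call(rbind, siteRows))
  })
}

#' Generate a multi-donor TE insertion table
#'
#' Each insertion picks a gene: with probability \code{effectiveBias}
#' uniformly from the truth's effective genes, otherwise uniformly
#' from all model genes. Bias 0 is the uniform null; bias 1 puts every
#' insertion in an effective gene.
#'
#' @param truth the truth component of [makeToyNetwork()].
#' @param donors character vector of donor ids.
#' @param insertionsPerDonor insertions per donor (scalar or per-donor
#'   vector).
#' @param effectiveBias in \code{[0, 1]}.
#' @param seed integer seed.
#' @return data.frame with columns \code{donor}, \code{gene}.
#' @seealso [scanInsertions()]
#' @export
makeInsertions <- function(truth, donors, insertionsPerDonor,
                           effectiveBias, seed) {
  stopifnot(effectiveBias >= 0, effectiveBias <= 1)
  nIns <- rep_len(insertionsPerDonor, length(donors))
  if (effectiveBias > 0 && !length(truth$effectiveGenes))
    stop("truth has no effective genes to bias towards")
  withr::with_seed(seed, {
    rows <- list()
    for (d in seq_along(donors)) {
      useEff <- stats::runif(nIns[d]) < effectiveBias
      gene <- character(nIns[d])
      if (any(useEff))
        gene[useEff] <- sample(truth$effectiveGenes, sum(useEff),
                               replace = TRUE)
      if (any(!useEff))
        gene[!useEff] <- sample(truth$genes, sum(!useEff), replace = TRUE)
      rows[[d]] <- data.frame(donor = donors[d], gene = gene,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a random metabolite-disease map, optionally with planted
#' enrichment
#'
#' Draws \code{nDiseases} random metabolite sets of size
#' \code{setSize} from the supplied key universe. When
#' \code{plantedKeys} is given, one additional disease
#' (\code{"planted_disease"}) is built from those keys (the
#' truly-affected pool of a synthetic truth), so an enrichment test on
#' matching insertions should flag it.
#'
#' @param metaboliteKeys universe of compartment-stripped keys.
#' @param nDiseases number of random diseases.
#' @param setSize metabolites per disease (<= number of keys).
#' @param plantedKeys optional character vector of truly affected keys.
#' @param seed integer seed.
#' @return data.frame with columns \code{disease},
#'   \code{metabolite_key}; the planted disease name is in
#'   \code{attr(, "planted")}.
#' @seealso [enrichmentTest()]
#' @export
makeDiseaseMap <- function(metaboliteKeys, nDiseases, setSize,
                           plantedKeys = NULL, seed = 1) {
  stopifnot(setSize <= length(metaboliteKeys), nDiseases >= 0)
  if (!is.null(plantedKeys) && !length(plantedKeys))
    stop("empty metabolite pool for the planted disease")
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nDiseases), function(i)
      data.frame(disease = sprintf("disease%02d", i),
                 metabolite_key = sample(metaboliteKeys, setSize),
                 stringsAsFactors = FALSE))
    if (!is.null(plantedKeys)) {
      rows[[length(rows) + 1L]] <- data.frame(
        disease = "planted_disease",
        metabolite_key = unique(plantedKeys),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "planted") <- if (is.null(plantedKeys)) NA_character_
      else "planted_disease"
    out
  })
}

#' Turn a disease-map data.frame into the list form used by the tests
#' and [enrichmentTest()]
#'
#' @param mapDf data.frame with columns \code{disease},
#'   \code{metabolite_key} (e.g. from [makeDiseaseMap()]).
#' @return named list of normalized metabolite key sets.
#' @export
diseaseMapList <- function(mapDf) {
  lapply(split(normalizeMetKey(mapDf$metabolite_key), mapDf$disease),
         unique)
}
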
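#' Read a TE insertion table
#'
#' Tab-separated table with header columns \code{donor} and
#' \code{gene_id}; one row per insertion event. Duplicate rows are
#' allowed (a gene hit by several insertions).
#'
#' @param path TSV file.
#' @return data.frame with columns \code{donor}, \code{gene}.
#' @export
readInsertions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("donor", "gene_id")
  if (!all(need %in% names(d)))
    stop("insertion table must have columns: ", paste(need, collapse = ", "))
  data.frame(donor = as.character(d$donor), gene = as.character(d$gene_id),
             stringsAsFactors = FALSE)
}

#' Scan a set of somatic TE insertions against a metabolic model
#'
#' The full knockdown screen. Every distinct insertion-hit gene that
#' maps into the model gene set is classified as isozyme-buffered or
#' effective; each effective gene is knocked down (fold reduction per
#' \code{config}) and the metabolites whose maximal biosynthesis drops
#' are recorded. Summary counts follow the partition
#' hit genes = buffered + effective and
#' effective = no-impact + impact. Per-donor affected-metabolite sets
#' (compartment-stripped keys) and their pairwise and all-donor
#' overlaps are reported alongside the pooled analysis. FVA envelopes
#' depend only on the model and the metabolite objective, so they are
#' shared across donors.
#'
#' @param model a [MetabolicModel-class].
#' @param insertions data.frame with columns \code{donor} and
#'   \code{gene} (one row per insertion), or a TSV path accepted by
#'   [readInsertions()].
#' @param config a [knockdownConfig()].
#' @param verbose print progress per gene.
#' @return an [InsertionScan-class].
#' @examples
#' toy <- makeToyNetwork(2, 3, 0.3, 0.2, seed = 7)
#' ins <- makeInsertions(toy$truth, donors = c("A", "B"),
#'                       insertionsPerDonor = 4, effectiveBias = 1, seed = 7)
#' scanInsertions(toy$model, ins)
#' @seealso [geneImpact()], [enrichmentTest()]
#' @export
scanInsertions <- function(model, insertions, config = knockdownConfig(),
                           verbose = FALSE) {
  if (is.character(insertions)) insertions <- readInsertions(insertions)
  if (!nrow(insertions)) stop("empty insertion table")
  stopifnot(all(c("donor", "gene") %in% names(insertions)))

  inModel <- insertions$gene %in% model@genes
  unmapped <- sort(unique(insertions$gene[!inModel]))
  if (length(unmapped))
    message(length(unmapped), " insertion gene(s) not in the model gene set")
  ins <- insertions[inModel, , drop = FALSE]
  if (!nrow(ins)) stop("no insertion maps to a model gene")

  hit <- sort(unique(ins$gene))
  # baseline production, shared across genes
  mets <- nonBoundaryMets(model)
  baselines <- vapply(mets, function(m) maxProduction(model, m), numeric(1))

  status <- character(length(hit)); names(status) <- hit
  nrxn <- integer(length(hit)); names(nrxn) <- hit
  impacts <- list()
  catalysed <- character()
  for (g in hit) {
    if (verbose) message("gene ", g)
    cat_r <- names(Filter(function(tr) g %in% gprGenes(tr), model@gprs))
    catalysed <- union(catalysed, cat_r)
    nrxn[g] <- length(cat_r)
    cls <- classifyGene(model, g)
    if (cls$status == "buffered") {
      status[g] <- "buffered"
      next
    }
    imp <- geneImpact(model, g, config, baselines = baselines)
    status[g] <- if (nrow(imp)) "impact" else "no_impact"
    if (nrow(imp)) impacts[[g]] <- imp
  }
  impactTab <- if (length(impacts)) do.call(rbind, impacts) else
    data.frame(gene = character(), metabolite = character(),
               key = character(), compartment = character(),
               baseline = numeric(), perturbed = numeric(),
               relative_drop = numeric(), stringsAsFactors = FALSE)
  rownames(impactTab) <- NULL

  impactSets <- lapply(impacts, function(d) unique(d$key))
  donorKeys <- function(genes) {
    unique(unlist(impactSets[intersect(genes, names(impactSets))]))
  }
  donors <- sort(unique(ins$donor))
  perDonor <- lapply(donors, function(d) unique(ins$gene[ins$donor == d]))
  names(perDonor) <- donors
  donorMetSets <- lapply(perDonor, donorKeys)

  donorCounts <- data.frame(
    donor = donors,
    insertions = vapply(donors, function(d) sum(ins$donor == d), integer(1)),
    genes_hit = lengths(perDonor),
    impact_genes = vapply(perDonor, function(g)
      sum(status[intersect(g, hit)] == "impact"), integer(1)),
    affected_metabolites = lengths(donorMetSets),
    stringsAsFactors = FALSE)
  rownames(donorCounts) <- NULL

  ov <- list()
  if (length(donors) >= 2) {
    prs <- utils::combn(donors, 2, simplify = FALSE)
    for (p in prs) {
      ov[[length(ov) + 1L]] <- data.frame(
        donors = paste(p, collapse = "&"),
        overlap = length(intersect(donorMetSets[[p[1]]],
                                   donorMetSets[[p[2]]])),
        stringsAsFactors = FALSE)
    }
    if (length(donors) > 2) {
      ov[[length(ov) + 1L]] <- data.frame(
        donors = paste(donors, collapse = "&"),
        overlap = length(Reduce(intersect, donorMetSets)),
        stringsAsFactors = FALSE)
    }
  }
  overlaps <- if (length(ov)) do.call(rbind, ov) else
    data.frame(donors = character(), overlap = integer(),
               stringsAsFactors = FALSE)

  counts <- list(
    insertions = nrow(insertions),
    insertions_in_model = nrow(ins),
    genes_hit = length(hit),
    reactions_catalysed = length(catalysed),
    buffered_genes = sum(status == "buffered"),
    effective_genes = sum(status != "buffered"),
    no_impact_genes = sum(status == "no_impact"),
    impact_genes = sum(status == "impact"),
    affected_metabolites = length(unique(impactTab$key))
  )

  new("InsertionScan",
      impacts = impactTab,
      geneStatus = data.frame(gene = hit, status = unname(status[hit]),
                              n_reactions = unname(nrxn[hit]),
                              stringsAsFactors = FALSE),
      counts = counts,
      donorCounts = donorCounts,
      overlaps = overlaps,
      unmapped = unmapped)
}

#' Accessors for InsertionScan
#'
#' \code{impactTable()} returns the long gene-by-metabolite table,
#' \code{geneStatus()} the per-gene classification and
#' \code{scanCounts()} the pooled summary counts.
#'
#' @param object an [InsertionScan-class].
#' @name InsertionScan-accessors
#' @aliases impactTable geneStatus scanCounts
NULL

#' @rdname InsertionScan-accessors
#' @export
setMethod("impactTable", "InsertionScan", function(object) object@impacts)

#' @rdname InsertionScan-accessors
#' @export
setMethod("geneStatus", "InsertionScan", function(object) object@geneStatus)

#' @rdname InsertionScan-accessors
#' @export
setMethod("scanCounts", "InsertionScan", function(object) object@counts)

setMethod("show", "InsertionScan", function(object) {
  ct <- object@counts
  cat("InsertionScan:", ct$insertions, "insertions,",
      ct$genes_hit, "model genes hit catalysing",
      ct$reactions_catalysed, "reactions\n")
  cat("  buffered:", ct$buffered_genes,
      " effective:", ct$effective_genes,
      " (no impact:", ct$no_impact_genes,
      ", impact:", paste0(ct$impact_genes, ")"), "\n")
  cat("  distinct affected metabolites:", ct$affected_metabolites, "\n")
  if (nrow(object@donorCounts) > 1) {
    cat("  donors:", paste(object@donorCounts$donor, collapse = ", "), "\n")
  }
})

#' Affected-metabolite lookup per gene
#'
#' Builds the gene-to-affected-metabolite-key map used as the
#' per-gene statistic source by [enrichmentTest()]. Genes screened
#' but without impact map to empty sets.
#'
#' @param scan an [InsertionScan-class].
#' @return named list of character vectors (compartment-stripped keys).
#' @export
impactLookup <- function(scan) {
  tab <- scan@impacts
  lk <- split(tab$key, tab$gene)
  lk <- lapply(lk, unique)
  for (g in scan@geneStatus$gene)
    if (is.null(lk[[g]])) lk[[g]] <- character()
  lk
}
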
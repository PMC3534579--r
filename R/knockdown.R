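#' Knockdown configuration
#'
#' Parameters of the in-silico partial knockdown. Intronic L1
#' insertions in sense orientation reduce expression of the host gene
#' about 70-fold; flux through the reactions the gene catalyses is
#' assumed to fall by the same linear factor, so 70 is the default
#' fold reduction.
#'
#' @param foldReduction fold by which falsified reactions' attainable
#'   flux is divided (>= 1; default 70).
#' @param dropThreshold minimal relative drop in maximal production for
#'   a metabolite to count as affected (default 1e-6, the LP noise
#'   floor).
#' @param productionFloor baseline production below which a metabolite
#'   is treated as not producible and skipped (default 1e-9).
#' @param boundsMode \code{"envelope"} (default): knocked bounds are
#'   the FVA envelope under the current production objective divided by
#'   the fold; \code{"raw"}: the model's raw bounds divided by the
#'   fold.
#' @param optimalityFraction passed to [fva()] when envelopes are
#'   computed (default 0).
#' @return list of class \code{"KnockdownConfig"}.
#' @export
knockdownConfig <- function(foldReduction = 70, dropThreshold = 1e-6,
                            productionFloor = 1e-9,
                            boundsMode = c("envelope", "raw"),
                            optimalityFraction = 0) {
  stopifnot(foldReduction >= 1, dropThreshold > 0, productionFloor >= 0)
  boundsMode <- match.arg(boundsMode)
  structure(list(foldReduction = foldReduction,
                 dropThreshold = dropThreshold,
                 productionFloor = productionFloor,
                 boundsMode = boundsMode,
                 optimalityFraction = optimalityFraction),
            class = "KnockdownConfig")
}

#' Classify a gene as isozyme-buffered or effective
#'
#' Evaluates every reaction's GPR with the gene set absent and all
#' other genes present. Reactions whose rule turns false are
#' "falsified" — the gene's loss removes their catalytic capacity. A
#' gene falsifying no reaction is buffered (an isozyme or a redundant
#' complex member keeps every rule true) and its knockdown can have no
#' metabolic effect.
#'
#' @param model a [MetabolicModel-class].
#' @param gene a model gene id.
#' @return list with \code{status} (\code{"buffered"} or
#'   \code{"effective"}) and \code{falsified} (character vector of
#'   reaction ids).
#' @examples
#' toy <- makeToyNetwork(2, 3, 0.5, 0, seed = 1)$model
#' classifyGene(toy, geneIds(toy)[1])
#' @seealso [applyKnockdown()], [geneImpact()]
#' @export
classifyGene <- function(model, gene) {
  if (!gene %in% model@genes) stop("unknown gene: ", gene)
  falsified <- character()
  for (rid in model@rxnInfo$id) {
    tr <- model@gprs[[rid]]
    if (is.null(tr) || !(gene %in% gprGenes(tr))) next
    if (!evalGPR(tr, absent = gene)) falsified <- c(falsified, rid)
  }
  list(status = if (length(falsified)) "effective" else "buffered",
       falsified = falsified)
}

scaledBounds <- function(lb, ub, vmin, vmax, f) {
  # knocked capacity: envelope scaled 1/f in magnitude, clipped to the
  # correct sign side, intersected with the original bounds
  c(max(lb, min(vmin / f, 0)), min(ub, max(vmax / f, 0)))
}

#' Apply a partial knockdown of one gene to a model
#'
#' For each reaction falsified by removing \code{gene} (see
#' [classifyGene()]), shrinks the flux bounds to the attainable flux
#' envelope divided by the fold reduction — a linear coupling of
#' expression to catalytic capacity. Reversible reactions are scaled on
#' both sides. All other reactions are untouched; a new model is
#' returned.
#'
#' @param model a [MetabolicModel-class].
#' @param gene a model gene id.
#' @param envelope a [FluxEnvelope-class] computed under the production
#'   objective currently being evaluated; it must cover every falsified
#'   reaction. Ignored (may be \code{NULL}) when
#'   \code{config$boundsMode == "raw"}.
#' @param config a [knockdownConfig()].
#' @return a new [MetabolicModel-class] with tightened bounds.
#' @examples
#' toy <- makeToyNetwork(1, 3, 0, 0, seed = 1)$model
#' g <- geneIds(toy)[1]
#' env <- fva(toy, reactions(toy)$id[1])
#' kd <- applyKnockdown(toy, g, env, knockdownConfig(foldReduction = 70))
#' @seealso [geneImpact()]
#' @export
applyKnockdown <- function(model, gene, envelope, config = knockdownConfig()) {
  cls <- classifyGene(model, gene)
  if (!length(cls$falsified)) return(model)
  ri <- model@rxnInfo
  f <- config$foldReduction
  for (rid in cls$falsified) {
    j <- match(rid, ri$id)
    if (config$boundsMode == "raw") {
      vmin <- ri$lb[j]; vmax <- ri$ub[j]
    } else {
      if (is.null(envelope) || !rid %in% rownames(envelope@ranges))
        stop("envelope is missing falsified reaction ", rid)
      vmin <- envelope@ranges[rid, "min"]
      vmax <- envelope@ranges[rid, "max"]
    }
    bb <- scaledBounds(ri$lb[j], ri$ub[j], vmin, vmax, f)
    ri$lb[j] <- bb[1]; ri$ub[j] <- bb[2]
  }
  m2 <- model
  m2@rxnInfo <- ri
  validObject(m2)
  m2
}

#' Metabolites whose biosynthesis drops under a gene knockdown
#'
#' For every non-boundary metabolite with baseline maximal production
#' above the production floor, recomputes the maximal production after
#' a fold-reduction knockdown of \code{gene} (envelope per that
#' metabolite's own production objective) and reports the metabolites
#' whose relative drop exceeds the threshold. Buffered genes return an
#' empty table.
#'
#' @param model a [MetabolicModel-class].
#' @param gene a model gene id.
#' @param config a [knockdownConfig()].
#' @param baselines optional named numeric of cached baseline maximal
#'   production rates (names = metabolite ids); missing entries are
#'   computed.
#' @return data.frame with columns \code{gene}, \code{metabolite},
#'   \code{key} (compartment-stripped), \code{compartment},
#'   \code{baseline}, \code{perturbed}, \code{relative_drop}.
#' @examples
#' toy <- makeToyNetwork(1, 3, 0, 0, seed = 1)
#' geneImpact(toy$model, geneIds(toy$model)[1])
#' @seealso [scanInsertions()], [classifyGene()]
#' @export
geneImpact <- function(model, gene, config = knockdownConfig(),
                       baselines = NULL) {
  cls <- classifyGene(model, gene)
  empty <- data.frame(gene = character(), metabolite = character(),
                      key = character(), compartment = character(),
                      baseline = numeric(), perturbed = numeric(),
                      relative_drop = numeric(), stringsAsFactors = FALSE)
  if (cls$status == "buffered") return(empty)
  mets <- nonBoundaryMets(model)
  rows <- vector("list", length(mets))
  for (i in seq_along(mets)) {
    m <- mets[i]
    base <- if (!is.null(baselines) && m %in% names(baselines))
      baselines[[m]] else maxProduction(model, m)
    if (base <= config$productionFloor) next
    po <- addProductionObjective(model, m)
    env <- NULL
    if (config$boundsMode == "envelope") {
      env <- fva(po$model, po$reaction,
                 optimalityFraction = config$optimalityFraction,
                 reactions = cls$falsified)
    }
    kd <- applyKnockdown(po$model, gene, env, config)
    pert <- fba(kd, po$reaction)$objective
    pert <- min(max(pert, 0), base)   # clamp LP noise
    drop <- (base - pert) / base
    if (drop > config$dropThreshold) {
      rows[[i]] <- data.frame(
        gene = gene, metabolite = m,
        key = metKeys(model, m),
        compartment = model@metInfo[m, "compartment"],
        baseline = base, perturbed = pert, relative_drop = drop,
        stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
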
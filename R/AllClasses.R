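#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t colSums rowSums
NULL

#' MetabolicModel: a stoichiometric network with GPR rules
#'
#' Container for a constraint-based metabolic model: a sparse
#' stoichiometric matrix (metabolites x reactions), per-metabolite
#' annotation (name, compartment, boundary flag), per-reaction flux
#' bounds, and gene-protein-reaction (GPR) boolean rules. Boundary
#' metabolites represent the environment and are exempt from the
#' steady-state constraint.
#'
#' All flux bounds must be finite; models read from SBML without
#' explicit bounds receive the COBRA-conventional defaults
#' (\code{[-1000, 1000]} for reversible reactions, \code{[0, 1000]}
#' otherwise).
#'
#' @slot stoich sparse numeric matrix, metabolites in rows, reactions in
#'   columns; entries are signed stoichiometric coefficients.
#' @slot metInfo data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{boundary}; one row per metabolite, in row
#'   order of \code{stoich}.
#' @slot rxnInfo data.frame with columns \code{id}, \code{lb},
#'   \code{ub}, \code{gpr}; one row per reaction, in column order of
#'   \code{stoich}.
#' @slot gprs list of parsed GPR trees (see [parseGPR()]), one per
#'   reaction; \code{NULL} entries denote reactions with no gene rule.
#' @slot genes character vector: the union of all GPR leaf genes.
#'
#' @seealso [readSBML()], [makeToyNetwork()], [fba()], [fva()]
#' @export
setClass("MetabolicModel",
  representation(
    stoich  = "Matrix",
    metInfo = "data.frame",
    rxnInfo = "data.frame",
    gprs    = "list",
    genes   = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  S <- object@stoich
  mi <- object@metInfo
  ri <- object@rxnInfo
  if (nrow(S) != nrow(mi))
    msg <- c(msg, "stoich rows do not match metInfo rows")
  if (ncol(S) != nrow(ri))
    msg <- c(msg, "stoich columns do not match rxnInfo rows")
  if (anyDuplicated(mi$id))
    msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(ri$id))
    msg <- c(msg, "duplicate reaction ids")
  if (any(!nzchar(mi$compartment)))
    msg <- c(msg, "empty compartment token")
  if (any(!is.finite(ri$lb)) || any(!is.finite(ri$ub)))
    msg <- c(msg, "flux bounds must be finite")
  if (any(ri$lb > ri$ub))
    msg <- c(msg, "lower bound exceeds upper bound")
  if (length(object@gprs) != nrow(ri))
    msg <- c(msg, "gprs length does not match reaction count")
  leafGenes <- unique(unlist(lapply(object@gprs, gprGenes)))
  if (!setequal(leafGenes, object@genes))
    msg <- c(msg, "gene set does not equal union of GPR leaves")
  if (length(msg)) msg else TRUE
})

#' FluxEnvelope: per-reaction flux ranges under a production objective
#'
#' Result of flux variability analysis: for each reaction the minimal
#' and maximal steady-state flux compatible with the bounds and,
#' optionally, with the objective attaining at least a stated fraction
#' of its optimum.
#'
#' @slot ranges numeric matrix with columns \code{min} and \code{max},
#'   one row per analysed reaction (rownames are reaction ids).
#' @slot objective id of the objective reaction the envelope was
#'   computed under.
#' @slot optimum the FBA optimum of that objective.
#' @slot optimalityFraction the fraction of the optimum enforced while
#'   ranging each reaction (0 = unconstrained objective).
#'
#' @seealso [fva()], [applyKnockdown()]
#' @export
setClass("FluxEnvelope",
  representation(
    ranges = "matrix",
    objective = "character",
    optimum = "numeric",
    optimalityFraction = "numeric"
  )
)

setValidity("FluxEnvelope", function(object) {
  r <- object@ranges
  if (!identical(colnames(r), c("min", "max")))
    return("ranges must have columns 'min' and 'max'")
  if (any(r[, "min"] > r[, "max"] + 1e-6))
    return("envelope min exceeds max")
  TRUE
})

#' TargetSiteIndex: endonuclease target sites per gene
#'
#' Per-gene positions of L1 endonuclease target hexamers (TTAAAA and
#' within-mismatch variants, both strands) found by [scanTargetSites()]
#' over a set of gene sequences.
#'
#' @slot sites named list (one element per gene) of data.frames with
#'   columns \code{position} (1-based start of the hexamer on the
#'   forward sequence), \code{strand} (\code{"+"}/\code{"-"}) and
#'   \code{mismatches}; genes with no sites keep a zero-row data.frame.
#' @slot maxMismatch maximum Hamming distance allowed in the scan.
#'
#' @seealso [buildSiteIndex()], [sampleInsertionSets()]
#' @export
setClass("TargetSiteIndex",
  representation(
    sites = "list",
    maxMismatch = "integer"
  )
)

setValidity("TargetSiteIndex", function(object) {
  if (is.null(names(object@sites)) && length(object@sites))
    return("sites list must be named by gene id")
  ok <- vapply(object@sites, function(d) {
    is.data.frame(d) &&
      all(c("position", "strand", "mismatches") %in% names(d)) &&
      all(d$mismatches <= object@maxMismatch)
  }, logical(1))
  if (!all(ok)) return("malformed per-gene site table")
  TRUE
})

#' InsertionScan: knockdown-impact summary of a TE insertion set
#'
#' Result bundle of [scanInsertions()]: the long gene-by-metabolite
#' impact table, the per-gene classification (buffered / effective
#' without impact / impact), pooled summary counts mirroring the
#' published arithmetic (hit genes = buffered + effective;
#' effective = no-impact + impact), per-donor counts and donor
#' overlaps of affected metabolites.
#'
#' @slot impacts data.frame: \code{gene}, \code{metabolite},
#'   \code{key} (compartment-stripped), \code{compartment},
#'   \code{baseline}, \code{perturbed}, \code{relative_drop}.
#' @slot geneStatus data.frame: \code{gene}, \code{status} (one of
#'   \code{buffered}, \code{no_impact}, \code{impact}),
#'   \code{n_reactions} catalysed.
#' @slot counts named list of pooled summary counts.
#' @slot donorCounts data.frame of per-donor counts.
#' @slot overlaps data.frame of pairwise and all-donor overlaps of
#'   affected metabolite keys.
#' @slot unmapped character: insertion genes absent from the model.
#'
#' @seealso [scanInsertions()]
#' @export
setClass("InsertionScan",
  representation(
    impacts = "data.frame",
    geneStatus = "data.frame",
    counts = "list",
    donorCounts = "data.frame",
    overlaps = "data.frame",
    unmapped = "character"
  )
)
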
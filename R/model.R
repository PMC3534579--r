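#' Construct a MetabolicModel
#'
#' Low-level constructor assembling a [MetabolicModel-class] from a
#' stoichiometric matrix and annotation tables. GPR rule strings are
#' parsed with [parseGPR()] and the model gene set is derived as the
#' union of all rule leaves.
#'
#' @param stoich numeric (sparse or dense) matrix, metabolites x
#'   reactions; dimnames are taken as ids when \code{metInfo} /
#'   \code{rxnInfo} omit them.
#' @param metInfo data.frame with columns \code{id}, and optionally
#'   \code{name}, \code{compartment}, \code{boundary}.
#' @param rxnInfo data.frame with columns \code{id}, \code{lb},
#'   \code{ub}, and optionally \code{gpr} (rule strings).
#' @return a validated [MetabolicModel-class].
#' @seealso [readSBML()], [makeToyNetwork()]
#' @export
MetabolicModel <- function(stoich, metInfo, rxnInfo) {
  stoich <- Matrix::Matrix(stoich, sparse = TRUE)
  if (is.null(metInfo$name)) metInfo$name <- metInfo$id
  if (is.null(metInfo$compartment)) metInfo$compartment <- "c"
  if (is.null(metInfo$boundary)) metInfo$boundary <- FALSE
  if (is.null(rxnInfo$gpr)) rxnInfo$gpr <- ""
  metInfo <- as.data.frame(metInfo, stringsAsFactors = FALSE)
  rxnInfo <- as.data.frame(rxnInfo, stringsAsFactors = FALSE)
  if (anyDuplicated(metInfo$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxnInfo$id)) stop("duplicate reaction ids")
  rownames(metInfo) <- metInfo$id
  rownames(rxnInfo) <- rxnInfo$id
  dimnames(stoich) <- list(metInfo$id, rxnInfo$id)
  gprs <- lapply(rxnInfo$gpr, parseGPR)
  names(gprs) <- rxnInfo$id
  genes <- sort(unique(unlist(lapply(gprs, gprGenes))))
  if (is.null(genes)) genes <- character()
  new("MetabolicModel", stoich = stoich, metInfo = metInfo,
      rxnInfo = rxnInfo, gprs = gprs, genes = genes)
}

#' Accessors for MetabolicModel
#'
#' \code{metabolites()} and \code{reactions()} return the annotation
#' data.frames; \code{geneIds()} the model gene set;
#' \code{stoichMatrix()} the sparse stoichiometric matrix;
#' \code{fluxBounds()} a two-column matrix of lower/upper flux bounds;
#' \code{gprRules()} the parsed GPR trees.
#'
#' @param object a [MetabolicModel-class].
#' @param ... unused.
#' @name MetabolicModel-accessors
#' @aliases metabolites reactions geneIds stoichMatrix fluxBounds gprRules
NULL

#' @rdname MetabolicModel-accessors
#' @export
setMethod("metabolites", "MetabolicModel", function(object, ...) object@metInfo)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("reactions", "MetabolicModel", function(object, ...) object@rxnInfo)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("geneIds", "MetabolicModel", function(object) object@genes)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("stoichMatrix", "MetabolicModel", function(object) object@stoich)

#' @rdname MetabolicModel-accessors
#' @export
setMethod("fluxBounds", "MetabolicModel", function(object) {
  cbind(lb = object@rxnInfo$lb, ub = object@rxnInfo$ub)
})

#' @rdname MetabolicModel-accessors
#' @export
setMethod("gprRules", "MetabolicModel", function(object) object@gprs)

metIds <- function(model) model@metInfo$id
rxnIds <- function(model) model@rxnInfo$id
nonBoundaryMets <- function(model) model@metInfo$id[!model@metInfo$boundary]

setMethod("show", "MetabolicModel", function(object) {
  nb <- sum(!object@metInfo$boundary)
  cat("MetabolicModel:",
      nrow(object@metInfo), "metabolites",
      sprintf("(%d non-boundary),", nb),
      nrow(object@rxnInfo), "reactions,",
      length(object@genes), "genes\n")
  cat("  compartments:",
      paste(sort(unique(object@metInfo$compartment)), collapse = ", "), "\n")
})

#' @rdname FluxEnvelope-accessors
#' @param object a [FluxEnvelope-class].
#' @param ... unused.
#' @export
setMethod("fluxRanges", "FluxEnvelope", function(object, ...) object@ranges)

setMethod("show", "FluxEnvelope", function(object) {
  cat("FluxEnvelope under objective", object@objective,
      sprintf("(optimum %.6g, fraction %g):", object@optimum,
              object@optimalityFraction),
      nrow(object@ranges), "reactions\n")
})

#' Add (or reuse) a production objective for a metabolite
#'
#' Ensures the model contains a single-metabolite export reaction
#' consuming one unit of \code{met} — the production objective used to
#' quantify the maximal biosynthesis rate of that metabolite. If such
#' an export already exists it is reused and the model is returned
#' unchanged; otherwise a reaction with stoichiometry
#' \code{{met: -1}} and bounds \code{[0, 1000]} is appended. The input
#' model is never modified in place.
#'
#' @param model a [MetabolicModel-class].
#' @param met id of a non-boundary metabolite.
#' @return list with elements \code{model} (the possibly extended
#'   model) and \code{reaction} (the id of the production objective).
#' @examples
#' toy <- makeToyNetwork(1, 3, 0, 0, seed = 1)$model
#' obj <- addProductionObjective(toy, metabolites(toy)$id[2])
#' fba(obj$model, obj$reaction)$objective
#' @seealso [maxProduction()], [fva()]
#' @export
addProductionObjective <- function(model, met) {
  mi <- model@metInfo
  if (!met %in% mi$id) stop("unknown metabolite: ", met)
  if (mi[met, "boundary"])
    stop("metabolite ", met,
         " is a boundary species; production objectives are only ",
         "defined for non-boundary metabolites")
  S <- model@stoich
  row <- which(mi$id == met)
  # reuse an existing pure export: only this metabolite, coefficient -1
  nper <- Matrix::colSums(S != 0)
  cand <- which(nper == 1L & S[row, ] == -1 & model@rxnInfo$ub > 0)
  if (length(cand)) {
    return(list(model = model, reaction = model@rxnInfo$id[cand[1]]))
  }
  rid <- paste0("EXPORT_", met)
  while (rid %in% model@rxnInfo$id) rid <- paste0(rid, "_x")
  newcol <- Matrix::sparseMatrix(i = row, j = 1L, x = -1,
                                 dims = c(nrow(S), 1L))
  S2 <- cbind(S, newcol)
  ri <- rbind(model@rxnInfo,
              data.frame(id = rid, lb = 0, ub = 1000, gpr = "",
                         stringsAsFactors = FALSE))
  m2 <- MetabolicModel(S2, mi, ri)
  list(model = m2, reaction = rid)
}

#' Summary statistics of a metabolic model
#'
#' @param model a [MetabolicModel-class].
#' @return one-row data.frame: metabolite / non-boundary metabolite /
#'   reaction / gene counts and the number of gene-associated
#'   reactions.
#' @export
modelStats <- function(model) {
  data.frame(
    metabolites = nrow(model@metInfo),
    non_boundary_metabolites = sum(!model@metInfo$boundary),
    reactions = nrow(model@rxnInfo),
    genes = length(model@genes),
    gene_associated_reactions = sum(!vapply(model@gprs, is.null, logical(1)))
  )
}

#' Strip the compartment suffix from metabolite ids
#'
#' Metabolites of compartmentalised models carry an organelle suffix
#' (e.g. \code{glu_c}, \code{glu_m}). Counting "different metabolites"
#' across organelles uses the compartment-stripped key. When
#' \code{compartments} is supplied only those exact tokens are
#' stripped; otherwise any trailing 1-2 character token is.
#'
#' @param ids character vector of metabolite ids.
#' @param compartments optional character vector of compartment tokens.
#' @return character vector of compartment-free keys.
#' @examples
#' stripCompartment(c("dopa_c", "dopa_m", "atp_x"))
#' @export
stripCompartment <- function(ids, compartments = NULL) {
  if (is.null(compartments)) {
    pat <- "_[A-Za-z0-9]{1,2}$"
  } else {
    pat <- paste0("_(", paste(compartments, collapse = "|"), ")$")
  }
  sub(pat, "", ids)
}

metKeys <- function(model, ids) {
  stripCompartment(ids, unique(model@metInfo$compartment))
}
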
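#' @rdname MetabolicModel-accessors
#' @export
setGeneric("metabolites", function(object, ...) standardGeneric("metabolites"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("reactions", function(object, ...) standardGeneric("reactions"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("fluxBounds", function(object) standardGeneric("fluxBounds"))

#' @rdname MetabolicModel-accessors
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))

#' @rdname FluxEnvelope-accessors
#' @export
setGeneric("fluxRanges", function(object, ...) standardGeneric("fluxRanges"))

#' @rdname TargetSiteIndex-accessors
#' @export
setGeneric("siteCounts", function(object) standardGeneric("siteCounts"))

#' @rdname TargetSiteIndex-accessors
#' @export
setGeneric("totalSites", function(object) standardGeneric("totalSites"))

#' @rdname InsertionScan-accessors
#' @export
setGeneric("impactTable", function(object) standardGeneric("impactTable"))

#' @rdname InsertionScan-accessors
#' @export
setGeneric("geneStatus", function(object) standardGeneric("geneStatus"))

#' @rdname InsertionScan-accessors
#' @export
setGeneric("scanCounts", function(object) standardGeneric("scanCounts"))
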
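# Minimal SBML support, scoped to constraint-based models: species
# with boundary flags, reactions with stoichiometry and flux bounds,
# and GPR rules either as fbc:geneProductAssociation (L3) or as
# "GENE_ASSOCIATION:" notes (the legacy L2 convention of COBRA-style
# genome-scale reconstructions). Written on xml2; kinetic laws beyond
# the bound-parameter convention are ignored.

xmlEsc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

sanitizeSId <- function(x) {
  y <- gsub("[^A-Za-z0-9_]", "_", x)
  bad <- !grepl("^[A-Za-z_]", y)
  y[bad] <- paste0("x_", y[bad])
  y
}

#' Write a metabolic model as SBML Level 3 with fbc
#'
#' Emits SBML L3v1 with the fbc v2 extension: flux bounds as global
#' parameters referenced from each reaction, boundary species via
#' \code{boundaryCondition}, and GPR rules as nested
#' \code{fbc:and}/\code{fbc:or} gene-product associations. Gene ids
#' are stored verbatim in \code{fbc:label} (the SBML id is a sanitized
#' form), so [readSBML()] round-trips them exactly.
#'
#' @param model a [MetabolicModel-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @seealso [readSBML()]
#' @export
writeSBML <- function(model, path) {
  mi <- model@metInfo
  ri <- model@rxnInfo
  S <- model@stoich
  ln <- character()
  add <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">')
  add('  <model id="model" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (cp in unique(mi$compartment))
    add('      <compartment id="', xmlEsc(cp),
        '" constant="true" size="1"/>')
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(mi)))
    add('      <species id="', xmlEsc(mi$id[i]),
        '" name="', xmlEsc(mi$name[i]),
        '" compartment="', xmlEsc(mi$compartment[i]),
        '" boundaryCondition="', tolower(as.character(mi$boundary[i])),
        '" hasOnlySubstanceUnits="false" constant="false"/>')
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  for (i in seq_len(nrow(ri))) {
    sid <- sanitizeSId(ri$id[i])
    add('      <parameter id="', sid, '_lb" value="',
        format(ri$lb[i], digits = 17), '" constant="true"/>')
    add('      <parameter id="', sid, '_ub" value="',
        format(ri$ub[i], digits = 17), '" constant="true"/>')
  }
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  for (i in seq_len(nrow(ri))) {
    sid <- sanitizeSId(ri$id[i])
    col <- S[, i]
    subs <- which(col < 0); prods <- which(col > 0)
    add('      <reaction id="', xmlEsc(ri$id[i]),
        '" reversible="', tolower(as.character(ri$lb[i] < 0)),
        '" fast="false" fbc:lowerFluxBound="', sid,
        '_lb" fbc:upperFluxBound="', sid, '_ub">')
    if (length(subs)) {
      add('        <listOfReactants>')
      for (k in subs)
        add('          <speciesReference species="', xmlEsc(mi$id[k]),
            '" stoichiometry="', format(-col[k], digits = 17),
            '" constant="true"/>')
      add('        </listOfReactants>')
    }
    if (length(prods)) {
      add('        <listOfProducts>')
      for (k in prods)
        add('          <speciesReference species="', xmlEsc(mi$id[k]),
            '" stoichiometry="', format(col[k], digits = 17),
            '" constant="true"/>')
      add('        </listOfProducts>')
    }
    tr <- model@gprs[[i]]
    if (!is.null(tr)) {
      add('        <fbc:geneProductAssociation>')
      add(gprToFbc(tr, indent = 10L))
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  if (length(model@genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model@genes)
      add('      <fbc:geneProduct fbc:id="G_', sanitizeSId(g),
          '" fbc:label="', xmlEsc(g), '"/>')
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(ln, path)
  invisible(path)
}

gprToFbc <- function(tree, indent = 0L) {
  pad <- strrep(" ", indent)
  if (is.character(tree))
    return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_',
                  sanitizeSId(tree), '"/>'))
  tag <- paste0("fbc:", tree$op)
  inner <- vapply(tree$args, gprToFbc, character(1), indent = indent + 2L)
  paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", pad, "</", tag, ">")
}

nodeAttr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, names(at))
  if (is.na(hit)) {
    plain <- sub("^.*:", "", names(at))
    hit <- match(name, plain)
  }
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

fbcToGpr <- function(node, labelOf) {
  nm <- xml2::xml_name(node)   # name without prefix
  if (nm == "geneProductRef") {
    gid <- nodeAttr(node, "geneProduct")
    lab <- labelOf[[gid]]
    return(if (is.null(lab)) gid else lab)
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = nm,
                args = lapply(kids, fbcToGpr, labelOf = labelOf)))
  }
  stop("unsupported element in gene association: ", nm)
}

#' Read a metabolic model from SBML
#'
#' Supports SBML Level 2 and Level 3 constraint-based models. Flux
#' bounds are taken from fbc bound parameters (L3) or from
#' \code{LOWER_BOUND}/\code{UPPER_BOUND} kinetic-law parameters (L2);
#' reactions without bounds default to \code{[-1000, 1000]} when
#' reversible and \code{[0, 1000]} otherwise, with a warning. GPR
#' rules come from \code{fbc:geneProductAssociation} elements or from
#' \code{GENE_ASSOCIATION:} notes. A species is boundary when its
#' \code{boundaryCondition} attribute is true or its compartment
#' equals \code{boundaryCompartment} (the \code{"_b"} convention of
#' genome-scale human reconstructions).
#'
#' @param path SBML file.
#' @param boundaryCompartment compartment token marking environment
#'   species (default \code{"b"}).
#' @return a [MetabolicModel-class].
#' @seealso [writeSBML()], [modelStats()]
#' @export
readSBML <- function(path, boundaryCompartment = "b") {
  doc <- xml2::read_xml(path)
  spNodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(spNodes)) stop("no species found in ", path)
  spId <- vapply(spNodes, nodeAttr, character(1), "id")
  spName <- vapply(spNodes, nodeAttr, character(1), "name")
  spComp <- vapply(spNodes, nodeAttr, character(1), "compartment")
  spBC <- vapply(spNodes, nodeAttr, character(1), "boundaryCondition")
  boundary <- (!is.na(spBC) & tolower(spBC) == "true") |
    (!is.na(spComp) & spComp == boundaryCompartment)
  spName[is.na(spName)] <- spId[is.na(spName)]
  spComp[is.na(spComp)] <- "c"

  # global parameters (fbc flux bounds live here in L3)
  parNodes <- xml2::xml_find_all(
    doc,
    ".//*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parVal <- stats::setNames(
    as.numeric(vapply(parNodes, nodeAttr, character(1), "value")),
    vapply(parNodes, nodeAttr, character(1), "id"))

  gpNodes <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  labelOf <- list()
  for (gp in gpNodes) {
    gid <- nodeAttr(gp, "id")
    lab <- nodeAttr(gp, "label")
    labelOf[[gid]] <- if (is.na(lab)) gid else lab
  }

  rxNodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rxNodes)) stop("no reactions found in ", path)
  nR <- length(rxNodes)
  rid <- character(nR); lb <- rep(NA_real_, nR); ub <- rep(NA_real_, nR)
  rev <- logical(nR); gpr <- character(nR)
  ii <- integer(); jj <- integer(); xx <- numeric()
  unknownSpecies <- character()
  for (j in seq_len(nR)) {
    rx <- rxNodes[[j]]
    rid[j] <- nodeAttr(rx, "id")
    rv <- nodeAttr(rx, "reversible")
    rev[j] <- is.na(rv) || tolower(rv) == "true"   # SBML default: true
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(
        rx, paste0("./*[local-name()='", tag,
                   "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sp <- nodeAttr(ref, "species")
        st <- nodeAttr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        k <- match(sp, spId)
        if (is.na(k)) { unknownSpecies <- c(unknownSpecies, sp); next }
        ii <- c(ii, k); jj <- c(jj, j); xx <- c(xx, side * st)
      }
    }
    # bounds: fbc attributes, then kinetic-law parameters
    lbRef <- nodeAttr(rx, "lowerFluxBound")
    ubRef <- nodeAttr(rx, "upperFluxBound")
    if (!is.na(lbRef) && lbRef %in% names(parVal)) lb[j] <- parVal[[lbRef]]
    if (!is.na(ubRef) && ubRef %in% names(parVal)) ub[j] <- parVal[[ubRef]]
    if (is.na(lb[j]) || is.na(ub[j])) {
      klPars <- xml2::xml_find_all(
        rx, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      for (p in klPars) {
        pid <- nodeAttr(p, "id")
        pv <- as.numeric(nodeAttr(p, "value"))
        if (identical(pid, "LOWER_BOUND")) lb[j] <- pv
        if (identical(pid, "UPPER_BOUND")) ub[j] <- pv
      }
    }
    # GPR: fbc association, else notes
    ga <- xml2::xml_find_first(
      rx, "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      kids <- xml2::xml_children(ga)
      if (length(kids))
        gpr[j] <- deparseGPR(fbcToGpr(kids[[1]], labelOf))
    } else {
      notes <- xml2::xml_find_first(rx, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        mobj <- regmatches(
          txt, regexpr("GENE[ _]ASSOCIATION:[^\n]*", txt))
        if (length(mobj))
          gpr[j] <- trimws(sub("^GENE[ _]ASSOCIATION:", "", mobj))
      }
    }
  }
  if (length(unknownSpecies))
    stop("reaction(s) reference undeclared species: ",
         paste(unique(unknownSpecies), collapse = ", "))
  nodef <- is.na(lb) | is.na(ub)
  if (any(nodef)) {
    warning(sum(nodef), " reaction(s) without explicit bounds; ",
            "defaulting to [-1000,1000] (reversible) or [0,1000]")
    lb[is.na(lb)] <- ifelse(rev[is.na(lb)], -1000, 0)
    ub[is.na(ub)] <- 1000
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(spId), nR))
  model <- MetabolicModel(
    S,
    metInfo = data.frame(id = spId, name = spName, compartment = spComp,
                         boundary = boundary, stringsAsFactors = FALSE),
    rxnInfo = data.frame(id = rid, lb = lb, ub = ub, gpr = gpr,
                         stringsAsFactors = FALSE))
  message("read SBML: ", nrow(model@metInfo), " species (",
          sum(!model@metInfo$boundary), " non-boundary), ",
          nR, " reactions, ", length(model@genes), " genes")
  model
}
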
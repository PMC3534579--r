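#' Normalize metabolite keys for disease matching
#'
#' Case-folds a key and strips one trailing compartment token (default
#' tokens: the usual cytosol/mitochondrion/peroxisome/... suffixes),
#' so that \code{"Dopa_c"}, \code{"dopa_m"} and \code{"dopa"} all
#' compare equal. Matching between model metabolites and disease-map
#' entries is name-based; supply a synonym table to [countLinked()]
#' when the two vocabularies differ.
#'
#' @param keys character vector.
#' @param compartments compartment tokens to strip.
#' @return normalized character vector.
#' @export
normalizeMetKey <- function(keys,
                            compartments = c("c", "m", "x", "r", "g",
                                             "l", "n", "e", "b", "i",
                                             "p", "v")) {
  if (!length(keys)) return(character())
  pat <- paste0("_(", paste(compartments, collapse = "|"), ")$")
  sub(pat, "", tolower(keys))
}

#' Load a metabolite-disease association map
#'
#' Reads a tab-separated table with header columns \code{disease} and
#' \code{metabolite_key} (one association per row, e.g. an export of
#' HMDB-style disease associations). Keys are normalized with
#' [normalizeMetKey()]; duplicate associations collapse; diseases with
#' no remaining metabolites are dropped.
#'
#' @param path TSV file.
#' @return named list: disease name -> character vector of normalized
#'   metabolite keys.
#' @seealso [countLinked()], [enrichmentTest()]
#' @export
loadDiseaseMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("disease", "metabolite_key")
  if (!all(need %in% names(d)))
    stop("disease map must have columns: ", paste(need, collapse = ", "))
  if (!nrow(d)) stop("disease map has no rows")
  d$metabolite_key <- normalizeMetKey(d$metabolite_key)
  d <- d[nzchar(d$disease) & nzchar(d$metabolite_key), , drop = FALSE]
  if (!nrow(d)) stop("disease map has no usable rows")
  mp <- lapply(split(d$metabolite_key, d$disease), unique)
  message("disease map: ", length(mp), " disease(s), ",
          sum(lengths(mp)), " association(s)")
  mp
}

#' Load a model-to-map metabolite synonym table
#'
#' Two-column TSV (\code{model_key}, \code{map_key}) translating model
#' metabolite keys into the disease map's vocabulary.
#'
#' @param path TSV file.
#' @return named character vector: normalized model key -> normalized
#'   map key.
#' @export
loadSynonyms <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("model_key", "map_key")
  if (!all(need %in% names(d)))
    stop("synonym table must have columns: ", paste(need, collapse = ", "))
  stats::setNames(normalizeMetKey(d$map_key), normalizeMetKey(d$model_key))
}

#' Count disease-linked metabolites in an affected set
#'
#' For each disease of the map, the number of distinct affected
#' metabolite keys associated with it. Input keys are normalized (and
#' optionally translated through a synonym table) before intersecting,
#' so counts are invariant under compartment decoration. Diseases with
#' an empty intersection are reported with count 0.
#'
#' @param affected character vector of metabolite keys.
#' @param map a disease map from [loadDiseaseMap()].
#' @param synonyms optional named vector from [loadSynonyms()].
#' @return named integer vector, one entry per disease.
#' @examples
#' mp <- list(pd = c("dopamine", "serotonin"), mdd = "serotonin")
#' countLinked(c("Dopamine_c", "taurine"), mp)
#' @export
countLinked <- function(affected, map, synonyms = NULL) {
  keys <- normalizeMetKey(affected)
  if (!is.null(synonyms)) {
    hit <- keys %in% names(synonyms)
    keys[hit] <- synonyms[keys[hit]]
  }
  keys <- unique(keys)
  vapply(map, function(s) length(intersect(keys, s)), integer(1))
}
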
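# L1 endonuclease target-site scanning. The L1 endonuclease nicks DNA
# preferentially at TT|AAAA; insertions of L1, Alu and SVA all use this
# machinery, so target sites are TTAAAA hexamers (and within-mismatch
# variants) on either strand. A reverse-strand site corresponds to a
# forward-strand match of the reverse complement, TTTTAA.

L1_TARGET <- "TTAAAA"
L1_TARGET_RC <- "TTTTAA"

#' Scan a sequence for L1 endonuclease target sites
#'
#' Reports every position where the 6-mer window matches TTAAAA within
#' the allowed Hamming distance on the forward strand, or matches the
#' reverse-complement pattern TTTTAA within the same distance (a site
#' on the minus strand). \code{N} bases count as mismatches, never as
#' wildcards. Overlapping sites are all reported; a window within
#' distance of both patterns yields one row per strand.
#'
#' @param sequence character scalar or [Biostrings::DNAString] over
#'   \code{A,C,G,T,N}.
#' @param maxMismatch maximum Hamming distance (default 1).
#' @return data.frame with columns \code{position} (1-based start of
#'   the window), \code{strand} (\code{"+"}/\code{"-"}) and
#'   \code{mismatches}, ordered by position then strand.
#' @examples
#' scanTargetSites("GGTTAAAAGG")
#' scanTargetSites("TTAAAT")   # one substitution away
#' @seealso [buildSiteIndex()]
#' @export
scanTargetSites <- function(sequence, maxMismatch = 1) {
  stopifnot(maxMismatch >= 0)
  s <- toupper(as.character(sequence))
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0)
    stop("invalid nucleotide '", substr(s, bad, bad),
         "' at position ", bad)
  if (nchar(s) < 6)
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  subj <- Biostrings::DNAString(s)
  rows <- list()
  for (pat in list(c(L1_TARGET, "+"), c(L1_TARGET_RC, "-"))) {
    hits <- Biostrings::matchPattern(pat[1], subj,
                                     max.mismatch = maxMismatch,
                                     fixed = TRUE)
    if (length(hits)) {
      starts <- Biostrings::start(hits)
      # matchPattern with mismatches reports edge overhangs; only
      # fully contained windows are genuine sites
      starts <- starts[starts >= 1L & starts <= nchar(s) - 5L]
      if (!length(starts)) next
      mm <- vapply(starts, function(p) {
        w <- substr(s, p, p + 5L)
        sum(strsplit(w, "")[[1]] != strsplit(pat[1], "")[[1]])
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        position = starts, strand = pat[2], mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a target-site index over the genes of a model
#'
#' Scans each gene sequence for endonuclease target sites and indexes
#' the hits by gene. Only genes present in both the sequence set and
#' the model gene set are indexed; genes with no sites are retained
#' with empty tables so they remain visible to the sampler with weight
#' zero. Coverage gaps (model genes without a sequence) are reported
#' via \code{message()}.
#'
#' @param sequences a named [Biostrings::DNAStringSet], a named
#'   character vector, or a FASTA path; names must be gene ids.
#' @param model a [MetabolicModel-class], or a character vector of
#'   gene ids.
#' @param maxMismatch maximum Hamming distance (default 1).
#' @return a [TargetSiteIndex-class].
#' @examples
#' idx <- buildSiteIndex(c(g1 = "GGTTAAAAGGGGGG", g2 = "GGGGGGGGGGGGGG"),
#'                       c("g1", "g2"))
#' siteCounts(idx)
#' @seealso [scanTargetSites()], [sampleInsertionSets()]
#' @export
buildSiteIndex <- function(sequences, model, maxMismatch = 1) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  nm <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- nm
  if (!length(seqs)) stop("empty sequence set")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by gene id")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  modelGenes <- if (is(model, "MetabolicModel")) geneIds(model) else model
  extra <- setdiff(names(seqs), modelGenes)
  if (length(extra)) {
    warning(length(extra), " sequence(s) not in the model gene set, ",
            "excluded: ", paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
    seqs <- seqs[names(seqs) %in% modelGenes]
  }
  if (!length(seqs)) stop("no sequence maps to a model gene")
  gaps <- setdiff(modelGenes, names(seqs))
  if (length(gaps))
    message(length(gaps), " model gene(s) without a sequence")
  sites <- lapply(seqs, scanTargetSites, maxMismatch = maxMismatch)
  new("TargetSiteIndex", sites = sites,
      maxMismatch = as.integer(maxMismatch))
}

#' Accessors for TargetSiteIndex
#'
#' \code{siteCounts()} returns the per-gene number of target sites;
#' \code{totalSites()} their sum.
#'
#' @param object a [TargetSiteIndex-class].
#' @name TargetSiteIndex-accessors
#' @aliases siteCounts totalSites
NULL

#' @rdname TargetSiteIndex-accessors
#' @export
setMethod("siteCounts", "TargetSiteIndex", function(object) {
  vapply(object@sites, nrow, integer(1))
})

#' @rdname TargetSiteIndex-accessors
#' @export
setMethod("totalSites", "TargetSiteIndex", function(object) {
  sum(vapply(object@sites, nrow, integer(1)))
})

setMethod("show", "TargetSiteIndex", function(object) {
  ct <- vapply(object@sites, nrow, integer(1))
  cat("TargetSiteIndex:", length(ct), "genes,", sum(ct),
      "target sites (<=", object@maxMismatch, "mismatch)\n")
})
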
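#' Assemble and validate a pipeline run configuration
#'
#' Collects all inputs and parameters of the end-to-end analysis. The
#' defaults are the study conditions of the knockdown screen: 70-fold
#' flux reduction, one mismatch allowed in the TTAAAA target site,
#' 100000 Monte Carlo samples.
#'
#' @param model SBML path or a [MetabolicModel-class].
#' @param insertions TSV path or data.frame (\code{donor},
#'   \code{gene}).
#' @param outDir output directory (created if absent).
#' @param fasta optional gene-sequence FASTA (or named character /
#'   DNAStringSet); required for the enrichment stage.
#' @param diseaseMap optional disease-map TSV path or data.frame;
#'   required for the enrichment stage.
#' @param synonyms optional synonym TSV path.
#' @param foldReduction,maxMismatch,samples,seed,optimalityFraction
#'   analysis parameters (see [knockdownConfig()],
#'   [enrichmentTest()]).
#' @return list of class \code{"RunConfig"}.
#' @seealso [runPipeline()]
#' @export
runConfig <- function(model, insertions, outDir,
                      fasta = NULL, diseaseMap = NULL, synonyms = NULL,
                      foldReduction = 70, maxMismatch = 1,
                      samples = 100000, seed = 1,
                      optimalityFraction = 0) {
  stopifnot(samples >= 1)
  for (p in Filter(is.character, list(model = model,
                                      insertions = insertions,
                                      fasta = fasta,
                                      diseaseMap = diseaseMap,
                                      synonyms = synonyms))) {
    if (length(p) == 1 && !file.exists(p)) stop("file not found: ", p)
  }
  structure(list(model = model, insertions = insertions,
                 fasta = fasta, diseaseMap = diseaseMap,
                 synonyms = synonyms, foldReduction = foldReduction,
                 maxMismatch = maxMismatch, samples = samples,
                 seed = seed, optimalityFraction = optimalityFraction,
                 outDir = outDir),
            class = "RunConfig")
}

tsvHeader <- function(config, extra = character()) {
  c(paste0("# teflux ", as.character(utils::packageVersion("teflux"))),
    paste0("# seed=", config$seed,
           " fold_reduction=", config$foldReduction,
           " max_mismatch=", config$maxMismatch,
           " samples=", config$samples,
           " optimality_fraction=", config$optimalityFraction),
    extra)
}

writeTSV <- function(d, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(d, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full insertion-to-enrichment analysis
#'
#' Orchestrates every stage: model loading, the knockdown scan of the
#' insertion set (gene-by-metabolite impact table, summary counts,
#' donor overlaps), target-site indexing, and the Monte Carlo disease
#' enrichment test. Outputs are written as TSV with \code{#}-prefixed
#' metadata headers recording seed and parameters, so a rerun with the
#' same config and seed reproduces the payloads byte for byte;
#' wall-clock metadata is confined to \code{run_metadata.tsv}. When
#' the FASTA or disease map is absent the enrichment stage is skipped
#' with a notice and all earlier outputs are still produced.
#'
#' @param config a [runConfig()].
#' @param verbose passed to [scanInsertions()].
#' @return invisibly, a list with \code{scan} (the
#'   [InsertionScan-class]), \code{enrichment} (data.frame or
#'   \code{NULL}), and \code{files} (paths written).
#' @examples
#' \donttest{
#' toy <- makeToyNetwork(2, 3, 0.3, 0, seed = 5)
#' ins <- makeInsertions(toy$truth, "A", 4, 1, seed = 5)
#' cfg <- runConfig(toy$model, ins, outDir = tempfile(), samples = 100)
#' res <- runPipeline(cfg)
#' }
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- "model"
  res <- tryCatch({
    model <- if (is(config$model, "MetabolicModel")) config$model
      else readSBML(config$model)

    stage <- "knockdown scan"
    kcfg <- knockdownConfig(
      foldReduction = config$foldReduction,
      optimalityFraction = config$optimalityFraction)
    scan <- scanInsertions(model, config$insertions, kcfg,
                           verbose = verbose)

    files <- character()
    hdr <- tsvHeader(config)
    f <- file.path(config$outDir, "gene_impacts.tsv")
    writeTSV(impactTable(scan), f, hdr); files <- c(files, f)

    ct <- scanCounts(scan)
    f <- file.path(config$outDir, "summary_counts.tsv")
    writeTSV(data.frame(quantity = names(ct),
                        value = unlist(ct, use.names = FALSE)),
             f, hdr); files <- c(files, f)

    f <- file.path(config$outDir, "gene_status.tsv")
    writeTSV(geneStatus(scan), f, hdr); files <- c(files, f)

    f <- file.path(config$outDir, "donor_counts.tsv")
    writeTSV(scan@donorCounts, f, hdr); files <- c(files, f)
    if (nrow(scan@overlaps)) {
      f <- file.path(config$outDir, "donor_overlaps.tsv")
      writeTSV(scan@overlaps, f, hdr); files <- c(files, f)
    }

    enrichment <- NULL
    if (is.null(config$fasta) || is.null(config$diseaseMap)) {
      message("enrichment stage skipped: ",
              if (is.null(config$fasta)) "no gene FASTA supplied; "
              else "",
              if (is.null(config$diseaseMap)) "no disease map supplied"
              else "")
    } else {
      stage <- "target-site index"
      index <- buildSiteIndex(config$fasta, model, config$maxMismatch)
      stage <- "enrichment"
      dmap <- config$diseaseMap
      if (is.character(dmap)) dmap <- loadDiseaseMap(dmap)
      if (is.data.frame(dmap)) dmap <- diseaseMapList(dmap)
      ins <- config$insertions
      if (is.character(ins)) ins <- readInsertions(ins)
      obs <- ins$gene[ins$gene %in% geneIds(model)]
      enrichment <- enrichmentTest(
        obs, impactLookup(scan), dmap, index,
        N = config$samples, seed = config$seed)
      f <- file.path(config$outDir, "disease_enrichment.tsv")
      writeTSV(enrichment, f, hdr); files <- c(files, f)
    }

    f <- file.path(config$outDir, "run_metadata.tsv")
    meta <- data.frame(
      key = c("teflux_version", "r_version", "seed", "fold_reduction",
              "max_mismatch", "samples", "optimality_fraction",
              "started", "runtime_sec"),
      value = c(as.character(utils::packageVersion("teflux")),
                paste(R.version$major, R.version$minor, sep = "."),
                config$seed, config$foldReduction, config$maxMismatch,
                config$samples, config$optimalityFraction,
                format(t0), round(as.numeric(
                  difftime(Sys.time(), t0, units = "secs")), 2)))
    writeTSV(meta, f, "# run metadata"); files <- c(files, f)

    list(scan = scan, enrichment = enrichment, files = files)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
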
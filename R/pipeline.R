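#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
#' @importFrom rlang hash
NULL

#' Assemble a validated pipeline configuration
#'
#' Collects every threshold and seed of the pipeline in one serializable
#' list: the FPKM floor and BH cutoff of the enrichment caller, the GSEA FDR
#' flag threshold, the intensity-ratio bounds and background fraction of the
#' cell classifier, optional catalogue/rule overrides, and the simulation
#' settings used when no real input files are given. Every field has the
#' pipeline default; `...` entries override nested fields supplied as named
#' lists (e.g. `thresholds = list(q_max = 0.01)`).
#'
#' @param ... named overrides for the blocks `thresholds`, `catalogue`,
#'   `rules`, `simulation`, `seed`.
#' @return a named list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    thresholds = list(fpkm_floor = 0.05, q_max = 0.05, gsea_fdr = 0.25,
                      ratio_low = 0.5, ratio_high = 2,
                      background_fraction = 0.10),
    catalogue = NULL,   # named list kind -> patterns, or NULL for default
    rules = list(d_min = 0L, d_max = 100L),
    simulation = list(n_transcripts = 2000L, n_bound = 50L,
                      enrichment_fold = 4, dispersion = 0.1,
                      n_replicates = 2L,
                      library_size_factors = c(1.0, 1.3, 0.8, 1.1),
                      mean_depth = 50, n_utrs = 100L,
                      class_mix = list(activation_competent = 0.4,
                                       repression_configured = 0.3,
                                       non_regulated = 0.3),
                      n_cells = 5000L, coexpression_fraction = 0.9))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config block: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[nm] <- list(over[[nm]])   # keeps explicit NULLs in place
  }
  .validateConfig(cfg)
  structure(cfg, class = "pipelineConfig")
}

.validateConfig <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(th$fpkm_floor >= 0, th$q_max >= 0, th$q_max <= 1,
            th$gsea_fdr > 0, th$gsea_fdr <= 1,
            th$ratio_low > 0, th$ratio_high >= th$ratio_low,
            th$background_fraction >= 0, th$background_fraction <= 1)
  stopifnot(cfg$rules$d_min >= 0, cfg$rules$d_max >= cfg$rules$d_min)
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys are the [pipelineConfig()] blocks
#' and merges it over the defaults, so a config file only needs to state
#' what it changes. Writing the returned object back with [yaml::write_yaml()]
#' round-trips.
#'
#' @param path YAML file.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- read_yaml(path)
  if (!is.null(raw$simulation$class_mix))
    raw$simulation$class_mix <- as.list(raw$simulation$class_mix)
  do.call(pipelineConfig, raw)
}

.rulesFromConfig <- function(cfg)
  regulationRules(cfg$rules$d_min, cfg$rules$d_max)

.catalogueFromConfig <- function(cfg) {
  if (is.null(cfg$catalogue)) defaultCatalogue()
  else .catalogueFromList(cfg$catalogue)
}

#' Run the full target-identification pipeline
#'
#' Drives every stage in order: simulate (or load) inputs, call bound
#' transcripts from the RIP counts, scan and classify the 3'-UTRs, intersect
#' the bound set with the polyadenylation-regulated set, score that final
#' set against a ranked contrast by permutation GSEA, classify the cell
#' intensity table, and write a report. The report JSON records the filter
#' funnel (counts after every stage), all thresholds and seeds, and a config
#' hash, which together reproduce the run exactly.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory; created if needed.
#' @param inputs optional list of real inputs overriding simulation: any of
#'   `experiment` (a [RipExperiment-class]), `utrs` (an `RNAStringSet` or
#'   FASTA path), `ranking` (a [rankedList()]), `cells` (a data frame or TSV
#'   path). Stages with no input fall back to the seeded generators.
#' @return the report, invisibly (a named list, also written to
#'   `report.json`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, inputs = list()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  sim <- config$simulation
  seed <- as.integer(config$seed)
  catalogue <- .catalogueFromConfig(config)
  rules <- .rulesFromConfig(config)

  ## --- stage 1: inputs -----------------------------------------------------
  stage <- "simulate"
  report <- tryCatch({
    if (is.null(inputs$experiment)) {
      rip <- simulateRipCounts(
        nTranscripts = sim$n_transcripts, nBound = sim$n_bound,
        enrichmentFold = sim$enrichment_fold, dispersion = sim$dispersion,
        nReplicates = sim$n_replicates,
        librarySizeFactors = sim$library_size_factors,
        meanDepth = sim$mean_depth, seed = seed)
      experiment <- rip$experiment
      truthBound <- rip$bound
    } else {
      experiment <- inputs$experiment
      truthBound <- NULL
    }
    if (is.null(inputs$utrs)) {
      ## scan the UTRs of the (simulated) transcripts, planted bound ones
      ## first, so the bound-set/CPE-regulated intersection is exercised
      utrIDs <- if (!is.null(truthBound))
        utils::head(c(truthBound,
                      setdiff(rownames(experiment), truthBound)),
                    sim$n_utrs)
      else NULL
      usim <- simulateUTRs(n = sim$n_utrs, classMix = sim$class_mix,
                           catalogue = catalogue, rules = rules,
                           transcriptIDs = utrIDs, seed = seed + 1L)
      utrs <- usim$utrs
      truthKlass <- usim$truth
    } else {
      utrs <- inputs$utrs
      truthKlass <- NULL
    }
    if (is.null(inputs$cells)) {
      csim <- simulateCells(
        n = sim$n_cells, coexpressionFraction = sim$coexpression_fraction,
        threshold = backgroundThreshold(255L, th$background_fraction),
        seed = seed + 2L)
      cells <- csim$cells
    } else {
      cells <- if (is.character(inputs$cells)) readCellTable(inputs$cells)
               else inputs$cells
    }

    ## --- stage 2: RIP enrichment -------------------------------------------
    stage <- "enrich"
    enr <- callTargets(experiment, fpkmFloor = th$fpkm_floor,
                       qMax = th$q_max)
    writeEnrichmentResults(enr, outDir)

    ## --- stage 3: UTR scan + classification --------------------------------
    stage <- "scan"
    scan <- scanBatch(utrs, catalogue, rules)
    writeMotifGFF3(scan$maps, file.path(outDir, "motif_hits.gff3"))
    write.table(as.data.frame(scan$calls),
                file.path(outDir, "regulation_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- stage 4: intersection funnel --------------------------------------
    stage <- "intersect"
    finalSet <- intersect(enr$bound, scan$regulated)
    writeLines(finalSet, file.path(outDir, "final_target_set.txt"))

    ## --- stage 5: set analysis ---------------------------------------------
    stage <- "gsea"
    gsea <- NULL
    ranking <- inputs$ranking
    if (is.null(ranking)) {
      rec <- enr$records[[1]]
      ranking <- rankedList(rec$transcript_id, rec$log2fc)
    }
    testSet <- if (length(finalSet) >= 3) finalSet else enr$bound
    if (length(testSet) >= 3 && length(testSet) < nrow(ranking)) {
      gsea <- permutationTest(ranking, list(final_targets = testSet),
                              nPerm = 1000L, seed = seed + 3L,
                              fdrMax = th$gsea_fdr)
      write.table(as.data.frame(gsea), file.path(outDir, "gsea.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    ## --- stage 6: co-expression --------------------------------------------
    stage <- "classify-cells"
    cthr <- backgroundThreshold(255L, th$background_fraction)
    calls <- classifyCells(cells, cthr)
    write.table(calls, file.path(outDir, "cell_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    coexpr <- coexpressionSummary(cells, cthr)

    ## --- report --------------------------------------------------------------
    stage <- "report"
    perRep <- lapply(enr$records, function(r)
      list(n_tested = sum(!r$low_expression),
           n_low_expression = sum(r$low_expression),
           n_significant = sum(r$significant),
           n_bound = sum(r$bound)))
    report <- list(
      provenance = list(
        package_version = as.character(utils::packageVersion("cpeTargets")),
        config_hash = hash(unclass(config)),
        seed = seed,
        thresholds = th),
      funnel = list(
        n_transcripts = nrow(experiment),
        per_replicate = perRep,
        n_bound_intersect = length(enr$bound),
        n_utrs_scanned = length(utrs),
        n_cpe_regulated = length(scan$regulated),
        n_final_targets = length(finalSet)),
      gsea = if (!is.null(gsea))
        list(es = gsea$es[1], perm_p = gsea$perm_p[1],
             fdr_q = gsea$fdr_q[1], enriched = gsea$enriched[1]),
      coexpression = list(
        fraction_coexpressing = coexpr$fraction_coexpressing,
        class_counts = as.list(coexpr$class_counts),
        pearson_r = coexpr$pearson_r),
      truth = if (!is.null(truthBound) || !is.null(truthKlass)) list(
        n_planted_bound = length(truthBound),
        sensitivity = if (!is.null(truthBound) && length(truthBound))
          mean(truthBound %in% enr$bound),
        empirical_fdr = if (!is.null(truthBound) && length(enr$bound))
          mean(!(enr$bound %in% truthBound)) else 0,
        utr_class_recovery = if (!is.null(truthKlass))
          mean(scan$calls$klass == truthKlass$klass)))
    write_json(report, file.path(outDir, "report.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(report)
}
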
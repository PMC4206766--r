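#' @include AllClasses.R peaks.R annotation.R cooccupancy.R motif.R
#' @include cross_species.R association.R
NULL

.pipeline_config_paths <- function(cfg) {
  paths <- character()
  for (f in c("factorA", "factorB")) {
    pk <- cfg$peaks[[f]]
    paths <- c(paths, unlist(pk[intersect(names(pk),
                                          c("peaks", "replicate1",
                                            "replicate2"))]))
  }
  paths <- c(paths, cfg$annotation, cfg$genome, cfg$motif)
  for (sp in cfg$orthologs)
    paths <- c(paths, sp$map, sp$bound_genes)
  for (de in cfg$expression)
    paths <- c(paths, de$path)
  unname(unlist(paths))
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("config must be a file path or a list")
  missing <- setdiff(c("peaks", "annotation"), names(config))
  if (length(missing))
    stop("config validation error: missing field(s): ",
         paste(missing, collapse = ", "))
  for (f in c("factorA", "factorB")) {
    pk <- config$peaks[[f]]
    if (is.null(pk) || is.null(pk$name) ||
        (is.null(pk$peaks) && (is.null(pk$replicate1) ||
                               is.null(pk$replicate2))))
      stop("config validation error: peaks$", f,
           " needs 'name' and either 'peaks' or 'replicate1'+'replicate2'")
  }
  config
}

.config_to_analysis <- function(params) {
  defaults <- AnalysisConfig()
  if (is.null(params)) return(defaults)
  known <- c("proximal_window" = "proximalWindow",
             "min_overlap" = "minOverlap",
             "de_p_threshold_array" = "dePThresholdArray",
             "de_p_threshold_rnaseq" = "dePThresholdRnaseq",
             "motif_rel_threshold" = "motifRelThreshold",
             "pseudocount" = "pseudocount")
  for (key in names(params)) {
    if (!key %in% names(known))
      stop("config validation error: unknown parameter '", key, "'")
    slot(defaults, known[[key]]) <- as.numeric(params[[key]])
  }
  validObject(defaults)
  defaults
}

.load_factor_peaks <- function(pk, build, minOverlap) {
  if (!is.null(pk$peaks))
    return(readPeaks(pk$peaks, factorName = pk$name, genomeBuild = build))
  r1 <- readPeaks(pk$replicate1, factorName = pk$name, genomeBuild = build)
  r2 <- readPeaks(pk$replicate2, factorName = pk$name, genomeBuild = build)
  replicateConsensus(r1, r2, minOverlap = minOverlap)
}

#' Run the integrative binding/expression pipeline
#'
#' Executes the full analysis from a structured config: replicate
#' consensus (when replicates are given), proximal assignment of both
#' factors, peak sharing and gene binding classes, motif hit statistics
#' and between-set enrichment (when a genome and motif are configured),
#' cross-species conservation (when ortholog maps and foreign bound sets
#' are configured), and binding-class/responsiveness association for each
#' configured DE table.  All referenced files are checked before any
#' stage runs; per-stage tables are written under `outDir` together with
#' a JSON report from which every number can be re-derived.
#'
#' The config is YAML (or an equivalent list) with fields `peaks`
#' (`factorA`/`factorB`, each with `name` and either `peaks` or
#' `replicate1`+`replicate2`), `annotation` (GTF), and optional `genome`
#' (FASTA), `motif` (JASPAR), `orthologs` (per-species `map` TSV and
#' `bound_genes` file of foreign bound gene ids), `expression` (list of
#' `path`/`provenance` entries), `params` (AnalysisConfig overrides,
#' snake_case), `genome_build` and `seed`.
#'
#' @param config path to a YAML config file or an equivalent named list.
#' @param outDir output directory (created if needed).
#' @return the pipeline report, invisibly (also written to
#'   `outDir/report.json`).
#' @export
runPipeline <- function(config, outDir) {
  cfg <- .read_config(config)
  paths <- .pipeline_config_paths(cfg)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config validation error: input file(s) not found: ",
         paste(missing, collapse = ", "))
  params <- .config_to_analysis(cfg$params)
  build <- if (!is.null(cfg$genome_build)) cfg$genome_build else "unknown"
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    tool = "peakCobind",
    version = as.character(utils::packageVersion("peakCobind")),
    seed = seed,
    inputs = lapply(stats::setNames(paths, basename(paths)),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    params = list(proximal_window = params@proximalWindow,
                  min_overlap = params@minOverlap,
                  de_p_threshold_array = params@dePThresholdArray,
                  de_p_threshold_rnaseq = params@dePThresholdRnaseq,
                  motif_rel_threshold = params@motifRelThreshold,
                  pseudocount = params@pseudocount,
                  background = as.list(params@background)))

  run_stage <- function(name, expr) {
    message("[peakCobind] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- peaks + consensus
  setA <- run_stage("peaks", .load_factor_peaks(cfg$peaks$factorA, build,
                                                params@minOverlap))
  setB <- run_stage("peaks", .load_factor_peaks(cfg$peaks$factorB, build,
                                                params@minOverlap))
  writePeaks(setA, file.path(outDir, "peaks_factorA.bed"))
  writePeaks(setB, file.path(outDir, "peaks_factorB.bed"))

  ## --- proximal assignment
  genes <- run_stage("annotation", readGeneModels(cfg$annotation))
  assignA <- run_stage("assign", assignProximal(setA, genes,
                                                params@proximalWindow))
  assignB <- run_stage("assign", assignProximal(setB, genes,
                                                params@proximalWindow))
  utils::write.table(assignmentPairs(assignA),
                     file.path(outDir, "proximal_factorA.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assignmentPairs(assignB),
                     file.path(outDir, "proximal_factorB.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- sharing and gene classes
  sharing <- run_stage("cooccur", sharePeaks(setA, setB, params@minOverlap))
  classes <- run_stage("cooccur", geneBindingClasses(assignA, assignB,
                                                     sharing, names(genes)))
  utils::write.table(sharingCounts(sharing),
                     file.path(outDir, "sharing_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  clsDf <- data.frame(gene_id = names(bindingClasses(classes)),
                      class = as.character(bindingClasses(classes)),
                      stringsAsFactors = FALSE)
  utils::write.table(clsDf, file.path(outDir, "gene_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$sharing <- as.list(stats::setNames(
    as.integer(unlist(sharingCounts(sharing)[, c("n_shared", "n_only")])),
    c("shared_A", "shared_B", "only_A", "only_B")))
  report$gene_classes <- as.list(as.integer(classCounts(classes)))
  names(report$gene_classes) <- names(classCounts(classes))

  ## --- motif analysis
  if (!is.null(cfg$genome) && !is.null(cfg$motif)) {
    pfm <- run_stage("scan", readJaspar(cfg$motif,
                                        pseudocount = params@pseudocount,
                                        background = params@background))
    genome <- run_stage("scan", .load_genome(cfg$genome))
    statsA <- run_stage("scan", peakHitStats(setA, genome, pfm,
                                             params@motifRelThreshold))
    statsB <- run_stage("scan", peakHitStats(setB, genome, pfm,
                                             params@motifRelThreshold))
    ## common peaks = factor-A peaks shared with B
    sharedSet <- PeakSet(peakRanges(setA)[peakIds(setA) %in%
                                            sharing@sharedA],
                         factorName = paste0(factorName(setA), "_common"),
                         genomeBuild = build)
    statsC <- if (length(sharedSet))
      peakHitStats(sharedSet, genome, pfm, params@motifRelThreshold)
    else NULL
    utils::write.table(statsA$perPeak,
                       file.path(outDir, "motif_hits_factorA.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(statsB$perPeak,
                       file.path(outDir, "motif_hits_factorB.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$motif <- list(
      motif_id = pfm@motifID,
      fraction_A = statsA$fraction,
      fraction_B = statsB$fraction,
      fraction_common = if (!is.null(statsC)) statsC$fraction else NA)
    if (!is.null(statsC) && statsC$n > 0) {
      enr <- motifSetEnrichment(statsC$nWithHit, statsC$n,
                                statsB$nWithHit, statsB$n)
      report$motif$enrichment_common_vs_B <-
        list(chi2 = enr@statistic, p = enr@pValue,
             fold = enr@foldEnrichment)
    }
  }

  ## --- cross-species conservation
  if (!is.null(cfg$orthologs)) {
    projected <- run_stage("conserve", lapply(cfg$orthologs, function(sp) {
      map <- readOrthologMap(sp$map)
      fg <- readLines(sp$bound_genes)
      projectGeneSet(fg[nzchar(fg)], map)
    }))
    refSet <- boundGenes(assignA)
    ct <- conservationClasses(refSet, lapply(projected, `[[`, "genes"),
                              referenceName = factorName(setA))
    utils::write.table(ct@membership,
                       file.path(outDir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    venn <- vennPartition(c(stats::setNames(list(refSet),
                                            factorName(setA)),
                            lapply(projected, `[[`, "genes")))
    report$conservation <- list(
      classes = as.list(stats::setNames(conservationSummary(ct)$n_genes,
                                        conservationSummary(ct)$class)),
      venn = as.list(venn),
      unmapped = lapply(projected, `[[`, "nUnmapped"))
  }

  ## --- binding/response association
  if (!is.null(cfg$expression)) {
    assoc <- list()
    for (de in cfg$expression) {
      prov <- if (!is.null(de$provenance)) de$provenance else "rnaseq"
      tab <- run_stage("associate", readDETable(de$path, prov))
      thr <- if (!is.null(de$p_threshold)) as.numeric(de$p_threshold)
             else if (prov == "array") params@dePThresholdArray
             else params@dePThresholdRnaseq
      up <- responsiveSets(tab, thr, "up")
      down <- responsiveSets(tab, thr, "down")
      universe <- names(bindingClasses(classes))
      one <- list(provenance = prov, p_threshold = thr,
                  n_up = length(up), n_down = length(down))
      for (cl in c("A_only", "common", "uncommon", "B_only")) {
        if (!cl %in% as.character(bindingClasses(classes))) next
        ## a zero marginal (e.g. no responsive genes) leaves the test
        ## undefined for this class; record that instead of failing
        r <- tryCatch(bindingResponseAssociation(classes,
                                                 intersect(up, universe),
                                                 universe, cl),
                      error = function(e) NULL)
        one[[paste0("up_vs_", cl)]] <- if (is.null(r))
          list(chi2 = NA, p = NA, fold = NA, odds_ratio = NA,
               note = "undefined: zero marginal")
        else
          list(chi2 = r@statistic, p = r@pValue,
               fold = r@foldEnrichment, odds_ratio = r@oddsRatio)
      }
      assoc[[basename(de$path)]] <- one
    }
    report$association <- assoc
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
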
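#' Merge hit lists from multiple screens into a seed-gene list
#'
#' Case-insensitive union of the genes called across the epistasis screen,
#' the chemical-genomic screen and the microscopy scoring, with per-source
#' provenance flags.
#'
#' @param ... Named character vectors of called genes, e.g.
#'   \code{sga = ..., chemgen = ..., microscopy = ...}.
#' @return data.frame with a \code{gene} column plus one logical column per
#'   source; one row per unique gene, sorted.
#' @export
mergeGeneLists <- function(...) {
  lists <- list(...)
  stopIfNot(length(lists) > 0 && !is.null(names(lists)) &&
            all(nzchar(names(lists))), "gene lists must be named")
  lists <- lapply(lists, function(x) unique(toupper(x)))
  genes <- sort(unique(unlist(lists)))
  stopIfNot(length(genes) > 0,
            "zero total hits: nothing to seed the network with",
            class = "chemnetNoHits")
  flags <- lapply(lists, function(x) genes %in% x)
  res <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nmn in names(flags)) res[[nmn]] <- flags[[nmn]]
  res
}

#' Default pipeline configuration
#'
#' All tunable parameters of the synthetic end-to-end run, echoed into the
#' manifest so no default is hidden.
#'
#' @param seed Master seed.
#' @param outDir Output directory.
#' @return Named list of configuration values.
#' @export
defaultConfig <- function(seed = 1L, outDir = "chemnet_out") {
  list(
    seed = as.integer(seed),
    out_dir = outDir,
    stages = c("simulate", "screen", "microscopy", "network", "enrichment"),
    screen = list(n_strains = 50, n_sensitive = 5, n_resistant = 5,
                  sensitive_multiplier = 0.5, resistant_multiplier = 1.5,
                  noise_sd = 0.05, replicates = 3, n_screens = 3,
                  effect = "od",
                  lower = 75, upper = 130, alpha = 0.05, min_screens = 2),
    microscopy = list(n_strains = 20, n_cells = 200, cutoff = 20,
                      min_cells = 50, n_shifted = 3, shift_pct = 50),
    network = list(n_nodes = 100, n_blocks = 4, p_in = 0.3, p_out = 0.02,
                   min_combined = 900, require_experimental = TRUE,
                   frac_high_conf = 0.7, frac_experimental = 0.95,
                   mode = "minimum", n_null = 199),
    enrichment = list(n_sets = 50, set_size = 20, n_planted = 3,
                      planted_fraction = 0.8, fdr = 0.05, min_size = 3)
  )
}

#' Read a pipeline configuration file (YAML)
#'
#' Values present in the file override the defaults of
#' \code{\link{defaultConfig}}; everything else keeps its default, and the
#' full effective configuration is echoed into the run manifest.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
  stopIfNot(file.exists(path), sprintf("config file '%s' does not exist", path))
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig()
  mergeIn <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        mergeIn(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- mergeIn(cfg, user)
  stopIfNot(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
            "seed must be an integer")
  stopIfNot(cfg$screen$lower < cfg$screen$upper,
            "screen thresholds: lower must be below upper")
  cfg
}

.stageLog <- function(quiet, stage, msg) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a chemical-genomic growth screen, a microscopy table, a
#' planted-partition interactome and a gene-set collection (all planted
#' truths recorded), then scores the screens, merges hit lists into seeds,
#' extracts and annotates the seed network, runs per-community enrichment,
#' and writes every stage output plus a manifest (config echo, seed, file
#' checksums, package version) to the output directory. Fully deterministic
#' given the configuration: rerunning yields byte-identical files.
#'
#' @param config Configuration list (\code{\link{defaultConfig}} or
#'   \code{\link{readPipelineConfig}}).
#' @param outDir Output directory (default from the config).
#' @param quiet Suppress stage log messages.
#' @return Invisibly, a list with the main per-stage results and the
#'   manifest path.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = config$out_dir,
                        quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- config$stages
  written <- character(0)
  results <- list()
  saveJson <- function(x, file) {
    path <- file.path(outDir, file)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, path)
    path
  }
  saveTsv <- function(df, file) {
    path <- file.path(outDir, file)
    writeTsv(df, path)
    written <<- c(written, path)
    path
  }

  if ("simulate" %in% stages) {
    .stageLog(quiet, "simulate", "generating synthetic inputs")
    sc <- config$screen
    screens <- lapply(seq_len(sc$n_screens), function(i)
      simulateGrowthScreen(nStrains = sc$n_strains, nSensitive = sc$n_sensitive,
                           nResistant = sc$n_resistant,
                           sensitiveMultiplier = sc$sensitive_multiplier,
                           resistantMultiplier = sc$resistant_multiplier,
                           noiseSd = sc$noise_sd, replicates = sc$replicates,
                           effect = sc$effect,
                           seed = substreamSeed(seed, "screen", i)))
    mc <- config$microscopy
    shifts <- stats::setNames(rep(mc$shift_pct, mc$n_shifted),
                              sprintf("S%04d", seq_len(mc$n_shifted)))
    mic <- simulateMicroscopy(nStrains = mc$n_strains, nCells = mc$n_cells,
                              abundanceShifts = shifts,
                              seed = substreamSeed(seed, "microscopy"))
    nw <- config$network
    net <- simulateInteractome(nNodes = nw$n_nodes, model = "planted_partition",
                               nBlocks = nw$n_blocks, pIn = nw$p_in,
                               pOut = nw$p_out,
                               fracHighConf = nw$frac_high_conf,
                               fracExperimental = nw$frac_experimental,
                               seed = substreamSeed(seed, "interactome"))
    results$simulated <- list(screens = screens, microscopy = mic,
                              interactome = net)
    saveTsv(do.call(rbind, lapply(seq_along(screens), function(i)
      cbind(screen = i, screens[[i]]$records))), "growth_records.tsv")
    saveTsv(mic$cells, "microscopy_cells.tsv")
    saveTsv(net$edges, "interactome_edges.tsv")
    saveJson(list(screens = lapply(screens, `[[`, "truth"),
                  microscopy = mic$truth, interactome = net$truth),
             "truth.json")
  }

  calledGenes <- list()
  if ("screen" %in% stages) {
    .stageLog(quiet, "screen", "scoring growth screens and calling hits")
    sc <- config$screen
    screens <- results$simulated$screens
    perScreen <- lapply(seq_along(screens), function(i) {
      cg <- chemgenScore(screens[[i]]$records)
      cbind(screen = i, cg$scores)
    })
    allScores <- do.call(rbind, perScreen)
    calls <- callHits(allScores, stage = "screen",
                      lower = sc$lower, upper = sc$upper, alpha = sc$alpha,
                      minScreens = sc$min_screens, nScreens = sc$n_screens)
    results$calls <- calls
    saveTsv(allScores, "screen_scores.tsv")
    saveTsv(calls, "screen_calls.tsv")
    saveJson(as.list(table(calls$call)), "screen_call_counts.json")
    hits <- calls$strain[calls$call %in% c("sensitive", "resistant")]
    ## strain ids double as gene/node ids in the synthetic study
    calledGenes$chemgen <- hits
  }

  if ("microscopy" %in% stages) {
    .stageLog(quiet, "microscopy", "scoring abundance and localization")
    mc <- config$microscopy
    micScores <- scoreMicroscopy(results$simulated$microscopy$cells,
                                 cutoff = mc$cutoff, minCells = mc$min_cells)
    results$microscopy <- micScores
    saveTsv(micScores, "microscopy_scores.tsv")
    flagged <- micScores$strain[!is.na(micScores$flagged) & micScores$flagged]
    ## map microscopy strain ids (S....) onto interactome gene ids (G....)
    calledGenes$microscopy <- sub("^S", "G", flagged)
  }

  if ("network" %in% stages) {
    .stageLog(quiet, "network", "seed network extraction and annotation")
    nw <- config$network
    seedsDf <- do.call(mergeGeneLists, calledGenes)
    results$seeds <- seedsDf
    saveTsv(seedsDf, "seed_genes.tsv")
    inter <- makeInteractome(results$simulated$interactome$edges,
                             minCombined = nw$min_combined,
                             requireExperimental = nw$require_experimental)
    sn <- if (identical(nw$mode, "minimum"))
      minimumNetwork(inter, seedsDf$gene)
    else firstOrderNetwork(inter, seedsDf$gene)
    sn <- annotateSubnetwork(sn, seed = substreamSeed(seed, "network"),
                             nNull = nw$n_null)
    results$subnetwork <- sn
    saveTsv(nodeTable(sn), "subnetwork_nodes.tsv")
    el <- igraph::as_edgelist(interactionGraph(sn))
    saveTsv(data.frame(protein1 = el[, 1], protein2 = el[, 2],
                       stringsAsFactors = FALSE), "subnetwork_edges.tsv")
  }

  if ("enrichment" %in% stages) {
    .stageLog(quiet, "enrichment", "per-community pathway enrichment")
    en <- config$enrichment
    universe <- results$simulated$interactome$truth$nodes
    nt <- nodeTable(results$subnetwork)
    memb <- stats::setNames(nt$community, nt$node)
    gs <- simulateGeneSets(universe = universe,
                           query = nt$node[nt$is_seed],
                           nSets = en$n_sets, setSize = en$set_size,
                           nPlanted = en$n_planted,
                           plantedFraction = en$planted_fraction,
                           seed = substreamSeed(seed, "genesets"))
    writeGMT(gs$sets, file.path(outDir, "gene_sets.gmt"))
    written <- c(written, file.path(outDir, "gene_sets.gmt"))
    results$genesetTruth <- gs$truth
    commEnr <- suppressMessages(
      enrichCommunities(memb, gs$sets, universe, minSize = en$min_size,
                        fdr = en$fdr))
    results$enrichment <- commEnr
    saveTsv(commEnr, "community_enrichment.tsv")
    topRows <- commEnr[commEnr$significant, , drop = FALSE]
    saveJson(list(n_significant = nrow(topRows),
                  significant_sets = unique(topRows$set),
                  communities = unique(topRows$community)),
             "enrichment_summary.json")
  }

  manifest <- list(
    package = "chemnet",
    version = as.character(utils::packageVersion("chemnet")),
    seed = seed,
    config = config,
    outputs = lapply(stats::setNames(nm = basename(sort(unique(written)))),
                     function(f) unname(tools::md5sum(file.path(outDir, f)))))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$manifest <- manifestPath
  .stageLog(quiet, "done", sprintf("outputs in %s", outDir))
  invisible(results)
}
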
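#' Closed-form logistic growth curve
#'
#' OD at time t for logistic growth with rate \code{r}, carrying capacity
#' \code{K} and inoculum \code{od0}.
#'
#' @param times Hours (numeric vector).
#' @param r Maximum specific growth rate (1/h), > 0.
#' @param K Carrying capacity (OD600), > 0.
#' @param od0 Inoculum density (OD600), > 0.
#' @return OD600 values, one per time point.
#' @export
logisticOD <- function(times, r = 0.35, K = 1.2, od0 = 0.01) {
  stopIfNot(all(c(r, K, od0) > 0), "logistic parameters r, K, od0 must be > 0")
  K * od0 * exp(r * times) / (K + od0 * (exp(r * times) - 1))
}

#' Simulate a replicated growth screen with planted hits
#'
#' Generates OD600 time courses for a deletion-library screen under a vehicle
#' and a treated condition. Control strains follow logistic growth with
#' multiplicative log-normal noise; planted sensitive/resistant strains carry
#' an effect multiplier applied, under treatment, either to the growth rate
#' (\code{effect = "rate"}) or to the whole OD trajectory
#' (\code{effect = "od"}, in which case the multiplier equals the noise-free
#' percent growth / 100 at any fixed time). Each strain draws from its own RNG
#' substream, so enlarging the library never reshuffles existing strains.
#'
#' @param nStrains Number of library strains.
#' @param nSensitive,nResistant Numbers of planted sensitive/resistant strains.
#' @param sensitiveMultiplier Effect multiplier in (0,1) for sensitive strains.
#' @param resistantMultiplier Effect multiplier > 1 for resistant strains.
#' @param noiseSd Relative (log-normal) OD noise s.d.; 0 gives noise-free curves.
#' @param replicates Replicates per condition, >= 1.
#' @param times Strictly increasing sampling times (hours).
#' @param r,K,od0 Logistic parameters of the control curve.
#' @param effect How the multiplier acts: \code{"rate"} or \code{"od"}.
#' @param seed Master seed.
#' @return A list with \code{records} (data.frame: strain, condition,
#'   replicate, time_h, od600) and \code{truth} (list with planted sets,
#'   multipliers and all generator parameters).
#' @export
simulateGrowthScreen <- function(nStrains = 50, nSensitive = 5, nResistant = 5,
                                 sensitiveMultiplier = 0.5,
                                 resistantMultiplier = 1.5,
                                 noiseSd = 0.05, replicates = 3,
                                 times = 0:14, r = 0.35, K = 1.2, od0 = 0.01,
                                 effect = c("rate", "od"), seed = 1L) {
  effect <- match.arg(effect)
  stopIfNot(nStrains >= 1, "strain list must be non-empty")
  stopIfNot(all(diff(times) > 0), "times must be strictly increasing")
  stopIfNot(all(c(r, K, od0) > 0), "growth model parameters must be positive")
  stopIfNot(sensitiveMultiplier > 0 && sensitiveMultiplier < 1,
            "sensitive multiplier must lie in (0,1)")
  stopIfNot(resistantMultiplier > 1, "resistant multiplier must be > 1")
  stopIfNot(nSensitive + nResistant <= nStrains, "too many planted strains")
  stopIfNot(replicates >= 1, "need at least one replicate")

  strains <- sprintf("G%04d", seq_len(nStrains))
  sensitive <- strains[seq_len(nSensitive)]
  resistant <- strains[nSensitive + seq_len(nResistant)]
  mult <- stats::setNames(rep(1, nStrains), strains)
  mult[sensitive] <- sensitiveMultiplier
  mult[resistant] <- resistantMultiplier

  conditions <- c("vehicle", "treated")
  nt <- length(times)
  rows <- vector("list", nStrains)
  for (i in seq_len(nStrains)) {
    s <- strains[i]
    od <- withSubstream(seed, "growth", s, expr = {
      out <- numeric(0)
      for (cond in conditions) {
        m <- if (cond == "treated") mult[[s]] else 1
        base <- switch(effect,
          rate = logisticOD(times, r = r * m, K = K, od0 = od0),
          od   = m * logisticOD(times, r = r, K = K, od0 = od0))
        for (rep_ in seq_len(replicates)) {
          eps <- if (noiseSd > 0) exp(stats::rnorm(nt, 0, noiseSd)) else rep(1, nt)
          out <- c(out, base * eps)
        }
      }
      out
    })
    rows[[i]] <- data.frame(
      strain = s,
      condition = rep(conditions, each = replicates * nt),
      replicate = rep(rep(seq_len(replicates), each = nt), times = 2),
      time_h = rep(times, times = 2 * replicates),
      od600 = od,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  truth <- list(kind = "growth_screen", strains = strains,
                planted_sensitive = sensitive, planted_resistant = resistant,
                multipliers = as.list(mult[mult != 1]),
                sensitive_multiplier = sensitiveMultiplier,
                resistant_multiplier = resistantMultiplier,
                noise_sd = noiseSd, replicates = replicates, effect = effect,
                growth_model = list(r = r, K = K, od0 = od0),
                times = times, seed = seed)
  list(records = records, truth = truth)
}

#' Simulate a STRING-like confidence-scored interactome
#'
#' Generates an undirected simple graph under one of three models and decorates
#' each edge with an integer \code{combined_score} in [150, 1000] (a
#' configurable fraction at >= 900, so the high-confidence filter is exercised)
#' and an \code{experimental} channel score (0 for edges lacking experimental
#' evidence).
#'
#' @param nNodes Number of nodes, >= 2.
#' @param model \code{"planted_partition"}, \code{"erdos_renyi"} or
#'   \code{"preferential_attachment"}.
#' @param p Edge probability (erdos_renyi).
#' @param nBlocks,pIn,pOut Planted-partition parameters; requires
#'   \code{0 <= pOut < pIn <= 1}.
#' @param mEdges Edges added per step (preferential_attachment).
#' @param fracHighConf Fraction of edges with combined_score >= 900.
#' @param fracExperimental Fraction of edges with experimental evidence.
#' @param seed Master seed.
#' @return A list with \code{edges} (data.frame: protein1, protein2,
#'   experimental, combined_score) and \code{truth} (block assignment and
#'   parameters).
#' @export
simulateInteractome <- function(nNodes = 100,
                                model = c("planted_partition", "erdos_renyi",
                                          "preferential_attachment"),
                                p = 0.05, nBlocks = 4, pIn = 0.3, pOut = 0.02,
                                mEdges = 2, fracHighConf = 0.6,
                                fracExperimental = 0.9, seed = 1L) {
  model <- match.arg(model)
  stopIfNot(nNodes >= 2, "need at least two nodes")
  nodes <- sprintf("G%04d", seq_len(nNodes))
  blocks <- NULL
  g <- withSubstream(seed, "interactome", model, expr = {
    switch(model,
      erdos_renyi = igraph::sample_gnp(nNodes, p),
      preferential_attachment =
        igraph::as_undirected(igraph::sample_pa(nNodes, m = mEdges), mode = "collapse"),
      planted_partition = {
        stopIfNot(pOut >= 0 && pOut < pIn && pIn <= 1,
                  "planted partition requires 0 <= pOut < pIn <= 1")
        sizes <- rep(nNodes %/% nBlocks, nBlocks)
        sizes[seq_len(nNodes %% nBlocks)] <- sizes[seq_len(nNodes %% nBlocks)] + 1L
        pm <- matrix(pOut, nBlocks, nBlocks); diag(pm) <- pIn
        igraph::sample_sbm(nNodes, pref.matrix = pm, block.sizes = sizes)
      })
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- nodes
  if (model == "planted_partition") {
    sizes <- rep(nNodes %/% nBlocks, nBlocks)
    sizes[seq_len(nNodes %% nBlocks)] <- sizes[seq_len(nNodes %% nBlocks)] + 1L
    blocks <- stats::setNames(rep(seq_len(nBlocks), times = sizes), nodes)
  }
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  scores <- withSubstream(seed, "interactome_scores", model, expr = {
    hi <- stats::runif(m) < fracHighConf
    combined <- ifelse(hi, sample(900:1000, m, replace = TRUE),
                       sample(150:899, m, replace = TRUE))
    hasExp <- stats::runif(m) < fracExperimental
    experimental <- ifelse(hasExp, sample(150:1000, m, replace = TRUE), 0L)
    data.frame(experimental = as.integer(experimental),
               combined_score = as.integer(combined))
  })
  edges <- if (m > 0) {
    data.frame(protein1 = el[, 1], protein2 = el[, 2],
               experimental = scores$experimental,
               combined_score = scores$combined_score,
               stringsAsFactors = FALSE)
  } else {
    data.frame(protein1 = character(0), protein2 = character(0),
               experimental = integer(0), combined_score = integer(0))
  }
  truth <- list(kind = "interactome", model = model, nodes = nodes,
                blocks = as.list(blocks),
                params = list(p = p, nBlocks = nBlocks, pIn = pIn, pOut = pOut,
                              mEdges = mEdges, fracHighConf = fracHighConf,
                              fracExperimental = fracExperimental),
                seed = seed)
  list(edges = edges, truth = truth)
}

#' Simulate a gene-set collection with planted over-representation
#'
#' Builds a GMT-style collection over a gene universe: \code{nPlanted} sets
#' draw a stated fraction of their members from the query list (guaranteeing
#' overlap above the hypergeometric expectation), the remaining decoy sets are
#' sampled uniformly from the universe.
#'
#' @param universe Character vector of universe gene ids.
#' @param query Query gene list; must be a subset of \code{universe}.
#' @param nSets Total number of sets.
#' @param setSize Genes per set (must not exceed the universe size).
#' @param nPlanted Number of planted enriched sets.
#' @param plantedFraction Fraction of each planted set drawn from the query.
#' @param seed Master seed.
#' @return A list with \code{sets} (named list of character vectors) and
#'   \code{truth} (planted set ids and parameters).
#' @export
simulateGeneSets <- function(universe, query, nSets = 100, setSize = 50,
                             nPlanted = 3, plantedFraction = 0.8, seed = 1L) {
  stopIfNot(all(query %in% universe), "query must be a subset of the universe")
  stopIfNot(setSize <= length(universe), "set size exceeds universe")
  stopIfNot(nPlanted <= nSets, "more planted sets than sets")
  setIds <- sprintf("SET%03d", seq_len(nSets))
  planted <- setIds[seq_len(nPlanted)]
  nFromQuery <- min(length(query), round(plantedFraction * setSize))
  sets <- stats::setNames(vector("list", nSets), setIds)
  for (i in seq_len(nSets)) {
    id <- setIds[i]
    sets[[id]] <- withSubstream(seed, "genesets", id, expr = {
      if (i <= nPlanted) {
        fromQ <- sample(query, nFromQuery)
        rest <- sample(setdiff(universe, fromQ), setSize - nFromQuery)
        sort(c(fromQ, rest))
      } else sort(sample(universe, setSize))
    })
  }
  truth <- list(kind = "genesets", planted_enriched = planted,
                universe_size = length(universe), n_sets = nSets,
                set_size = setSize, planted_fraction = plantedFraction,
                query_size = length(query), seed = seed)
  list(sets = sets, truth = truth)
}

.compartments <- c("cytosol", "nucleus", "vacuole", "ER", "plasma_membrane",
                   "endosome", "cytoplasmic_foci", "other")

#' Simulate a per-cell fluorescence quantification table
#'
#' Emulates high-content microscopy exports: per cell, a GFP intensity for the
#' tagged protein and an RFP reference intensity, both log-normal around
#' strain-level means, plus a compartment label. Planted abundance shifts
#' scale the treated-condition GFP mean; planted localization shifts move the
#' treated compartment distribution's mass to a target compartment.
#'
#' @param nStrains Number of strains.
#' @param nCells Cells per strain per condition, >= 10.
#' @param abundanceShifts Named numeric vector, percent GFP change under
#'   treatment for planted strains (e.g. \code{c(S0001 = 50)}); must be
#'   > -100.
#' @param localizationShifts Named character vector, target compartment for
#'   planted localization movers.
#' @param noiseSd Log-scale intensity noise s.d.
#' @param baseFractions Control-condition compartment distribution (named,
#'   sums to 1); default is predominantly cytosolic.
#' @param shiftFraction Treated-condition fraction in the target compartment
#'   for localization movers.
#' @param seed Master seed.
#' @return A list with \code{cells} (data.frame: strain, condition, cell_id,
#'   gfp, rfp, compartment) and \code{truth}.
#' @export
simulateMicroscopy <- function(nStrains = 30, nCells = 200,
                               abundanceShifts = NULL,
                               localizationShifts = NULL,
                               noiseSd = 0.1,
                               baseFractions = c(cytosol = 0.88, nucleus = 0.04,
                                                 vacuole = 0.03, ER = 0.02,
                                                 plasma_membrane = 0.01,
                                                 endosome = 0.01,
                                                 cytoplasmic_foci = 0.005,
                                                 other = 0.005),
                               shiftFraction = 0.9, seed = 1L) {
  stopIfNot(nCells >= 10, "need at least 10 cells per strain")
  stopIfNot(is.null(abundanceShifts) || all(abundanceShifts > -100),
            "abundance shift of -100% or lower is not meaningful")
  stopIfNot(all(names(baseFractions) %in% .compartments),
            "unknown compartment in baseFractions")
  baseFractions <- baseFractions / sum(baseFractions)
  strains <- sprintf("S%04d", seq_len(nStrains))
  shifts <- stats::setNames(rep(0, nStrains), strains)
  if (!is.null(abundanceShifts)) {
    stopIfNot(all(names(abundanceShifts) %in% strains),
              "abundanceShifts names must be strain ids")
    shifts[names(abundanceShifts)] <- abundanceShifts
  }
  movers <- stats::setNames(rep(NA_character_, nStrains), strains)
  if (!is.null(localizationShifts)) {
    stopIfNot(all(names(localizationShifts) %in% strains) &&
              all(localizationShifts %in% .compartments),
              "localizationShifts must map strain ids to known compartments")
    movers[names(localizationShifts)] <- localizationShifts
  }
  gfpMean <- log(1000); rfpMean <- log(500)
  conditions <- c("control", "treated")
  rows <- vector("list", nStrains)
  for (i in seq_len(nStrains)) {
    s <- strains[i]
    dat <- withSubstream(seed, "microscopy", s, expr = {
      out <- NULL
      for (cond in conditions) {
        mult <- if (cond == "treated") 1 + shifts[[s]] / 100 else 1
        gfp <- exp(stats::rnorm(nCells, gfpMean + log(mult), noiseSd))
        rfp <- exp(stats::rnorm(nCells, rfpMean, noiseSd))
        fr <- baseFractions
        if (cond == "treated" && !is.na(movers[[s]])) {
          tgt <- movers[[s]]
          fr <- baseFractions * (1 - shiftFraction) / sum(baseFractions[setdiff(names(baseFractions), tgt)])
          fr[tgt] <- shiftFraction
          fr <- fr / sum(fr)
        }
        comp <- sample(names(fr), nCells, replace = TRUE, prob = fr)
        out <- rbind(out, data.frame(
          strain = s, condition = cond, cell_id = seq_len(nCells),
          gfp = gfp, rfp = rfp, compartment = comp, stringsAsFactors = FALSE))
      }
      out
    })
    rows[[i]] <- dat
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  truth <- list(kind = "microscopy", strains = strains,
                abundance_shifts = as.list(shifts[shifts != 0]),
                localization_shifts = as.list(movers[!is.na(movers)]),
                noise_sd = noiseSd, n_cells = nCells,
                shift_fraction = shiftFraction, seed = seed)
  list(cells = cells, truth = truth)
}

#' Simulate a colony-size plate grid with spatial gradients and planted hits
#'
#' Builds a rows x cols colony-size matrix around a common mean, optionally
#' multiplied by smooth row/column gradients (pinned-plate artefacts), with
#' planted positions scaled by an effect multiplier.
#'
#' @param nrow,ncol Plate dimensions (32 x 48 is the 1536 format).
#' @param meanSize Mean colony size (pixels).
#' @param noiseSd Relative log-normal noise s.d.
#' @param rowGradient,colGradient Multiplicative ranges, e.g. \code{c(0.8, 1.2)};
#'   \code{NULL} for none.
#' @param planted Integer matrix positions (two columns: row, col) to scale.
#' @param plantedMultiplier Effect multiplier for planted positions.
#' @param seed Master seed.
#' @return A list with \code{sizes} (matrix) and \code{truth}.
#' @export
simulatePlateGrid <- function(nrow = 32, ncol = 48, meanSize = 100,
                              noiseSd = 0.05, rowGradient = NULL,
                              colGradient = NULL, planted = NULL,
                              plantedMultiplier = 0.5, seed = 1L) {
  sizes <- withSubstream(seed, "plate", nrow, ncol, expr = {
    matrix(meanSize * exp(stats::rnorm(nrow * ncol, 0, noiseSd)), nrow, ncol)
  })
  if (!is.null(rowGradient))
    sizes <- sizes * seq(rowGradient[1], rowGradient[2], length.out = nrow)
  if (!is.null(colGradient))
    sizes <- sizes * rep(seq(colGradient[1], colGradient[2], length.out = ncol),
                         each = nrow)
  if (!is.null(planted)) {
    planted <- as.matrix(planted)
    sizes[planted] <- sizes[planted] * plantedMultiplier
  }
  list(sizes = sizes,
       truth = list(kind = "plate", planted = planted,
                    planted_multiplier = plantedMultiplier, seed = seed))
}
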
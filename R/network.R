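#' Build an Interactome from an edge table
#'
#' Applies the confidence filter (STRING-style \code{combined_score} at or
#' above \code{minCombined}, and, when required, a positive
#' \code{experimental} evidence score), removes self-loops, and collapses
#' duplicate undirected edges (keeping the first occurrence). Node names are
#' case-normalized to upper case.
#'
#' @param edges data.frame with columns \code{protein1}, \code{protein2},
#'   \code{experimental}, \code{combined_score}.
#' @param minCombined Minimum combined confidence score (default 900).
#' @param requireExperimental Keep only edges with experimental evidence
#'   (score > 0).
#' @param verbose Log edge counts before/after filtering.
#' @return An \code{\linkS4class{Interactome}}.
#' @export
makeInteractome <- function(edges, minCombined = 900,
                            requireExperimental = TRUE, verbose = FALSE) {
  need <- c("protein1", "protein2", "experimental", "combined_score")
  stopIfNot(all(need %in% names(edges)), "edge table lacks required columns")
  bad <- which(!is.finite(edges$combined_score) | !is.finite(edges$experimental))
  stopIfNot(length(bad) == 0,
            sprintf("malformed edge row(s): %s (non-numeric scores)",
                    paste(utils::head(bad, 5), collapse = ", ")))
  stopIfNot(all(edges$combined_score >= 0 & edges$combined_score <= 1000) &&
            all(edges$experimental >= 0 & edges$experimental <= 1000),
            "scores must lie in [0, 1000]")
  nInput <- nrow(edges)
  keep <- edges$combined_score >= minCombined
  if (requireExperimental) keep <- keep & edges$experimental > 0
  e <- edges[keep, , drop = FALSE]
  e$protein1 <- toupper(e$protein1); e$protein2 <- toupper(e$protein2)
  e <- e[e$protein1 != e$protein2, , drop = FALSE]             # self-loops out
  key <- ifelse(e$protein1 < e$protein2,
                paste(e$protein1, e$protein2, sep = "\r"),
                paste(e$protein2, e$protein1, sep = "\r"))
  e <- e[!duplicated(key), , drop = FALSE]                     # undirected de-dup
  if (verbose)
    message(sprintf("interactome: %d input rows -> %d edges after filtering",
                    nInput, nrow(e)))
  if (nrow(e) == 0) {
    warning("interactome is empty after filtering")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      e[, c("protein1", "protein2", "experimental", "combined_score")],
      directed = FALSE)
  }
  new("Interactome", graph = g, nEdgesInput = as.integer(nInput))
}

#' Read a STRING-like edge TSV into an Interactome
#'
#' The file must have a header with columns \code{protein1}, \code{protein2},
#' \code{experimental}, \code{combined_score}. Malformed rows are reported
#' with their line numbers.
#'
#' @inheritParams makeInteractome
#' @param path Path to the edge TSV.
#' @return An \code{\linkS4class{Interactome}}.
#' @export
readInteractome <- function(path, minCombined = 900, requireExperimental = TRUE,
                            verbose = TRUE) {
  edges <- tryCatch(readTsv(path, colClasses = c(protein1 = "character",
                                                 protein2 = "character")),
                    error = function(e) stop(errorCondition(
                      sprintf("cannot parse edge file '%s': %s", path,
                              conditionMessage(e)),
                      class = c("chemnetParseError", "error"))))
  need <- c("protein1", "protein2", "experimental", "combined_score")
  stopIfNot(all(need %in% names(edges)),
            sprintf("edge file '%s' lacks header columns %s", path,
                    paste(setdiff(need, names(edges)), collapse = ", ")))
  for (col in c("experimental", "combined_score")) {
    v <- suppressWarnings(as.numeric(edges[[col]]))
    badLines <- which(is.na(v)) + 1L   # +1 for the header line
    stopIfNot(length(badLines) == 0,
              sprintf("malformed %s at line(s) %s of '%s'", col,
                      paste(utils::head(badLines, 5), collapse = ", "), path))
    edges[[col]] <- v
  }
  makeInteractome(edges, minCombined = minCombined,
                  requireExperimental = requireExperimental, verbose = verbose)
}

.asGraph <- function(x) {
  if (methods::is(x, "Interactome") || methods::is(x, "Subnetwork")) x@graph
  else if (igraph::is_igraph(x)) x
  else stop("expected an Interactome, Subnetwork or igraph object")
}

.newSubnetwork <- function(graph, seeds, unmapped, mode) {
  nm <- igraph::V(graph)$name
  nt <- data.frame(node = nm, is_seed = nm %in% seeds, stringsAsFactors = FALSE)
  nt <- nt[order(nt$node), , drop = FALSE]
  rownames(nt) <- NULL
  new("Subnetwork", graph = graph, seeds = sort(seeds),
      unmappedSeeds = sort(unmapped), mode = mode, nodeTable = nt)
}

#' First-order network around seed genes
#'
#' The subgraph induced by the mapped seeds plus all of their direct
#' interactome neighbors. Seeds with no edges are retained as isolated nodes;
#' seed identifiers absent from the interactome are reported via
#' \code{\link{unmappedSeeds}}.
#'
#' @param interactome An \code{\linkS4class{Interactome}}.
#' @param seeds Character vector of seed gene identifiers (case-insensitive).
#' @return A \code{\linkS4class{Subnetwork}} with mode \code{"first-order"}.
#' @export
firstOrderNetwork <- function(interactome, seeds) {
  stopIfNot(length(seeds) > 0, "seeds must be non-empty")
  g <- .asGraph(interactome)
  seeds <- unique(toupper(seeds))
  nm <- igraph::V(g)$name
  mapped <- intersect(seeds, nm)
  unmapped <- setdiff(seeds, nm)
  stopIfNot(length(mapped) > 0, "no seed maps to the interactome")
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(g, mapped), names)))
  nodes <- sort(unique(c(mapped, nbrs)))
  sub <- igraph::induced_subgraph(g, nodes)
  .newSubnetwork(sub, mapped, unmapped, "first-order")
}

## Deterministic level-synchronous BFS from a set of source nodes over a
## sorted adjacency list. Parents break equal-length ties lexicographically
## (frontier scanned in sorted order). Returns integer distances and parents.
.bfsFromSet <- function(adj, nodes, sources) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  frontier <- sort(sources)
  dist[idx[frontier]] <- 0L
  d <- 0L
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        iv <- idx[[v]]
        if (is.na(dist[iv])) {
          dist[iv] <- d + 1L
          parent[iv] <- idx[[u]]
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- sort(unique(nxt))
    d <- d + 1L
  }
  list(dist = dist, parent = parent, idx = idx)
}

#' Minimum connector network joining seed genes
#'
#' Approximates, per connected component of the interactome containing seeds,
#' the Steiner tree connecting all seeds in that component, using the
#' Takahashi-Matsuyama incremental shortest-path heuristic on unit edge
#' lengths (a 2-approximation): starting from the lexicographically smallest
#' seed, the nearest unconnected seed is repeatedly attached along a shortest
#' path, with lexicographic tie-breaking on both the seed and the path. The
#' result is the union of the trees' nodes with all induced interactome
#' edges. Non-seed tree leaves are pruned, so every retained connector lies on
#' a seed-to-seed path.
#'
#' @inheritParams firstOrderNetwork
#' @return A \code{\linkS4class{Subnetwork}} with mode \code{"minimum"}.
#' @export
minimumNetwork <- function(interactome, seeds) {
  stopIfNot(length(seeds) > 0, "seeds must be non-empty")
  g <- .asGraph(interactome)
  seeds <- unique(toupper(seeds))
  nm <- igraph::V(g)$name
  mapped <- intersect(seeds, nm)
  unmapped <- setdiff(seeds, nm)
  stopIfNot(length(mapped) > 0, "no seed maps to the interactome")

  comp <- igraph::components(g)$membership
  adj <- lapply(igraph::adjacent_vertices(g, nm), function(v) sort(names(v)))
  names(adj) <- nm

  allNodes <- character(0)
  for (cid in sort(unique(comp[mapped]))) {
    compSeeds <- sort(mapped[comp[mapped] == cid])
    compNodes <- sort(nm[comp == cid])
    treeNodes <- compSeeds[1]
    treeEdges <- matrix(character(0), ncol = 2)
    remaining <- setdiff(compSeeds, treeNodes)
    while (length(remaining)) {
      bfs <- .bfsFromSet(adj, compNodes, intersect(treeNodes, compNodes))
      dRem <- bfs$dist[bfs$idx[remaining]]
      best <- remaining[order(dRem, remaining)][1]
      ## trace the shortest path from the chosen seed back into the tree
      path <- best
      cur <- bfs$idx[[best]]
      while (!is.na(bfs$parent[cur])) {
        cur <- bfs$parent[cur]
        path <- c(path, compNodes[cur])
      }
      for (i in seq_len(length(path) - 1))
        treeEdges <- rbind(treeEdges, c(path[i], path[i + 1]))
      treeNodes <- union(treeNodes, path)
      remaining <- setdiff(remaining, treeNodes)
    }
    ## prune non-seed leaves of the tree (guarantee, not expectation)
    if (nrow(treeEdges)) {
      repeat {
        degTree <- table(factor(c(treeEdges[, 1], treeEdges[, 2]),
                                levels = treeNodes))
        drop <- treeNodes[degTree <= 1 & !(treeNodes %in% compSeeds)]
        if (!length(drop)) break
        keepE <- !(treeEdges[, 1] %in% drop | treeEdges[, 2] %in% drop)
        treeEdges <- treeEdges[keepE, , drop = FALSE]
        treeNodes <- setdiff(treeNodes, drop)
      }
    }
    allNodes <- union(allNodes, treeNodes)
  }
  sub <- igraph::induced_subgraph(g, sort(allNodes))
  .newSubnetwork(sub, mapped, unmapped, "minimum")
}

#' Degree and betweenness centrality of subnetwork nodes
#'
#' Brandes betweenness on the unweighted undirected graph: unnormalized,
#' endpoints excluded, shortest-path multiplicity shared fractionally.
#'
#' @param x A \code{\linkS4class{Subnetwork}}, \code{\linkS4class{Interactome}}
#'   or igraph object.
#' @return data.frame: node, degree, betweenness, ordered by decreasing
#'   betweenness then node id.
#' @export
nodeCentralities <- function(x) {
  g <- .asGraph(x)
  stopIfNot(igraph::vcount(g) > 0, "graph is empty")
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  df <- data.frame(node = igraph::V(g)$name,
                   degree = as.integer(igraph::degree(g)),
                   betweenness = as.numeric(btw), stringsAsFactors = FALSE)
  df <- df[order(-df$betweenness, df$node), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Two-level map equation (bits) from module statistics.
## degSum, cut are per-module totals; totDeg = 2|E|.
.mapEqFromStats <- function(degSum, cut, totDeg, nodeTerm) {
  q <- cut / totDeg
  pmod <- degSum / totDeg
  plogp(sum(q)) - 2 * sum(plogp(q)) + sum(plogp(q + pmod)) - nodeTerm
}

#' Two-level map equation of a partition
#'
#' Description length (bits per step) of a random walk on the unweighted
#' undirected graph under a two-level modular code: node visit rates are
#' degree-proportional, module exit rates are boundary-edge fractions, no
#' teleportation.
#'
#' @param x Graph-bearing object (igraph, Interactome or Subnetwork).
#' @param membership Named (by node) or node-ordered module labels.
#' @return Code length in bits.
#' @export
mapEquation <- function(x, membership) {
  g <- .asGraph(x)
  n <- igraph::vcount(g)
  memb <- .alignMembership(g, membership)
  deg <- as.numeric(igraph::degree(g))
  totDeg <- sum(deg)
  if (totDeg == 0) return(0)
  el <- igraph::as_edgelist(g, names = FALSE)
  mods <- sort(unique(memb))
  degSum <- vapply(mods, function(m) sum(deg[memb == m]), numeric(1))
  cut <- vapply(mods, function(m) {
    sum(xor(memb[el[, 1]] == m, memb[el[, 2]] == m))
  }, numeric(1))
  nodeTerm <- sum(plogp(deg / totDeg))
  .mapEqFromStats(degSum, cut, totDeg, nodeTerm)
}

.alignMembership <- function(g, membership) {
  nm <- igraph::V(g)$name
  if (!is.null(names(membership))) {
    stopIfNot(all(nm %in% names(membership)),
              "membership must cover every node")
    membership <- membership[nm]
  } else {
    stopIfNot(length(membership) == length(nm),
              "membership length must equal node count")
  }
  as.integer(factor(membership))
}

#' Detect communities by greedy map-equation minimization
#'
#' Two-level map-equation partitioning: starting from singleton modules,
#' repeated node-moving passes (each node may join the best-improving
#' neighboring module) alternate with module-merge steps until no move lowers
#' the code length. Deterministic given \code{seed}, which fixes the node
#' visit order of each pass. The per-pass code lengths are attached as
#' attribute \code{"codelengths"} and are non-increasing by construction.
#'
#' @param x Graph-bearing object (igraph, Interactome or Subnetwork).
#' @param seed Integer seed for the node-visit order.
#' @param tol Minimum code-length improvement to accept a move (bits).
#' @param maxPasses Safety cap on node-moving passes.
#' @return Named integer vector of community labels (consecutive, starting at
#'   1), with attribute \code{codelengths}.
#' @export
detectCommunities <- function(x, seed = 1L, tol = 1e-10, maxPasses = 200L) {
  g <- .asGraph(x)
  n <- igraph::vcount(g)
  stopIfNot(n > 0, "graph is empty")
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  deg <- as.numeric(igraph::degree(g))
  totDeg <- sum(deg)
  if (igraph::ecount(g) == 0) {
    warning("edgeless graph: returning all-singleton partition")
    res <- stats::setNames(seq_len(n), nm)
    attr(res, "codelengths") <- 0
    return(res)
  }
  adjl <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  memb <- seq_len(n)
  degSum <- deg
  cut <- deg                       # singleton modules: every edge is external
  nodeTerm <- sum(plogp(deg / totDeg))
  SQ <- sum(cut) / totDeg
  sumPlogpQ <- sum(plogp(cut / totDeg))
  sumPlogpQP <- sum(plogp((cut + degSum) / totDeg))
  L <- plogp(SQ) - 2 * sumPlogpQ + sumPlogpQP - nodeTerm
  codelengths <- L

  moduleTerms <- function(cutM, degM)
    c(q = cutM / totDeg, pq = plogp(cutM / totDeg),
      pqp = plogp((cutM + degM) / totDeg))

  applyGlobal <- function(dq, dpq, dpqp) {
    SQ <<- SQ + dq
    sumPlogpQ <<- sumPlogpQ + dpq
    sumPlogpQP <<- sumPlogpQP + dpqp
    L <<- plogp(SQ) - 2 * sumPlogpQ + sumPlogpQP - nodeTerm
  }

  set.seed(seed)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > maxPasses) break
    order_ <- sample.int(n)
    moved <- FALSE
    for (v in order_) {
      kv <- deg[v]
      if (kv == 0) next
      A <- memb[v]
      nbrMods <- memb[adjl[[v]]]
      eTab <- table(nbrMods)
      eToA <- if (as.character(A) %in% names(eTab)) eTab[[as.character(A)]] else 0
      cand <- setdiff(as.integer(names(eTab)), A)
      if (!length(cand)) next
      oldA <- moduleTerms(cut[A], degSum[A])
      bestDelta <- -tol; bestB <- NA_integer_
      bestNew <- NULL
      for (B in cand) {
        eToB <- eTab[[as.character(B)]]
        cutA2 <- cut[A] - kv + 2 * eToA
        cutB2 <- cut[B] + kv - 2 * eToB
        degA2 <- degSum[A] - kv
        degB2 <- degSum[B] + kv
        oldB <- moduleTerms(cut[B], degSum[B])
        newA <- moduleTerms(cutA2, degA2)
        newB <- moduleTerms(cutB2, degB2)
        dq <- (newA["q"] + newB["q"]) - (oldA["q"] + oldB["q"])
        dpq <- (newA["pq"] + newB["pq"]) - (oldA["pq"] + oldB["pq"])
        dpqp <- (newA["pqp"] + newB["pqp"]) - (oldA["pqp"] + oldB["pqp"])
        Lnew <- plogp(SQ + dq) - 2 * (sumPlogpQ + dpq) +
          (sumPlogpQP + dpqp) - nodeTerm
        delta <- Lnew - L
        if (delta < bestDelta) {
          bestDelta <- delta; bestB <- B
          bestNew <- list(cutA2 = cutA2, cutB2 = cutB2,
                          degA2 = degA2, degB2 = degB2,
                          dq = dq, dpq = dpq, dpqp = dpqp)
        }
      }
      if (!is.na(bestB)) {
        memb[v] <- bestB
        cut[A] <- bestNew$cutA2; cut[bestB] <- bestNew$cutB2
        degSum[A] <- bestNew$degA2; degSum[bestB] <- bestNew$degB2
        applyGlobal(bestNew$dq, bestNew$dpq, bestNew$dpqp)
        moved <- TRUE
      }
    }
    codelengths <- c(codelengths, L)
    if (moved) next
    ## no single-node move helps: try merging connected module pairs
    el <- igraph::as_edgelist(g, names = FALSE)
    mA <- memb[el[, 1]]; mB <- memb[el[, 2]]
    cross <- mA != mB
    if (!any(cross)) break
    pairKey <- paste(pmin(mA[cross], mB[cross]), pmax(mA[cross], mB[cross]))
    eAB <- table(pairKey)
    bestDelta <- -tol; bestPair <- NULL
    for (k in names(eAB)) {
      ab <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
      A <- ab[1]; B <- ab[2]
      oldA <- moduleTerms(cut[A], degSum[A])
      oldB <- moduleTerms(cut[B], degSum[B])
      cutM <- cut[A] + cut[B] - 2 * eAB[[k]]
      degM <- degSum[A] + degSum[B]
      newM <- moduleTerms(cutM, degM)
      dq <- newM["q"] - oldA["q"] - oldB["q"]
      dpq <- newM["pq"] - oldA["pq"] - oldB["pq"]
      dpqp <- newM["pqp"] - oldA["pqp"] - oldB["pqp"]
      Lnew <- plogp(SQ + dq) - 2 * (sumPlogpQ + dpq) +
        (sumPlogpQP + dpqp) - nodeTerm
      delta <- Lnew - L
      if (delta < bestDelta) {
        bestDelta <- delta
        bestPair <- list(A = A, B = B, cutM = cutM, degM = degM,
                         dq = dq, dpq = dpq, dpqp = dpqp)
      }
    }
    if (is.null(bestPair)) break
    memb[memb == bestPair$B] <- bestPair$A
    cut[bestPair$A] <- bestPair$cutM; cut[bestPair$B] <- 0
    degSum[bestPair$A] <- bestPair$degM; degSum[bestPair$B] <- 0
    applyGlobal(bestPair$dq, bestPair$dpq, bestPair$dpqp)
    codelengths <- c(codelengths, L)
  }
  ## renumber communities deterministically by smallest member node name
  first <- vapply(split(nm, memb), function(x) min(x), character(1))
  lab <- match(memb, as.integer(names(sort(first))))
  res <- stats::setNames(as.integer(lab), nm)
  attr(res, "codelengths") <- as.numeric(codelengths)
  res
}

#' Community significance under a degree-preserving null
#'
#' For each community, the internal edge count is compared with its
#' distribution over \code{nNull} degree-preserving edge rewirings of the
#' whole graph (10 x |E| swap attempts per sample), giving
#' \code{p = (1 + #(null >= observed)) / (nNull + 1)}.
#'
#' @param x Graph-bearing object.
#' @param membership Community labels (named by node, or node-ordered).
#' @param nNull Number of null rewirings, >= 19.
#' @param seed Master seed; each null sample uses its own substream.
#' @return data.frame: community, n_nodes, internal_edges, p.
#' @export
communitySignificance <- function(x, membership, nNull = 999, seed = 1L) {
  stopIfNot(nNull >= 19, "nNull < 19 gives too coarse a p-value resolution")
  g <- .asGraph(x)
  memb <- .alignMembership(g, membership)
  mods <- sort(unique(memb))
  internal <- function(graph) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    same <- memb[el[, 1]] == memb[el[, 2]]
    vapply(mods, function(m)
      sum(same & memb[el[, 1]] == m), numeric(1))
  }
  obs <- internal(g)
  geq <- rep(0, length(mods))
  nSwaps <- max(1L, 10L * igraph::ecount(g))
  for (i in seq_len(nNull)) {
    gNull <- withSubstream(seed, "rewire", i, expr =
      igraph::rewire(g, igraph::keeping_degseq(niter = nSwaps)))
    geq <- geq + (internal(gNull) >= obs)
  }
  data.frame(community = mods,
             n_nodes = as.integer(table(factor(memb, levels = mods))),
             internal_edges = as.integer(obs),
             p = (1 + geq) / (nNull + 1))
}

#' Annotate a Subnetwork with centralities, communities and significance
#'
#' Fills the node table with degree, betweenness, community labels and
#' community p-values.
#'
#' @param sn A \code{\linkS4class{Subnetwork}}.
#' @param seed Seed for community detection and null rewirings.
#' @param nNull Null samples for community significance (0 to skip).
#' @return The annotated \code{\linkS4class{Subnetwork}}.
#' @export
annotateSubnetwork <- function(sn, seed = 1L, nNull = 999) {
  stopIfNot(methods::is(sn, "Subnetwork"), "expected a Subnetwork")
  cent <- nodeCentralities(sn)
  nt <- merge(nodeTable(sn)[, c("node", "is_seed")], cent, by = "node")
  if (igraph::ecount(sn@graph) > 0) {
    memb <- detectCommunities(sn, seed = seed)
    nt$community <- as.integer(memb[nt$node])
    if (nNull > 0) {
      sig <- communitySignificance(sn, memb, nNull = nNull, seed = seed)
      nt$community_p <- sig$p[match(nt$community, sig$community)]
    }
  } else {
    nt$community <- seq_len(nrow(nt))
    nt$community_p <- NA_real_
  }
  nt <- nt[order(-nt$betweenness, nt$node), , drop = FALSE]
  rownames(nt) <- NULL
  methods::initialize(sn, nodeTable = nt)
}
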
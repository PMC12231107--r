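## Independent brute-force oracles used to verify the package's graph and
## counting routines on small instances. These deliberately share no code
## with the implementations they check.

## Random named undirected simple graph.
randomTestGraph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n))
  g
}

## Betweenness by explicit enumeration of all shortest paths: for every
## unordered pair (s, t), every shortest path is generated by backtracking
## over BFS distances, and each interior node collects 1 / (#shortest paths).
bruteBetweenness <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), as.integer)
  btw <- stats::setNames(rep(0, n), nm)
  allPaths <- function(s, t, dist) {
    ## enumerate shortest s->t paths by walking dist downwards from t
    extend <- function(node) {
      if (node == s) return(list(s))
      preds <- adj[[node]][dist[adj[[node]]] == dist[node] - 1]
      out <- list()
      for (p in preds)
        for (pp in extend(p)) out <- c(out, list(c(pp, node)))
      out
    }
    extend(t)
  }
  for (s in seq_len(n - 1)) {
    dist <- suppressWarnings(
      as.integer(igraph::distances(g, v = s, mode = "all")))
    for (t in (s + 1):n) {
      if (!is.finite(dist[t]) || is.na(dist[t])) next
      paths <- allPaths(s, t, dist)
      np <- length(paths)
      if (np == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        for (v in interior) btw[v] <- btw[v] + 1 / np
      }
    }
  }
  btw
}

## Exhaustive Steiner optimum: the smallest number of non-seed connector
## nodes whose addition makes all (reachable) seeds mutually connected.
bruteSteinerConnectors <- function(g, seeds) {
  nm <- igraph::V(g)$name
  seeds <- intersect(seeds, nm)
  others <- setdiff(nm, seeds)
  connectsSeeds <- function(nodes) {
    sub <- igraph::induced_subgraph(g, nodes)
    memb <- igraph::components(sub)$membership
    length(unique(memb[igraph::V(sub)$name %in% seeds])) == 1
  }
  for (k in 0:length(others)) {
    combos <- if (k == 0) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (cs in combos)
      if (connectsSeeds(c(seeds, cs))) return(k)
  }
  Inf
}

## Hypergeometric upper tail by direct summation of binomial-coefficient
## ratios (exact for the small N used in tests).
bruteHypergeomUpper <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Classical equal-variance two-sample t statistic, textbook formula.
bruteStudentT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  list(t = tstat, p = p)
}

## Exhaustive search over all 2- and 1-block partitions that respect
## connectivity is infeasible in general; for the bridged-clique case the
## candidate set is all bipartitions of the 12 nodes into two non-empty
## groups plus the single-module partition. Returns the best map-equation
## bipartition (labels).
bruteBestBipartition <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  best <- list(L = chemnet::mapEquation(g, rep(1, n)), memb = rep(1L, n))
  for (code in 1:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    L <- chemnet::mapEquation(g, memb)
    if (L < best$L - 1e-12) best <- list(L = L, memb = memb)
  }
  stats::setNames(best$memb, nm)
}

## Normalized mutual information between two labelings (via igraph).
nmi <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)), method = "nmi")
}
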
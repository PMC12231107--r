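#' @import methods
NULL

setOldClass("igraph")

#' Interactome: a confidence-scored protein interaction network
#'
#' An undirected simple graph whose edges carry a STRING-style
#' \code{combined_score} and an \code{experimental} evidence-channel score,
#' both on the 0--1000 integer scale. Constructed by
#' \code{\link{makeInteractome}} or \code{\link{readInteractome}}.
#'
#' @slot graph An \code{igraph} object; edge attributes \code{combined_score}
#'   and \code{experimental}.
#' @slot nEdgesInput Number of edge rows seen before filtering/de-duplication.
#' @export
setClass("Interactome",
         representation(graph = "igraph", nEdgesInput = "integer"))

setValidity("Interactome", function(object) {
  g <- object@graph
  msgs <- character(0)
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (any(igraph::which_loop(g))) msgs <- c(msgs, "self-loops are not allowed")
  if (any(igraph::which_multiple(g))) msgs <- c(msgs, "parallel edges are not allowed")
  cs <- igraph::E(g)$combined_score
  ex <- igraph::E(g)$experimental
  if (igraph::ecount(g) > 0) {
    if (is.null(cs) || any(cs < 0 | cs > 1000))
      msgs <- c(msgs, "combined_score must lie in [0, 1000]")
    if (is.null(ex) || any(ex < 0 | ex > 1000))
      msgs <- c(msgs, "experimental score must lie in [0, 1000]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Subnetwork: a seed-flagged subgraph with node statistics
#'
#' Produced by \code{\link{firstOrderNetwork}} or \code{\link{minimumNetwork}}.
#' Holds the induced subgraph, the seed flags, any seed identifiers that could
#' not be mapped to the interactome, and a per-node table that accumulates
#' degree, betweenness, community labels and community p-values as the
#' corresponding steps are run.
#'
#' @slot graph Induced \code{igraph} subgraph.
#' @slot seeds Character vector of mapped seed node names.
#' @slot unmappedSeeds Seed identifiers absent from the interactome.
#' @slot mode Extraction mode, \code{"first-order"} or \code{"minimum"}.
#' @slot nodeTable data.frame with columns \code{node}, \code{is_seed} and,
#'   once computed, \code{degree}, \code{betweenness}, \code{community},
#'   \code{community_p}.
#' @export
setClass("Subnetwork",
         representation(graph = "igraph", seeds = "character",
                        unmappedSeeds = "character", mode = "character",
                        nodeTable = "data.frame"))

setValidity("Subnetwork", function(object) {
  nm <- igraph::V(object@graph)$name
  msgs <- character(0)
  if (!all(object@seeds %in% nm)) msgs <- c(msgs, "all mapped seeds must be nodes")
  if (!identical(sort(object@nodeTable$node), sort(nm)))
    msgs <- c(msgs, "nodeTable must cover exactly the graph's nodes")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Interactome-class Underlying igraph object.
#' @param object An \code{Interactome} or \code{Subnetwork}.
#' @export
setGeneric("interactionGraph", function(object) standardGeneric("interactionGraph"))

#' @export
setMethod("interactionGraph", "Interactome", function(object) object@graph)

#' @export
setMethod("interactionGraph", "Subnetwork", function(object) object@graph)

#' @describeIn Subnetwork-class Mapped seed node names.
#' @export
setGeneric("seedGenes", function(object) standardGeneric("seedGenes"))

#' @export
setMethod("seedGenes", "Subnetwork", function(object) object@seeds)

#' @describeIn Subnetwork-class Seed identifiers that did not map.
#' @export
setGeneric("unmappedSeeds", function(object) standardGeneric("unmappedSeeds"))

#' @export
setMethod("unmappedSeeds", "Subnetwork", function(object) object@unmappedSeeds)

#' @describeIn Subnetwork-class Per-node statistics table.
#' @export
setGeneric("nodeTable", function(object) standardGeneric("nodeTable"))

#' @export
setMethod("nodeTable", "Subnetwork", function(object) object@nodeTable)

setMethod("show", "Interactome", function(object) {
  g <- object@graph
  cat("Interactome:", igraph::vcount(g), "nodes,", igraph::ecount(g), "edges",
      sprintf("(from %d input rows)\n", object@nEdgesInput))
})

setMethod("show", "Subnetwork", function(object) {
  g <- object@graph
  cat(sprintf("Subnetwork (%s): %d nodes (%d seeds), %d edges\n",
              object@mode, igraph::vcount(g), length(object@seeds),
              igraph::ecount(g)))
  if (length(object@unmappedSeeds))
    cat("  unmapped seeds:", paste(object@unmappedSeeds, collapse = ", "), "\n")
  if (!is.null(object@nodeTable$community))
    cat("  communities:", length(unique(object@nodeTable$community)), "\n")
})
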
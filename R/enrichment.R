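#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing an overlap of at least \code{k}
#' between a query of size \code{n} and a set of size \code{K} drawn from a
#' universe of size \code{N}; evaluated in log space by the stable
#' hypergeometric tail routine.
#'
#' @param N Universe size.
#' @param K Set size (<= N).
#' @param n Query size (<= N).
#' @param k Observed overlap (<= min(n, K)).
#' @return The p-value in (0, 1]; exactly 1 when \code{k = 0}.
#' @export
#' @examples
#' hypergeomTest(20, 5, 5, 5) * choose(20, 5)  # 1
hypergeomTest <- function(N, K, n, k) {
  stopIfNot(K <= N && n <= N, "set and query sizes cannot exceed the universe")
  stopIfNot(k >= 0 && k <= min(n, K), "overlap inconsistent with sizes")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement, capped at 1, order-preserving
#' with the input.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bhAdjust <- function(p) {
  stopIfNot(length(p) > 0, "empty p-value list")
  stopIfNot(all(is.finite(p)) && all(p > 0) && all(p <= 1),
            "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a query gene list
#'
#' Tests each gene set for over-representation in the query by the
#' hypergeometric upper tail, reporting fold enrichment
#' \code{(k/n)/(K/N)}, the standardized hypergeometric deviation
#' \code{z = (k - nK/N) / sd}, the combined score \code{z * (-ln p)} (the
#' Enrichr-style ranking statistic; \code{-ln} of the unadjusted p by
#' default), and BH-adjusted p-values. Sets are intersected with the
#' universe before testing; rows are sorted by adjusted p, then combined
#' score descending, then set id.
#'
#' @param query Character vector of query genes; must lie in the universe.
#' @param sets Named list of character vectors (e.g. \code{\link{readGMT}}).
#' @param universe Character vector, the background gene universe.
#' @param useAdjustedInCombined Use BH-adjusted p in the \code{-ln p} factor.
#' @return data.frame: set, N, K, n, k, fold, p, p_adj, z, combined.
#' @export
enrich <- function(query, sets, universe, useAdjustedInCombined = FALSE) {
  stopIfNot(length(query) > 0, "empty query")
  stopIfNot(length(universe) > 0, "empty universe")
  query <- unique(toupper(query)); universe <- unique(toupper(universe))
  stopIfNot(all(query %in% universe), "query must be a subset of the universe")
  stopIfNot(length(sets) > 0 && !is.null(names(sets)), "sets must be named")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(id) {
    s <- intersect(unique(toupper(sets[[id]])), universe)
    K <- length(s)
    k <- length(intersect(query, s))
    p <- if (K == 0) 1 else hypergeomTest(N, K, n, k)
    expK <- n * K / N
    sd <- sqrt(n * (K / N) * (1 - K / N) * (N - n) / (N - 1))
    z <- if (sd > 0) (k - expK) / sd else 0
    fold <- if (K > 0) (k / n) / (K / N) else 0
    data.frame(set = id, N = N, K = K, n = n, k = k, fold = fold, p = p,
               z = z, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bhAdjust(res$p)
  pUse <- if (useAdjustedInCombined) res$p_adj else res$p
  res$combined <- res$z * (-log(pUse))
  res <- res[order(res$p_adj, -res$combined, res$set),
             c("set", "N", "K", "n", "k", "fold", "p", "p_adj", "z", "combined")]
  rownames(res) <- NULL
  res
}

#' Per-community pathway enrichment
#'
#' Runs \code{\link{enrich}} with each community's gene list as the query,
#' skipping communities smaller than \code{minSize} (noted in the
#' \code{"skipped"} attribute), and returns the long-format table used for
#' community-by-pathway reporting.
#'
#' @param membership Community labels named by gene/node.
#' @param sets Named list of gene sets.
#' @param universe Background universe; community members outside it are
#'   dropped from the query.
#' @param minSize Minimum community size to test (default 3).
#' @param fdr Significance threshold recorded in the \code{significant}
#'   column (default 0.05).
#' @return data.frame: community, set, k, K, fold, p, p_adj, z, combined,
#'   significant; attribute \code{skipped} lists untested communities.
#' @export
enrichCommunities <- function(membership, sets, universe, minSize = 3,
                              fdr = 0.05) {
  stopIfNot(!is.null(names(membership)), "membership must be named by gene")
  universe <- unique(toupper(universe))
  comms <- sort(unique(membership))
  skipped <- integer(0)
  out <- list()
  for (cm in comms) {
    genes <- intersect(toupper(names(membership)[membership == cm]), universe)
    if (length(genes) < minSize) {
      skipped <- c(skipped, cm)
      next
    }
    tab <- enrich(genes, sets, universe)
    tab$community <- cm
    out[[as.character(cm)]] <- tab
  }
  res <- if (length(out)) do.call(rbind, out) else {
    tmp <- enrich(universe[1], sets, universe)[0, ]
    tmp$community <- integer(0)
    tmp
  }
  res$significant <- res$p_adj < fdr
  res <- res[, c("community", "set", "k", "K", "fold", "p", "p_adj", "z",
                 "combined", "significant")]
  rownames(res) <- NULL
  if (length(skipped))
    message(sprintf("communities skipped (size < %d): %s", minSize,
                    paste(skipped, collapse = ", ")))
  attr(res, "skipped") <- skipped
  res
}
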
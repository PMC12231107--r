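#' Normalize a colony-size plate grid
#'
#' Removes plate-level, row/column and border artefacts from a pinned-colony
#' size matrix: sizes are divided by the plate median, then row and column
#' medians (computed over interior positions only) are polished out
#' iteratively until all interior row/column medians equal 1, border
#' positions are rescaled by the border/interior median ratio, and the plate
#' is rescaled so the interior median is exactly 1. Missing colonies
#' (\code{NA}) are preserved. The procedure is idempotent to numerical
#' precision.
#'
#' @param sizes Numeric matrix of colony sizes (>= 0, \code{NA} allowed).
#' @param borderWidth Number of outer rows/columns treated as border.
#' @param tol Convergence tolerance on the row/column medians.
#' @return Normalized matrix of the same shape; interior median 1.
#' @export
normalizePlate <- function(sizes, borderWidth = 1L, tol = 1e-12) {
  stopIfNot(is.matrix(sizes) && is.numeric(sizes), "sizes must be a numeric matrix")
  ok <- !is.na(sizes)
  stopIfNot(any(ok), "all-missing plate")
  stopIfNot(mean(ok) >= 0.5, "more than half of the plate positions are missing")
  stopIfNot(all(sizes[ok] >= 0), "colony sizes must be non-negative")

  nr <- nrow(sizes); nc <- ncol(sizes)
  interiorRows <- seq_len(nr) > borderWidth & seq_len(nr) <= nr - borderWidth
  interiorCols <- seq_len(nc) > borderWidth & seq_len(nc) <= nc - borderWidth
  interior <- outer(interiorRows, interiorCols, `&`)
  if (!any(interior)) { interior[] <- TRUE; interiorRows[] <- TRUE; interiorCols[] <- TRUE }

  borderMask <- !interior
  x <- sizes / stats::median(sizes[ok])
  ## median polish of row/column effects, estimated from interior positions.
  ## Row effects are removed from interior rows (whole row of cells) and
  ## column effects from interior columns; border rows/columns are corrected
  ## solely by the border/interior ratio below, which makes the whole map
  ## idempotent (a second application divides by medians that are already 1).
  for (iter in seq_len(1000)) {
    rowMed <- apply(x[, interiorCols, drop = FALSE], 1, stats::median,
                    na.rm = TRUE)
    rowMed[!is.finite(rowMed) | rowMed <= 0 | !interiorRows] <- 1
    x <- x / rowMed
    colMed <- apply(x[interiorRows, , drop = FALSE], 2, stats::median,
                    na.rm = TRUE)
    colMed[!is.finite(colMed) | colMed <= 0 | !interiorCols] <- 1
    x <- sweep(x, 2, colMed, `/`)
    if (max(abs(c(rowMed, colMed) - 1)) < tol) break
  }
  ## border positions: remove the residual border/interior pinning offset
  bm <- stats::median(x[borderMask & ok], na.rm = TRUE)
  im <- stats::median(x[interior & ok], na.rm = TRUE)
  if (is.finite(bm) && is.finite(im) && bm > 0 && im > 0)
    x[borderMask] <- x[borderMask] / (bm / im)
  ## anchor the interior median at exactly 1
  im <- stats::median(x[interior & ok], na.rm = TRUE)
  if (is.finite(im) && im > 0) x <- x / im
  x
}

#' Epistasis score of a double mutant
#'
#' Deviation of double-mutant growth from the multiplicative expectation of
#' the two single mutants, on the percent scale:
#' \code{((gDouble / gQuery) / (gArray / gWt)) * 100}. When the observed
#' score of the phenotypically neutral reference double (the his3-partial
#' analogue of the query single mutant) is supplied, scores are rescaled so
#' the reference scores exactly 100.
#'
#' @param gDouble Growth of the double mutant (>= 0).
#' @param gQuery Growth of the query single mutant (> 0).
#' @param gArray Growth of the array single mutant (> 0).
#' @param gWt Growth of wild type (> 0).
#' @param referenceScore Observed raw score of the neutral reference double,
#'   or \code{NULL} for no reference normalization.
#' @return Epistasis score (percent; 100 = multiplicative neutrality).
#' @export
epistasisScore <- function(gDouble, gQuery, gArray, gWt, referenceScore = NULL) {
  stopIfNot(all(c(gQuery, gArray, gWt) > 0),
            "single-mutant and wild-type growth must be > 0")
  stopIfNot(gDouble >= 0, "double-mutant growth must be non-negative")
  raw <- ((gDouble / gQuery) / (gArray / gWt)) * 100
  if (!is.null(referenceScore)) {
    stopIfNot(referenceScore > 0, "reference score must be > 0")
    raw <- raw * (100 / referenceScore)
  }
  raw
}

#' Per-strain chemical-genetic interaction scores from liquid growth curves
#'
#' For each strain present in both conditions, evaluates percent residual
#' growth at the strain's vehicle mid-log time point, per replicate pair, and
#' reports the replicate-level and mean scores. Strains present in only one
#' condition are reported as unscored, never silently dropped.
#'
#' @param records Growth table (columns strain, condition, replicate, time_h,
#'   od600), as produced by \code{\link{simulateGrowthScreen}}.
#' @param treated,vehicle Condition labels.
#' @param window Mid-log OD window for the vehicle curve.
#' @return List with \code{scores} (data.frame: strain, replicate,
#'   percent_growth), \code{summary} (data.frame: strain, mean_growth,
#'   n_replicates) and \code{unscored} (character vector with reasons as
#'   names).
#' @export
chemgenScore <- function(records, treated = "treated", vehicle = "vehicle",
                         window = c(0.3, 0.5)) {
  need <- c("strain", "condition", "replicate", "time_h", "od600")
  stopIfNot(all(need %in% names(records)), "records lack required columns")
  strains <- sort(unique(records$strain))
  scoreRows <- list(); unscored <- character(0)
  for (s in strains) {
    rs <- records[records$strain == s, ]
    tr <- rs[rs$condition == treated, ]
    ve <- rs[rs$condition == vehicle, ]
    if (nrow(tr) == 0 || nrow(ve) == 0) {
      unscored[s] <- sprintf("missing %s condition",
                             if (nrow(tr) == 0) treated else vehicle)
      next
    }
    ## vehicle replicate-mean curve defines the evaluation time
    vAvg <- stats::aggregate(od600 ~ time_h, data = ve, FUN = mean)
    vAvg <- vAvg[order(vAvg$time_h), ]
    idx <- tryCatch(midLogIndex(vAvg$od600, window = window, strain = s),
                    chemnetMidLogError = function(e) NA_integer_)
    if (is.na(idx)) { unscored[s] <- "mid-log not reached"; next }
    t0 <- vAvg$time_h[idx]
    reps <- sort(intersect(unique(tr$replicate), unique(ve$replicate)))
    if (length(reps) == 0) { unscored[s] <- "no paired replicates"; next }
    pct <- vapply(reps, function(rp) {
      tv <- tr$od600[tr$replicate == rp & tr$time_h == t0]
      vv <- ve$od600[ve$replicate == rp & ve$time_h == t0]
      if (length(tv) != 1 || length(vv) != 1) return(NA_real_)
      percentGrowth(tv, vv)
    }, numeric(1))
    keep <- is.finite(pct)
    if (!any(keep)) { unscored[s] <- "no readings at mid-log time"; next }
    scoreRows[[s]] <- data.frame(strain = s, replicate = reps[keep],
                                 percent_growth = pct[keep],
                                 stringsAsFactors = FALSE)
  }
  scores <- if (length(scoreRows)) do.call(rbind, scoreRows) else
    data.frame(strain = character(0), replicate = integer(0),
               percent_growth = numeric(0))
  rownames(scores) <- NULL
  summary <- if (nrow(scores)) {
    agg <- stats::aggregate(percent_growth ~ strain, data = scores, FUN = mean)
    n <- stats::aggregate(percent_growth ~ strain, data = scores, FUN = length)
    data.frame(strain = agg$strain, mean_growth = agg$percent_growth,
               n_replicates = n$percent_growth, stringsAsFactors = FALSE)
  } else data.frame(strain = character(0), mean_growth = numeric(0),
                    n_replicates = integer(0))
  list(scores = scores, summary = summary, unscored = unscored)
}

#' Chemical-genetic scores from normalized agar colony grids
#'
#' Ratio of treated to vehicle normalized colony sizes per position, as
#' percent growth, averaged per strain over replicate positions.
#'
#' @param treatedSizes,vehicleSizes Normalized size matrices
#'   (\code{\link{normalizePlate}}), same shape.
#' @param strains Character matrix of strain ids, same shape.
#' @return data.frame: strain, mean_growth, n_replicates.
#' @export
chemgenScoreAgar <- function(treatedSizes, vehicleSizes, strains) {
  stopIfNot(all(dim(treatedSizes) == dim(vehicleSizes)) &&
            all(dim(treatedSizes) == dim(strains)),
            "treated, vehicle and strain grids must be congruent")
  ok <- !is.na(treatedSizes) & !is.na(vehicleSizes) & vehicleSizes > 0
  df <- data.frame(strain = strains[ok],
                   pct = treatedSizes[ok] / vehicleSizes[ok] * 100,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(pct ~ strain, data = df, FUN = mean)
  n <- stats::aggregate(pct ~ strain, data = df, FUN = length)
  data.frame(strain = agg$strain, mean_growth = agg$pct,
             n_replicates = n$pct, stringsAsFactors = FALSE)
}

#' Call interaction hits from per-replicate screen scores
#'
#' Two-stage hit calling. At the \code{"screen"} stage a strain is a putative
#' hit when, in at least \code{minScreens} of the independent screens, its
#' mean score crosses the stage threshold with a per-screen two-tailed
#' one-sample t-test p-value below \code{alpha} (t-test of the replicate
#' scores against the neutral value 100). At the \code{"validation"} stage
#' calls are made from a single replicated screen with the stricter defaults
#' (sensitive < 75, resistant > 130). Strains whose vehicle-condition growth
#' falls below \code{viabilityFloor} are reported as inviable and excluded
#' from interaction calls. Setting \code{lower}/\code{upper} to \code{NULL}
#' disables the effect-size requirement (calls on significance alone), which
#' is the configuration used for null calibration.
#'
#' @param scores data.frame with columns strain, screen (screen stage only),
#'   replicate, percent_growth.
#' @param stage \code{"validation"} (default) or \code{"screen"}.
#' @param lower,upper Effect thresholds (percent); defaults 75/130 at
#'   validation, 40/140 at screen stage; \code{NULL} disables that bound's
#'   effect requirement (it collapses to the neutral value 100, so any
#'   significant deviation is called).
#' @param alpha Significance level for the per-strain t-test.
#' @param minScreens,nScreens Replication rule at screen stage (default
#'   2 of 3).
#' @param vehicleLevel Optional named vector of vehicle growth levels
#'   (fraction of plate median, or percent of expectation) used for the
#'   inviability floor.
#' @param viabilityFloor Vehicle level below which a strain is inviable.
#' @param adjust Multiple-testing adjustment for the per-strain p-values
#'   (\code{"none"}, the default, or \code{"BH"}).
#' @return data.frame: strain, mean_growth, p, call (sensitive / resistant /
#'   none / inviable), screens_supporting.
#' @export
callHits <- function(scores, stage = c("validation", "screen"),
                     lower, upper, alpha = 0.05,
                     minScreens = 2L, nScreens = 3L,
                     vehicleLevel = NULL, viabilityFloor = 0.1,
                     adjust = c("none", "BH")) {
  stage <- match.arg(stage)
  adjust <- match.arg(adjust)
  need <- c("strain", "replicate", "percent_growth")
  stopIfNot(all(need %in% names(scores)), "scores lack required columns")
  if (missing(lower)) lower <- if (stage == "validation") 75 else 40
  if (missing(upper)) upper <- if (stage == "validation") 130 else 140
  if (is.null(lower)) lower <- 100  # disabled: any significant decrease calls
  if (is.null(upper)) upper <- 100  # disabled: any significant increase calls
  stopIfNot(lower <= upper, "lower threshold must not exceed upper")
  stopIfNot(minScreens >= 1 && minScreens <= nScreens,
            "minScreens must lie in 1..nScreens")

  hasScreen <- "screen" %in% names(scores)
  if (stage == "screen") stopIfNot(hasScreen, "screen stage needs a screen column")
  if (!hasScreen) scores$screen <- 1L

  perScreen <- function(v) {
    m <- mean(v)
    p <- if (length(v) >= 2 && stats::var(v) > 0)
      stats::t.test(v, mu = 100)$p.value else NA_real_
    c(mean = m, p = p)
  }

  strains <- sort(unique(scores$strain))
  out <- lapply(strains, function(s) {
    ss <- scores[scores$strain == s, ]
    if (!is.null(vehicleLevel) && !is.na(vehicleLevel[s]) &&
        vehicleLevel[s] < viabilityFloor) {
      return(data.frame(strain = s, mean_growth = mean(ss$percent_growth),
                        p = NA_real_, call = "inviable",
                        screens_supporting = 0L, stringsAsFactors = FALSE))
    }
    byScreen <- lapply(split(ss$percent_growth, ss$screen), perScreen)
    means <- vapply(byScreen, `[[`, numeric(1), "mean")
    ps <- vapply(byScreen, `[[`, numeric(1), "p")
    overallMean <- mean(ss$percent_growth)
    if (stage == "screen") {
      sensOk <- sum(means < lower & !is.na(ps) & ps < alpha)
      resOk <- sum(means > upper & !is.na(ps) & ps < alpha)
      call <- if (sensOk >= minScreens) "sensitive"
              else if (resOk >= minScreens) "resistant" else "none"
      supp <- max(sensOk, resOk)
      p <- suppressWarnings(min(ps, na.rm = TRUE))
      if (!is.finite(p)) p <- NA_real_
      data.frame(strain = s, mean_growth = overallMean, p = p, call = call,
                 screens_supporting = as.integer(supp), stringsAsFactors = FALSE)
    } else {
      st <- perScreen(ss$percent_growth)
      p <- st[["p"]]
      sig <- !is.na(p) && p < alpha
      call <- if (sig && overallMean < lower) "sensitive"
              else if (sig && overallMean > upper) "resistant" else "none"
      data.frame(strain = s, mean_growth = overallMean, p = p, call = call,
                 screens_supporting = if (call == "none") 0L else 1L,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (adjust == "BH") {
    padj <- rep(NA_real_, nrow(res))
    okp <- !is.na(res$p)
    padj[okp] <- stats::p.adjust(res$p[okp], method = "BH")
    res$p_adj <- padj
    recheck <- res$call %in% c("sensitive", "resistant") & !is.na(padj) & padj >= alpha
    res$call[recheck] <- "none"
    res$screens_supporting[recheck] <- 0L
  }
  res
}
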
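#' Controlled vocabulary of subcellular compartments
#' @return Character vector of valid compartment labels.
#' @export
compartmentLabels <- function() .compartments

.checkCells <- function(cells, what) {
  need <- c("gfp", "rfp")
  stopIfNot(all(need %in% names(cells)), sprintf("%s cells lack gfp/rfp columns", what))
  stopIfNot(all(is.finite(cells$gfp)) && all(cells$gfp > 0) &&
            all(is.finite(cells$rfp)) && all(cells$rfp > 0),
            sprintf("%s intensities must be finite and positive", what))
}

#' Protein abundance change from per-cell reporter ratios
#'
#' Per cell, the GFP intensity of the tagged protein is normalized to the RFP
#' reference channel; per condition, the median ratio summarises the strain;
#' the percent change is \code{(treated_median / control_median - 1) * 100}.
#' The strain is flagged when the absolute change exceeds \code{cutoff}
#' percent (the threshold at which changes are reliably confirmed visually)
#' and both conditions have at least \code{minCells} cells.
#'
#' @param controlCells,treatedCells data.frames with columns \code{gfp},
#'   \code{rfp} (one row per cell).
#' @param cutoff Percent-change cutoff for flagging (default 20).
#' @param minCells Minimum cells per condition for a call (default 50).
#' @return List with \code{percent_change}, \code{flagged}, \code{n_control},
#'   \code{n_treated}, \code{cutoff}.
#' @export
abundanceChange <- function(controlCells, treatedCells, cutoff = 20,
                            minCells = 50) {
  .checkCells(controlCells, "control"); .checkCells(treatedCells, "treated")
  nc <- nrow(controlCells); nt <- nrow(treatedCells)
  stopIfNot(nc >= minCells && nt >= minCells,
            sprintf("insufficient cells for a call (%d control, %d treated; need %d)",
                    nc, nt, minCells),
            class = "chemnetInsufficientCells")
  mCtrl <- stats::median(controlCells$gfp / controlCells$rfp)
  mTrt <- stats::median(treatedCells$gfp / treatedCells$rfp)
  change <- (mTrt / mCtrl - 1) * 100
  list(percent_change = change, flagged = abs(change) > cutoff,
       n_control = nc, n_treated = nt, cutoff = cutoff)
}

#' Compartment fractions of a cell population
#'
#' @param cells data.frame with a \code{compartment} column.
#' @return Named fractions over the full compartment vocabulary (sum to 1).
#' @export
compartmentFractions <- function(cells) {
  stopIfNot("compartment" %in% names(cells), "cells lack a compartment column")
  bad <- setdiff(unique(cells$compartment), .compartments)
  stopIfNot(length(bad) == 0,
            sprintf("unknown compartment label(s): %s", paste(bad, collapse = ", ")))
  tab <- table(factor(cells$compartment, levels = .compartments))
  stats::setNames(as.numeric(tab) / nrow(cells), .compartments)
}

#' Call a protein localization shift between conditions
#'
#' Compares the per-condition compartment distributions. A shift is called
#' when the modal compartment differs between conditions and the treated
#' fraction of the new modal compartment exceeds its control fraction by at
#' least \code{minShift} percentage points.
#'
#' @param controlCells,treatedCells data.frames with \code{compartment}.
#' @param minShift Minimum gain (percentage points) of the new modal
#'   compartment.
#' @param minCells Minimum cells per condition.
#' @return List with \code{from_compartment}, \code{to_compartment},
#'   \code{shifted}, \code{control_fractions}, \code{treated_fractions}.
#' @export
localizationCall <- function(controlCells, treatedCells, minShift = 20,
                             minCells = 50) {
  stopIfNot(nrow(controlCells) >= minCells && nrow(treatedCells) >= minCells,
            "insufficient cells for a localization call",
            class = "chemnetInsufficientCells")
  frC <- compartmentFractions(controlCells)
  frT <- compartmentFractions(treatedCells)
  modal <- function(fr) names(fr)[which.max(fr)]  # ties: vocabulary order
  from <- modal(frC); to <- modal(frT)
  shifted <- (from != to) && ((frT[[to]] - frC[[to]]) * 100 >= minShift)
  list(from_compartment = from, to_compartment = to, shifted = shifted,
       control_fractions = frC, treated_fractions = frT)
}

#' Score a full per-cell table for abundance and localization changes
#'
#' Applies \code{\link{abundanceChange}} and \code{\link{localizationCall}}
#' per strain to a long per-cell table with control and treated conditions.
#'
#' @param cells data.frame: strain, condition, cell_id, gfp, rfp, compartment.
#' @param control,treated Condition labels.
#' @param cutoff Abundance percent-change cutoff.
#' @param minCells Minimum cells per condition.
#' @param minShift Localization shift threshold (percentage points).
#' @return data.frame: strain, pct_change, flagged, from_loc, to_loc, shifted,
#'   n_control, n_treated. Strains with insufficient cells get NA calls.
#' @export
scoreMicroscopy <- function(cells, control = "control", treated = "treated",
                            cutoff = 20, minCells = 50, minShift = 20) {
  strains <- sort(unique(cells$strain))
  rows <- lapply(strains, function(s) {
    cc <- cells[cells$strain == s & cells$condition == control, ]
    tc <- cells[cells$strain == s & cells$condition == treated, ]
    ab <- tryCatch(abundanceChange(cc, tc, cutoff = cutoff, minCells = minCells),
                   chemnetInsufficientCells = function(e) NULL)
    lc <- tryCatch(localizationCall(cc, tc, minShift = minShift,
                                    minCells = minCells),
                   chemnetInsufficientCells = function(e) NULL)
    data.frame(strain = s,
               pct_change = if (is.null(ab)) NA_real_ else ab$percent_change,
               flagged = if (is.null(ab)) NA else ab$flagged,
               from_loc = if (is.null(lc)) NA_character_ else lc$from_compartment,
               to_loc = if (is.null(lc)) NA_character_ else lc$to_compartment,
               shifted = if (is.null(lc)) NA else lc$shifted,
               n_control = nrow(cc), n_treated = nrow(tc),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
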
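#' Index of the first mid-log time point
#'
#' Finds the earliest time index at which a control culture's OD600 lies
#' within the mid-log window (inclusive on both ends). No interpolation is
#' performed: residual growth is read off at a measured time point.
#'
#' @param od600 Control OD600 readings, ordered by time.
#' @param window Mid-log OD window, default \code{c(0.3, 0.5)}.
#' @param strain Strain label used in the error message.
#' @return Integer index into \code{od600}.
#' @export
#' @examples
#' midLogIndex(c(0.10, 0.20, 0.35, 0.60))  # 3
midLogIndex <- function(od600, window = c(0.3, 0.5), strain = "control") {
  stopIfNot(window[1] < window[2], "mid-log window lower bound must be < upper")
  stopIfNot(all(is.finite(od600)) && all(od600 >= 0),
            "od600 must be finite and non-negative")
  idx <- which(od600 >= window[1] & od600 <= window[2])
  stopIfNot(length(idx) > 0,
            sprintf("mid-log not reached for strain '%s' (window %.2f-%.2f)",
                    strain, window[1], window[2]),
            class = "chemnetMidLogError")
  idx[1]
}

#' Percent residual growth
#'
#' Residual growth of a treated culture relative to its vehicle control,
#' \code{(treated / control) * 100}, evaluated at the control's mid-log time
#' point. With replicate vectors of equal length, replicates are paired by
#' index and the per-pair percentages averaged; with unequal lengths the mean
#' over all treated x control pairs is returned.
#'
#' @param treated Treated OD600 value(s) at the evaluation time.
#' @param control Control OD600 value(s); must all be > 0.
#' @return Mean percent growth (scalar).
#' @export
percentGrowth <- function(treated, control) {
  stopIfNot(length(treated) > 0 && length(control) > 0, "empty inputs")
  stopIfNot(all(is.finite(treated)) && all(is.finite(control)), "non-finite OD")
  stopIfNot(all(control > 0), "control OD must be > 0")
  if (length(treated) == length(control)) {
    mean(treated / control) * 100
  } else {
    mean(outer(treated, control, `/`)) * 100
  }
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Least-squares fit of
#' \code{response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)}
#' on the log10(dose) scale, the standard 4PL inhibition model. To stabilise
#' small-n fits on the percent-growth scale, \code{bottom} is constrained to
#' >= 0 and \code{top} to <= 120.
#'
#' @param doses Doses (> 0); at least 4 distinct values.
#' @param responses Percent growth, one per dose entry (replicates allowed as
#'   repeated dose values).
#' @return List with \code{ic50}, \code{hill}, \code{top}, \code{bottom},
#'   \code{rss} and \code{extrapolated} (TRUE when ic50 falls outside the
#'   tested dose range).
#' @export
fitIC50 <- function(doses, responses) {
  stopIfNot(length(doses) == length(responses), "doses/responses length mismatch")
  stopIfNot(all(doses > 0), "doses must be positive")
  stopIfNot(length(unique(doses)) >= 4, "need >= 4 distinct doses")
  stopIfNot(all(is.finite(responses)), "responses must be finite")
  span <- max(responses) - min(responses)
  stopIfNot(span >= 10,
            "no dose dependence: response span below 10 percentage points",
            class = "chemnetFlatDoseResponse")
  ld <- log10(doses)
  model <- function(par) par[["bottom"]] +
    (par[["top"]] - par[["bottom"]]) / (1 + 10^(par[["hill"]] * (ld - par[["l50"]])))
  residFun <- function(par) responses - model(par)
  ## starting values: asymptotes from the data, ic50 at the half-response dose
  top0 <- max(responses); bot0 <- max(0, min(responses))
  half <- (top0 + bot0) / 2
  i50 <- ld[which.min(abs(responses - half))]
  fit <- minpack.lm::nls.lm(
    par = c(bottom = bot0, top = min(top0, 120), hill = 1, l50 = i50),
    lower = c(bottom = 0, top = 10, hill = 0.05, l50 = min(ld) - 3),
    upper = c(bottom = 100, top = 120, hill = 10, l50 = max(ld) + 3),
    fn = residFun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  stopIfNot(fit$info %in% 1:4,
            sprintf("IC50 fit did not converge (best RSS %.4g): %s",
                    fit$deviance, fit$message),
            class = "chemnetFitError")
  cf <- fit$par
  ic50 <- 10^cf[["l50"]]
  list(ic50 = ic50, hill = cf[["hill"]], top = cf[["top"]],
       bottom = cf[["bottom"]], rss = fit$deviance,
       extrapolated = ic50 < min(doses) || ic50 > max(doses))
}

#' Drug-drug synergy percentage
#'
#' Growth of the combination relative to the multiplicative (Bliss-like)
#' expectation from the single agents:
#' \code{((combo / drugA) / (drugB / vehicle)) * 100}. Values below 100
#' indicate the combination is worse than expected (synergy); 100 is exact
#' multiplicative non-interaction.
#'
#' @param combo Growth under both drugs.
#' @param drugA Growth under drug A alone.
#' @param drugB Growth under drug B alone.
#' @param vehicle Growth under vehicle.
#' @return Synergy percent (scalar).
#' @export
synergyPercent <- function(combo, drugA, drugB, vehicle) {
  stopIfNot(all(c(drugA, drugB, vehicle) > 0),
            "single-agent and vehicle growth must be > 0")
  stopIfNot(combo >= 0, "combination growth must be non-negative")
  ((combo / drugA) / (drugB / vehicle)) * 100
}

#' Percent viability from dead-cell staining counts
#'
#' Fraction of cells excluding the dead-cell stain:
#' \code{unlabeled / (labeled + unlabeled) * 100}.
#'
#' @param unlabeled Count of unstained (viable) cells.
#' @param labeled Count of stain-positive (dead) cells.
#' @return Percent viability.
#' @export
viabilityPercent <- function(unlabeled, labeled) {
  stopIfNot(unlabeled >= 0 && labeled >= 0 &&
            unlabeled == round(unlabeled) && labeled == round(labeled),
            "counts must be non-negative integers")
  total <- unlabeled + labeled
  stopIfNot(total > 0, "total cell count must be > 0")
  unlabeled / total * 100
}

#' Sterol fractions of the three-sterol total
#'
#' Each of squalene, lanosterol and ergosterol as a percentage of their sum,
#' e.g. \code{ergosterol / (squalene + lanosterol + ergosterol) * 100}.
#'
#' @param squalene,lanosterol,ergosterol Amounts (arbitrary units, >= 0).
#' @return Named numeric vector of three percentages summing to 100.
#' @export
sterolFractions <- function(squalene, lanosterol, ergosterol) {
  v <- c(squalene = squalene, lanosterol = lanosterol, ergosterol = ergosterol)
  stopIfNot(all(v >= 0), "sterol amounts must be non-negative")
  total <- sum(v)
  stopIfNot(total > 0, "total sterol amount must be > 0")
  v / total * 100
}

#' Two-sample Student's t-test
#'
#' Classical equal-variance two-tailed Student's t-test (Welch's correction
#' available by flag). Degenerate inputs (n < 2 per group, or zero pooled
#' variance) raise an error rather than returning an artificial p-value.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance form.
#' @return List with \code{t} and two-tailed \code{p}.
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
  stopIfNot(length(a) >= 2 && length(b) >= 2, "each group needs >= 2 values")
  stopIfNot(all(is.finite(a)) && all(is.finite(b)), "non-finite values")
  stopIfNot(stats::var(a) > 0 || stats::var(b) > 0,
            "degenerate groups: zero pooled variance",
            class = "chemnetDegenerateTest")
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}
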
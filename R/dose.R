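# Nuclear TDP-43 dose model: total-nuclear estimation, isotonic
# dose-response fitting, passive-diffusion-fraction estimation by
# equal-response matching, and skipping-onset threshold extrapolation.
#
# Levels are expressed in multiples of normal endogenous TDP-43; the
# skipping response is a percentage in [0, 100]. A nuclear-import-deficient
# construct (NLSm) contributes to the nucleus only through passive
# diffusion: total nuclear fold = endogenous + diffusion_fraction * level.

#' Total nuclear TDP-43 in multiples of normal
#'
#' `WT` constructs are fully nuclear (`endogenous + level`); `NLSm`
#' constructs contribute only the passively diffusing fraction
#' (`endogenous + diffusion_fraction * level`, default fraction 0.45).
#'
#' @param endogenous_level Endogenous TDP-43 level (multiples of normal;
#'   autoregulation may drive it below 1).
#' @param construct_level Construct expression level (multiples of normal).
#' @param construct `"WT"` or `"NLSm"` (vectorized).
#' @param diffusion_fraction Fraction of the NLSm construct entering the
#'   nucleus passively, in `[0, 1]` (default 0.45).
#' @return Numeric vector of total nuclear folds.
#' @export
total_nuclear_tdp43 <- function(endogenous_level, construct_level,
                                construct = c("WT", "NLSm"),
                                diffusion_fraction = 0.45) {
  if (any(endogenous_level < 0) || any(construct_level < 0)) {
    stop_data("expression levels must be non-negative")
  }
  if (diffusion_fraction < 0 || diffusion_fraction > 1) {
    stop_config("diffusion_fraction must be in [0, 1]")
  }
  if (length(construct) == 1L && length(endogenous_level) > 1L) {
    construct <- rep(construct, length(endogenous_level))
  }
  if (any(!construct %in% c("WT", "NLSm"))) {
    stop_data("construct must be 'WT' or 'NLSm'")
  }
  mult <- ifelse(construct == "WT", 1, diffusion_fraction)
  endogenous_level + mult * construct_level
}

#' Isotonic piecewise-linear dose-response curve
#'
#' Fits a non-decreasing piecewise-linear curve through pooled
#' (fold, skipping) points by isotonic regression (pool-adjacent-violators
#' via [stats::isoreg()]; observations at identical folds are averaged
#' first). Evaluation between knots is by linear interpolation; beyond the
#' fitted range the curve is clamped to its terminal values.
#'
#' @param fold Total nuclear fold values (>= 2 distinct values required).
#' @param skipping Observed skipping percentages in `[0, 100]`.
#' @return An object of class `response_curve` with a `knots` data frame.
#' @export
response_curve <- function(fold, skipping) {
  if (length(fold) != length(skipping)) {
    stop_data("fold and skipping must have equal length")
  }
  if (length(unique(fold)) < 2L) {
    stop_data("at least two distinct fold values are required")
  }
  y <- tapply(skipping, fold, mean)
  x <- as.numeric(names(y))
  ord <- order(x)
  x <- x[ord]
  y <- as.numeric(y)[ord]
  fit <- stats::isoreg(x, y)
  structure(
    list(knots = data.frame(fold = x, skipping = fit$yf)),
    class = "response_curve"
  )
}

#' @export
print.response_curve <- function(x, ...) {
  cat("Isotonic dose-response curve with", nrow(x$knots), "knots\n")
  print(x$knots)
  invisible(x)
}

#' Evaluate a response curve
#'
#' @param object A [response_curve()].
#' @param fold Fold values to evaluate at.
#' @param ... Unused.
#' @return Skipping percentages (clamped to terminal values outside the
#'   knot range).
#' @export
predict.response_curve <- function(object, fold, ...) {
  k <- object$knots
  stats::approx(k$fold, k$skipping, xout = fold, rule = 2,
                ties = "ordered")$y
}

#' Invert a response curve (leftmost solution)
#'
#' Smallest fold at which the curve reaches `target` skipping; `NA` when
#' the curve never reaches it.
#'
#' @param curve A [response_curve()].
#' @param target Skipping percentage to invert at (vectorized).
#' @return Numeric vector of folds (NA where not attained).
#' @export
invert_response <- function(curve, target) {
  k <- curve$knots
  vapply(target, function(t) {
    if (t > k$skipping[nrow(k)]) return(NA_real_)
    j <- which(k$skipping >= t)[1]
    if (j == 1L) return(k$fold[1])
    x0 <- k$fold[j - 1L]; x1 <- k$fold[j]
    y0 <- k$skipping[j - 1L]; y1 <- k$skipping[j]
    x0 + (x1 - x0) * (t - y0) / (y1 - y0)
  }, numeric(1))
}

#' Fit a response curve from dose observations
#'
#' Computes the total nuclear fold of every observation via
#' [total_nuclear_tdp43()] and fits the isotonic piecewise-linear curve.
#'
#' @param observations A dose `data.frame` with columns `construct,
#'   construct_level, endogenous_level, skipping_percent`.
#' @inheritParams total_nuclear_tdp43
#' @return A [response_curve()].
#' @export
fit_response_curve <- function(observations, diffusion_fraction = 0.45) {
  need <- c("construct", "construct_level", "endogenous_level",
            "skipping_percent")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop_data("dose observations missing columns: ",
              paste(miss, collapse = ", "))
  }
  folds <- total_nuclear_tdp43(observations$endogenous_level,
                               observations$construct_level,
                               observations$construct,
                               diffusion_fraction)
  response_curve(folds, observations$skipping_percent)
}

#' Estimate the NLSm passive-diffusion fraction by equal-response matching
#'
#' Fits the WT response curve (WT constructs are fully nuclear), then for
#' every NLSm observation whose skipping response is bracketed by the WT
#' curve, inverts the curve to the equivalent nuclear fold and solves
#' `fraction = (equivalent fold - endogenous) / construct level`. The
#' point estimate is the median across matched observations; the
#' per-point range mirrors the spread across expression bins.
#'
#' @param wt_obs Dose observations for the fully nuclear (WT) construct.
#' @param nlsm_obs Dose observations for the NLSm construct.
#' @return A list with `estimate` (median), `range` (min-max across
#'   matched points) and a per-point `data.frame` `per_point`.
#' @export
estimate_diffusion_fraction <- function(wt_obs, nlsm_obs) {
  folds_wt <- wt_obs$endogenous_level + wt_obs$construct_level
  curve <- response_curve(folds_wt, wt_obs$skipping_percent)
  yr <- range(curve$knots$skipping)
  usable <- nlsm_obs$construct_level > 0 &
    nlsm_obs$skipping_percent >= yr[1] &
    nlsm_obs$skipping_percent <= yr[2]
  if (!any(usable)) {
    stop_data("no overlapping response range between the NLSm series and ",
              "the WT curve")
  }
  d <- nlsm_obs[usable, , drop = FALSE]
  f_eq <- invert_response(curve, d$skipping_percent)
  est <- (f_eq - d$endogenous_level) / d$construct_level
  per_point <- data.frame(
    fraction_id = if ("fraction_id" %in% names(d)) d$fraction_id
                  else as.character(seq_len(nrow(d))),
    construct_level = d$construct_level,
    skipping_percent = d$skipping_percent,
    equivalent_fold = f_eq,
    fraction = est,
    stringsAsFactors = FALSE
  )
  list(estimate = stats::median(est), range = range(est),
       per_point = per_point, wt_curve = curve)
}

#' Skipping-onset threshold fold
#'
#' Smallest total nuclear fold `f >= 1` at which the response curve
#' reaches `detection_floor` percent skipping, by inverting the
#' piecewise-linear curve. Returns `NA` (not attained) when the curve
#' never reaches the floor.
#'
#' @param curve A [response_curve()].
#' @param detection_floor Detection floor in percent skipping, in
#'   `[0, 100]` (default 5).
#' @return The threshold fold, or `NA_real_` if not attained.
#' @export
skipping_threshold <- function(curve, detection_floor = 5) {
  if (detection_floor < 0 || detection_floor > 100) {
    stop_config("detection_floor must be within [0, 100] percent")
  }
  f <- invert_response(curve, detection_floor)
  if (is.na(f)) return(NA_real_)
  max(1, f)
}

#' Read/write a dose observation TSV
#'
#' Columns: `construct` (WT or NLSm), `fraction_id`, `construct_level`,
#' `endogenous_level`, `skipping_percent`.
#'
#' @param path File path.
#' @export
read_dose_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("construct", "fraction_id", "construct_level",
            "endogenous_level", "skipping_percent")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_data("dose table missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(df$skipping_percent < 0 | df$skipping_percent > 100)) {
    stop_data("skipping_percent must be within [0, 100]")
  }
  if (any(df$construct_level < 0) || any(df$endogenous_level < 0)) {
    stop_data("expression levels must be non-negative")
  }
  df
}

#' @rdname read_dose_tsv
#' @param observations Dose observation `data.frame`.
#' @export
write_dose_tsv <- function(observations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# skipticr dose observations",
    "# levels in multiples of normal endogenous TDP-43; skipping in percent"
  ), con)
  utils::write.table(observations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
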
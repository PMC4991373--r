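# Amplification-curve modelling: threshold-cycle calling and
# window-of-linearity efficiency estimation from raw fluorescence.

as_curve <- function(curve) {
  if (is.data.frame(curve)) {
    stopifnot(all(c("cycle", "fluorescence") %in% names(curve)))
    curve <- curve[order(curve$cycle), , drop = FALSE]
    if (any(diff(curve$cycle) <= 0)) {
      stop("curve cycles must be strictly increasing", call. = FALSE)
    }
    list(cycle = curve$cycle, f = curve$fluorescence)
  } else if (is.numeric(curve)) {
    list(cycle = seq_along(curve), f = as.numeric(curve))
  } else {
    stop("curve must be a data.frame with cycle/fluorescence or a numeric vector",
         call. = FALSE)
  }
}

subtract_baseline <- function(f, method = c("median5", "none")) {
  method <- match.arg(method)
  if (method == "none") return(f)
  f - stats::median(f[seq_len(min(5L, length(f)))])
}

#' Call the threshold cycle (Ct) of an amplification curve
#'
#' Returns the fractional cycle at which baseline-subtracted fluorescence
#' first crosses `threshold`, interpolating in log fluorescence between the
#' bracketing cycles (consistent with exponential growth; falls back to
#' linear interpolation when the lower bracket is non-positive). Reactions
#' that never cross within `max_cycle` cycles are undetected and return
#' `NA`, following the convention that 40 cycles is the detection threshold.
#'
#' @param curve A data.frame with `cycle` and `fluorescence` columns, or a
#'   numeric fluorescence vector measured at cycles `1..C`.
#' @param threshold Positive fluorescence threshold.
#' @param baseline `"median5"` subtracts the median of the first five
#'   cycles; `"none"` uses the raw trace.
#' @param max_cycle Detection limit in cycles (default 40).
#' @return A single numeric Ct in `(0, max_cycle]`, or `NA_real_` when
#'   undetected.
#' @export
#' @examples
#' call_ct(0.001 * 2^(1:40), threshold = 1, baseline = "none") # ~ log2(1000)
call_ct <- function(curve, threshold, baseline = c("median5", "none"),
                    max_cycle = 40) {
  stopifnot(is.numeric(threshold), threshold > 0)
  cv <- as_curve(curve)
  fb <- subtract_baseline(cv$f, baseline)
  if (all(fb < threshold)) return(NA_real_)
  # Garbage guard: a trace that sits above threshold while trending downward
  # has no detectable exponential phase.
  if (stats::cor(cv$cycle, cv$f, method = "spearman") < 0) {
    stop("no exponential phase detectable: fluorescence not increasing",
         call. = FALSE)
  }
  i <- which(fb >= threshold)[1]
  ct <- if (i == 1L) {
    cv$cycle[1]
  } else {
    lo <- fb[i - 1L]; hi <- fb[i]
    frac <- if (lo > 0) {
      (log(threshold) - log(lo)) / (log(hi) - log(lo))
    } else {
      (threshold - lo) / (hi - lo)
    }
    cv$cycle[i - 1L] + frac * (cv$cycle[i] - cv$cycle[i - 1L])
  }
  if (ct > max_cycle) return(NA_real_)
  ct
}

#' Estimate amplification efficiency from raw fluorescence
#'
#' Window-of-linearity estimation: after baseline subtraction, a straight
#' line is fitted to log10 fluorescence over every window of `window`
#' consecutive cycles lying in the exponential phase (above the noise floor,
#' below `plateau_frac` of the maximal signal), and the window with maximal
#' R-squared is kept. When the trace has visibly reached its plateau, the
#' logistic saturation is first divided out using the observed plateau level
#' (`F / (1 - F/Fmax)`), which removes the downward bias that saturation
#' otherwise imposes on the fitted slope; traces still in pure exponential
#' growth are fitted untouched. The per-cycle amplification base is
#' `10^slope`; the percent efficiency is `100 * base / 2`, i.e. the fraction
#' of perfect doubling (so base 1.7 is 85\% and base 1.75 is 87.5\%,
#' reported as 88\%).
#'
#' @inheritParams call_ct
#' @param window Window width in cycles (>= 4).
#' @param r2_floor Minimal acceptable R-squared of the best window; below it
#'   the curve is flagged as a weak amplification and `base` is `NA`.
#' @param plateau_frac Upper exclusion bound as a fraction of the maximal
#'   baseline-subtracted fluorescence.
#' @return List of class `"efficiency_estimate"`: `base`, `percent`
#'   (`100 * base / 2`), `window` (first and last cycle of the fit),
#'   `fit_r2`, `flagged`, `reason`.
#' @export
estimate_efficiency <- function(curve, window = 5L, r2_floor = 0.98,
                                baseline = c("median5", "none"),
                                plateau_frac = 0.5) {
  stopifnot(window >= 4L)
  cv <- as_curve(curve)
  fb <- subtract_baseline(cv$f, baseline)
  fmax <- max(fb)
  flagged <- function(reason) {
    structure(list(base = NA_real_, percent = NA_real_,
                   window = c(NA_real_, NA_real_), fit_r2 = NA_real_,
                   flagged = TRUE, reason = reason),
              class = "efficiency_estimate")
  }
  if (fmax <= 0) return(flagged("no_amplification"))
  noise_floor <- 3 * stats::sd(cv$f[seq_len(min(5L, length(cv$f)))])
  if (!is.finite(noise_floor) || noise_floor <= 0) noise_floor <- fmax * 1e-9
  # Divide out logistic saturation against the observed maximum; for traces
  # still deep in exponential growth the ratio fb/fmax is tiny inside the
  # fitted window and the compensation is a no-op.
  g <- fb / (1 - pmin(fb / fmax, 0.9))
  eligible <- fb > noise_floor & fb < plateau_frac * fmax & g > 0
  idx <- which(eligible)
  if (length(idx) < window) return(flagged("no_exponential_phase"))

  best <- NULL
  for (s in seq_len(length(idx) - window + 1L)) {
    w <- idx[s:(s + window - 1L)]
    if (any(diff(w) != 1L)) next  # windows must be consecutive cycles
    x <- cv$cycle[w]
    y <- log10(g[w])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    if (is.null(best) || r2 > best$r2) {
      best <- list(slope = slope, r2 = r2, win = range(cv$cycle[w]))
    }
  }
  if (is.null(best)) return(flagged("no_exponential_phase"))
  if (best$r2 < r2_floor) return(flagged("weak_amplification"))
  base <- unname(10^best$slope)
  structure(list(base = base, percent = 100 * base / 2,
                 window = best$win, fit_r2 = unname(best$r2),
                 flagged = FALSE, reason = NA_character_),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  if (x$flagged) {
    cat("Efficiency estimate: flagged (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Efficiency estimate: base %.4f (%.1f%% of doubling), cycles %d-%d, R2 %.4f\n",
                x$base, x$percent, x$window[1], x$window[2], x$fit_r2))
  }
  invisible(x)
}

#' Aggregate per-reaction efficiencies into plate-level bases
#'
#' Combines per-reaction efficiency estimates into the single amplification
#' base used for fold-change computation in a plate or assay context, so
#' that reactions of similar efficiency are compared and between-plate batch
#' effects are avoided.
#'
#' @param estimates A list of [estimate_efficiency()] results, or a numeric
#'   vector of bases.
#' @param policy `"mean"` or `"median"` return one global base; `"per_mir"`
#'   returns one base per miRNA (requires `mir_ids`).
#' @param mir_ids Character vector parallel to `estimates` (per-miRNA policy
#'   only).
#' @return A single base, or a named vector of bases for `"per_mir"`.
#' @export
plate_efficiency <- function(estimates, policy = c("mean", "median", "per_mir"),
                             mir_ids = NULL) {
  policy <- match.arg(policy)
  bases <- if (is.numeric(estimates)) estimates
           else vapply(estimates, function(e) e$base, numeric(1))
  keep <- !is.na(bases)
  bases <- bases[keep]
  if (!length(bases)) stop("no efficiency estimates to aggregate", call. = FALSE)
  switch(policy,
    mean = mean(bases),
    median = stats::median(bases),
    per_mir = {
      if (is.null(mir_ids)) stop("per_mir policy requires mir_ids", call. = FALSE)
      tapply(bases, mir_ids[keep], mean)
    })
}
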
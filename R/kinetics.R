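# First-order sorption kinetics: nonlinear fit of R(t) = a exp(-b t) + c on
# the stable breathing window, R^2, and the two-regime log-linear
# decomposition (early straight line log(a) - b t, late saturation level
# log(c)) that also seeds the nonlinear optimizer.

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot} of predictions against observations.
#'
#' @param observed,predicted equal-length numeric vectors (>= 2 values;
#'   \code{observed} must not be constant).
#' @return a single number (1 for a perfect fit, 0 for the mean-only model).
#' @examples
#' rSquared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
rSquared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0)
    stop("observed series is constant; R^2 is undefined")
  1 - sum((observed - predicted)^2) / ssTot
}

# subset a (time, values) pair to the open window (lo, hi)
.inWindow <- function(time, values, window) {
  sel <- time > window[1] & time < window[2]
  list(time = time[sel], values = values[sel])
}

#' Two-regime log-linear decomposition
#'
#' On a log scale the saturation curve splits into two straight regimes:
#' early, while \code{a exp(-b t) >> c}, \code{log(R) ~ log(a) - b t}
#' (slope -b, intercept log(a)); late, once the exponential has decayed,
#' \code{log(R) ~ log(c)}. This fits the early segment by ordinary least
#' squares of log(R) against time (referenced to the window start) and
#' estimates the late level as the mean log-resistance after the
#' breakpoint. Natural logarithms.
#'
#' When no breakpoint is supplied it is located automatically: a
#' provisional early line (first quarter of the window) is extrapolated
#' until it first comes within 0.05 log-units of a provisional late level
#' (last quarter), and the fits are then recomputed on the resulting split.
#'
#' @param time,values the series (ohms; positive inside the window).
#' @param window (t_lo, t_hi) seconds, open interval.
#' @param breakpoint optional split time inside the window.
#' @param minSegment minimum samples per segment.
#' @return list(logInterceptEarly, logSlopeEarly, logLevelLate, breakpoint,
#'   nEarly, nLate).
#' @export
twoRegimeLogFit <- function(time, values, window = c(200, 1920),
                            breakpoint = NULL, minSegment = 10L) {
  d <- .inWindow(time, values, window)
  if (any(d$values <= 0))
    stop("nonpositive values in the fit window; log fit undefined")
  if (length(d$time) < 2L * minSegment)
    stop("too few samples in the fit window")
  lo <- window[1]; hi <- window[2]
  L <- log(d$values)
  tt <- d$time - lo
  fitEarly <- function(bp) {
    sel <- d$time < bp
    stats::lm.fit(cbind(1, tt[sel]), L[sel])$coefficients
  }
  lateLevel <- function(bp) mean(L[d$time >= bp])
  clampBp <- function(bp) {
    # keep both segments populated
    tsort <- d$time
    lims <- c(tsort[minSegment], tsort[length(tsort) - minSegment + 1L])
    min(max(bp, lims[1]), lims[2])
  }
  if (is.null(breakpoint)) {
    q <- lo + c(0.25, 0.75) * (hi - lo)
    co0 <- fitEarly(q[1])
    lev0 <- mean(L[d$time >= q[2]])
    bp <- if (is.finite(co0[2]) && co0[2] < 0)
      lo + (lev0 + 0.05 - co0[1]) / co0[2]
    else lo + 0.5 * (hi - lo)
    breakpoint <- clampBp(bp)
  } else {
    breakpoint <- clampBp(breakpoint)
  }
  co <- fitEarly(breakpoint)
  list(logInterceptEarly = unname(co[1]), logSlopeEarly = unname(co[2]),
       logLevelLate = lateLevel(breakpoint), breakpoint = breakpoint,
       nEarly = sum(d$time < breakpoint),
       nLate = sum(d$time >= breakpoint))
}

#' Fit the exponential saturation model
#'
#' Bounded Levenberg-Marquardt least-squares fit of
#' \code{R(t) = a * exp(-b * (t - t_lo)) + c} on the stable breathing
#' window (default 200--1920 s from recording start; time is referenced to
#' the window start, so \code{a + c} is the modelled resistance at t_lo).
#' The breathing oscillation is deliberately not part of the model; it is a
#' structured residual around the saturation baseline. The two-regime log
#' fit provides the starting values; bounds keep all three coefficients
#' positive and identifiable (a in (0, 10 max R), b in (1e-6, 1) 1/s, c in
#' (0, max R)).
#'
#' @param time sample times in seconds, or an \code{\link{ArrayMeanSeries}}
#'   / \code{\link{CleanSeries}} (then \code{values} is ignored).
#' @param values resistance, ohms.
#' @param window (t_lo, t_hi) seconds, open interval.
#' @return an \code{\link{ExpFitResult}}.
#' @section Errors: non-convergence (e.g. a constant series, for which b is
#'   unidentifiable) raises a condition of class \code{maskflowFitError}
#'   carrying the starting values in its \code{start} field.
#' @export
fitExponential <- function(time, values = NULL, window = c(200, 1920)) {
  if (is(time, "ArrayMeanSeries") || is(time, "CleanSeries")) {
    values <- time@values
    time <- time@time
  }
  d <- .inWindow(time, values, window)
  if (length(d$time) < 50L)
    stop("need at least 50 samples inside the fit window")
  if (any(d$values <= 0))
    stop("resistance values in the window must be positive")
  lg <- twoRegimeLogFit(time, values, window)
  maxR <- max(d$values)
  c0 <- min(max(exp(lg$logLevelLate), 1e-8), maxR * 0.999)
  a0 <- min(max(exp(lg$logInterceptEarly) - c0, 1e-3 * maxR), 10 * maxR)
  b0 <- min(max(-lg$logSlopeEarly, 1e-6), 1)
  start <- c(a = a0, b = b0, c = c0)
  tt <- d$time - window[1]
  df <- data.frame(tt = tt, v = d$values)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a * exp(-b * tt) + c, data = df,
                      start = as.list(start),
                      lower = c(a = 1e-12, b = 1e-6, c = 1e-12),
                      upper = c(a = 10 * maxR, b = 1, c = maxR),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(errorCondition(
        paste0("exponential fit did not converge: ", conditionMessage(e),
               " (start: a=", signif(start[1], 4), ", b=",
               signif(start[2], 4), ", c=", signif(start[3], 4), ")"),
        start = start, class = "maskflowFitError")))
  co <- coef(fit)
  r2 <- tryCatch(rSquared(d$values, fitted(fit)),
                 error = function(e)
                   stop(errorCondition(
                     "constant series: R^2 undefined",
                     start = start, class = "maskflowFitError")))
  new("ExpFitResult", a = unname(co["a"]), b = unname(co["b"]),
      c = unname(co["c"]), rSquared = max(0, min(1, r2)),
      window = as.numeric(window),
      logInterceptEarly = lg$logInterceptEarly,
      logSlopeEarly = lg$logSlopeEarly,
      logLevelLate = lg$logLevelLate, breakpoint = lg$breakpoint,
      nPoints = length(d$time))
}

#' Tabulate kinetic fits across sessions
#'
#' Collects (a, b, c, R^2) for a set of session fits and, when participants
#' are given, the relative spread (sd/mean) of the decay rate b across each
#' participant's sessions -- the decay rate is expected to stay consistent
#' day to day while a and c track ambient humidity.
#'
#' @param fits list of \code{\link{ExpFitResult}} (length >= 1).
#' @param labels session labels (default F1, F2, ...).
#' @param participants optional participant id per fit.
#' @return list(coefficients = data.frame(label, participant, a, b, c,
#'   r_squared), bSpread = data.frame(participant, n, b_rel_spread) or NULL).
#' @export
compareSessions <- function(fits, labels = NULL, participants = NULL) {
  stopifnot(length(fits) >= 1L)
  if (is.null(labels)) labels <- paste0("F", seq_along(fits))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(label = labels[i],
               participant = if (is.null(participants)) NA_character_
                             else participants[i],
               a = f@a, b = f@b, c = f@c, r_squared = f@rSquared)
  }))
  spread <- NULL
  if (!is.null(participants)) {
    spread <- do.call(rbind, lapply(split(tab, tab$participant), function(g)
      data.frame(participant = g$participant[1], n = nrow(g),
                 b_rel_spread = if (nrow(g) > 1L) sd(g$b) / mean(g$b) else 0)))
    rownames(spread) <- NULL
  }
  list(coefficients = tab, bSpread = spread)
}
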
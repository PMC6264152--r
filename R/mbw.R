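# Multiple-breath washout protocol and clinical indices: the tracer starts
# at concentration 1 everywhere, regular sinusoidal breathing washes it out
# through a zero-concentration mouth on inhalation, and the mouth
# concentration/flow series yields FRC_approx, LCI, phase-III slopes,
# S_cond and per-acinus fractional ventilation.

#' Simulate a multiple-breath washout
#'
#' Runs the coupled ventilation/transport model until the end-tidal mouth
#' concentration falls below the stopping fraction (default 2.5\%), plus a
#' margin of extra breaths for interpolation.
#'
#' @param network a \code{lung_network}.
#' @param gas tracer gas name (must be configured, e.g. \code{"SF6"},
#'   \code{"N2"}).
#' @param numerics optional list overriding numerical controls
#'   (\code{steps_per_cycle}, \code{cells_per_edge}, \code{max_breaths},
#'   \code{stop_frac}, \code{extra_breaths}).
#' @param fixed_breaths simulate exactly this many breaths instead of using
#'   the stopping criterion (used by the sensitivity machinery so that
#'   perturbed runs share identical breath counts).
#' @return object of class \code{washout_trace}: per-sample mouth
#'   concentration and flow, per-breath records (volumes, end-tidal
#'   concentration, net expired tracer, cumulative expired volume),
#'   per-breath per-unit tracer content at end-tidal volume, and
#'   conservation diagnostics.
#' @export
run_washout <- function(network, gas = "SF6", numerics = list(),
                        fixed_breaths = NULL) {
  params <- network$params
  num <- modifyList(params$numerics, numerics)
  gs <- gas_spec(params, gas)
  sys <- build_mechanics(network)
  wf <- calibrate_waveform(sys, n_steps = num$steps_per_cycle)
  disc <- discretise(network, cells_per_edge = num$cells_per_edge)
  dt <- params$tau / num$steps_per_cycle
  res <- washout_core(disc$disc, gs, wf$cycleV * CM3_PER_L, dt,
                      rep(1, disc$n_cells), num$max_breaths,
                      num$stop_frac, num$extra_breaths,
                      fixed_breaths %||% 0L, 0L)
  if (is.null(fixed_breaths) && res$crossing_breath == 0)
    stop(sprintf(
      "washout stop criterion unreached in %d breaths (end-tidal %.3g, residual tracer fraction %.3g): unventilated pathology?",
      res$n_breaths, tail(res$end_tidal, 1),
      res$total_final / res$total_init))
  nb <- res$n_breaths
  breaths <- data.frame(
    breath = seq_len(nb),
    inhaled = res$inhaled / CM3_PER_L,
    exhaled = res$exhaled / CM3_PER_L,
    net_tracer_out = res$net_out / CM3_PER_L,
    end_tidal = res$end_tidal,
    cum_expired = cumsum(res$exhaled) / CM3_PER_L)
  conservation <- abs((res$total_init - res$total_final) - res$cum_net_out) /
    res$total_init
  structure(list(
    t = seq_len(length(res$mouth_c)) * dt,
    c_mouth = res$mouth_c,
    flow = res$mouth_q / CM3_PER_L,
    breaths = breaths,
    crossing_breath = res$crossing_breath,
    unit_tracer = res$unit_tracer / CM3_PER_L,
    units = network$units,
    stop_frac = num$stop_frac,
    steps_per_cycle = num$steps_per_cycle,
    dt = dt,
    gas = gs,
    tracer_init = res$total_init / CM3_PER_L,
    tracer_final = res$total_final / CM3_PER_L,
    tracer_out = res$cum_net_out / CM3_PER_L,
    conservation_error = conservation,
    waveform = wf[c("amplitude", "tau", "tidal")],
    network = network),
    class = "washout_trace")
}

#' @export
print.washout_trace <- function(x, ...) {
  cat(sprintf("washout_trace: %d breaths (%s), end-tidal %.4g -> %.4g\n",
              nrow(x$breaths), x$gas$name, x$breaths$end_tidal[1],
              tail(x$breaths$end_tidal, 1)))
  cat(sprintf("  expired tracer %.4g L of %.4g L initial | conservation error %.2g\n",
              x$tracer_out, x$tracer_init, x$conservation_error))
  invisible(x)
}

#' Measured FRC from expired tracer
#'
#' Clinical convention: the cumulative net tracer volume expired through
#' the mouth divided by the concentration drop from the start of the test
#' to the final end-tidal sample.
#'
#' @param trace a \code{\link{run_washout}} result.
#' @return FRC estimate (L).
#' @export
compute_frc_approx <- function(trace) {
  denom <- 1 - tail(trace$breaths$end_tidal, 1)
  if (!is.finite(denom) || denom <= 1e-6)
    stop("degenerate concentration drop: cannot estimate FRC")
  trace$tracer_out / denom
}

#' Lung clearance index
#'
#' Number of lung turnovers (cumulative expired volume over measured FRC)
#' at which the end-tidal concentration crosses the stopping fraction
#' (2.5\% of the initial value), interpolated linearly in log end-tidal
#' concentration versus turnover between the bracketing breaths.
#'
#' @param trace a \code{\link{run_washout}} result.
#' @param frc optional precomputed \code{\link{compute_frc_approx}} value.
#' @return LCI (dimensionless turnovers), with the bracketing breath index
#'   as attribute \code{"breath"}.
#' @export
compute_lci <- function(trace, frc = compute_frc_approx(trace)) {
  et <- trace$breaths$end_tidal
  to <- trace$breaths$cum_expired / frc
  thr <- trace$stop_frac
  b <- which(et < thr)[1]
  if (is.na(b)) stop("end-tidal series never crosses the stop fraction")
  if (b == 1) stop("end-tidal series starts below the stop fraction")
  f <- (log(thr) - log(et[b - 1])) / (log(et[b]) - log(et[b - 1]))
  lci <- to[b - 1] + f * (to[b] - to[b - 1])
  attr(lci, "breath") <- b
  lci
}

#' Normalised phase-III slope of one expirogram
#'
#' Least-squares slope of the expired concentration versus expired volume
#' over the configured late-expiration window, divided by the window's mean
#' concentration.
#'
#' @param volume cumulative expired volume within the breath (L).
#' @param conc concentration at the mouth at the matching samples.
#' @param window fraction-of-expired-volume window, default 65-95\%.
#' @return normalised slope (1/L).
#' @export
phase3_slope <- function(volume, conc, window = c(0.65, 0.95)) {
  vtot <- max(volume)
  sel <- volume >= window[1] * vtot & volume <= window[2] * vtot
  if (sum(sel) < 5)
    stop("phase-III window under-sampled (", sum(sel), " samples)")
  fit <- stats::lm.fit(cbind(1, volume[sel]), conc[sel])
  m <- fit$coefficients[2]
  cbar <- mean(conc[sel])
  if (cbar <= 0) stop("non-positive mean concentration in phase-III window")
  unname(m / cbar)
}

# exhalation samples of one breath: cumulative expired volume and mouth
# concentration
breath_expirogram <- function(trace, breath) {
  n <- trace$steps_per_cycle
  idx <- ((breath - 1) * n + 1):(breath * n)
  q <- trace$flow[idx]
  keep <- q < 0
  list(volume = cumsum(-q[keep]) * trace$dt,
       conc = trace$c_mouth[idx][keep])
}

#' Per-breath normalised phase-III slopes of a washout
#' @param trace a \code{\link{run_washout}} result.
#' @param window see \code{\link{phase3_slope}}.
#' @return numeric vector, one S_nIII (1/L) per breath.
#' @export
phase3_slopes <- function(trace,
                          window = trace$network$params$mbw$phase3_window) {
  vapply(seq_len(nrow(trace$breaths)), function(b) {
    ex <- breath_expirogram(trace, b)
    phase3_slope(ex$volume, ex$conc, window)
  }, numeric(1))
}

#' Conductive ventilation heterogeneity index S_cond
#'
#' Least-squares slope of the normalised phase-III slopes against lung
#' turnover over the guideline turnover range (default 1.5-6), using only
#' breaths up to the 2.5\% crossing.
#'
#' @param snIII per-breath normalised phase-III slopes (1/L).
#' @param TO per-breath lung turnover.
#' @param to_range turnover window for the fit.
#' @return S_cond (1/L).
#' @export
compute_scond <- function(snIII, TO, to_range = c(1.5, 6.0)) {
  sel <- TO >= to_range[1] & TO <= to_range[2] & is.finite(snIII)
  if (sum(sel) < 3)
    stop("fewer than 3 breaths in the S_cond turnover range")
  unname(stats::lm.fit(cbind(1, TO[sel]), snIII[sel])$coefficients[2])
}

#' Per-unit fractional ventilation
#'
#' Fraction of each lung unit's tracer content turned over per breath:
#' \code{FV = 1 - I(n+1)/I(n)} with \code{I} the tracer volume in the unit
#' at successive end-tidal states.  A completely unventilated unit has
#' FV = 0; a well-mixed compartment of volume F receiving effective fresh
#' gas V per breath has FV = V/(F + V).
#'
#' @param trace a \code{\link{run_washout}} result.
#' @param breaths which breath transitions to use; defaults to all breaths
#'   up to the stopping-criterion crossing (test average).
#' @return list with the per-breath matrix \code{per_breath} (breaths x
#'   units) and the test-average \code{mean} per unit.
#' @export
compute_fv <- function(trace, breaths = NULL) {
  I <- trace$unit_tracer
  nb <- nrow(I) - 1
  if (nb < 1) stop("need at least two end-tidal states")
  fv <- 1 - I[-1, , drop = FALSE] / I[-nrow(I), , drop = FALSE]
  fv[!is.finite(fv)] <- 0
  rownames(fv) <- NULL
  colnames(fv) <- trace$units$unit_id
  if (is.null(breaths)) {
    last <- if (trace$crossing_breath > 0) trace$crossing_breath else nb
    breaths <- seq_len(min(last, nb))
  }
  list(per_breath = fv,
       mean = colMeans(fv[breaths, , drop = FALSE]))
}

#' All MBW indices of a washout
#'
#' @param trace a \code{\link{run_washout}} result.
#' @return object of class \code{mbw_indices} with \code{FRC_approx} (L),
#'   \code{LCI} (turnovers), \code{Scond} (1/L), per-breath \code{SnIII}
#'   and turnover \code{TO}, and test-average fractional ventilation
#'   \code{FV} per lung unit.
#' @export
mbw_indices <- function(trace) {
  params <- trace$network$params
  frc <- compute_frc_approx(trace)
  lci <- compute_lci(trace, frc)
  to <- trace$breaths$cum_expired / frc
  sn <- phase3_slopes(trace)
  cross <- attr(lci, "breath")
  use <- seq_len(nrow(trace$breaths)) <= cross
  scond <- compute_scond(sn[use], to[use], params$mbw$scond_to_range)
  fv <- compute_fv(trace)
  structure(list(FRC_approx = frc, LCI = as.numeric(lci), Scond = scond,
                 SnIII = sn, TO = to, FV = fv$mean,
                 gas = trace$gas$name,
                 n_breaths = nrow(trace$breaths),
                 crossing_breath = cross),
            class = "mbw_indices")
}

#' @export
print.mbw_indices <- function(x, ...) {
  cat(sprintf("MBW indices (%s): LCI %.3f | S_cond %.3g 1/L | FRC %.3f L\n",
              x$gas, x$LCI, x$Scond, x$FRC_approx))
  cat(sprintf("  FV range across units: %.4f - %.4f (%d breaths)\n",
              min(x$FV), max(x$FV), x$n_breaths))
  invisible(x)
}

#' Constriction-severity sweep
#'
#' Applies a localised constriction of each severity at each depth and
#' recomputes the MBW indices, reproducing the constriction-response
#' curves.
#'
#' @param network baseline \code{lung_network}.
#' @param severities numeric vector of radius-reduction fractions.
#' @param depths subset of \code{c("proximal", "central", "distal")}.
#' @param region constricted region.
#' @param gas tracer gas.
#' @param numerics numerical overrides passed to \code{\link{run_washout}}.
#' @return data.frame with one row per (depth, severity).
#' @export
constriction_sweep <- function(network, severities,
                               depths = c("proximal", "central", "distal"),
                               region = "RM", gas = "SF6",
                               numerics = list()) {
  out <- NULL
  for (depth in depths) for (sev in severities) {
    net <- if (sev > 0)
      apply_localised_constriction(
        network, constriction_spec("localised", depth, sev, region))
    else network
    idx <- mbw_indices(run_washout(net, gas, numerics))
    out <- rbind(out, data.frame(
      depth = depth, severity = sev, LCI = idx$LCI, Scond = idx$Scond,
      FRC_approx = idx$FRC_approx))
  }
  out
}
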
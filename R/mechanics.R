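# Lumped ventilation mechanics: (R_cond + R_acin) dV/dt + K (V - V*) = drive.
# The system is linear and time-invariant with sinusoidal pleural driving,
# so the periodic steady state of the Crank-Nicolson discretisation is
# available in closed form and is used both to calibrate the pleural
# amplitude and to initialise time stepping.

#' Poiseuille resistance of a mean-path edge
#'
#' Resistance of \code{N_b} identical parallel airways of length \code{l}
#' and single-airway cross-section \code{a}, assuming fully developed
#' laminar flow: \code{8 mu l / (pi r^4) / N_b}.
#'
#' @param l airway length (cm).
#' @param a single-airway cross-sectional area (cm^2).
#' @param mu dynamic viscosity in internal units (cmH2O.s); see
#'   \code{\link{global_params}} for the Pa.s boundary convention.
#' @param N_b number of identical parallel airways.
#' @return resistance in cmH2O.s/L.
#' @export
poiseuille_resistance <- function(l, a, mu, N_b = 1) {
  if (any(l <= 0) || any(a <= 0))
    stop("non-positive airway geometry")
  8 * mu * l * pi / a^2 / N_b * CM3_PER_L
}

# contiguous unit index range fed by each edge; errors if the unit ordering
# is not depth-first consistent
edge_unit_ranges <- function(network) {
  edges <- network$edges
  units <- network$units
  n <- nrow(edges)
  kids <- edge_children(edges)
  lo <- rep(NA_integer_, n); hi <- rep(NA_integer_, n)
  cnt <- integer(n)
  for (i in rev(dfs_order(edges))) {   # postorder accumulation
    ch <- kids[[i]]
    if (!length(ch) && !is.na(edges$unit_id[i])) {
      # the unit hangs off the terminal edge of its acinar chain
      u <- match(edges$unit_id[i], units$unit_id)
      lo[i] <- u; hi[i] <- u; cnt[i] <- 1L
    }
    if (length(ch)) {
      lo[i] <- min(lo[i], lo[ch], na.rm = TRUE)
      hi[i] <- max(hi[i], hi[ch], na.rm = TRUE)
      cnt[i] <- cnt[i] + sum(cnt[ch])
    }
  }
  if (any(is.na(lo)))
    stop("disconnected edge: no lung unit downstream of ",
         paste(edges$edge_id[is.na(lo)], collapse = ", "))
  if (any(hi - lo + 1L != cnt))
    stop("internal error: unit ordering is not depth-first contiguous")
  data.frame(edge_id = edges$edge_id, lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

dfs_order <- function(edges) {
  kids <- edge_children(edges)
  roots <- which(is.na(edges$parent))
  ord <- integer(0); stack <- rev(roots)
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, i)
    ch <- kids[[i]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  ord
}

#' Assemble the conducting resistance matrix
#'
#' Entry (alpha, beta) is the sum of mean-path edge resistances along the
#' shared mouthward path of lung units alpha and beta; the diagonal is the
#' full path resistance to the mouth.  Symmetric positive semi-definite by
#' construction.
#'
#' @param network a \code{lung_network}.
#' @return dense matrix (units x units), cmH2O.s/L.
#' @export
assemble_resistance_matrix <- function(network) {
  edges <- network$edges
  units <- network$units
  mu <- mu_internal(network$params)
  nu <- nrow(units)
  rng <- edge_unit_ranges(network)
  R <- matrix(0, nu, nu)
  cond <- which(edges$kind == "conducting")
  r_e <- poiseuille_resistance(edges$l[cond], edge_area_eff(edges)[cond],
                               mu, edges$N_b[cond])
  for (j in seq_along(cond)) {
    i <- cond[j]
    sel <- rng$lo[i]:rng$hi[i]
    R[sel, sel] <- R[sel, sel] + r_e[j]
  }
  dimnames(R) <- list(units$unit_id, units$unit_id)
  R
}

#' Build the mechanics system for a network
#'
#' @param network a \code{lung_network}.
#' @return object of class \code{mechanics_system}: resistance matrices,
#'   elastances, resting volumes and the unit ordering shared with the
#'   transport discretisation.
#' @export
build_mechanics <- function(network) {
  units <- network$units
  R_cond <- assemble_resistance_matrix(network)
  R <- R_cond + diag(units$R_acin, nrow(units))
  sys <- list(network = network, R_cond = R_cond,
              R_acin = units$R_acin, R = R,
              K = units$K, V_star = units$V_star,
              units = units, params = network$params)
  class(sys) <- "mechanics_system"
  sys
}

# Discrete periodic steady state of the Crank-Nicolson map under pleural
# drive (A/2)(1 - cos wt): constant part A/(2K), oscillatory part the
# complex response of the discretised operator.  Returns volumes at the
# n_steps + 1 step boundaries of one cycle.
discrete_cycle <- function(sys, amplitude, n_steps) {
  tau <- sys$params$tau
  dt <- tau / n_steps
  om <- 2 * pi / tau
  lam <- exp(1i * om * dt)
  nu <- length(sys$K)
  M <- sys$R * ((lam - 1) / dt) + diag(sys$K, nu) * ((1 + lam) / 2)
  z <- solve(M, rep(-(amplitude / 4) * (1 + lam), nu))
  Vc <- sys$V_star + (amplitude / 2) / sys$K
  ph <- lam^(0:n_steps)
  V <- matrix(rep(Vc, each = n_steps + 1), n_steps + 1, nu) +
    Re(outer(ph, z))
  V
}

# Continuous-time periodic solution (frequency response); used as an
# independent oracle for the stepping scheme.
continuous_cycle <- function(sys, amplitude, times) {
  om <- 2 * pi / sys$params$tau
  nu <- length(sys$K)
  z <- solve(1i * om * sys$R + diag(sys$K, nu),
             rep(-amplitude / 2, nu))
  Vc <- sys$V_star + (amplitude / 2) / sys$K
  matrix(rep(Vc, each = length(times)), length(times), nu) +
    Re(outer(exp(1i * om * times), z))
}

#' Calibrate the pleural pressure amplitude
#'
#' The pleural drive is \code{(A/2)(1 - cos(2 pi t / tau))} (inhalation
#' first, volumes rising from the resting state).  By linearity the
#' steady-cycle tidal volume is proportional to \code{A}, so a single
#' closed-form evaluation of the discrete periodic response yields the
#' amplitude giving the configured tidal volume exactly.
#'
#' @param sys a \code{mechanics_system}.
#' @param V_T target tidal volume (L); defaults to the configured value.
#' @param n_steps time steps per breath cycle.
#' @return object of class \code{breathing_waveform}: amplitude (cmH2O),
#'   period, step count and the periodic volume cycle (matrix of unit
#'   volumes at step boundaries).
#' @export
calibrate_waveform <- function(sys, V_T = sys$params$V_T,
                               n_steps = sys$params$numerics$steps_per_cycle) {
  V1 <- discrete_cycle(sys, 1, n_steps)
  tot <- rowSums(V1)
  T1 <- max(tot) - min(tot)
  if (!is.finite(T1) || T1 <= 0)
    stop("waveform calibration failed: degenerate tidal response")
  A <- V_T / T1
  V <- discrete_cycle(sys, A, n_steps)
  tot <- rowSums(V)
  achieved <- max(tot) - min(tot)
  if (abs(achieved - V_T) / V_T > 1e-3)
    stop(sprintf("waveform calibration failed: achieved V_T = %.6g L", achieved))
  structure(list(tau = sys$params$tau, amplitude = A, n_steps = n_steps,
                 cycleV = V, tidal = achieved,
                 form = "sinusoid", phase = "inhalation-first"),
            class = "breathing_waveform")
}

#' Integrate the ventilation ODEs
#'
#' Crank-Nicolson stepping of the linear system with one factorisation
#' reused across all steps.  By default the state is initialised from the
#' closed-form periodic solution and at least two pre-washout cycles are
#' stepped to verify periodicity (cycle-to-cycle max |dV| below the
#' configured tolerance).
#'
#' @param sys a \code{mechanics_system}.
#' @param waveform a \code{\link{calibrate_waveform}} result.
#' @param n_cycles number of breath cycles to integrate.
#' @param V0 optional initial unit volumes (L); defaults to the periodic
#'   state at the start of inhalation.
#' @return list with times, volume matrix \code{V}, flow matrix
#'   \code{Vdot}, \code{mouth_flow} (sum of unit flows, positive on
#'   inhalation) and the cycle-to-cycle periodicity error (L).
#' @export
solve_ventilation <- function(sys, waveform = calibrate_waveform(sys),
                              n_cycles = 2, V0 = NULL) {
  n_steps <- waveform$n_steps
  tau <- sys$params$tau
  dt <- tau / n_steps
  om <- 2 * pi / tau
  A <- waveform$amplitude
  nu <- length(sys$K)
  Kd <- diag(sys$K, nu)
  M1 <- sys$R / dt + Kd / 2
  M0 <- sys$R / dt - Kd / 2
  ch <- chol(M1)
  if (is.null(V0)) V0 <- waveform$cycleV[1, ]
  nt <- n_cycles * n_steps
  tgrid <- seq(0, by = dt, length.out = nt + 1)
  drive <- (A / 2) * (1 - cos(om * tgrid))
  V <- matrix(NA_real_, nt + 1, nu)
  V[1, ] <- V0
  KVstar <- sys$K * sys$V_star
  for (n in seq_len(nt)) {
    rhs <- M0 %*% V[n, ] + KVstar + (drive[n] + drive[n + 1]) / 2
    V[n + 1, ] <- backsolve(ch, forwardsolve(t(ch), rhs))
  }
  Vdot <- diff(V) / dt
  per_err <- if (n_cycles >= 2)
    max(abs(V[seq_len(n_steps + 1) + (n_cycles - 1) * n_steps, ] -
              V[seq_len(n_steps + 1) + (n_cycles - 2) * n_steps, ]))
  else NA_real_
  tol <- sys$params$numerics$periodicity_tol
  if (is.finite(per_err) && per_err > tol)
    warning(sprintf("periodic steady state not reached: max cycle-to-cycle |dV| = %.3g L", per_err))
  list(t = tgrid, V = V, Vdot = Vdot, mouth_flow = rowSums(Vdot),
       periodicity_error = per_err, dt = dt)
}

#' Per-edge volumetric flows from unit flows
#'
#' The flow through a conducting edge equals the summed volume-change rate
#' of all lung units it feeds (rigid airways, incompressible gas), so flow
#' is conserved at every junction by construction.
#'
#' @param network a \code{lung_network}.
#' @param Vdot matrix (times x units) of unit flows.
#' @return matrix (times x edges) of edge flows, positive toward the
#'   periphery.
#' @export
edge_flows <- function(network, Vdot) {
  rng <- edge_unit_ranges(network)
  cs <- cbind(0, t(apply(Vdot, 1, cumsum)))
  out <- sapply(seq_len(nrow(rng)), function(i)
    cs[, rng$hi[i] + 1] - cs[, rng$lo[i]])
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(Vdot))
  colnames(out) <- rng$edge_id
  out
}
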
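# Discretisation of the mean-path network into finite-volume cells and the
# R-level surface of the transport operators.  The heavy time loop lives in
# src/transport.cpp; the functions here build the cell arrays it consumes
# and expose the pointwise formulas for direct testing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Taylor dispersion coefficient in a conducting airway
#'
#' Effective axial diffusivity \code{D0 + C |u| d} with the dispersion
#' constant switching between inspiration (\code{C = 1.08}) and expiration
#' (\code{C = 0.37}) according to the local flow direction.
#'
#' @param gas a \code{\link{gas_spec}}.
#' @param u local mean gas speed in a single airway (cm/s).
#' @param d airway diameter (cm).
#' @param phase \code{"insp"} or \code{"exp"}.
#' @return dispersion coefficient (cm^2/s).
#' @export
taylor_dispersion <- function(gas, u, d, phase = c("insp", "exp")) {
  phase <- match.arg(phase)
  if (any(d <= 0)) stop("non-positive diameter")
  C <- if (phase == "insp") gas$C_insp else gas$C_exp
  gas$D0 + C * abs(u) * d
}

#' Acinar duct diffusivity
#'
#' Molecular diffusion enhanced by the alveolar sleeve:
#' \code{D0 (1 + phi (S/s - 1))}, where \code{S} is the outer (duct plus
#' sac) and \code{s} the inner (duct lumen) cross-section and \code{phi}
#' the fraction of the sac cross-section taking part in axial diffusion.
#'
#' @param gas a \code{\link{gas_spec}}.
#' @param S outer cross-section (cm^2).
#' @param s inner cross-section (cm^2), \code{0 < s <= S}.
#' @return diffusivity (cm^2/s), at least \code{D0}.
#' @export
acinar_diffusivity <- function(gas, S, s) {
  if (any(s <= 0)) stop("non-positive duct cross-section")
  if (any(S < s)) stop("sac volume cannot be negative (S < s)")
  gas$D0 * (1 + gas$phi * (S / s - 1))
}

#' Mouth boundary closure
#'
#' During inhalation the mouth is a Dirichlet boundary at zero tracer
#' concentration (fresh gas); during exhalation the diffusive flux is
#' suppressed and the advective outflux leaves freely (zero-gradient).
#' At a zero-flow instant the two closures carry identical (zero) flux.
#'
#' @param phase \code{"inhalation"} or \code{"exhalation"}.
#' @return list describing the closure.
#' @export
mouth_boundary <- function(phase = c("inhalation", "exhalation")) {
  phase <- match.arg(phase)
  if (phase == "inhalation")
    list(type = "dirichlet", value = 0)
  else
    list(type = "zero_diffusive_flux")
}

#' Discretise a network for transport
#'
#' Splits every edge into finite-volume cells, precomputes the interface
#' geometry, the unit-range weights that map lung-unit flows onto interface
#' flows, and the per-cell alveolar-sac apportionment weights used to build
#' the time-dependent outer cross-section.
#'
#' @param network a \code{lung_network}.
#' @param cells_per_edge cells per mean-path edge (default from the network
#'   configuration).
#' @return object of class \code{transport_disc}.
#' @export
discretise <- function(network,
                       cells_per_edge =
                         network$params$numerics$cells_per_edge) {
  params <- network$params
  edges <- network$edges
  units <- network$units
  rng <- edge_unit_ranges(network)
  dfo <- dfs_order(edges)
  edges <- edges[dfo, ]
  rng <- rng[dfo, ]
  if (sum(is.na(edges$parent)) != 1)
    stop("network must have a single root edge")
  n_e <- nrow(edges)
  nu <- nrow(units)
  a_eff <- edge_area_eff(edges)
  d_eff <- edge_d_eff(edges)
  s_edge <- edges$N_b * a_eff
  uix <- match(edges$unit_id, units$unit_id)

  # per-unit sac volume shares by edge (same bookkeeping as finalize_units)
  tbo <- params$terminal_bronchiole_order
  w <- sac_weights(params)
  sac_edge <- ifelse(is.na(uix), 0,
                     w[as.character(edges$order)] *
                       edges$N_b / 2^(tbo - edges$order))
  sac_edge[is.na(sac_edge)] <- 0
  unit_sac_tot <- tapply(sac_edge, factor(uix, levels = seq_len(nu)), sum)
  sac_edge_frac <- ifelse(is.na(uix), 0,
                          sac_edge / unit_sac_tot[uix])

  n_c <- rep(as.integer(cells_per_edge), n_e)
  cell_edge <- rep(seq_len(n_e), n_c)
  n <- length(cell_edge)
  dx <- edges$l[cell_edge] / n_c[cell_edge]
  s <- s_edge[cell_edge]
  acinar <- as.integer(edges$kind[cell_edge] == "acinar_duct")
  unit <- ifelse(is.na(uix[cell_edge]), 0L, uix[cell_edge])
  # sac weight: edge share split uniformly across its cells
  sacw <- sac_edge_frac[cell_edge] / n_c[cell_edge]

  # parent cell index: previous cell within the edge; first cell links to
  # the last cell of the parent edge (0 = mouth)
  first_cell <- cumsum(c(1, n_c[-n_e]))
  last_cell <- cumsum(n_c)
  pos_in_edge <- sequence(n_c)
  pe <- match(edges$parent, edges$edge_id)
  parent_cell <- integer(n)
  for (e in seq_len(n_e)) {
    cells <- first_cell[e]:last_cell[e]
    parent_cell[cells] <- c(
      if (is.na(pe[e])) 0L else last_cell[pe[e]],
      cells[-length(cells)])
  }
  dist <- ifelse(parent_cell == 0L, dx / 2,
                 (dx + dx[pmax(parent_cell, 1L)]) / 2)
  s_int <- s
  d_int <- d_eff[cell_edge]
  acinar_int <- acinar
  # interface flow weights
  wq <- numeric(n)
  ulo <- integer(n); uhi <- integer(n)
  cond_cells <- acinar == 0L
  wq[cond_cells] <- 1
  ulo[cond_cells] <- rng$lo[cell_edge[cond_cells]]
  uhi[cond_cells] <- rng$hi[cell_edge[cond_cells]]
  # acinar: flow through an interface feeds all sacs at or distal to the
  # cell; unit chains are contiguous in the DFS cell ordering
  if (any(!cond_cells)) {
    for (u in seq_len(nu)) {
      cells <- which(unit == u)
      wq[cells] <- rev(cumsum(rev(sacw[cells])))
      ulo[cells] <- u
      uhi[cells] <- u
    }
  }
  Vduct <- vapply(seq_len(nu), function(u) {
    e <- which(uix == u)
    sum(edges$N_b[e] * a_eff[e] * edges$l[e])
  }, numeric(1))

  disc <- list(parent = parent_cell, dx = dx, s = s, sacw = sacw,
               s_int = s_int, d_int = d_int, dist = dist, wq = wq,
               Vduct = Vduct, acinar = acinar, unit = unit,
               acinar_int = acinar_int, ulo = ulo, uhi = uhi,
               elim_order = rev(seq_len(n)))
  structure(list(disc = disc, n_cells = n, n_units = nu,
                 cell_edge = cell_edge, edges = edges, units = units,
                 edge_first_cell = first_cell, edge_last_cell = last_cell,
                 params = params),
            class = "transport_disc")
}

#' Outer cross-section profile for given unit volumes
#'
#' Distributes each lung unit's alveolar-sac volume (unit volume minus
#' rigid duct lumen) over the cells of its acinar chain according to the
#' configured per-order sac profile, returning the outer cross-section
#' \code{S} per cell.  Integrating \code{S - s} over a unit's cells
#' recovers the unit's sac volume exactly.
#'
#' @param disc a \code{\link{discretise}} result.
#' @param V unit volumes (L).
#' @return numeric vector of outer cross-sections (cm^2) per cell.
#' @export
distribute_sac_volume <- function(disc, V) {
  d <- disc$disc
  sac <- V * CM3_PER_L - d$Vduct
  if (any(sac < -1e-9))
    stop("unit volume below duct volume: sac volume cannot be negative")
  extra <- ifelse(d$unit > 0, d$sacw * pmax(sac, 0)[pmax(d$unit, 1L)] / d$dx, 0)
  d$s + extra
}

#' Advance a concentration field
#'
#' Implicit conservative finite-volume update of the tracer field over the
#' steps of a supplied unit-volume sequence, using the same solver as the
#' full washout.  Total tracer change equals the net flux through the
#' mouth boundary to solver tolerance.
#'
#' @param disc a \code{\link{discretise}} result.
#' @param gas a \code{\link{gas_spec}}.
#' @param c0 initial cell concentrations.
#' @param Vseq matrix (m + 1 rows x units) of unit volumes (L) at step
#'   boundaries.
#' @param dt time step (s).
#' @param mouth one of \code{"washout"} (Dirichlet 0 on inhalation,
#'   zero-gradient on exhalation) or \code{"closed"} (zero-gradient both
#'   phases).
#' @return list with the new field \code{c}, the tracer volume leaving
#'   through the mouth \code{net_out} (cm^3) and the remaining
#'   \code{total_tracer} (cm^3).
#' @export
advance_concentration <- function(disc, gas, c0, Vseq, dt,
                                  mouth = c("washout", "closed")) {
  mouth <- match.arg(mouth)
  if (is.null(dim(Vseq))) Vseq <- matrix(Vseq, ncol = disc$n_units)
  transport_advance(disc$disc, gas, Vseq * CM3_PER_L, dt,
                    as.numeric(c0), if (mouth == "closed") 1L else 0L)
}
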
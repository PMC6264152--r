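# Independent validation models: a two-compartment analytic washout
# (closed-form sinusoidally forced mechanics plus per-breath well-mixed gas
# bookkeeping with common dead-space re-breathing) and a non-perturbative
# Monte-Carlo heterogeneity sampler that builds each random lung as a
# partially collapsed exact network and runs the full pipeline on it.

#' Two-compartment analytic washout model
#'
#' @param r_shared resistance of the shared (common) airway (cmH2O.s/L).
#' @param r1,r2 lower-airway resistances of the two compartments.
#' @param K1,K2 compartment elastances (cmH2O/L).
#' @param Vstar1,Vstar2 resting volumes (L).
#' @param V_D common dead-space volume (L).
#' @param tau breath period (s).
#' @param V_T tidal volume (L).
#' @param stop_frac end-tidal stopping fraction.
#' @param extra_breaths margin beyond the stopping criterion.
#' @param max_breaths safety limit.
#' @return a \code{two_compartment_model} specification.
#' @export
two_compartment_model <- function(r_shared, r1, r2, K1, K2, Vstar1, Vstar2,
                                  V_D, tau, V_T, stop_frac = 0.025,
                                  extra_breaths = 3L, max_breaths = 200L) {
  vals <- c(r_shared = r_shared, r1 = r1, r2 = r2, K1 = K1, K2 = K2,
            Vstar1 = Vstar1, Vstar2 = Vstar2, V_D = V_D, tau = tau,
            V_T = V_T)
  if (any(vals[-(1:3)] <= 0) || any(vals[1:3] < 0))
    stop("two-compartment parameters must be positive")
  structure(as.list(c(as.list(vals),
                      stop_frac = stop_frac,
                      extra_breaths = as.integer(extra_breaths),
                      max_breaths = as.integer(max_breaths))),
            class = "two_compartment_model")
}

#' Derive a two-compartment model from a two-unit network
#'
#' Maps a network with exactly two lung units onto the analytic model: the
#' shared resistance is the off-diagonal of the conducting resistance
#' matrix, each compartment's lower resistance is its remaining path plus
#' acinar resistance, and elastances, resting volumes and dead space carry
#' over directly.
#'
#' @param network a two-unit \code{lung_network}.
#' @return a \code{\link{two_compartment_model}}.
#' @export
two_compartment_from_network <- function(network) {
  if (nrow(network$units) != 2)
    stop("network must have exactly two lung units")
  R <- assemble_resistance_matrix(network)
  u <- network$units
  two_compartment_model(
    r_shared = R[1, 2],
    r1 = R[1, 1] - R[1, 2] + u$R_acin[1],
    r2 = R[2, 2] - R[1, 2] + u$R_acin[2],
    K1 = u$K[1], K2 = u$K[2],
    Vstar1 = u$V_star[1], Vstar2 = u$V_star[2],
    V_D = conducting_dead_space(network),
    tau = network$params$tau, V_T = network$params$V_T,
    stop_frac = network$params$numerics$stop_frac)
}

#' Analytic washout of the two-compartment model
#'
#' Mechanics: closed-form sinusoidally forced solution of the two-unit
#' ventilation ODEs (pleural drive \code{(A/2)(1 - cos)}, amplitude
#' calibrated to the tidal volume by linearity).  Gas: per-breath
#' well-mixed update of the compartment concentrations including
#' re-breathing of the mixed expirate stored in the common dead space.
#' Indices follow the same conventions as the full model (net expired
#' tracer FRC estimate, log-linear LCI interpolation).
#'
#' @param model a \code{\link{two_compartment_model}}.
#' @return list with the per-breath table, end-tidal series, tidal volumes
#'   per compartment, \code{FRC_approx} and interpolated \code{LCI}.
#' @export
two_compartment_washout <- function(model) {
  m <- model
  om <- 2 * pi / m$tau
  R <- matrix(c(m$r_shared + m$r1, m$r_shared,
                m$r_shared, m$r_shared + m$r2), 2, 2)
  K <- c(m$K1, m$K2)
  # oscillatory response per unit pleural amplitude, then calibrate
  z1 <- solve(1i * om * R + diag(K), c(-0.5, -0.5))
  A <- m$V_T / (2 * abs(sum(z1)))
  z <- z1 * A
  dV <- 2 * abs(z)                       # compartment tidal volumes
  if (sum(dV) < m$V_D)
    stop("tidal volume below dead space: no alveolar ventilation")
  w <- dV / sum(dV)
  F0 <- c(m$Vstar1, m$Vstar2)            # end-exhalation volumes
  c_comp <- c(1, 1)
  c_ds <- 1
  et <- inh_tracer <- net_out <- numeric(0)
  crossing <- 0L
  b <- 0L
  repeat {
    b <- b + 1L
    # inhalation: dead-space gas first (split by flow share), then fresh
    c_new <- (F0 * c_comp + w * m$V_D * c_ds) / (F0 + dV)
    c_comp <- c_new
    # exhalation: mixed alveolar expirate refills the dead space
    c_mix <- sum(w * c_comp)
    out_b <- (sum(dV) - m$V_D) * c_mix
    c_ds <- c_mix
    et <- c(et, c_mix)
    net_out <- c(net_out, out_b)
    if (crossing == 0L && c_mix < m$stop_frac) crossing <- b
    if ((crossing > 0L && b >= crossing + m$extra_breaths) ||
        b >= m$max_breaths) break
  }
  frc <- sum(net_out) / (1 - et[length(et)])
  to <- cumsum(rep(sum(dV), b)) / frc
  lci <- NA_real_
  if (crossing > 1) {
    f <- (log(m$stop_frac) - log(et[crossing - 1])) /
      (log(et[crossing]) - log(et[crossing - 1]))
    lci <- to[crossing - 1] + f * (to[crossing] - to[crossing - 1])
  }
  list(breaths = data.frame(breath = seq_len(b), end_tidal = et,
                            net_tracer_out = net_out, TO = to),
       end_tidal = et, tidal = dV, amplitude = A,
       FRC_approx = frc, LCI = lci, crossing_breath = crossing)
}

#' Monte-Carlo heterogeneity specification
#'
#' @param sigma_a,sigma_l coefficients of variation of airway area and
#'   length (the reference comparison uses \code{sigma_a = sigma_l}).
#' @param mode \code{"independent"} or \code{"correlated"} draws.
#' @param rho_al within-branch correlation (correlated mode).
#' @param deepest_order lowest Strahler order carrying perturbations;
#'   airways below it remain perfectly symmetric.
#' @param n_realisations number of random lungs (at least 50).
#' @param truncation perturbations are redrawn until inside
#'   \code{(-truncation, truncation)}.
#' @param seed integer seed; realisation k uses \code{seed + k}.
#' @return a \code{monte_carlo_spec}.
#' @export
monte_carlo_spec <- function(sigma_a = 0.2, sigma_l = 0.2,
                             mode = c("independent", "correlated"),
                             rho_al = 0, deepest_order = 14L,
                             n_realisations = 100L, truncation = 1,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (n_realisations < 50)
    stop("n_realisations must be at least 50 for a usable variance estimate")
  structure(list(sigma_a = sigma_a, sigma_l = sigma_l, mode = mode,
                 rho_al = rho_al, deepest_order = as.integer(deepest_order),
                 n_realisations = as.integer(n_realisations),
                 truncation = truncation, seed = as.integer(seed)),
            class = "monte_carlo_spec")
}

#' Expand a mean-path network to explicit airways down to an order
#'
#' Every within-region airway of Strahler order at or above
#' \code{deepest_order} becomes an individual edge; each edge at the
#' deepest order roots a collapsed symmetric sub-chain with its own lung
#' unit.  Constriction factors of the collapsed baseline are inherited
#' per order.
#'
#' @param network a single-chain-per-region \code{lung_network}.
#' @param deepest_order lowest order kept explicit.
#' @return a \code{lung_network} whose edge table marks the explicit
#'   airways with \code{meta$distinct_edges}.
#' @export
expand_to_order <- function(network, deepest_order) {
  params <- network$params
  edges <- network$edges[network$edges$region == "proximal", ]
  units <- NULL
  distinct <- character(0)
  lineages <- list()
  for (r in names(params$region_entry_orders)) {
    reg <- network$edges[network$edges$region == r, ]
    cf_map <- stats::setNames(reg$cf, reg$order)
    entry <- max(reg$order)
    attach_id <- reg$parent[reg$order == entry]
    if (deepest_order > entry) {
      lineages[[length(lineages) + 1]] <-
        region_lineage(r, entry, 1, attach_id, r, params, cf_map = cf_map)
      next
    }
    n_lev <- entry - deepest_order + 1
    for (lev in seq_len(n_lev)) {
      o <- entry - lev + 1
      n <- 2^(lev - 1)
      ids <- sprintf("%s.x%02d.%05d", r, o, seq_len(n))
      parents <- if (lev == 1) attach_id else
        sprintf("%s.x%02d.%05d", r, o + 1, ceiling(seq_len(n) / 2))
      gi <- match(o, params$conducting_geometry$order)
      edges <- rbind(edges, data.frame(
        edge_id = ids, parent = parents, region = r, order = o,
        kind = "conducting", d = params$conducting_geometry$d[gi],
        l = params$conducting_geometry$l[gi],
        a = area_of_d(params$conducting_geometry$d[gi]),
        N_b = 1, cf = unname(cf_map[as.character(o)]),
        unit_id = NA_character_, stringsAsFactors = FALSE))
      distinct <- c(distinct, ids)
      if (lev == n_lev) {
        for (id in ids)
          lineages[[length(lineages) + 1]] <-
            region_lineage(r, deepest_order - 1L, 2, id, id, params,
                           cf_map = cf_map)
      }
    }
  }
  for (lin in lineages) {
    edges <- rbind(edges, lin$edges)
    units <- rbind(units, data.frame(
      unit_id = lin$unit_id, region = lin$region, n_acini = NA_real_,
      V_star = NA_real_, K = NA_real_, R_acin = NA_real_,
      stringsAsFactors = FALSE))
  }
  # conducting areas of the explicit layer still carry raw table geometry:
  # apply the baseline dead-space area scaling
  sc <- network$meta$vd_area_scale %||% 1
  fresh <- !(edges$edge_id %in% network$edges$edge_id)
  cond <- fresh & edges$kind == "conducting"
  edges$a[cond] <- edges$a[cond] * sc
  edges$d[cond] <- edges$d[cond] * sqrt(sc)
  net <- reorder_network(new_lung_network(
    edges, units, params,
    meta = c(network$meta, list(distinct_edges = sort(distinct),
                                deepest_order = deepest_order))))
  finalize_units(net)
}

# draw per-airway (eps_a, eps_l) for the explicit airways of an expanded
# network; returns a data.frame aligned with meta$distinct_edges (sorted)
draw_perturbations <- function(net, spec) {
  ids <- net$meta$distinct_edges
  edges <- net$edges
  i <- match(ids, edges$edge_id)
  trunc_draw <- function(n, sd) {
    x <- stats::rnorm(n, 0, sd)
    bad <- abs(x) >= spec$truncation
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), 0, sd)
      bad <- abs(x) >= spec$truncation
    }
    x
  }
  if (spec$mode == "independent") {
    data.frame(edge_id = ids,
               eps_a = trunc_draw(length(ids), spec$sigma_a),
               eps_l = trunc_draw(length(ids), spec$sigma_l),
               stringsAsFactors = FALSE)
  } else {
    Sig <- covariance_model("correlated", spec$sigma_a, spec$sigma_l,
                            spec$rho_al)$Sigma
    L <- t(chol(Sig))
    eps <- matrix(0, nrow(edges), 2)
    pidx <- match(edges$parent, edges$edge_id)
    for (j in order(edges$order[i], decreasing = TRUE)) {
      e <- i[j]
      base <- if (!is.na(pidx[e]) && edges$edge_id[pidx[e]] %in% ids)
        eps[pidx[e], ] else c(0, 0)
      repeat {
        cand <- base + as.numeric(L %*% stats::rnorm(2))
        if (all(abs(cand) < spec$truncation)) break
      }
      eps[e, ] <- cand
    }
    data.frame(edge_id = ids, eps_a = eps[i, 1], eps_l = eps[i, 2],
               stringsAsFactors = FALSE)
  }
}

# apply drawn perturbations to the explicit airways of an expanded network
perturb_expanded <- function(net, draws) {
  i <- match(draws$edge_id, net$edges$edge_id)
  net$edges$a[i] <- net$edges$a[i] * (1 + draws$eps_a)
  net$edges$d[i] <- net$edges$d[i] * sqrt(1 + draws$eps_a)
  net$edges$l[i] <- net$edges$l[i] * (1 + draws$eps_l)
  finalize_units(net)
}

#' Non-perturbative Monte-Carlo variance of washout indices
#'
#' Draws truncated-normal per-airway perturbations for every explicit
#' airway down to the spec's deepest order, builds each realisation as a
#' partially collapsed exact network, runs the full washout pipeline and
#' returns sample statistics with a bootstrap confidence interval on the
#' standard deviation.
#'
#' @param network baseline (possibly constricted) single-chain network.
#' @param spec a \code{\link{monte_carlo_spec}}.
#' @param gas tracer gas.
#' @param numerics numerical overrides for the per-realisation washouts.
#' @param n_boot bootstrap resamples for the sd confidence interval.
#' @return list: per-realisation data.frame, \code{mean}, \code{sd},
#'   \code{sd_ci} (95\% bootstrap), number of failed realisations.
#' @export
monte_carlo_variance <- function(network, spec, gas = "SF6",
                                 numerics = list(), n_boot = 1000L) {
  expanded <- expand_to_order(network, spec$deepest_order)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  lci <- numeric(spec$n_realisations)
  for (k in seq_len(spec$n_realisations)) {
    set.seed(spec$seed + k)
    draws <- draw_perturbations(expanded, spec)
    lci[k] <- tryCatch({
      tr <- run_washout(perturb_expanded(expanded, draws), gas, numerics)
      as.numeric(compute_lci(tr))
    }, error = function(e) {
      warning("realisation ", k, " failed: ", conditionMessage(e))
      NA_real_
    })
  }
  ok <- is.finite(lci)
  set.seed(spec$seed)
  boots <- vapply(seq_len(n_boot), function(b)
    stats::sd(sample(lci[ok], replace = TRUE)), numeric(1))
  list(per_realisation = data.frame(realisation = seq_along(lci),
                                    LCI = lci),
       mean = mean(lci[ok]), sd = stats::sd(lci[ok]),
       sd_ci = stats::quantile(boots, c(0.025, 0.975), names = FALSE),
       n_failed = sum(!ok), spec = spec)
}
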
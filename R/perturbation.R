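# Perturbative extension of the mean-path model: linear sensitivities of
# washout outputs to per-airway area/length and per-acinus elastance
# changes, computed on split networks that isolate one perturbed branch per
# degeneracy class (region x Strahler order).  Tree-structured Gaussian
# covariance models are propagated to output variances with closed-form
# pair-count combinatorics (ancestor counting) rather than enumeration of
# the ~1e7 branches.

#' Baseline model-M evaluation
#'
#' Runs the washout once on the unperturbed network and freezes the breath
#' count so that perturbed re-runs share an identical protocol, making
#' finite-difference sensitivities smooth functions of the perturbation.
#'
#' @param network a \code{lung_network}.
#' @param gas tracer gas name.
#' @param numerics numerical overrides, see \code{\link{run_washout}}.
#' @return object of class \code{model_m}: the trace, its indices, and the
#'   frozen protocol.
#' @export
model_m_baseline <- function(network, gas = "SF6", numerics = list()) {
  trace <- run_washout(network, gas, numerics)
  idx <- mbw_indices(trace)
  structure(list(network = network, gas = gas, numerics = numerics,
                 trace = trace, indices = idx,
                 n_breaths = nrow(trace$breaths),
                 crossing_breath = idx$crossing_breath),
            class = "model_m")
}

#' Perturbation target
#'
#' One degeneracy class of perturbations: all airways at a given Strahler
#' order of a region (kinds \code{"a"}, area, and \code{"l"}, length), or
#' the acini of a region (kind \code{"K"}, elastance).
#'
#' @param kind \code{"a"}, \code{"l"} or \code{"K"}.
#' @param region region name.
#' @param order Strahler order of the perturbed airway class (ignored for
#'   kind \code{"K"}).
#' @return a \code{perturbation_target}.
#' @export
perturbation_target <- function(kind = c("a", "l", "K"), region,
                                order = NA_integer_) {
  kind <- match.arg(kind)
  structure(list(kind = kind, region = region, order = as.integer(order)),
            class = "perturbation_target")
}

# Split one region chain at `order`: a perturbed branch of multiplicity 1
# with its own sub-chain and lung unit, and a sibling sub-chain carrying
# the remaining multiplicity.  For acinar orders the split is made at the
# terminal bronchiole (one whole acinus is isolated) and the perturbation
# is applied to the mean-path duct generation inside it; the resulting
# response is divided by the duct multiplicity afterwards (linearity plus
# within-acinus symmetry).  Baseline constrictions are inherited through
# the per-order cf profile.
split_network <- function(network, region, order) {
  params <- network$params
  tbo <- params$terminal_bronchiole_order
  split_at <- max(order, tbo)
  reg <- network$edges[network$edges$region == region, ]
  if (!nrow(reg)) stop("unknown region ", region)
  if (anyDuplicated(reg$order))
    stop("split_network requires a single-chain region")
  cf_map <- stats::setNames(reg$cf, reg$order)
  entry <- max(reg$order)
  if (split_at > entry) stop("order ", order, " above region entry order")
  N_split <- reg$N_b[reg$order == split_at]
  edges <- network$edges[network$edges$region != region, ]
  units <- network$units[network$units$region != region, ]
  if (split_at < entry) {
    upper <- reg[reg$order > split_at, ]
    edges <- rbind(edges, upper)
    parent_id <- upper$edge_id[which.min(upper$order)]
  } else {
    parent_id <- reg$parent[reg$order == entry]
  }
  sc <- network$meta$vd_area_scale %||% 1
  lin_p <- region_lineage(region, split_at, 1, parent_id,
                          paste0(region, ".pert"), params, cf_map = cf_map)
  lin_p$edges <- apply_vd_scale(lin_p$edges, sc)
  edges <- rbind(edges, lin_p$edges)
  units <- rbind(units, data.frame(
    unit_id = lin_p$unit_id, region = region, n_acini = NA_real_,
    V_star = NA_real_, K = NA_real_, R_acin = NA_real_,
    stringsAsFactors = FALSE))
  sib_unit <- NA_character_
  if (N_split > 1) {
    lin_s <- region_lineage(region, split_at, N_split - 1, parent_id,
                            paste0(region, ".sib"), params, cf_map = cf_map)
    lin_s$edges <- apply_vd_scale(lin_s$edges, sc)
    edges <- rbind(edges, lin_s$edges)
    units <- rbind(units, data.frame(
      unit_id = lin_s$unit_id, region = region, n_acini = NA_real_,
      V_star = NA_real_, K = NA_real_, R_acin = NA_real_,
      stringsAsFactors = FALSE))
    sib_unit <- lin_s$unit_id
  }
  pert_edge <- paste0(region, if (order >= tbo) sprintf(".pert.o%02d", order)
                      else sprintf(".pert.ac.o%02d", order))
  net <- reorder_network(new_lung_network(edges, units, params,
                                          network$meta))
  net <- finalize_units(net)
  list(network = net, pert_edge = pert_edge, pert_unit = lin_p$unit_id,
       sib_unit = sib_unit,
       duct_multiplicity = if (order >= tbo) 1 else 2^(tbo - order))
}

# apply a multiplicative perturbation to one edge (area or length) or one
# unit's elastance
apply_perturbation <- function(network, kind, id, eps) {
  if (abs(eps) >= 1)
    stop("perturbation magnitude must be below 1")
  if (kind == "a") {
    i <- match(id, network$edges$edge_id)
    network$edges$a[i] <- network$edges$a[i] * (1 + eps)
    network$edges$d[i] <- network$edges$d[i] * sqrt(1 + eps)
    finalize_units(network)
  } else if (kind == "l") {
    i <- match(id, network$edges$edge_id)
    network$edges$l[i] <- network$edges$l[i] * (1 + eps)
    finalize_units(network)
  } else {
    network <- finalize_units(network)
    i <- match(id, network$units$unit_id)
    network$units$K[i] <- network$units$K[i] * (1 + eps)
    network
  }
}

# washout outputs of a (possibly split) network under the baseline's frozen
# protocol, as a flat named vector
pipeline_outputs <- function(network, baseline, unit_map) {
  tr <- run_washout(network, baseline$gas, baseline$numerics,
                    fixed_breaths = baseline$n_breaths)
  frc <- compute_frc_approx(tr)
  lci <- compute_lci(tr, frc)
  to <- tr$breaths$cum_expired / frc
  sn <- phase3_slopes(tr)
  use <- seq_len(nrow(tr$breaths)) <= attr(lci, "breath")
  scond <- compute_scond(sn[use], to[use],
                         network$params$mbw$scond_to_range)
  fv <- compute_fv(tr, breaths = seq_len(min(baseline$crossing_breath,
                                             nrow(tr$breaths) - 1)))$mean
  names(fv) <- paste0("FV.", unit_map[names(fv)])
  c(LCI = as.numeric(lci), Scond = scond, FRC_approx = frc, fv)
}

#' Linear sensitivity of all outputs to one perturbation class
#'
#' Builds the split network isolating a single airway (or acinus) of the
#' target class, reruns the full washout pipeline at +/- the probe size and
#' returns the central-difference linear responses
#' \code{delta_g = f dg/df = (g(+e) - g(-e)) / (2 e)} for LCI, S_cond,
#' FRC_approx and the per-unit-class fractional ventilation (\code{FV.own}:
#' acini descended from the perturbed airway; \code{FV.sib}: the rest of
#' the perturbed region; \code{FV.<region>} otherwise).
#'
#' @param baseline a \code{\link{model_m_baseline}}.
#' @param target a \code{\link{perturbation_target}}.
#' @param eps probe size (relative perturbation, default 1e-3).
#' @param richardson if \code{TRUE}, repeat at half the probe and error if
#'   the two estimates differ by 1\% or more (non-convergent
#'   linearisation), after one automatic halving.
#' @return named numeric vector of linear responses, with the target as
#'   attributes.
#' @export
compute_sensitivity <- function(baseline, target, eps = 1e-3,
                                richardson = FALSE) {
  net <- baseline$network
  one <- function(e) {
    if (target$kind == "K") {
      sp <- split_network(net, target$region,
                          net$params$terminal_bronchiole_order)
      id <- sp$pert_unit
      mult <- 1
    } else {
      sp <- split_network(net, target$region, target$order)
      id <- sp$pert_edge
      mult <- sp$duct_multiplicity
    }
    unit_map <- stats::setNames(sp$network$units$region,
                                sp$network$units$unit_id)
    unit_map[sp$pert_unit] <- "own"
    if (!is.na(sp$sib_unit)) unit_map[sp$sib_unit] <- "sib"
    gp <- pipeline_outputs(apply_perturbation(sp$network, target$kind, id, e),
                           baseline, unit_map)
    gm <- pipeline_outputs(apply_perturbation(sp$network, target$kind, id, -e),
                           baseline, unit_map)
    (gp - gm) / (2 * e) / mult
  }
  d1 <- one(eps)
  if (richardson) {
    d2 <- one(eps / 2)
    ref <- max(abs(d1[c("LCI", "FRC_approx")]))
    if (max(abs(d1[c("LCI", "FRC_approx")] -
                  d2[c("LCI", "FRC_approx")])) >= 0.01 * ref) {
      d1 <- d2
      d2 <- one(eps / 4)
      if (max(abs(d1[c("LCI", "FRC_approx")] -
                    d2[c("LCI", "FRC_approx")])) >= 0.01 * ref)
        stop("non-convergent linearisation: responses differ by >= 1% ",
             "after probe halving; reduce eps or expect nonlinearity")
    }
  }
  attr(d1, "target") <- target
  d1
}

#' Sensitivity matrix over many perturbation classes
#'
#' @param baseline a \code{\link{model_m_baseline}}.
#' @param targets data.frame with columns \code{kind}, \code{region},
#'   \code{order}; see \code{\link{sensitivity_targets}}.
#' @param eps probe size.
#' @param progress print one line per target.
#' @return long data.frame of class \code{sensitivity_matrix}: one row per
#'   (target, output) with the per-airway linear response \code{delta} and
#'   the class multiplicity \code{N_b}.
#' @export
sensitivity_matrix <- function(baseline, targets, eps = 1e-3,
                               progress = FALSE) {
  edges <- baseline$network$edges
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- perturbation_target(targets$kind[i], targets$region[i],
                              targets$order[i])
    if (progress)
      message(sprintf("sensitivity %d/%d: %s %s order %s", i, nrow(targets),
                      tg$region, tg$kind, tg$order))
    d <- compute_sensitivity(baseline, tg, eps)
    N_b <- if (tg$kind == "K") {
      sum(baseline$network$units$n_acini[
        baseline$network$units$region == tg$region])
    } else {
      edges$N_b[edges$region == tg$region & edges$order == tg$order]
    }
    out[[i]] <- data.frame(kind = tg$kind, region = tg$region,
                           order = tg$order, N_b = N_b,
                           output = names(d), delta = as.numeric(d),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("sensitivity_matrix", class(res))
  attr(res, "eps") <- eps
  res
}

#' Enumerate perturbation classes
#'
#' @param network a \code{lung_network}.
#' @param regions region names (default all).
#' @param orders Strahler orders to include (default every order present in
#'   the chosen regions).
#' @param kinds subset of \code{c("a", "l", "K")}.
#' @return data.frame of targets for \code{\link{sensitivity_matrix}}.
#' @export
sensitivity_targets <- function(network, regions = NULL, orders = NULL,
                                kinds = c("a", "l")) {
  edges <- network$edges
  regions <- regions %||% setdiff(unique(edges$region), "proximal")
  out <- NULL
  for (r in regions) {
    os <- sort(unique(edges$order[edges$region == r]), decreasing = TRUE)
    if (!is.null(orders)) os <- intersect(os, orders)
    for (k in setdiff(kinds, "K"))
      out <- rbind(out, data.frame(kind = k, region = r, order = os))
    if ("K" %in% kinds)
      out <- rbind(out, data.frame(kind = "K", region = r,
                                   order = NA_integer_))
  }
  out
}

#' Superpose linear responses onto the baseline (model P reconstruction)
#'
#' First-order reconstruction of an output for an arbitrary assignment of
#' small perturbations over individual airways:
#' \code{g_P = g_M + sum_i delta_g(class(i)) eps_i}.  Means are left at
#' their model-M values; no second-order corrections are applied.
#'
#' @param baseline a \code{\link{model_m_baseline}}.
#' @param sens a \code{\link{sensitivity_matrix}}.
#' @param eps_assignment data.frame with columns \code{kind},
#'   \code{region}, \code{order}, \code{eps} and optionally \code{n}
#'   (number of airways of the class carrying this perturbation, default
#'   1).
#' @param outputs which outputs to reconstruct.
#' @return named numeric vector of model-P outputs.
#' @export
superpose <- function(baseline, sens, eps_assignment,
                      outputs = c("LCI", "Scond", "FRC_approx")) {
  if (any(abs(eps_assignment$eps) >= 1))
    stop("unphysical perturbation: |eps| must be below 1")
  if (is.null(eps_assignment$n)) eps_assignment$n <- 1
  base <- c(LCI = baseline$indices$LCI, Scond = baseline$indices$Scond,
            FRC_approx = baseline$indices$FRC_approx)
  vapply(outputs, function(g) {
    s <- sens[sens$output == g, ]
    tot <- 0
    for (j in seq_len(nrow(eps_assignment))) {
      row <- s[s$kind == eps_assignment$kind[j] &
                 s$region == eps_assignment$region[j] &
                 (s$kind == "K" | s$order == eps_assignment$order[j]), ]
      if (nrow(row) != 1)
        stop("no sensitivity for class ", eps_assignment$kind[j], "/",
             eps_assignment$region[j], "/", eps_assignment$order[j])
      tot <- tot + row$delta * eps_assignment$eps[j] * eps_assignment$n[j]
    }
    unname(base[g] + tot)
  }, numeric(1))
}

#' Gaussian heterogeneity model for airway perturbations
#'
#' In \code{"independent"} mode the relative area and length perturbations
#' of every airway are independent with standard deviations \code{sigma_a}
#' and \code{sigma_l}.  In \code{"correlated"} mode each airway's
#' perturbation is normally distributed about its parent's with
#' within-branch increment covariance
#' \code{Sigma = [[sa^2, rho sa sl], [rho sa sl, sl^2]]}, so geometric
#' fluctuations are inherited down the tree.
#'
#' @param mode \code{"independent"} or \code{"correlated"}.
#' @param sigma_a,sigma_l coefficients of variation of airway area and
#'   length.
#' @param rho_al within-branch area-length correlation (correlated mode).
#' @param sigma_K coefficient of variation of acinar elastance (default 0:
#'   geometry dominates the output variance).
#' @return a \code{covariance_model}.
#' @export
covariance_model <- function(mode = c("independent", "correlated"),
                             sigma_a = 0.2, sigma_l = 0.1, rho_al = 0,
                             sigma_K = 0) {
  mode <- match.arg(mode)
  if (abs(rho_al) > 1) stop("rho_al must lie in [-1, 1]")
  Sigma <- matrix(c(sigma_a^2, rho_al * sigma_a * sigma_l,
                    rho_al * sigma_a * sigma_l, sigma_l^2), 2, 2,
                  dimnames = list(c("a", "l"), c("a", "l")))
  if (min(eigen(Sigma, only.values = TRUE)$values) < -1e-12)
    stop("within-branch covariance is not positive semi-definite")
  structure(list(mode = mode, sigma_a = sigma_a, sigma_l = sigma_l,
                 rho_al = rho_al, sigma_K = sigma_K, Sigma = Sigma),
            class = "covariance_model")
}

#' Covariance between two airway perturbations
#'
#' Independent mode: \code{sigma_p^2} when the two indices refer to the
#' same airway and the same parameter, zero otherwise.  Correlated mode:
#' each perturbation is the sum of independent per-generation increments
#' along the path from the region root, so the covariance is the number of
#' shared path generations times the within-branch increment covariance.
#'
#' @param model a \code{\link{covariance_model}}.
#' @param depth_i,depth_j generation depths of the two airways within the
#'   region (the region root is depth 1).
#' @param shared number of generations on their common root path (for
#'   \code{i == j} this equals the depth; for siblings, depth - 1).
#' @param p,p2 perturbed parameters, \code{"a"} or \code{"l"}.
#' @param same_airway are the two indices the same airway?
#' @return scalar covariance.
#' @export
tree_covariance <- function(model, depth_i, depth_j, shared, p = "a",
                            p2 = "a", same_airway = depth_i == depth_j &&
                              shared == depth_i) {
  if (shared > min(depth_i, depth_j))
    stop("shared path cannot exceed either depth")
  if (model$mode == "independent") {
    if (same_airway && p == p2)
      return(switch(p, a = model$sigma_a^2, l = model$sigma_l^2))
    return(0)
  }
  shared * model$Sigma[p, p2]
}

# sensitivities of one output as per-region matrices delta[depth, param]
sens_by_region <- function(sens, network, output) {
  s <- sens[sens$output == output & sens$kind %in% c("a", "l"), ]
  entry <- tapply(network$edges$order, network$edges$region, max)
  out <- list()
  for (r in unique(s$region)) {
    sr <- s[s$region == r, ]
    depths <- entry[[r]] - sr$order + 1
    G <- max(depths)
    m <- matrix(0, G, 2, dimnames = list(NULL, c("a", "l")))
    pres <- logical(G)
    for (j in seq_len(nrow(sr))) {
      m[depths[j], sr$kind[j]] <- sr$delta[j]
      pres[depths[j]] <- TRUE
    }
    out[[r]] <- list(delta = m, present = pres, entry = entry[[r]])
  }
  out
}

#' Output variance under a heterogeneity model
#'
#' Evaluates the first-order variance propagation
#' \code{var(g) = sum_{i,i',p,p'} cov(eps_i^p, eps_i'^p') delta_i delta_i'}
#' using the degeneracy of the symmetric regions: pairs are counted in
#' closed form by summing over common ancestors (\code{2^(m-1)} nodes at
#' depth m, each contributing the squared summed response of its subtree),
#' never enumerating individual branches.  Perturbations are restricted to
#' the classes present in the sensitivity matrix.
#'
#' @param sens a \code{\link{sensitivity_matrix}}.
#' @param model a \code{\link{covariance_model}}.
#' @param network the baseline network the sensitivities were computed on.
#' @param outputs outputs to propagate.
#' @return data.frame with \code{output}, \code{var}, \code{sd}.
#' @export
output_variance <- function(sens, model, network,
                            outputs = c("LCI", "Scond", "FRC_approx")) {
  sig2 <- c(a = model$sigma_a^2, l = model$sigma_l^2)
  res <- lapply(outputs, function(g) {
    br <- sens_by_region(sens, network, g)
    v <- 0
    for (r in names(br)) {
      delta <- br[[r]]$delta
      pres <- br[[r]]$present
      G <- nrow(delta)
      if (model$mode == "independent") {
        for (p in c("a", "l"))
          v <- v + sig2[[p]] * sum(2^(which(pres) - 1) *
                                     delta[pres, p]^2)
      } else {
        for (m in which(pres)) {
          Tm <- vapply(c("a", "l"), function(p)
            sum(2^(seq(m, G)[pres[m:G]] - m) *
                  delta[seq(m, G)[pres[m:G]], p]), numeric(1))
          v <- v + 2^(m - 1) * drop(t(Tm) %*% model$Sigma %*% Tm)
        }
      }
    }
    if (model$sigma_K > 0) {
      sK <- sens[sens$output == g & sens$kind == "K", ]
      if (nrow(sK))
        v <- v + model$sigma_K^2 * sum(sK$N_b * sK$delta^2)
    }
    data.frame(output = g, var = v, sd = sqrt(pmax(v, 0)))
  })
  do.call(rbind, res)
}

#' Variance of the fractional ventilation of a single acinus
#'
#' Unlike the global outputs, the FV of one acinus responds differently to
#' perturbations on its own feeding path (\code{FV.own}) and to
#' perturbations elsewhere in its region (\code{FV.sib}) or in other
#' regions.  The ancestor-counting sum distinguishes the two: below the
#' terminal bronchiole all ducts of the acinus carry the own-path
#' response.
#'
#' @param sens a \code{\link{sensitivity_matrix}} (FV outputs included).
#' @param model a \code{\link{covariance_model}}.
#' @param network baseline network.
#' @param region region whose acinus class is evaluated.
#' @return variance of the acinus FV.
#' @export
fv_acinus_variance <- function(sens, model, network, region) {
  params <- network$params
  tbo <- params$terminal_bronchiole_order
  entry <- tapply(network$edges$order, network$edges$region, max)
  sig2 <- c(a = model$sigma_a^2, l = model$sigma_l^2)
  v <- 0
  for (r in unique(sens$region[sens$kind %in% c("a", "l")])) {
    sr <- sens[sens$region == r & sens$kind %in% c("a", "l"), ]
    if (r == region) {
      own <- sr[sr$output == "FV.own", ]
      sib <- sr[sr$output == "FV.sib", ]
      G <- entry[[r]] + 1
      Gtb <- entry[[r]] - tbo + 1
      do <- ds <- matrix(0, G, 2, dimnames = list(NULL, c("a", "l")))
      pres <- logical(G)
      for (j in seq_len(nrow(own))) {
        dpt <- entry[[r]] - own$order[j] + 1
        do[dpt, own$kind[j]] <- own$delta[j]
        pres[dpt] <- TRUE
      }
      for (j in seq_len(nrow(sib))) {
        dpt <- entry[[r]] - sib$order[j] + 1
        ds[dpt, sib$kind[j]] <- sib$delta[j]
      }
      own_count <- function(g) ifelse(g <= Gtb, 1, 2^(g - Gtb))
      if (model$mode == "independent") {
        for (p in c("a", "l")) {
          g <- which(pres)
          v <- v + sig2[[p]] * sum(own_count(g) * do[g, p]^2 +
                                     (2^(g - 1) - own_count(g)) * ds[g, p]^2)
        }
      } else {
        for (m in which(pres)) {
          n_own <- own_count(m)
          n_off <- 2^(m - 1) - n_own
          gs <- seq(m, G)[pres[m:G]]
          Town <- vapply(c("a", "l"), function(p) {
            opn <- own_count(gs) / n_own
            sum(opn * do[gs, p] + (2^(gs - m) - opn) * ds[gs, p])
          }, numeric(1))
          Toff <- vapply(c("a", "l"), function(p)
            sum(2^(gs - m) * ds[gs, p]), numeric(1))
          v <- v + n_own * drop(t(Town) %*% model$Sigma %*% Town)
          if (n_off > 0)
            v <- v + n_off * drop(t(Toff) %*% model$Sigma %*% Toff)
        }
      }
    } else {
      # other regions act on this acinus like a global output
      cross <- sr[sr$output == paste0("FV.", region), ]
      if (!nrow(cross)) next
      G <- entry[[r]] + 1
      delta <- matrix(0, G, 2, dimnames = list(NULL, c("a", "l")))
      pres <- logical(G)
      for (j in seq_len(nrow(cross))) {
        dpt <- entry[[r]] - cross$order[j] + 1
        delta[dpt, cross$kind[j]] <- cross$delta[j]
        pres[dpt] <- TRUE
      }
      if (model$mode == "independent") {
        for (p in c("a", "l")) {
          g <- which(pres)
          v <- v + sig2[[p]] * sum(2^(g - 1) * delta[g, p]^2)
        }
      } else {
        for (m in which(pres)) {
          gs <- seq(m, G)[pres[m:G]]
          Tm <- vapply(c("a", "l"), function(p)
            sum(2^(gs - m) * delta[gs, p]), numeric(1))
          v <- v + 2^(m - 1) * drop(t(Tm) %*% model$Sigma %*% Tm)
        }
      }
    }
  }
  max(v, 0)
}

#' Fractional ventilation probability density
#'
#' Mixture density of the FV of a randomly chosen acinus: each region's
#' acinus class contributes a Gaussian centred at its model-M FV with the
#' variance given by first-order propagation of the heterogeneity model,
#' weighted by its acinus count.  In the limit of many acini the FV
#' distribution of a single random lung realisation tends to this density.
#'
#' @param baseline a \code{\link{model_m_baseline}}.
#' @param sens a \code{\link{sensitivity_matrix}} including FV outputs.
#' @param model a \code{\link{covariance_model}}.
#' @param grid FV evaluation grid.
#' @return data.frame of class \code{fv_density} with the mixture density
#'   and per-component means, standard deviations and weights as
#'   attributes.
#' @export
fv_density <- function(baseline, sens, model,
                       grid = seq(0, 0.5, length.out = 1001)) {
  net <- baseline$network
  units <- net$units
  fv_m <- baseline$indices$FV[units$unit_id]
  wts <- units$n_acini / sum(units$n_acini)
  sds <- vapply(units$region, function(r)
    sqrt(fv_acinus_variance(sens, model, net, r)), numeric(1))
  if (any(!is.finite(sds))) {
    warning("negative or non-finite FV variance clamped to 0")
    sds[!is.finite(sds)] <- 0
  }
  dens <- rep(0, length(grid))
  for (i in seq_along(wts)) {
    if (sds[i] > 0) {
      dens <- dens + wts[i] * stats::dnorm(grid, fv_m[i], sds[i])
    } else {
      # degenerate component: a point mass at the class mean
      j <- which.min(abs(grid - fv_m[i]))
      dg <- mean(diff(grid))
      dens[j] <- dens[j] + wts[i] / dg
    }
  }
  out <- data.frame(fv = grid, density = dens)
  attr(out, "components") <- data.frame(
    unit_id = units$unit_id, region = units$region, weight = wts,
    mean = as.numeric(fv_m), sd = sds)
  class(out) <- c("fv_density", class(out))
  out
}

#' Sensitivity of outputs to global lung parameters
#'
#' Combines the per-class sensitivities into responses to three global
#' parameters: total airway dead space (isotropic scaling of all conducting
#' airways at fixed length-diameter ratio), conducting length-diameter
#' ratio (shape change at fixed volume) and total lung elastance.
#'
#' @param sens a \code{\link{sensitivity_matrix}} covering the conducting
#'   classes (and kind \code{"K"} for the elastance response).
#' @param network baseline network.
#' @param parameter \code{"V_D"}, \code{"LD_cond"} or \code{"K_lung"}.
#' @param output output name, default \code{"LCI"}.
#' @return scalar linear sensitivity \code{delta_g(parameter)}.
#' @export
global_sensitivity <- function(sens, network, parameter = c(
  "V_D", "LD_cond", "K_lung"), output = "LCI") {
  parameter <- match.arg(parameter)
  tbo <- network$params$terminal_bronchiole_order
  s <- sens[sens$output == output, ]
  if (parameter == "K_lung") {
    sK <- s[s$kind == "K", ]
    if (!nrow(sK)) stop("missing elastance (kind 'K') sensitivities")
    return(sum(sK$N_b * sK$delta))
  }
  sc <- s[s$kind %in% c("a", "l") & s$order >= tbo, ]
  wide <- merge(sc[sc$kind == "a", c("region", "order", "N_b", "delta")],
                sc[sc$kind == "l", c("region", "order", "delta")],
                by = c("region", "order"), suffixes = c("_a", "_l"))
  if (!nrow(wide)) stop("no conducting a/l sensitivity pairs available")
  if (parameter == "V_D")
    sum(wide$N_b * (wide$delta_l + 2 * wide$delta_a)) / 3
  else
    2 * sum(wide$N_b * (wide$delta_l - wide$delta_a)) / 3
}
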
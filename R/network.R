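# Mean-path airway network: seven lobar regions, each a symmetric
# bifurcating tree collapsed to a chain of edges with branch multiplicities
# N_b, hanging off an asymmetric proximal tree.  Networks are plain lists
# with an edge table, a lung-unit table and the parameters that built them.

#' @rdname build_model_m
#' @export
new_lung_network <- function(edges, units, params, meta = list()) {
  rownames(edges) <- NULL
  rownames(units) <- NULL
  net <- list(edges = edges, units = units, params = params, meta = meta)
  class(net) <- "lung_network"
  net
}

area_of_d <- function(d) pi * d^2 / 4

# effective single-airway cross-section and diameter after constriction
# (severity acts on radius, so area scales with cf^2)
edge_area_eff <- function(edges) edges$a * edges$cf^2
edge_d_eff <- function(edges) edges$d * edges$cf

edge_children <- function(edges) split(seq_len(nrow(edges)), factor(
  edges$parent, levels = edges$edge_id))

# single chain of one generation per order, N_b doubling each generation
chain_rows <- function(region, orders, N_b_first, parent, prefix, geom,
                       kind) {
  idx <- match(orders, geom$order)
  if (anyNA(idx))
    stop("configuration error: missing per-order geometry for order(s) ",
         paste(orders[is.na(idx)], collapse = ", "))
  n <- length(orders)
  ids <- sprintf("%s.o%02d", prefix, orders)
  data.frame(
    edge_id = ids,
    parent = c(parent, ids[-n]),
    region = region,
    order = as.integer(orders),
    kind = kind,
    d = geom$d[idx],
    l = geom$l[idx],
    a = area_of_d(geom$d[idx]),
    N_b = N_b_first * 2^(seq_len(n) - 1),
    cf = 1,
    unit_id = NA_character_,
    stringsAsFactors = FALSE
  )
}

# Builds one region lineage: conducting chain from `from_order` down to the
# terminal bronchiole, acinar chain below it, one lung unit at the end.
# `N_b_first` is the multiplicity of the topmost edge.  For sub-acinar
# lineages (`from_order` < tbo) only the acinar part is produced.
region_lineage <- function(region, from_order, N_b_first, parent, prefix,
                           params, cf_orders = integer(0), cf = 1,
                           cf_map = NULL) {
  tbo <- params$terminal_bronchiole_order
  rows <- NULL
  if (from_order >= tbo) {
    rows <- chain_rows(region, seq(from_order, tbo), N_b_first, parent,
                       prefix, params$conducting_geometry, "conducting")
    ac_first <- N_b_first * 2^(from_order - tbo + 1)
    parent_ac <- rows$edge_id[nrow(rows)]
    ac_orders <- seq(tbo - 1L, 0L)
  } else {
    ac_first <- N_b_first
    parent_ac <- parent
    ac_orders <- seq(from_order, 0L)
  }
  ac <- chain_rows(region, ac_orders, ac_first, parent_ac,
                   paste0(prefix, ".ac"), params$acinar_geometry,
                   "acinar_duct")
  unit_id <- paste0(prefix, ".unit")
  ac$unit_id <- unit_id
  rows <- rbind(rows, ac)
  if (!is.null(cf_map)) {
    m <- cf_map[as.character(rows$order)]
    rows$cf <- rows$cf * ifelse(is.na(m), 1, m)
  }
  if (length(cf_orders)) {
    hit <- rows$order %in% cf_orders
    rows$cf[hit] <- rows$cf[hit] * cf
  }
  list(edges = rows, unit_id = unit_id, region = region)
}

# apply the network's dead-space area calibration to freshly built
# conducting rows (geometry tables carry raw, unscaled dimensions)
apply_vd_scale <- function(rows, scale) {
  cond <- rows$kind == "conducting"
  rows$a[cond] <- rows$a[cond] * scale
  rows$d[cond] <- rows$d[cond] * sqrt(scale)
  rows
}

# per-acinus sac-volume weights by acinar order (normalised to sum 1)
sac_weights <- function(params) {
  g <- params$acinar_geometry
  tbo <- params$terminal_bronchiole_order
  g <- g[g$order < tbo, ]
  w <- if (identical(params$sac_profile, "per_length")) {
    2^(tbo - g$order) * g$l
  } else {
    prof <- params$sac_profile[as.character(g$order)]
    if (anyNA(prof))
      stop("configuration error: sac profile missing order(s) ",
           paste(g$order[is.na(prof)], collapse = ", "))
    as.numeric(prof)
  }
  if (abs(sum(w / sum(w)) - 1) > 1e-12)
    stop("configuration error: sac profile weights do not normalise")
  stats::setNames(w / sum(w), g$order)
}

# Populate the unit table from the acinar edge chains: resting volume
# (ducts + alveolar sacs), elastance partitioned so the parallel
# combination equals K_lung, and acinar duct resistance.
finalize_units <- function(net) {
  params <- net$params
  tbo <- params$terminal_bronchiole_order
  edges <- net$edges
  w <- sac_weights(params)
  ac_geom <- params$acinar_geometry
  v_acinar_tot <- params$FRC - params$V_D       # L
  # duct lumen volume of one whole acinus (L)
  idx <- match(as.integer(names(w)), ac_geom$order)
  duct_per_ac <- sum(2^(tbo - ac_geom$order[idx]) *
                       area_of_d(ac_geom$d[idx]) * ac_geom$l[idx]) / CM3_PER_L
  n_ac_total <- sum(2^(params$region_entry_orders - tbo))
  v_per_ac <- v_acinar_tot / n_ac_total
  if (duct_per_ac >= v_per_ac)
    stop("configuration error: acinar duct volume exceeds acinus volume; ",
         "increase FRC or shrink the duct geometry")
  sac_per_ac <- v_per_ac - duct_per_ac
  units <- net$units
  mu <- mu_internal(params)
  ac <- !is.na(edges$unit_id)
  g <- factor(edges$unit_id[ac], levels = units$unit_id)
  sac_e <- sac_per_ac * w[as.character(edges$order[ac])] *
    edges$N_b[ac] / 2^(tbo - edges$order[ac])
  duct_e <- edges$N_b[ac] * edges$a[ac] * edges$l[ac] / CM3_PER_L
  r_e <- poiseuille_resistance(edges$l[ac], edge_area_eff(edges[ac, ]), mu,
                               edges$N_b[ac])
  # acini represented: terminal duct count over ducts per whole acinus
  term <- edges$order[ac] == 0L
  units$n_acini <- as.numeric(rowsum(edges$N_b[ac] * term, g)) / 2^tbo
  units$V_star <- as.numeric(rowsum(duct_e + sac_e, g))
  units$K <- params$K_lung * v_acinar_tot / units$V_star
  units$R_acin <- if (identical(params$acinar_resistance, "poiseuille")) {
    as.numeric(rowsum(r_e, g))
  } else {
    as.numeric(params$acinar_resistance) * v_acinar_tot / units$V_star
  }
  net$units <- units
  net
}

#' Build the seven-region mean-path lung network (model M)
#'
#' Constructs the collapsed airway tree: an asymmetric proximal tree
#' (trachea, main and lobar bronchi) feeding one symmetric mean-path chain
#' per lobar region, each terminating in an acinar duct chain and one lung
#' unit.  Conducting cross-sections are scaled uniformly so the total
#' conducting dead space matches the configured \code{V_D} exactly, and
#' lung-unit resting volumes partition \code{FRC - V_D} equally per acinus.
#'
#' @param params a \code{\link{global_params}} object.
#' @return object of class \code{lung_network} with an edge table
#'   (\code{edge_id}, \code{parent}, \code{region}, \code{order},
#'   \code{kind}, single-airway \code{d}, \code{l}, \code{a}, multiplicity
#'   \code{N_b}, radius constriction factor \code{cf}, \code{unit_id}) and a
#'   lung-unit table (\code{V_star}, elastance \code{K}, \code{R_acin},
#'   \code{n_acini}).
#' @export
build_model_m <- function(params) {
  validate_params(params)
  prox <- params$proximal_tree
  tbo <- params$terminal_bronchiole_order
  edges <- data.frame(
    edge_id = prox$name, parent = prox$parent, region = "proximal",
    order = NA_integer_, kind = "conducting", d = prox$d, l = prox$l,
    a = area_of_d(prox$d), N_b = 1, cf = 1, unit_id = NA_character_,
    stringsAsFactors = FALSE)
  units <- NULL
  for (i in seq_len(nrow(prox))) {
    regs <- strsplit(prox$attach[i], ",")[[1]]
    for (r in regs[nzchar(regs)]) {
      o <- params$region_entry_orders[[r]]
      if (is.null(o)) stop("proximal tree attaches unknown region ", r)
      lin <- region_lineage(r, o, 1, prox$name[i], r, params)
      edges <- rbind(edges, lin$edges)
      units <- rbind(units, data.frame(
        unit_id = lin$unit_id, region = r, n_acini = NA_real_,
        V_star = NA_real_, K = NA_real_, R_acin = NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  miss <- setdiff(names(params$region_entry_orders), units$region)
  if (length(miss))
    stop("configuration error: region(s) not attached to proximal tree: ",
         paste(miss, collapse = ", "))
  # uniform area scaling of the conducting tree to match configured V_D
  cond <- edges$kind == "conducting"
  raw_vd <- sum(edges$N_b[cond] * edges$a[cond] * edges$l[cond]) / CM3_PER_L
  scale <- params$V_D / raw_vd
  edges$a[cond] <- edges$a[cond] * scale
  edges$d[cond] <- edges$d[cond] * sqrt(scale)
  net <- new_lung_network(edges, units, params,
                          meta = list(vd_area_scale = scale))
  net$edges$order <- strahler_order_map(net)
  net <- reorder_network(net)
  net <- finalize_units(net)
  net
}

#' Strahler order of every edge
#'
#' Orders count generations from zero at the periphery: a terminal edge has
#' order 0 and every parent has order one greater than the maximum of its
#' children — for the symmetric collapsed chains this is the subtree height
#' including the acinar duct generations.
#'
#' @param network a \code{lung_network}.
#' @return integer vector named by \code{edge_id}.
#' @export
strahler_order_map <- function(network) {
  edges <- network$edges
  n <- nrow(edges)
  kids <- edge_children(edges)
  ord <- rep(NA_integer_, n)
  n_kids <- lengths(kids)
  queue <- which(n_kids == 0)
  ord[queue] <- 0L
  remaining <- n_kids
  pidx <- match(edges$parent, edges$edge_id)
  done <- 0L
  while (length(queue)) {
    done <- done + length(queue)
    nxt <- integer(0)
    for (i in queue) {
      p <- pidx[i]
      if (!is.na(p)) {
        remaining[p] <- remaining[p] - 1L
        if (remaining[p] == 0L) {
          ord[p] <- 1L + max(ord[kids[[p]]])
          nxt <- c(nxt, p)
        }
      }
    }
    queue <- nxt
  }
  if (done < n || anyNA(ord))
    stop("structural error: cycle detected in airway network")
  stats::setNames(ord, edges$edge_id)
}

#' Constriction scenario specification
#'
#' @param mode \code{"localised"} (all airways of one region in a
#'   generation band) or \code{"distributed"} (a random subset of airways
#'   at the band's top order throughout the lung, plus their descendants).
#' @param depth \code{"proximal"} (Strahler orders 19-16), \code{"central"}
#'   (15-12) or \code{"distal"} (11-8); alternatively supply \code{orders}
#'   directly.
#' @param severity fraction of airway radius removed, in [0, 1).  Fully
#'   occluded airways (severity 1) are rejected.
#' @param region region name (localised mode).
#' @param affected_volume_fraction fraction of acinar volume fed by the
#'   constricted airways (distributed mode).
#' @param seed integer seed for the distributed-mode airway selection.
#' @param orders optional explicit integer vector of Strahler orders.
#' @return a \code{constriction_spec} list.
#' @export
constriction_spec <- function(mode = c("localised", "distributed"),
                              depth = c("central", "proximal", "distal"),
                              severity = 0, region = "RM",
                              affected_volume_fraction = 0.10,
                              seed = 1L, orders = NULL) {
  mode <- match.arg(mode)
  depth <- match.arg(depth)
  if (severity < 0 || severity >= 1)
    stop("severity must lie in [0, 1): fully closed airways are disallowed")
  if (is.null(orders))
    orders <- switch(depth, proximal = 19:16, central = 15:12, distal = 11:8)
  structure(list(mode = mode, depth = depth, severity = severity,
                 region = region,
                 affected_volume_fraction = affected_volume_fraction,
                 seed = as.integer(seed), orders = as.integer(orders)),
            class = "constriction_spec")
}

#' Apply identical constrictions to one region's generation band
#'
#' Every edge of the named region whose Strahler order falls in the band
#' has its radius reduced by the spec's severity (cross-section scaled by
#' \code{(1 - severity)^2}); all other edges are untouched and the network
#' remains a mean-path model.
#'
#' @param network a \code{lung_network}.
#' @param spec a \code{\link{constriction_spec}} with
#'   \code{mode = "localised"}.
#' @return the constricted network.
#' @export
apply_localised_constriction <- function(network, spec) {
  stopifnot(inherits(spec, "constriction_spec"))
  if (spec$mode != "localised") stop("spec mode is not 'localised'")
  hit <- network$edges$region == spec$region &
    network$edges$order %in% spec$orders
  if (!any(hit))
    stop("depth range (orders ", paste(range(spec$orders), collapse = "-"),
         ") absent from region ", spec$region)
  network$edges$cf[hit] <- network$edges$cf[hit] * (1 - spec$severity)
  network$meta$constriction <- spec
  finalize_units(network)
}

#' Apply randomly distributed constrictions
#'
#' Selects a fraction of the individual airways at the top order of the
#' spec's generation band uniformly from the fully expanded tree (by
#' sorting airway identifiers and shuffling with the spec's seed) and
#' constricts each selected airway together with the three generations
#' descended from it.  Every affected region is re-collapsed into the
#' minimal pair of symmetric sub-chains (constricted lineage and untouched
#' lineage), each feeding its own lung unit.
#'
#' @param network a pristine seven-chain \code{lung_network}.
#' @param spec a \code{\link{constriction_spec}} with
#'   \code{mode = "distributed"}.
#' @return the re-collapsed constricted network.
#' @export
apply_distributed_constrictions <- function(network, spec) {
  stopifnot(inherits(spec, "constriction_spec"))
  if (spec$mode != "distributed") stop("spec mode is not 'distributed'")
  params <- network$params
  o_top <- max(spec$orders)
  entry <- params$region_entry_orders
  if (any(entry < o_top))
    stop("top order ", o_top, " above entry order of region(s) ",
         paste(names(entry)[entry < o_top], collapse = ", "))
  n_r <- 2^(entry - o_top)
  N <- sum(n_r)
  k <- round(spec$affected_volume_fraction * N)
  if ((k == 0 && spec$affected_volume_fraction > 0) ||
      abs(k / N - spec$affected_volume_fraction) > 0.5 / N + 1e-12)
    stop("affected fraction ", spec$affected_volume_fraction,
         " unreachable with ", N, " airways at order ", o_top,
         "; achievable fractions are multiples of ", signif(1 / N, 3))
  ids <- unlist(lapply(names(entry), function(r)
    sprintf("%s.%05d", r, seq_len(n_r[[r]]))))
  ids <- sort(ids)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  sel <- if (k > 0) sample(ids, k) else character(0)
  sel_region <- sub("\\..*$", "", sel)
  m_r <- vapply(names(entry), function(r) sum(sel_region == r), numeric(1))

  edges <- network$edges
  units <- network$units
  for (r in names(entry)) {
    if (m_r[[r]] == 0) next
    reg_rows <- edges$region == r
    upper <- edges[reg_rows & edges$order > o_top, ]
    edges <- edges[!reg_rows, ]
    units <- units[units$region != r, ]
    parent_id <- if (nrow(upper)) upper$edge_id[which.min(upper$order)] else
      network$edges$parent[network$edges$region == r &
                             network$edges$order == entry[[r]]]
    lin_con <- region_lineage(r, o_top, m_r[[r]], parent_id,
                              paste0(r, ".con"), params,
                              cf_orders = spec$orders,
                              cf = 1 - spec$severity)
    lin_con$edges <- apply_vd_scale(lin_con$edges,
                                    network$meta$vd_area_scale %||% 1)
    new_units <- data.frame(
      unit_id = lin_con$unit_id, region = r, n_acini = NA_real_,
      V_star = NA_real_, K = NA_real_, R_acin = NA_real_,
      stringsAsFactors = FALSE)
    new_edges <- rbind(upper, lin_con$edges)
    if (m_r[[r]] < n_r[[r]]) {
      lin_cln <- region_lineage(r, o_top, n_r[[r]] - m_r[[r]], parent_id,
                                paste0(r, ".cln"), params)
      lin_cln$edges <- apply_vd_scale(lin_cln$edges,
                                      network$meta$vd_area_scale %||% 1)
      new_edges <- rbind(new_edges, lin_cln$edges)
      new_units <- rbind(new_units, data.frame(
        unit_id = lin_cln$unit_id, region = r, n_acini = NA_real_,
        V_star = NA_real_, K = NA_real_, R_acin = NA_real_,
        stringsAsFactors = FALSE))
    }
    edges <- rbind(edges, new_edges)
    units <- rbind(units, new_units)
  }
  # keep unit order consistent with a depth-first traversal of the tree
  net <- new_lung_network(edges, units, params,
                          meta = c(network$meta,
                                   list(constriction = spec,
                                        selected = sel,
                                        per_region_selected = m_r)))
  net <- reorder_network(net)
  finalize_units(net)
}

# depth-first reordering of edges and units so that the units fed by any
# edge form a contiguous block (required by the transport discretisation)
reorder_network <- function(net) {
  edges <- net$edges
  kids <- edge_children(edges)
  roots <- which(is.na(edges$parent))
  ord <- integer(0)
  stack <- rev(roots)
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, i)
    ch <- kids[[i]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  edges <- edges[ord, ]
  uid <- edges$unit_id[!is.na(edges$unit_id)]
  uid <- uid[!duplicated(uid)]
  units <- net$units[match(uid, net$units$unit_id), ]
  new_lung_network(edges, units, net$params, net$meta)
}

#' Total acinar volume fed by constricted airways
#'
#' @param network a \code{lung_network}.
#' @return volume (L) of lung units whose feeding path contains at least one
#'   constricted edge.
#' @export
constricted_acinar_volume <- function(network) {
  edges <- network$edges
  units <- network$units
  pidx <- match(edges$parent, edges$edge_id)
  affected <- logical(nrow(units))
  for (i in seq_len(nrow(units))) {
    e <- which(!is.na(edges$unit_id) & edges$unit_id == units$unit_id[i])
    e <- e[which.min(edges$order[e])]
    while (!is.na(e)) {
      if (edges$cf[e] < 1) { affected[i] <- TRUE; break }
      e <- pidx[e]
    }
  }
  sum(units$V_star[affected])
}

#' Expand a mean-path region into its explicit binary tree
#'
#' Inverse of the mean-path collapse for one region, down to a given order;
#' used for brute-force validation on small trees.  Each collapsed edge of
#' multiplicity \code{N_b} becomes \code{N_b} identical edges.
#'
#' @param network a \code{lung_network}.
#' @param region region name.
#' @param down_to lowest Strahler order to expand (inclusive).
#' @return data.frame of individual airways with parent links.
#' @export
expand_region <- function(network, region, down_to = 0L) {
  ed <- network$edges[network$edges$region == region &
                        network$edges$order >= down_to, ]
  ed <- ed[order(-ed$order), ]
  if (any(diff(ed$N_b) / ed$N_b[-nrow(ed)] != 1))
    stop("expand_region requires a single chain region")
  out <- NULL
  prev_ids <- ed$parent[1]
  for (i in seq_len(nrow(ed))) {
    n <- ed$N_b[i]
    ids <- sprintf("%s.x%02d.%05d", region, ed$order[i], seq_len(n))
    parents <- if (i == 1) rep(prev_ids, n) else
      prev_ids[ceiling(seq_len(n) / 2)]
    out <- rbind(out, data.frame(
      edge_id = ids, parent = parents, order = ed$order[i], d = ed$d[i],
      l = ed$l[i], a = ed$a[i], cf = ed$cf[i], kind = ed$kind[i],
      stringsAsFactors = FALSE))
    prev_ids <- ids
  }
  out
}

#' Collapse an explicit binary tree back to mean-path chains
#'
#' Merges exactly-identical sibling subtrees recursively; the round trip
#' \code{expand_region} then \code{collapse_expanded} reproduces the
#' per-order multiplicities and geometry of the original chain.
#'
#' @param expanded data.frame from \code{\link{expand_region}}.
#' @return data.frame with columns \code{order}, \code{d}, \code{l},
#'   \code{a}, \code{cf}, \code{N_b}, one row per merged generation class.
#' @export
collapse_expanded <- function(expanded) {
  sig <- function(i, kids) {
    ch <- kids[[i]]
    own <- paste(expanded$order[i], expanded$d[i], expanded$l[i],
                 expanded$a[i], expanded$cf[i], sep = "|")
    if (!length(ch)) return(own)
    paste(own, paste(sort(vapply(ch, sig, "", kids = kids)),
                     collapse = ","), sep = ">")
  }
  kids <- split(seq_len(nrow(expanded)),
                factor(expanded$parent, levels = expanded$edge_id))
  sigs <- vapply(seq_len(nrow(expanded)), sig, "", kids = kids)
  agg <- stats::aggregate(list(N_b = rep(1, nrow(expanded))),
                          by = list(order = expanded$order, d = expanded$d,
                                    l = expanded$l, a = expanded$a,
                                    cf = expanded$cf, sig = sigs),
                          FUN = sum)
  # distinct subtree signatures at the same order become distinct chains
  agg[order(-agg$order), setdiff(names(agg), "sig")]
}

#' @export
print.lung_network <- function(x, ...) {
  cat(sprintf("lung_network: %d edges, %d lung units, %d region(s)\n",
              nrow(x$edges), nrow(x$units),
              length(unique(x$units$region))))
  vd <- conducting_dead_space(x)
  cat(sprintf("  conducting dead space %.4g L | acinar volume %.4g L\n",
              vd, sum(x$units$V_star)))
  ncon <- sum(x$edges$cf < 1)
  if (ncon) cat(sprintf("  %d constricted edge class(es)\n", ncon))
  invisible(x)
}

#' Conducting dead-space volume of a network
#' @param network a \code{lung_network}.
#' @return volume in L (using effective, possibly constricted, lumen).
#' @export
conducting_dead_space <- function(network) {
  ed <- network$edges[network$edges$kind == "conducting", ]
  sum(ed$N_b * edge_area_eff(ed) * ed$l) / CM3_PER_L
}

#' Serialise a network to JSON
#' @param network a \code{lung_network}.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return the JSON string (invisibly when written to file).
#' @export
network_to_json <- function(network, path = NULL) {
  params <- unclass(network$params)
  params$region_entry_orders <- as.list(params$region_entry_orders)
  doc <- list(edges = network$edges, units = network$units,
              meta = network$meta, params = params)
  js <- jsonlite::toJSON(doc, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         force = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a network back from JSON
#' @param path file path or JSON string produced by
#'   \code{\link{network_to_json}}.
#' @return a \code{lung_network}.
#' @export
network_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  params <- doc$params
  params$region_entry_orders <- unlist(params$region_entry_orders)
  for (k in c("conducting_geometry", "acinar_geometry", "proximal_tree"))
    params[[k]] <- as.data.frame(params[[k]])
  class(params) <- "ventnet_params"
  new_lung_network(as.data.frame(doc$edges), as.data.frame(doc$units),
                   params, doc$meta)
}
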
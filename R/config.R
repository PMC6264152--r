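# Global configuration: physiological parameters, per-order airway geometry,
# gas properties and numerical controls.  Units are fixed internally:
# lengths cm, areas cm^2, volumes L, pressures cmH2O, times s.  Viscosity is
# supplied in Pa.s at the boundary and converted to cmH2O.s internally.

PA_PER_CMH2O <- 98.0665
CM3_PER_L <- 1000

#' Default per-order conducting airway geometry
#'
#' Single-airway diameter and length (cm) for the within-region conducting
#' generations, indexed by Strahler order (order 9 = terminal bronchiole).
#' Values follow standard adult morphometry (Weibel-type regularised
#' dimensions mapped onto the Strahler ordering of a bifurcating tree).
#'
#' @return data.frame with columns \code{order}, \code{d}, \code{l}.
#' @export
default_conducting_geometry <- function() {
  data.frame(
    order = 22:9,
    d = c(0.560, 0.450, 0.350, 0.280, 0.230, 0.186, 0.154, 0.130,
          0.109, 0.095, 0.082, 0.074, 0.066, 0.060),
    l = c(0.760, 1.270, 1.070, 0.900, 0.760, 0.640, 0.540, 0.460,
          0.390, 0.330, 0.270, 0.230, 0.200, 0.165)
  )
}

#' Default acinar duct geometry
#'
#' Single-duct lumen diameter and length (cm) for the acinar generations
#' (Strahler orders 8 down to 0).  Lumen excludes the alveolar sleeve, whose
#' volume is carried by the outer cross-section of the trumpet model.
#'
#' @return data.frame with columns \code{order}, \code{d}, \code{l}.
#' @export
default_acinar_geometry <- function() {
  data.frame(
    order = 8:0,
    d = c(0.0310, 0.0290, 0.0280, 0.0260, 0.0255, 0.0250, 0.0250, 0.0250,
          0.0250),
    l = c(0.140, 0.117, 0.098, 0.083, 0.070, 0.060, 0.052, 0.046, 0.042)
  )
}

#' Default proximal (extra-regional) airway geometry
#'
#' The asymmetric proximal tree linking the trachea to the seven lobar
#' region entry airways.  \code{parent = NA} marks the trachea; the
#' \code{attach} column names the region whose chain hangs off each edge
#' (comma-separated when two regions share a lobar bronchus).
#'
#' @return data.frame describing the proximal tree.
#' @export
default_proximal_tree <- function() {
  data.frame(
    name   = c("trachea", "R_main", "L_main", "bronc_int", "RL_bronc",
               "LL_bronc"),
    parent = c(NA, "trachea", "trachea", "R_main", "bronc_int", "L_main"),
    d      = c(1.80, 1.22, 1.22, 0.83, 0.83, 0.83),
    l      = c(12.0, 4.76, 4.76, 1.90, 1.90, 1.90),
    attach = c("", "RU", "LU", "RM", "RL_min,RL_maj", "LL_min,LL_maj"),
    stringsAsFactors = FALSE
  )
}

#' Build a global parameter set
#'
#' Assembles the full configuration for a simulation: ventilation parameters,
#' airway geometry tables, gas table and numerical controls.  Defaults
#' represent a healthy adult male breathing regularly at rest.  The region
#' entry orders give a conducting tree with 40960 terminal bronchioles
#' (Strahler order 9), of which the right-middle lobe feeds exactly 10% of
#' the acini; acinar ducts occupy orders 8 down to 0.
#'
#' @param V_T tidal volume (L).
#' @param FRC functional residual capacity, total lung gas volume at
#'   end-tidal exhalation including airway dead space (L).
#' @param V_D conducting-airway (anatomical) dead-space volume (L).  The
#'   conducting cross-sections in the geometry table are scaled uniformly so
#'   the network dead space matches this value exactly.
#' @param K_lung total lung elastance (cmH2O/L); partitioned across lung
#'   units in inverse proportion to their resting volumes so that the
#'   parallel combination equals \code{K_lung}.
#' @param tau breath period (s).
#' @param mu air dynamic viscosity (Pa.s).
#' @param phi acinar diffusion fraction: the fraction of the alveolar-sac
#'   cross-section taking part in axial diffusion (dimensionless, 0-1).
#' @param region_entry_orders named integer vector: Strahler order of each
#'   lobar region's entry airway.
#' @param terminal_bronchiole_order first conducting order; orders below it
#'   are acinar ducts.
#' @param conducting_geometry,acinar_geometry,proximal_tree geometry tables,
#'   see the corresponding \code{default_*} functions.
#' @param sac_profile how alveolar-sac volume is apportioned across acinar
#'   duct orders: \code{"per_length"} (proportional to total duct length per
#'   order, the default) or a numeric vector of weights named by order.
#' @param acinar_resistance \code{"poiseuille"} to compute per-unit acinar
#'   resistance from the duct geometry, or a numeric total acinar resistance
#'   (cmH2O.s/L, partitioned like the elastance).
#' @param gases gas property table: molecular diffusivity \code{D0}
#'   (cm^2/s) per tracer gas.
#' @param numerics list of numerical controls: \code{steps_per_cycle},
#'   \code{cells_per_edge}, \code{max_breaths}, \code{stop_frac} (end-tidal
#'   stopping concentration), \code{extra_breaths} (margin beyond the
#'   stopping criterion), \code{periodicity_tol} (L).
#' @param mbw list of index-computation conventions: \code{phase3_window}
#'   (fraction of expired volume), \code{scond_to_range} (turnover range of
#'   the S_cond fit).
#' @param seed integer seed for stochastic scenario generators.
#' @return object of class \code{ventnet_params}.
#' @export
global_params <- function(V_T = 1.0,
                          FRC = 3.0,
                          V_D = 0.15,
                          K_lung = 5.0,
                          tau = 5.0,
                          mu = 1.92e-5,
                          phi = 0.4,
                          region_entry_orders = c(
                            RU = 22L, RM = 21L, RL_min = 21L, RL_maj = 22L,
                            LU = 22L, LL_min = 21L, LL_maj = 21L),
                          terminal_bronchiole_order = 9L,
                          conducting_geometry = default_conducting_geometry(),
                          acinar_geometry = default_acinar_geometry(),
                          proximal_tree = default_proximal_tree(),
                          sac_profile = "per_length",
                          acinar_resistance = "poiseuille",
                          gases = list(SF6 = list(D0 = 0.105),
                                       N2  = list(D0 = 0.225)),
                          numerics = list(),
                          mbw = list(),
                          seed = 1L) {
  num_default <- list(steps_per_cycle = 2000L, cells_per_edge = 10L,
                      max_breaths = 120L, stop_frac = 0.025,
                      extra_breaths = 3L, periodicity_tol = 1e-6)
  mbw_default <- list(phase3_window = c(0.65, 0.95),
                      scond_to_range = c(1.5, 6.0))
  p <- list(V_T = V_T, FRC = FRC, V_D = V_D, K_lung = K_lung, tau = tau,
            mu = mu, phi = phi,
            region_entry_orders = region_entry_orders,
            terminal_bronchiole_order = as.integer(terminal_bronchiole_order),
            conducting_geometry = conducting_geometry,
            acinar_geometry = acinar_geometry,
            proximal_tree = proximal_tree,
            sac_profile = sac_profile,
            acinar_resistance = acinar_resistance,
            gases = gases,
            numerics = modifyList(num_default, numerics),
            mbw = modifyList(mbw_default, mbw),
            seed = as.integer(seed))
  class(p) <- "ventnet_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks completeness, positivity, geometry-table coverage of the
#' configured order ranges, and uniqueness of gas names.  Errors name the
#' offending keys.
#'
#' @param p a \code{ventnet_params} object (or plain list with the same
#'   fields).
#' @return \code{p}, invisibly, on success.
#' @export
validate_params <- function(p) {
  required <- c("V_T", "FRC", "V_D", "K_lung", "tau", "mu", "phi")
  missing <- required[!vapply(required, function(k)
    !is.null(p[[k]]) && is.finite(p[[k]]), logical(1))]
  if (length(missing))
    stop("configuration error: missing or non-finite parameter(s): ",
         paste(missing, collapse = ", "))
  pos <- c("V_T", "FRC", "V_D", "K_lung", "tau", "mu")
  bad <- pos[vapply(pos, function(k) p[[k]] <= 0, logical(1))]
  if (length(bad))
    stop("configuration error: non-positive parameter(s): ",
         paste(bad, collapse = ", "))
  if (p$phi < 0 || p$phi > 1)
    stop("configuration error: phi must lie in [0, 1]")
  if (p$FRC <= p$V_D)
    stop("configuration error: FRC must exceed V_D")
  if (anyDuplicated(names(p$gases)))
    stop("configuration error: gas names must be unique")
  for (g in names(p$gases))
    if (is.null(p$gases[[g]]$D0) || p$gases[[g]]$D0 <= 0)
      stop("configuration error: gas ", g, " lacks a positive D0")
  tbo <- p$terminal_bronchiole_order
  need_cond <- seq(max(p$region_entry_orders), tbo)
  miss_o <- setdiff(need_cond, p$conducting_geometry$order)
  if (length(miss_o))
    stop("configuration error: conducting geometry missing order(s) ",
         paste(miss_o, collapse = ", "))
  need_ac <- seq(tbo - 1L, 0L)
  miss_a <- setdiff(need_ac, p$acinar_geometry$order)
  if (length(miss_a))
    stop("configuration error: acinar geometry missing order(s) ",
         paste(miss_a, collapse = ", "))
  invisible(p)
}

#' @export
print.ventnet_params <- function(x, ...) {
  cat("ventnet global parameters\n")
  cat(sprintf("  V_T %.3g L | FRC %.3g L | V_D %.3g L | K_lung %.3g cmH2O/L\n",
              x$V_T, x$FRC, x$V_D, x$K_lung))
  cat(sprintf("  tau %.3g s | mu %.3g Pa.s | phi %.2f\n", x$tau, x$mu, x$phi))
  cat("  gases:", paste(sprintf("%s (D0=%.3g)", names(x$gases),
                                vapply(x$gases, `[[`, 0, "D0")),
                        collapse = ", "), "\n")
  cat("  regions:", paste(sprintf("%s(%d)", names(x$region_entry_orders),
                                  x$region_entry_orders), collapse = " "),
      "\n")
  invisible(x)
}

#' Gas properties lookup
#' @param params a \code{ventnet_params} object.
#' @param gas gas name, e.g. \code{"SF6"}.
#' @return list with molecular diffusivity \code{D0}, dispersion constants
#'   \code{C_insp}/\code{C_exp}, and the acinar diffusion fraction
#'   \code{phi}.
#' @export
gas_spec <- function(params, gas = "SF6") {
  if (!gas %in% names(params$gases))
    stop("unknown gas: ", gas)
  g <- params$gases[[gas]]
  list(name = gas, D0 = g$D0,
       C_insp = g$C_insp %||% 1.08, C_exp = g$C_exp %||% 0.37,
       phi = g$phi %||% params$phi)
}

# viscosity in internal pressure units
mu_internal <- function(params) params$mu / PA_PER_CMH2O

#' Load a configuration from a YAML file
#'
#' Scalar fields override the defaults of \code{\link{global_params}};
#' geometry tables may be given as lists of columns.  The loaded object
#' passes \code{\link{validate_params}} and carries a content hash for
#' provenance (also attached to downstream result objects).
#'
#' @param path path to a YAML configuration file.
#' @return a \code{ventnet_params} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  args <- list()
  scalars <- c("V_T", "FRC", "V_D", "K_lung", "tau", "mu", "phi", "seed",
               "terminal_bronchiole_order", "sac_profile",
               "acinar_resistance")
  for (k in intersect(scalars, names(raw))) args[[k]] <- raw[[k]]
  if (!is.null(raw$region_entry_orders))
    args$region_entry_orders <- unlist(raw$region_entry_orders)
  yaml_df <- function(cols) {
    cols <- lapply(cols, function(col) {
      if (is.list(col))
        col <- unlist(lapply(col, function(x) if (is.null(x)) NA else x))
      col
    })
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  for (k in c("conducting_geometry", "acinar_geometry", "proximal_tree"))
    if (!is.null(raw[[k]]))
      args[[k]] <- yaml_df(raw[[k]])
  if (!is.null(raw$gases)) args$gases <- raw$gases
  for (k in c("numerics", "mbw"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  p <- do.call(global_params, args)
  attr(p, "hash") <- config_hash(p)
  attr(p, "source") <- normalizePath(path)
  p
}

#' Save a configuration to YAML
#' @param params a \code{ventnet_params} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(params, path) {
  out <- unclass(params)
  for (k in c("conducting_geometry", "acinar_geometry", "proximal_tree"))
    out[[k]] <- as.list(out[[k]])
  out$region_entry_orders <- as.list(out$region_entry_orders)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Content hash of a configuration
#'
#' MD5 of the canonical JSON rendering of the resolved parameter set; used
#' to stamp outputs so that any result can be traced to the exact
#' configuration that produced it.
#'
#' @param params a \code{ventnet_params} object.
#' @return character scalar (32 hex digits).
#' @export
config_hash <- function(params) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(params), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}
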
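# Orchestration: named experiments binding the modules into reproducible
# runs.  Every artifact embeds the resolved configuration hash so results
# can be traced to the exact parameter set that produced them.

#' Run a named experiment
#'
#' Composes the package modules into the standard analyses.  Outputs are
#' deterministic functions of the configuration and its seed; artifact
#' files (CSV/JSON) are written when \code{out_dir} is given, and the
#' results are returned invisibly either way.
#'
#' \describe{
#'   \item{baseline}{healthy washout for each configured gas; indices JSON.}
#'   \item{constriction-sweep}{localised-constriction severity sweep at the
#'     requested depths; one CSV row per (depth, severity).}
#'   \item{variance-sweep}{model-P standard deviations of LCI and S_cond
#'     across constriction severities for independent and structurally
#'     correlated heterogeneity.}
#'   \item{fv-density}{fractional ventilation mixture density at a given
#'     constriction severity.}
#'   \item{validate}{two-compartment analytic cross-check and a small
#'     Monte-Carlo comparison.}
#' }
#'
#' @param name experiment name, see Details.
#' @param params a \code{\link{global_params}} configuration.
#' @param out_dir optional output directory for artifact files.
#' @param ... experiment-specific options: \code{severities},
#'   \code{depths}, \code{region}, \code{gas}, \code{cov_models},
#'   \code{orders}, \code{numerics}, \code{mc_spec}.
#' @return experiment results, invisibly.
#' @export
run_experiment <- function(name = c("baseline", "constriction-sweep",
                                    "variance-sweep", "fv-density",
                                    "validate"),
                           params = global_params(), out_dir = NULL, ...) {
  name <- match.arg(name)
  opts <- list(...)
  t0 <- Sys.time()
  net <- build_model_m(params)
  prov <- list(config_hash = config_hash(params), seed = params$seed)
  res <- switch(
    name,
    "baseline" = {
      out <- list()
      for (g in names(params$gases)) {
        idx <- mbw_indices(run_washout(net, g,
                                       opts$numerics %||% list()))
        out[[g]] <- list(LCI = idx$LCI, Scond = idx$Scond,
                         FRC_approx = idx$FRC_approx,
                         FV = as.list(idx$FV))
      }
      c(out, provenance = list(prov))
    },
    "constriction-sweep" = {
      sw <- constriction_sweep(
        net, severities = opts$severities %||% seq(0, 0.95, by = 0.05),
        depths = opts$depths %||% c("proximal", "central", "distal"),
        region = opts$region %||% "RM", gas = opts$gas %||% "SF6",
        numerics = opts$numerics %||% list())
      attr(sw, "provenance") <- prov
      sw
    },
    "variance-sweep" = {
      severities <- opts$severities %||% c(0, 0.7, 0.8, 0.9)
      depth <- opts$depth %||% "central"
      cms <- opts$cov_models %||% list(
        independent = covariance_model("independent", 0.2, 0.1),
        corr0 = covariance_model("correlated", 0.2, 0.1, 0),
        corr1 = covariance_model("correlated", 0.2, 0.1, 1))
      out <- NULL
      for (sev in severities) {
        bnet <- if (sev > 0) apply_localised_constriction(
          net, constriction_spec("localised", depth, sev,
                                 opts$region %||% "RM")) else net
        bl <- model_m_baseline(bnet, opts$gas %||% "SF6",
                               opts$numerics %||% list())
        tg <- sensitivity_targets(bnet, regions = opts$regions,
                                  orders = opts$orders)
        sens <- sensitivity_matrix(bl, tg)
        for (cm in names(cms)) {
          v <- output_variance(sens, cms[[cm]], bnet)
          out <- rbind(out, cbind(severity = sev, model = cm, v))
        }
      }
      attr(out, "provenance") <- prov
      out
    },
    "fv-density" = {
      sev <- opts$severity %||% 0.815
      bnet <- if (sev > 0) apply_localised_constriction(
        net, constriction_spec("localised", opts$depth %||% "central",
                               sev, opts$region %||% "RM")) else net
      bl <- model_m_baseline(bnet, opts$gas %||% "SF6",
                             opts$numerics %||% list())
      sens <- sensitivity_matrix(
        bl, sensitivity_targets(bnet, regions = opts$regions,
                                orders = opts$orders))
      d <- fv_density(bl, sens,
                      opts$cov_model %||% covariance_model("independent",
                                                           0.2, 0.1))
      attr(d, "provenance") <- prov
      d
    },
    "validate" = {
      tc_net <- two_unit_test_network(params)
      tc <- two_compartment_washout(two_compartment_from_network(tc_net))
      mc <- monte_carlo_variance(
        net, opts$mc_spec %||% monte_carlo_spec(
          sigma_a = 0.1, sigma_l = 0.1, deepest_order = 19L,
          n_realisations = 50L, seed = params$seed),
        numerics = opts$numerics %||% list(steps_per_cycle = 300L,
                                           cells_per_edge = 3L))
      list(two_compartment = tc[c("LCI", "FRC_approx")],
           monte_carlo = mc[c("mean", "sd", "sd_ci", "n_failed")],
           provenance = prov)
    })
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  message(sprintf("experiment '%s' finished in %.1f s", name, elapsed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, paste0(gsub("-", "_", name),
                                      if (is.data.frame(res)) ".csv"
                                      else ".json"))
    if (is.data.frame(res))
      utils::write.csv(res, path, row.names = FALSE)
    else
      jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    message("wrote ", path)
  }
  invisible(res)
}

#' Two-unit reduction of the configuration
#'
#' Builds a network with a single shared airway feeding two symmetric
#' regions; used by the validation experiment to cross-check the numerical
#' pipeline against the analytic two-compartment model.
#'
#' @param params a \code{\link{global_params}}; its region table is
#'   replaced by two equal regions.
#' @param entry_order region entry Strahler order.
#' @param constrict optional severity applied to one region's central band
#'   to make the compartments asymmetric.
#' @return a two-unit \code{lung_network}.
#' @export
two_unit_test_network <- function(params, entry_order = 21L,
                                  constrict = 0) {
  p2 <- params
  p2$region_entry_orders <- c(C1 = entry_order, C2 = entry_order)
  p2$proximal_tree <- data.frame(
    name = "trachea", parent = NA_character_, d = 1.8, l = 12.0,
    attach = "C1,C2", stringsAsFactors = FALSE)
  class(p2) <- "ventnet_params"
  net <- build_model_m(p2)
  if (constrict > 0)
    net <- apply_localised_constriction(
      net, constriction_spec("localised", "central", constrict, "C1"))
  net
}
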
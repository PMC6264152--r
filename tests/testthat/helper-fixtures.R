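# Shared fixtures.  Networks and washouts are built in code and memoised
# for the duration of the test run; the "toy" configuration is a small
# two-region lung that keeps brute-force enumeration cheap.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

num_coarse <- list(steps_per_cycle = 300L, cells_per_edge = 3L)
num_mid <- list(steps_per_cycle = 600L, cells_per_edge = 4L)

default_params <- function() memo("default_params", global_params())

default_net <- function() memo("default_net",
                               build_model_m(default_params()))

# A miniature 24-acinus lung: per-acinus tidal load, airway dimensions and
# elastance match the full-scale model, so the breathing dynamics are
# physiological while brute-force enumeration stays cheap.
toy_params <- function() memo("toy_params", global_params(
  V_T = 6e-4, FRC = 1.75e-3, V_D = 8e-5, K_lung = 8500, tau = 4,
  region_entry_orders = c(A = 13L, B = 12L),
  proximal_tree = data.frame(
    name = c("trachea", "brA", "brB"),
    parent = c(NA, "trachea", "trachea"),
    d = c(0.20, 0.15, 0.15), l = c(1.0, 0.5, 0.5),
    attach = c("", "A", "B"), stringsAsFactors = FALSE),
  numerics = list(steps_per_cycle = 400L, cells_per_edge = 4L)))

toy_net <- function() memo("toy_net", build_model_m(toy_params()))

toy_trace <- function() memo("toy_trace", run_washout(toy_net(), "SF6"))

# a gas that makes the acinus well mixed each breath without Taylor
# dispersion: the regime in which compartment bookkeeping oracles apply
mix_params <- function() memo("mix_params", global_params(
  gases = list(SF6 = list(D0 = 0.105),
               MIX = list(D0 = 0.15, phi = 1, C_insp = 0, C_exp = 0))))

healthy_baseline_coarse <- function() memo(
  "healthy_baseline_coarse",
  model_m_baseline(default_net(), "SF6", num_coarse))
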
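test_that("Poiseuille resistance follows the r^-4 law and parallel rule", {
  mu <- 1.9e-7
  r <- 0.12; l <- 1.7
  a <- pi * r^2
  # independent hand evaluation of 8 mu l / (pi r^4), per litre
  expect_equal(poiseuille_resistance(l, a, mu),
               8 * mu * l / (pi * r^4) * 1000, tolerance = 1e-12)
  expect_equal(poiseuille_resistance(l, pi * (r / 2)^2, mu) /
                 poiseuille_resistance(l, a, mu), 16, tolerance = 1e-12)
  expect_equal(poiseuille_resistance(l, a, mu, N_b = 2),
               poiseuille_resistance(l, a, mu) / 2, tolerance = 1e-12)
  expect_error(poiseuille_resistance(-1, a, mu), "non-positive")
})

test_that("mean-path edge resistance equals brute-force parallel summation", {
  net <- toy_net()
  mu <- ventnet:::mu_internal(net$params)
  # expanded subtree of region B, orders 12..7: recursive series/parallel
  ex <- expand_region(net, "B", down_to = 7L)
  kids <- split(seq_len(nrow(ex)), factor(ex$parent, levels = ex$edge_id))
  subtree_res <- function(i) {
    r <- poiseuille_resistance(ex$l[i], ex$a[i] * ex$cf[i]^2, mu)
    ch <- kids[[i]]
    if (length(ch)) r <- r + 1 / sum(1 / vapply(ch, subtree_res, 0))
    r
  }
  brute <- subtree_res(which(ex$order == 12))
  chain <- net$edges[net$edges$region == "B" & net$edges$order >= 7, ]
  mean_path <- sum(poiseuille_resistance(
    chain$l, chain$a * chain$cf^2, mu, chain$N_b))
  expect_equal(mean_path, brute, tolerance = 1e-12)
})

test_that("resistance matrix entries are shared-path sums", {
  net <- toy_net()
  R <- assemble_resistance_matrix(net)
  expect_true(isSymmetric(R))
  expect_true(all(eigen(R, only.values = TRUE)$values > -1e-12))
  mu <- ventnet:::mu_internal(net$params)
  # independent path-walk oracle
  edges <- net$edges
  pidx <- match(edges$parent, edges$edge_id)
  path_of <- function(uid) {
    i <- which(!is.na(edges$unit_id) & edges$unit_id == uid)
    i <- i[which.min(edges$order[i])]
    path <- integer(0)
    while (!is.na(i)) { path <- c(path, i); i <- pidx[i] }
    path
  }
  r_e <- ifelse(edges$kind == "conducting",
                poiseuille_resistance(edges$l, edges$a * edges$cf^2, mu,
                                      edges$N_b), 0)
  for (ai in 1:2) for (bi in 1:2) {
    shared <- intersect(path_of(net$units$unit_id[ai]),
                        path_of(net$units$unit_id[bi]))
    expect_equal(R[ai, bi], sum(r_e[shared]), tolerance = 1e-12)
  }
  # two units sharing only the trachea: off-diagonal = tracheal resistance
  it <- which(edges$edge_id == "trachea")
  expect_equal(R[1, 2], r_e[it], tolerance = 1e-12)
})

test_that("waveform calibration matches the scalar closed form", {
  p <- toy_params()
  om <- 2 * pi / p$tau
  Kc <- 8; Rc <- 1.5; V_T <- 0.5
  sys <- list(R = matrix(Rc, 1, 1), K = Kc, V_star = 1,
              params = list(tau = p$tau,
                            numerics = list(steps_per_cycle = 5000L,
                                            periodicity_tol = 1e-6)))
  wf <- calibrate_waveform(sys, V_T = V_T, n_steps = 5000L)
  # pleural drive (A/2)(1 - cos): oscillation peak-to-peak A/sqrt(K^2+(wR)^2)
  expect_equal(wf$amplitude, V_T * sqrt(Kc^2 + (om * Rc)^2),
               tolerance = 1e-4)
  expect_equal(wf$tidal, V_T, tolerance = 1e-6)
  # elastic limit: R -> 0 gives amplitude K V_T
  sys$R <- matrix(1e-12, 1, 1)
  wf0 <- calibrate_waveform(sys, V_T = V_T, n_steps = 5000L)
  expect_equal(wf0$amplitude, Kc * V_T, tolerance = 1e-6)
})

test_that("stepping reproduces the closed-form periodic solution", {
  net <- toy_net()
  cn <- apply_localised_constriction(
    net, constriction_spec("localised", severity = 0.7, region = "B",
                           orders = 11:10))
  sys <- build_mechanics(cn)
  wf <- calibrate_waveform(sys, n_steps = 2000L)
  sol <- solve_ventilation(sys, wf, n_cycles = 2)
  expect_lt(sol$periodicity_error, 1e-9)
  cont <- ventnet:::continuous_cycle(sys, wf$amplitude,
                                     seq(0, sys$params$tau,
                                         length.out = 2001))
  expect_lt(max(abs(sol$V[1:2001, ] - cont)), 1e-6)
  # mouth flow is the sum of unit flows
  expect_equal(sol$mouth_flow, rowSums(sol$Vdot), tolerance = 1e-12)
})

test_that("linearity, energy and flow conservation hold", {
  net <- toy_net()
  sys <- build_mechanics(net)
  wf <- calibrate_waveform(sys, n_steps = 500L)
  V1 <- ventnet:::discrete_cycle(sys, wf$amplitude, 500L)
  V2 <- ventnet:::discrete_cycle(sys, 2 * wf$amplitude, 500L)
  osc1 <- sweep(V1, 2, colMeans(V1))
  osc2 <- sweep(V2, 2, colMeans(V2))
  expect_equal(osc2, 2 * osc1, tolerance = 1e-9)
  # mean power input over a steady cycle is non-negative
  dt <- sys$params$tau / 500
  drive <- (wf$amplitude / 2) *
    (1 - cos(2 * pi * seq(0, 499) / 500 + pi / 500))
  power <- mean(drive * rowSums(diff(V1) / dt))
  expect_gte(power, 0)
  # vertex flow balance at machine precision
  fl <- edge_flows(net, diff(V1) / dt)
  edges <- net$edges
  for (eid in c("trachea", "brA", "A.o13")) {
    ch <- edges$edge_id[!is.na(edges$parent) & edges$parent == eid]
    if (!length(ch)) next
    expect_equal(fl[, eid], rowSums(fl[, ch, drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("unequal unit time constants produce pendelluft flow reversal", {
  net <- toy_net()
  cn <- apply_localised_constriction(
    net, constriction_spec("localised", severity = 0.93, region = "B",
                           orders = 12:12))
  sys <- build_mechanics(cn)
  wf <- calibrate_waveform(sys, n_steps = 1000L)
  sol <- solve_ventilation(sys, wf, n_cycles = 2)
  fl <- edge_flows(cn, sol$Vdot[1:1000, ])
  mouth <- sol$mouth_flow[1:1000]
  reg_b <- fl[, "B.o12"]
  # during part of the cycle the constricted region moves gas against the
  # mouth flow direction
  expect_true(any(sign(reg_b) * sign(mouth) < 0 & abs(mouth) > 1e-6))
})

test_that("a near-blocked unit loses its tidal excursion", {
  net <- toy_net()
  cn <- apply_localised_constriction(
    net, constriction_spec("localised", severity = 0.97, region = "B",
                           orders = 12:10))
  sys <- build_mechanics(cn)
  wf <- calibrate_waveform(sys, n_steps = 500L)
  V <- wf$cycleV
  exc <- apply(V, 2, function(x) diff(range(x)))
  iB <- which(cn$units$region == "B")
  expect_lt(exc[iB] / sum(exc), 0.02)
})
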
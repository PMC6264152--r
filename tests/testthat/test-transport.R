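test_that("Taylor dispersion switches constants with breathing phase", {
  g <- gas_spec(default_params(), "SF6")
  expect_equal(taylor_dispersion(g, 0, 1, "insp"), g$D0)
  expect_equal(taylor_dispersion(g, 2, 0.5, "insp"), g$D0 + 1.08)
  expect_equal(taylor_dispersion(g, -2, 0.5, "exp"), g$D0 + 0.37)
  expect_error(taylor_dispersion(g, 1, -1), "diameter")
})

test_that("acinar diffusivity grows with the sac cross-section", {
  p <- default_params()
  g <- gas_spec(p, "SF6")
  expect_equal(acinar_diffusivity(g, 2, 2), g$D0)
  g0 <- g; g0$phi <- 0
  expect_equal(acinar_diffusivity(g0, 7, 2), g$D0)
  g1 <- g; g1$phi <- 1
  expect_equal(acinar_diffusivity(g1, 4, 2), 2 * g$D0)
  expect_error(acinar_diffusivity(g, 1, 2), "negative")
})

test_that("mouth boundary closures follow the breathing phase", {
  expect_equal(mouth_boundary("inhalation"),
               list(type = "dirichlet", value = 0))
  expect_equal(mouth_boundary("exhalation"),
               list(type = "zero_diffusive_flux"))
})

test_that("sac volume distribution integrates exactly and scales affinely", {
  net <- toy_net()
  disc <- discretise(net)
  d <- disc$disc
  V_lo <- net$units$V_star
  V_hi <- net$units$V_star * 1.2
  for (V in list(V_lo, V_hi)) {
    S <- distribute_sac_volume(disc, V)
    expect_true(all(S >= d$s - 1e-12))
    sac_cells <- (S - d$s) * d$dx
    for (u in seq_len(disc$n_units)) {
      got <- sum(sac_cells[d$unit == u])
      expect_equal(got, V[u] * 1000 - d$Vduct[u], tolerance = 1e-12)
    }
  }
  # affine in the unit volume, inner cross-section fixed
  S1 <- distribute_sac_volume(disc, V_lo)
  S2 <- distribute_sac_volume(disc, V_hi)
  S3 <- distribute_sac_volume(disc, (V_lo + V_hi) / 2)
  expect_equal(S3, (S1 + S2) / 2, tolerance = 1e-12)
  # per-length profile: edge sac shares proportional to N_b * l
  ed <- disc$edges
  ac <- which(ed$kind == "acinar_duct" &
                ed$unit_id == net$units$unit_id[1])
  share <- vapply(ac, function(e) {
    cells <- which(disc$cell_edge == e)
    sum((S1 - d$s)[cells] * d$dx[cells])
  }, numeric(1))
  expect_equal(share / sum(share),
               ed$N_b[ac] * ed$l[ac] / sum(ed$N_b[ac] * ed$l[ac]),
               tolerance = 1e-9)
  expect_error(distribute_sac_volume(disc, V_lo * 1e-4), "negative")
})

test_that("a uniform field is an exact solution with a closed mouth", {
  net <- toy_net()
  disc <- discretise(net)
  gas <- gas_spec(net$params, "SF6")
  sys <- build_mechanics(net)
  wf <- calibrate_waveform(sys, n_steps = 200L)
  dt <- net$params$tau / 200
  res <- advance_concentration(disc, gas, rep(1, disc$n_cells),
                               wf$cycleV, dt, mouth = "closed")
  expect_equal(res$c, rep(1, disc$n_cells), tolerance = 1e-12)
  expect_equal(res$net_out, sum(rowSums(wf$cycleV[c(1, 201), ]) *
                                  c(-1, 1)) * 1000, tolerance = 1e-6)
  # stagnant gas with no gradient stays put under the washout boundary
  Vconst <- wf$cycleV[rep(1, 11), ]
  res0 <- advance_concentration(disc, gas, rep(0.4, disc$n_cells),
                                Vconst, dt, mouth = "closed")
  expect_equal(res0$c, rep(0.4, disc$n_cells), tolerance = 1e-12)
})

test_that("the update is conservative to solver tolerance", {
  net <- toy_net()
  disc <- discretise(net)
  gas <- gas_spec(net$params, "SF6")
  sys <- build_mechanics(net)
  wf <- calibrate_waveform(sys, n_steps = 300L)
  dt <- net$params$tau / 300
  c0 <- rep(1, disc$n_cells)
  tot0 <- advance_concentration(disc, gas, c0, wf$cycleV[1, , drop = FALSE],
                                dt)$total_tracer
  res <- advance_concentration(disc, gas, c0, wf$cycleV, dt)
  expect_lt(abs((tot0 - res$total_tracer) - res$net_out) / tot0, 1e-10)
})

test_that("an advected front moves at the gas velocity", {
  net <- toy_net()
  disc <- discretise(net, cells_per_edge = 12L)
  # nearly pure advection: negligible diffusion, no dispersion
  gas <- list(name = "plug", D0 = 1e-9, C_insp = 0, C_exp = 0, phi = 0)
  trachea_cells <- which(disc$cell_edge == which(disc$edges$edge_id ==
                                                  "trachea"))
  l_tr <- sum(disc$disc$dx[trachea_cells])
  s_tr <- disc$disc$s[trachea_cells][1]
  c0 <- rep(1, disc$n_cells)                 # tracer everywhere
  # steady inhalation sized to displace ~40% of the trachea length
  m <- 40L
  dt <- 0.004
  Q <- 0.4 * l_tr * s_tr / 1000 / (m * dt)   # L/s total
  Vseq <- outer(seq(0, m) * dt * Q,
                net$units$V_star / sum(net$units$V_star)) +
    matrix(rep(net$units$V_star, each = m + 1), m + 1)
  res <- advance_concentration(disc, gas, c0, Vseq, dt)
  # method of characteristics: the fresh-gas front sits at the displaced
  # volume divided by the cross-section
  displacement <- Q * 1000 * m * dt / s_tr
  expect_lt(displacement, 0.9 * l_tr)        # front stays inside the edge
  fresh_cm3 <- sum((1 - res$c[trachea_cells]) *
                     disc$disc$dx[trachea_cells]) * s_tr
  expect_equal(fresh_cm3 / s_tr, displacement, tolerance = 1e-3)
  # globally, inhaled fresh volume is accounted for exactly
  S_end <- distribute_sac_volume(disc, Vseq[m + 1, ])
  fresh_tot <- sum((1 - res$c) * S_end * disc$disc$dx)
  expect_equal(fresh_tot, Q * 1000 * m * dt, tolerance = 1e-7)
  # no fresh gas beyond the trachea yet (within smearing tolerance)
  beyond <- setdiff(seq_len(disc$n_cells), trachea_cells)
  expect_gt(min(res$c[beyond]), 0.97)
})

test_that("washout respects monotonicity bounds and conserves tracer", {
  tr <- toy_trace()
  expect_true(all(tr$c_mouth >= -1e-9 & tr$c_mouth <= 1 + 1e-9))
  expect_lt(tr$conservation_error, 1e-10)
  # initial tracer = expired + residual (global balance)
  expect_equal(tr$tracer_init, tr$tracer_out + tr$tracer_final,
               tolerance = 1e-10)
  # end-tidal series decreases monotonically in the healthy model
  expect_true(all(diff(tr$breaths$end_tidal) < 0))
})
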
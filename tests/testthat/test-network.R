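test_that("healthy model M satisfies the structural invariants", {
  net <- default_net()
  p <- net$params
  # 40960 terminal conducting branches, one lung unit class per region
  tb <- net$edges$kind == "conducting" & net$edges$order == 9
  expect_equal(sum(net$edges$N_b[tb]), 40960)
  expect_equal(nrow(net$units), 7)
  expect_setequal(net$units$region, names(p$region_entry_orders))
  # dead space and acinar volume bookkeeping
  expect_lt(abs(conducting_dead_space(net) - p$V_D) / p$V_D, 1e-3)
  expect_lt(abs(sum(net$units$V_star) - (p$FRC - p$V_D)) /
              (p$FRC - p$V_D), 1e-3)
  # the right-middle lobe feeds exactly 10% of the acini
  expect_equal(net$units$n_acini[net$units$region == "RM"] /
                 sum(net$units$n_acini), 0.10)
  # elastances combine in parallel to K_lung
  expect_equal(1 / sum(1 / net$units$K), p$K_lung, tolerance = 1e-12)
  expect_true(all(net$edges$a > 0 & net$edges$l > 0 & net$edges$N_b >= 1))
  # N_b doubles along each symmetric chain
  rm_ord <- net$edges[net$edges$region == "RM", ]
  rm_ord <- rm_ord[order(-rm_ord$order), ]
  expect_equal(rm_ord$N_b, 2^(seq_len(nrow(rm_ord)) - 1))
})

test_that("dead space scales linearly with configured V_D", {
  p2 <- global_params(V_D = 0.30)
  net2 <- build_model_m(p2)
  expect_equal(conducting_dead_space(net2), 0.30, tolerance = 1e-12)
  expect_equal(sum(net2$units$V_star), p2$FRC - p2$V_D, tolerance = 1e-12)
})

test_that("Strahler orders count subtree height from zero at the periphery", {
  net <- toy_net()
  ord <- strahler_order_map(net)
  edges <- net$edges
  expect_true(all(ord[edges$edge_id[edges$order == 0]] == 0))
  expect_equal(unname(ord), edges$order)
  # terminal acinar ducts are order 0; terminal bronchioles order 9
  expect_true(all(edges$kind[edges$order <= 8] == "acinar_duct"))
  expect_true(all(edges$kind[edges$order >= 9] == "conducting"))
  # a single chain of n edges has root order n - 1
  chain <- data.frame(
    edge_id = paste0("e", 1:5), parent = c(NA, paste0("e", 1:4)),
    unit_id = NA_character_, stringsAsFactors = FALSE)
  net_chain <- list(edges = chain)
  expect_equal(unname(strahler_order_map(net_chain)), 4:0)
  # a cycle is a structural error
  cyc <- data.frame(edge_id = c("a", "b"), parent = c("b", "a"),
                    unit_id = NA_character_, stringsAsFactors = FALSE)
  expect_error(strahler_order_map(list(edges = cyc)), "cycle")
})

test_that("localised constrictions scale the selected band only", {
  net <- default_net()
  expect_error(constriction_spec(severity = 1), "disallowed")
  s0 <- constriction_spec("localised", "central", 0, "RM")
  expect_equal(apply_localised_constriction(net, s0)$edges$cf,
               net$edges$cf)
  s <- constriction_spec("localised", "central", 0.8, "RM")
  cn <- apply_localised_constriction(net, s)
  changed <- which(cn$edges$cf != net$edges$cf)
  expect_length(changed, 4)                      # orders 15-12, one region
  expect_setequal(cn$edges$order[changed], 12:15)
  expect_true(all(cn$edges$region[changed] == "RM"))
  expect_equal(cn$edges$cf[changed], rep(0.2, 4))
  # severity 0.5 multiplies Poiseuille resistance by 16 (radius^-4)
  s5 <- constriction_spec("localised", "central", 0.5, "RM")
  c5 <- apply_localised_constriction(net, s5)
  i <- which(net$edges$region == "RM" & net$edges$order == 15)
  mu <- 1
  r0 <- poiseuille_resistance(net$edges$l[i],
                              net$edges$a[i] * net$edges$cf[i]^2, mu)
  r5 <- poiseuille_resistance(c5$edges$l[i],
                              c5$edges$a[i] * c5$edges$cf[i]^2, mu)
  expect_equal(r5 / r0, 16, tolerance = 1e-12)
  expect_error(
    apply_localised_constriction(net, constriction_spec(
      "localised", severity = 0.5, region = "RM", orders = 40:40)),
    "absent")
})

test_that("distributed constrictions re-collapse to minimal sub-chains", {
  net <- default_net()
  # zero fraction leaves the network unchanged
  s0 <- constriction_spec("distributed", "central", 0.8,
                          affected_volume_fraction = 0, seed = 3L)
  expect_equal(apply_distributed_constrictions(net, s0)$edges$cf,
               net$edges$cf)
  # 10% at order 15: at most two sub-paths per region below the top order
  s <- constriction_spec("distributed", "central", 0.8,
                         affected_volume_fraction = 0.10, seed = 3L)
  dn <- apply_distributed_constrictions(net, s)
  expect_equal(length(dn$meta$selected), 64)     # 10% of 640 airways
  per_reg <- table(dn$units$region)
  expect_true(all(per_reg <= 2))
  # affected acinar volume exactly matches the requested fraction
  expect_equal(constricted_acinar_volume(dn),
               0.10 * sum(net$units$V_star), tolerance = 1e-12)
  # same seed reproduces the same selection
  dn2 <- apply_distributed_constrictions(net, s)
  expect_identical(dn$meta$selected, dn2$meta$selected)
  # localised and distributed agree on total constricted volume
  ln <- apply_localised_constriction(
    net, constriction_spec("localised", "central", 0.8, "RM"))
  expect_equal(constricted_acinar_volume(ln),
               constricted_acinar_volume(dn), tolerance = 1e-12)
  # fraction 1 constricts every airway of the band in every region
  s1 <- constriction_spec("distributed", "central", 0.8,
                          affected_volume_fraction = 1, seed = 3L)
  d1 <- apply_distributed_constrictions(net, s1)
  in_band <- d1$edges$order %in% 12:15 & d1$edges$region != "proximal"
  expect_equal(d1$edges$cf[in_band], rep(0.2, sum(in_band)))
  expect_true(all(d1$edges$cf[!in_band] == 1))
  expect_equal(nrow(d1$units), 7)
  # a fraction too small for a single airway at this order is unreachable
  s_bad <- constriction_spec("distributed", "proximal", 0.8,
                             affected_volume_fraction = 0.01, seed = 3L)
  expect_error(apply_distributed_constrictions(net, s_bad), "achievable")
})

test_that("mean-path collapse round-trips through explicit expansion", {
  net <- toy_net()
  exp_b <- expand_region(net, "B", down_to = 7L)
  expect_equal(nrow(exp_b), sum(2^(0:5)))        # orders 12..7 expanded
  col_b <- collapse_expanded(exp_b)
  orig <- net$edges[net$edges$region == "B" & net$edges$order >= 7, ]
  orig <- orig[order(-orig$order), ]
  expect_equal(col_b$N_b, orig$N_b)
  expect_equal(col_b$a, orig$a)
  expect_equal(col_b$l, orig$l)
  expect_equal(col_b$order, orig$order)
})

test_that("network serialisation round-trips losslessly", {
  net <- toy_net()
  tf <- tempfile(fileext = ".json")
  network_to_json(net, tf)
  back <- network_from_json(tf)
  expect_equal(back$edges, net$edges, tolerance = 1e-12)
  expect_equal(back$units, net$units, tolerance = 1e-12)
  expect_equal(back$params$region_entry_orders,
               net$params$region_entry_orders)
})
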
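# The pair-count combinatorics behind the variance propagation are checked
# against explicit enumeration of every airway pair on a small tree.

# ancestor of node (depth g, index i in 0..2^(g-1)-1) at depth m <= g
anc <- function(g, i, m) i %/% 2^(g - m)

# number of shared root-path generations of two nodes
shared_gens <- function(g1, i1, g2, i2) {
  sum(vapply(seq_len(min(g1, g2)), function(m)
    anc(g1, i1, m) == anc(g2, i2, m), logical(1)))
}

# brute-force variance of sum_i delta(i) eps_i over one region tree
enum_region_var <- function(depths, delta_fun, model) {
  nodes <- do.call(rbind, lapply(depths, function(g)
    data.frame(g = g, i = 0:(2^(g - 1) - 1))))
  params <- c("a", "l")
  sig2 <- c(a = model$sigma_a^2, l = model$sigma_l^2)
  v <- 0
  for (r1 in seq_len(nrow(nodes))) for (r2 in seq_len(nrow(nodes))) {
    g1 <- nodes$g[r1]; i1 <- nodes$i[r1]
    g2 <- nodes$g[r2]; i2 <- nodes$i[r2]
    sh <- shared_gens(g1, i1, g2, i2)
    for (p1 in params) for (p2 in params) {
      cv <- if (model$mode == "independent") {
        if (r1 == r2 && p1 == p2) sig2[[p1]] else 0
      } else sh * model$Sigma[p1, p2]
      if (cv != 0)
        v <- v + cv * delta_fun(g1, i1, p1) * delta_fun(g2, i2, p2)
    }
  }
  v
}

synthetic_sens <- function(region, orders, outputs, entry, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(kind = c("a", "l"), order = orders,
                      output = outputs, stringsAsFactors = FALSE)
  data.frame(kind = rows$kind, region = region, order = rows$order,
             N_b = 2^(entry - rows$order), output = rows$output,
             delta = round(rnorm(nrow(rows), 0, 1e-3), 8),
             stringsAsFactors = FALSE)
}

test_that("closed-form output variance equals brute-force enumeration", {
  net <- toy_net()                      # region A entry order 13
  sens <- synthetic_sens("A", 13:8, "LCI", 13L)
  look <- function(g, i, p)             # depth -> order 13 - (g - 1)
    sens$delta[sens$kind == p & sens$order == 13L - (g - 1L)]
  for (model in list(covariance_model("independent", 0.2, 0.1),
                     covariance_model("correlated", 0.2, 0.1, 0),
                     covariance_model("correlated", 0.2, 0.1, 0.6),
                     covariance_model("correlated", 0.2, 0.1, 1))) {
    brute <- enum_region_var(1:6, look, model)
    got <- output_variance(sens, model, net, outputs = "LCI")$var
    expect_equal(got, brute, tolerance = 1e-10)
  }
})

test_that("per-acinus FV variance matches enumeration incl. cross-region", {
  net <- toy_net()                      # A entry 13 (tb depth 5), B entry 12
  sensA <- synthetic_sens("A", 13:8, c("FV.own", "FV.sib"), 13L, seed = 2)
  sensB <- synthetic_sens("B", 12:9, "FV.A", 12L, seed = 3)
  sens <- rbind(sensA, sensB)
  Gtb <- 13 - 9 + 1                     # depth of the terminal bronchiole
  own_fun <- function(g, i) {
    if (g <= Gtb) i == 0 else anc(g, i, Gtb) == 0
  }
  lookA <- function(g, i, p) {
    o <- 13L - (g - 1L)
    out <- if (own_fun(g, i)) "FV.own" else "FV.sib"
    sens$delta[sens$region == "A" & sens$kind == p & sens$order == o &
                 sens$output == out]
  }
  lookB <- function(g, i, p)
    sens$delta[sens$region == "B" & sens$kind == p &
                 sens$order == 12L - (g - 1L)]
  for (model in list(covariance_model("independent", 0.2, 0.1),
                     covariance_model("correlated", 0.2, 0.1, 0.4))) {
    brute <- enum_region_var(1:6, lookA, model) +
      enum_region_var(1:4, lookB, model)
    got <- fv_acinus_variance(sens, model, net, "A")
    expect_equal(got, brute, tolerance = 1e-10)
  }
})

test_that("tree covariance matches its generative model", {
  m <- covariance_model("correlated", 0.25, 0.12, 0.5)
  # siblings at depth g share g - 1 increments
  expect_equal(tree_covariance(m, 4, 4, 3, "a", "a"), 3 * 0.25^2)
  expect_equal(tree_covariance(m, 4, 4, 3, "a", "l"),
               3 * 0.5 * 0.25 * 0.12)
  mi <- covariance_model("independent", 0.25, 0.12)
  expect_equal(tree_covariance(mi, 1, 1, 1, "a", "a",
                               same_airway = TRUE), 0.25^2)
  expect_equal(tree_covariance(mi, 3, 3, 2, "a", "a",
                               same_airway = FALSE), 0)
  expect_error(tree_covariance(m, 2, 2, 3), "exceed")
  # sampling oracle: two siblings at depth 3 constructed from their
  # generative definition (increments accumulated along the tree)
  set.seed(99)
  L <- t(chol(m$Sigma))
  n <- 2e5
  inc <- function() L %*% matrix(rnorm(2 * n), 2)
  root <- inc(); mid <- root + inc()
  sib1 <- mid + inc(); sib2 <- mid + inc()
  expect_equal(cov(sib1[1, ], sib2[1, ]),
               tree_covariance(m, 3, 3, 2, "a", "a"), tolerance = 0.05)
  expect_equal(cov(sib1[1, ], sib2[2, ]),
               tree_covariance(m, 3, 3, 2, "a", "l"), tolerance = 0.08)
})

test_that("superposition is exact at zero and additive by construction", {
  bl <- memo("toy_baseline", model_m_baseline(toy_net(), "SF6"))
  sens <- memo("toy_sens", sensitivity_matrix(
    bl, data.frame(kind = c("a", "l"), region = "B", order = 11L)))
  e0 <- data.frame(kind = "a", region = "B", order = 11L, eps = 0)
  expect_identical(superpose(bl, sens, e0)[["LCI"]], bl$indices$LCI)
  e1 <- data.frame(kind = "a", region = "B", order = 11L, eps = 0.02)
  e2 <- data.frame(kind = "l", region = "B", order = 11L, eps = -0.01)
  s12 <- superpose(bl, sens, rbind(e1, e2))
  s1 <- superpose(bl, sens, e1)
  s2 <- superpose(bl, sens, e2)
  expect_equal(s12[["LCI"]] - bl$indices$LCI,
               (s1[["LCI"]] - bl$indices$LCI) +
                 (s2[["LCI"]] - bl$indices$LCI), tolerance = 1e-12)
  e_bad <- data.frame(kind = "a", region = "B", order = 11L, eps = 1)
  expect_error(superpose(bl, sens, e_bad), "unphysical")
})

test_that("the linear probe passes its own convergence check", {
  bl <- memo("toy_baseline", model_m_baseline(toy_net(), "SF6"))
  d <- compute_sensitivity(bl, perturbation_target("a", "B", 11L),
                           richardson = TRUE)
  expect_true(all(is.finite(d)))
})

test_that("mirror-image regions have degenerate sensitivities", {
  bl <- healthy_baseline_coarse()
  d1 <- compute_sensitivity(bl, perturbation_target("a", "LL_min", 15L))
  d2 <- compute_sensitivity(bl, perturbation_target("a", "LL_maj", 15L))
  expect_equal(d1[["LCI"]], d2[["LCI"]], tolerance = 1e-3)
  expect_equal(d1[["FRC_approx"]], d2[["FRC_approx"]], tolerance = 1e-3)
})

test_that("fv_density is a unit-mass mixture over acinus classes", {
  bl <- memo("toy_baseline", model_m_baseline(toy_net(), "SF6"))
  sens <- rbind(
    synthetic_sens("A", 13:10, c("FV.own", "FV.sib", "FV.B"), 13L,
                   seed = 5),
    synthetic_sens("B", 12:10, c("FV.own", "FV.sib", "FV.A"), 12L,
                   seed = 6))
  d <- fv_density(bl, sens, covariance_model("independent", 0.2, 0.1),
                  grid = seq(0, 0.6, length.out = 2001))
  integral <- sum(d$density) * mean(diff(d$fv))
  expect_lt(abs(integral - 1), 1e-3)
  comp <- attr(d, "components")
  expect_equal(sum(comp$weight), 1)
  expect_true(all(comp$sd >= 0))
})

test_that("global parameter sensitivities combine the class responses", {
  net <- toy_net()
  sens <- synthetic_sens("A", 13:9, "LCI", 13L)
  vd <- global_sensitivity(sens, net, "V_D")
  ld <- global_sensitivity(sens, net, "LD_cond")
  wide <- merge(sens[sens$kind == "a", c("order", "N_b", "delta")],
                sens[sens$kind == "l", c("order", "delta")], by = "order")
  expect_equal(vd, sum(wide$N_b * (wide$delta.y + 2 * wide$delta.x)) / 3,
               tolerance = 1e-12)
  expect_equal(ld, 2 * sum(wide$N_b * (wide$delta.y - wide$delta.x)) / 3,
               tolerance = 1e-12)
  zero <- sens; zero$delta <- 0
  expect_equal(global_sensitivity(zero, net, "V_D"), 0)
  expect_error(global_sensitivity(sens, net, "K_lung"), "kind 'K'")
})
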
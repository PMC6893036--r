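par_default <- o2_params()

test_that("the Hill curve has the defining saturation properties", {
  expect_equal(hill_saturation(0, par_default), 0)
  expect_equal(hill_saturation(par_default$p50, par_default), 0.5)
  p <- seq(0, 150, by = 0.5)
  s <- hill_saturation(p, par_default)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s < 1))
  expect_error(hill_saturation(-1, par_default), "non-negative")
})

test_that("Poiseuille flow is no-slip, calibrated at rest, and scales as radius^4", {
  v <- poiseuille_velocity(par_default)
  expect_equal(v$v[which.max(v$r)], 0, tolerance = 1e-9) # no slip at the wall
  expect_equal(attr(v, "v_center"), 2000, tolerance = 0.01 * 2000)

  q1 <- attr(poiseuille_velocity(par_default, radius = par_default$R1), "flow")
  q2 <- attr(poiseuille_velocity(par_default, radius = 1.1 * par_default$R1), "flow")
  expect_equal(q2 / q1, 1.1^4, tolerance = 1e-9)
})

test_that("steady state with no consumption is uniform at the inlet tension", {
  st <- o2_steady_state(par_default, cmro2_factor = 0)
  expect_lt(max(abs(st$P - par_default$pao2_inlet_rest)), 1e-6)
})

test_that("the tissue annulus matches the closed-form Krogh profile within 1%", {
  st <- o2_steady_state(par_default,
    wall_po2 = 30, advection = FALSE,
    refine = 2
  )
  an <- krogh_annulus_profile(par_default, 30, st$tissue_profile$r)
  rel <- max(abs(st$tissue_profile$po2 - an$po2)) / diff(range(an$po2))
  expect_lt(rel, 0.01)
})

test_that("global oxygen balance closes and the grid is converged", {
  st <- o2_steady_state(par_default, refine = 2)
  bal <- o2_balance(st)
  expect_lt(abs(bal$rel_error), 0.01)

  st1 <- o2_steady_state(par_default)
  bal1 <- o2_balance(st1)
  expect_lt(abs(bal1$rel_error), 0.05)
  # halving the spacings moves the probe tension by < 2%
  expect_lt(
    abs(st$probe$pto2_probe - st1$probe$pto2_probe) / st1$probe$pto2_probe,
    0.02
  )
})

test_that("steady tissue oxygen is monotone in consumption, inlet tension and radius", {
  base <- o2_steady_state(par_default)$probe$pto2_probe
  expect_lt(o2_steady_state(par_default, cmro2_factor = 1.2)$probe$pto2_probe, base)
  expect_gt(o2_steady_state(par_default, pao2_inlet = 40)$probe$pto2_probe, base)
  expect_gt(o2_steady_state(par_default, radius_factor = 1.1)$probe$pto2_probe, base)
  expect_lt(o2_steady_state(par_default, radius_factor = 0.95)$probe$pto2_probe, base)
})

test_that("hemoglobin buffering carries most of the delivered oxygen", {
  st <- o2_steady_state(par_default)
  g <- st$grid
  nrb <- g$nrb
  vp <- poiseuille_velocity(par_default, r = g$rc[1:nrb])
  fflow <- vp$v * g$ring_area[1:nrb]
  ct_in <- respox:::o2_ctotal(st$p_in, TRUE, par_default)
  free_in <- par_default$alpha * st$p_in
  expect_gt((ct_in$ct - free_in) / ct_in$ct, 0.9) # bound fraction dominates
  # delivered total = free + 4 C_Hb S at every blood node
  S <- hill_saturation(st$P[1:nrb, ], par_default)
  ct_nodes <- par_default$alpha * st$P[1:nrb, ] + 4 * par_default$C_Hb * S
  expect_equal(
    respox:::o2_ctotal(as.vector(st$P[1:nrb, ]), TRUE, par_default)$ct,
    as.vector(ct_nodes)
  )
})

test_that("constant drivers preserve the steady state through time stepping", {
  tc <- o2_simulate(par_default, o2_scenario(), t_end = 5, dt = 0.25)
  drift <- max(abs(tc$pto2_probe - tc$pto2_probe[1])) / tc$pto2_probe[1]
  expect_lt(drift, 1e-3)
})

test_that("a step rise in inlet oxygenation drives a monotone rise to a higher steady state", {
  sc <- o2_scenario(pao2_rise = 5, t_on = 0.5, t_off = 1e6, ramp_up = 0.5)
  tc <- o2_simulate(par_default, sc, t_end = 8, dt = 0.1)
  after <- tc$pto2_probe[tc$time >= 1.2]
  expect_true(all(diff(after) > -1e-8))
  expect_gt(tc$pto2_probe[length(tc$pto2_probe)], tc$pto2_probe[1])
})

test_that("the frontal-cortex scenario changes sign with the arterial oxygenation rise", {
  # steady plateau states stand in for the slow part of the bout
  rest <- o2_steady_state(par_default)$probe$pto2_probe
  no_inlet <- o2_steady_state(par_default,
    radius_factor = 0.95,
    cmro2_factor = 1.04
  )$probe$pto2_probe
  with_inlet <- o2_steady_state(par_default,
    radius_factor = 0.95,
    cmro2_factor = 1.04, pao2_inlet = par_default$pao2_inlet_rest + 3
  )$probe$pto2_probe
  expect_lt(no_inlet - rest, 0)
  expect_gt(with_inlet - rest, 0)
})

test_that("blockade scenarios reduce consumption as configured", {
  sc <- blockade_scenario(par_default)
  expect_equal(round(sc$cmro2_blockade, 1), 1.2)
  expect_equal(blockade_scenario(par_default, suppression = 0)$cmro2_blockade, 3)
  expect_equal(
    blockade_scenario(par_default, activity_fraction = 1, suppression = 1)$cmro2_blockade,
    0
  )
  expect_equal(sc$dilation(10), 0)
  expect_error(blockade_scenario(par_default, suppression = 1.2), "0, 1")
  # silencing raises tissue oxygenation
  rest <- o2_steady_state(par_default)$probe$pto2_probe
  blocked <- o2_steady_state(par_default, cmro2_factor = 1 - 0.75 * 0.82)$probe$pto2_probe
  expect_gt(blocked, rest)
})

test_that("driver decomposition has the right signs and is additive for small perturbations", {
  sc <- o2_scenario(
    dilation = 0.01, cmro2_rise = 0.015, pao2_rise = 0.3,
    t_on = 2, t_off = 10
  )
  dc <- o2_decompose(par_default, sc, t_end = 14, dt = 0.25)
  w <- tidyr::pivot_wider(tibble::as_tibble(dc),
    names_from = "driver", values_from = "dpto2"
  )
  expect_true(all(w$cmro2 <= 1e-9)) # pure sink
  expect_true(all(w$pao2_inlet >= -1e-9)) # pure source
  expect_lt(attr(dc, "additivity_defect"), 0.1)
})
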
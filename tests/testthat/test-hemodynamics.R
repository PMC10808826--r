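test_that("inlet flow assignment follows velocity, diameter and split", {
  tree <- make_tree()
  tree$segments$PV$radius_r <- c(0.006, 0.006)  # D_PV = 12 mm
  bc <- boundary_conditions(pv_velocity = 0.15)
  q <- assign_inlet_flows(tree, bc)
  q_total <- 0.15 * pi * 0.006^2
  expect_equal(q_total, 1.696e-5, tolerance = 1e-3)
  expect_equal(sum(q), q_total)
  expect_equal(unname(q["SMV"]), 0.40 * q_total)

  # postoperative, default mode: SV share removed
  post <- apply_splenectomy(tree)
  qp <- assign_inlet_flows(post, bc)
  expect_setequal(names(qp), c("SMV", "LGV", "IMV"))
  expect_equal(sum(qp), (1 - 0.45) * q_total)
  expect_equal(sum(qp), 9.33e-6, tolerance = 1e-3)

  # renormalize mode preserves the preoperative total
  bc2 <- boundary_conditions(0.15, postop_flow_mode = "renormalize")
  expect_equal(sum(assign_inlet_flows(post, bc2)), q_total)
})

test_that("flow propagation conserves mass and respects topology", {
  tree <- make_tree()
  q <- c(SMV = 1e-6, SV = 2e-6, LGV = 3e-6, IMV = 4e-6)
  sol <- solve_flows(tree, q)
  expect_equal(sol$Q_outlet, 1e-5)
  expect_equal(segment_flow_at(sol, "PV", 0.9), 1e-5)

  # postoperative stump carries exactly zero
  post <- apply_splenectomy(tree)
  qp <- q[c("SMV", "LGV", "IMV")]
  solp <- solve_flows(post, qp)
  expect_identical(segment_flow_at(solp, "SV", c(0, 0.5, 1)), rep(0, 3))
  expect_equal(solp$Q_outlet, sum(qp))

  # Type 3: the SMV distal of the IMV junction carries Q_SMV + Q_IMV
  t3 <- make_tree(anatomy_type = 3)
  s3 <- solve_flows(t3, q)
  at <- t3$segments$IMV$attach_s
  expect_equal(segment_flow_at(s3, "SMV", at - 0.01), unname(q["SMV"]))
  expect_equal(segment_flow_at(s3, "SMV", at + 0.01),
               unname(q["SMV"] + q["IMV"]))
})

test_that("junction mass balance holds to 1e-12 on random trees", {
  set.seed(11)
  for (i in 1:100) {
    at <- sample(1:3, 1)
    tree <- make_tree(anatomy_type = at,
                      sv_diameter = runif(1, 0.007, 0.020),
                      sv_length = runif(1, 0.05, 0.18),
                      sv_tortuosity = runif(1, 1, 2))
    if (runif(1) < 0.5) {
      tree <- apply_splenectomy(tree)
      q <- setNames(runif(3, 0, 2e-5), c("SMV", "LGV", "IMV"))
    } else {
      q <- setNames(runif(4, 0, 2e-5), c("SMV", "SV", "LGV", "IMV"))
    }
    sol <- solve_flows(tree, q)
    # independent balance check: outlet equals summed inlets, and the flow
    # just downstream of each attachment equals upstream plus tributary
    expect_lt(abs(sol$Q_outlet - sum(q)) / sum(q), 1e-12)
    for (nm in names(tree$segments)) {
      seg <- tree$segments[[nm]]
      if (is.na(seg$parent) || seg$attach_s %in% c(0, 1)) next
      up <- segment_flow_at(sol, seg$parent, seg$attach_s)
      down <- segment_flow_at(sol, seg$parent, seg$attach_s + 1e-9)
      q_trib <- sol$segments[[nm]]$Q_distal
      expect_lt(abs(down - (up + q_trib)) /
                  max(down, .Machine$double.xmin), 1e-12)
    }
    expect_lt(check_conservation(tree, sol), 1e-12)
  }
})

test_that("WSS field matches the Poiseuille oracle on a Newtonian tree", {
  # uniform 10 mm vessels, equal split, so every non-stump strip is a
  # hand-computable Poiseuille tube
  p <- default_vessel_params()
  p$diameters[] <- 0.010
  tree <- build_tree(p$diameters, p$lengths, p$tortuosities, 1)
  post <- apply_splenectomy(tree)
  mu <- 0.0035
  pn <- newtonian_params(mu)
  q <- c(SMV = 4e-6, LGV = 3e-6, IMV = 2e-6)
  sol <- solve_flows(post, q)
  field <- compute_wss_field(post, sol, pn, dx = 0.001)
  strips <- field$strips
  for (i in seq_len(nrow(strips))) {
    nm <- strips$segment_id[i]
    if (post$segments[[nm]]$role == "stump") {
      expect_identical(strips$tau_w_pa[i], 0)
    } else {
      q_loc <- segment_flow_at(sol, nm, strips$axial_position[i])
      expect_equal(strips$tau_w_pa[i],
                   poiseuille_tau_w(q_loc, strips$radius_m[i], mu),
                   tolerance = 1e-6)
    }
  }
})

test_that("WSS rises where a tapered vessel narrows", {
  tree <- make_tree()
  tree$segments$SMV$radius_r <- c(0.006, 0.004)  # narrowing toward distal
  sol <- solve_flows(tree, c(SMV = 5e-6, SV = 5e-6, LGV = 1e-6, IMV = 1e-6))
  field <- compute_wss_field(tree, sol, carreau_params(), dx = 0.002)
  smv <- field$strips[field$strips$segment_id == "SMV", ]
  expect_true(all(diff(smv$tau_w_pa) > 0))
})

test_that("stump models behave as declared", {
  post <- apply_splenectomy(make_tree())
  q <- c(SMV = 6e-6, LGV = 1e-6, IMV = 2e-6)
  sol <- solve_flows(post, q)
  stasis <- compute_wss_field(post, sol, carreau_params(), 0.001, "stasis")
  sv <- stasis$strips$segment_id == "SV"
  expect_true(all(stasis$strips$tau_w_pa[sv] == 0))

  decay <- compute_wss_field(post, sol, carreau_params(), 0.001, "decay")
  sv_tau <- decay$strips$tau_w_pa[decay$strips$segment_id == "SV"]
  # decays monotonically away from the junction (strips ordered proximal
  # to distal; junction is the distal end)
  expect_true(all(diff(sv_tau) > 0))
  expect_true(max(sv_tau) > 0)
})

test_that("pressure integration reproduces the tube-flow drop", {
  # zero flow: uniform pressure at the outlet value
  tree <- make_tree()
  sol0 <- solve_flows(tree, c(SMV = 0, SV = 0, LGV = 0, IMV = 0))
  p0 <- compute_pressures(tree, sol0, outlet_pressure = 3332.9)
  expect_true(all(abs(p0 - 3332.9) < 1e-12))

  # Newtonian: PV drop equals 2 tau_w L / R; doubling Q doubles the drop
  mu <- 0.0035
  pn <- newtonian_params(mu)
  q1 <- c(SMV = 4e-6, SV = 4e-6, LGV = 1e-6, IMV = 1e-6)
  sol1 <- solve_flows(tree, q1)
  pv <- tree$segments$PV
  tau_pv <- poiseuille_tau_w(1e-5, pv$radius_r[1], mu)
  pr1 <- compute_pressures(tree, sol1, pn, outlet_pressure = 3332.9)
  drop1 <- pr1[["confluence"]] - pr1[["outlet"]]
  expect_equal(drop1, 2 * tau_pv * pv$length / pv$radius_r[1],
               tolerance = 1e-6)
  expect_true(all(pr1 >= 3332.9))

  sol2 <- solve_flows(tree, 2 * q1)
  pr2 <- compute_pressures(tree, sol2, pn, outlet_pressure = 3332.9)
  expect_equal(pr2[["confluence"]] - pr2[["outlet"]], 2 * drop1,
               tolerance = 1e-6)

  # ligated stump: no flow, no drop - tip node sits at junction pressure
  post <- apply_splenectomy(tree)
  solp <- solve_flows(post, q1[c("SMV", "LGV", "IMV")])
  prp <- compute_pressures(post, solp, pn)
  expect_equal(prp[["SV_in"]], prp[["confluence"]])
})
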
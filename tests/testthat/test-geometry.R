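test_that("anatomy types produce the three attachment configurations", {
  expected <- list(
    `1` = c(LGV = "SV", IMV = "SV"),
    `2` = c(LGV = "PV", IMV = "SV"),
    `3` = c(LGV = "SV", IMV = "SMV")
  )
  for (at in 1:3) {
    tree <- make_tree(anatomy_type = at)
    expect_identical(tree$segments$LGV$parent, unname(expected[[at]]["LGV"]))
    expect_identical(tree$segments$IMV$parent, unname(expected[[at]]["IMV"]))
    expect_length(tree$segments, 5)
    expect_setequal(
      names(Filter(function(s) s$role == "inlet", tree$segments)),
      c("SMV", "SV", "LGV", "IMV")
    )
  }
  # Type 2: LGV drains into the PV interior; Type 3: IMV into the SMV
  t2 <- make_tree(anatomy_type = 2)
  expect_true(t2$segments$LGV$attach_s < 1)
  t3 <- make_tree(anatomy_type = 3)
  expect_true(t3$segments$IMV$attach_s < 1)
})

test_that("invalid construction parameters are rejected", {
  p <- default_vessel_params()
  bad_d <- p$diameters; bad_d["SV"] <- -0.01
  expect_error(build_tree(bad_d, p$lengths), "positive")
  bad_l <- p$lengths; bad_l["PV"] <- 0
  expect_error(build_tree(p$diameters, bad_l), "positive")
  expect_error(build_tree(p$diameters, p$lengths, anatomy_type = 4),
               "anatomy_type")
})

test_that("virtual splenectomy closes the SV and touches nothing else", {
  for (at in 1:3) {
    pre <- make_tree(anatomy_type = at)
    post <- apply_splenectomy(pre)
    expect_identical(post$state, "postoperative")
    expect_identical(post$segments$SV$role, "stump")
    expect_setequal(
      names(Filter(function(s) s$role == "inlet", post$segments)),
      c("SMV", "LGV", "IMV")
    )
    # geometry byte-identical apart from the SV role and the state
    pre_mod <- pre
    pre_mod$segments$SV$role <- "stump"
    pre_mod$state <- "postoperative"
    expect_identical(post, pre_mod)
    expect_error(apply_splenectomy(post), "already postoperative")
  }
})

test_that("surface discretization recovers analytic lateral areas", {
  # constant-radius cylinder: 2*pi*R*L
  tree <- make_tree(sv_diameter = 0.010, sv_length = 0.100)
  strips <- discretize_surface(tree, dx = 0.001)
  sv_area <- sum(strips$area_m2[strips$segment_id == "SV"])
  expect_equal(sv_area, 2 * pi * 0.005 * 0.100, tolerance = 1e-3)

  # every segment's strip areas sum to its lateral area within 0.1%
  for (nm in names(tree$segments)) {
    seg <- tree$segments[[nm]]
    got <- sum(strips$area_m2[strips$segment_id == nm])
    expect_equal(got, 2 * pi * seg$radius_r[1] * seg$length,
                 tolerance = 1e-3)
  }

  # refinement consistency: halving dx moves the total by < 0.1%
  fine <- discretize_surface(tree, dx = 0.0005)
  expect_lt(abs(sum(fine$area_m2) - sum(strips$area_m2)) /
              sum(strips$area_m2), 1e-3)

  # linearly tapered segment: mean-radius (frustum, L >> dR) formula
  tree$segments$SV$radius_r <- c(0.006, 0.004)
  tapered <- discretize_surface(tree, dx = 0.001)
  sv_area <- sum(tapered$area_m2[tapered$segment_id == "SV"])
  expect_equal(sv_area, 2 * pi * 0.005 * 0.100, tolerance = 1e-3)

  expect_error(discretize_surface(tree, dx = 0.05), "shortest segment")
  expect_error(discretize_surface(tree, dx = 0), "dx")
})

test_that("distance metric is the endpoint chord length", {
  seg <- make_tree(sv_length = 0.120, sv_tortuosity = 1.5)$segments$SV
  expect_equal(distance_metric(seg), 0.080)
  seg$tortuosity <- 1
  expect_equal(distance_metric(seg), seg$length)
  seg$tortuosity <- 2
  seg$length <- 0.100
  expect_equal(distance_metric(seg), 0.050)
})

test_that("trees round-trip through JSON field-for-field", {
  path <- withr::local_tempfile(fileext = ".json")
  for (tree in list(make_tree(anatomy_type = 1),
                    make_tree(anatomy_type = 2),
                    apply_splenectomy(make_tree(anatomy_type = 3)))) {
    write_tree(tree, path)
    back <- read_tree(path)
    expect_equal(back, tree)
  }
  # postoperative stump role survives
  write_tree(apply_splenectomy(make_tree()), path)
  expect_identical(read_tree(path)$segments$SV$role, "stump")
})

test_that("schema violations are reported with the offending field", {
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(make_tree(), path)
  doc <- jsonlite::read_json(path)
  doc$anatomy_type <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_tree(path), "anatomy_type")

  write_tree(make_tree(), path)
  doc <- jsonlite::read_json(path)
  doc$segments[[1]]$length <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_tree(path), "segments.length")
})
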
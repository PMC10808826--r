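#' Boundary conditions and flow/WSS propagation
#'
#' Inflows are assigned from the ultrasound-measured portal vein velocity:
#' the total portal flow `Q_PV = V_PV * pi * (D_PV/2)^2` (diameter read from
#' the geometry at PV mid-length) is divided among the tributaries by
#' population-averaged flow proportions. After virtual splenectomy the
#' ligated SV contributes no inflow; by default its share is simply removed
#' (the PV then carries `Q_SMV + Q_LGV + Q_IMV`), with an alternative mode
#' that preserves the preoperative total by renormalizing the split over
#' the remaining inlets. Continuity is enforced exactly at every junction;
#' momentum is realized segment-wise by the fully developed tube model.
#'
#' @name hemodynamics
NULL

#' Population-averaged inlet flow split
#'
#' Fractions of total portal flow carried by each tributary in portal
#' hypertensive patients. The splenomegalic spleen dominates (SV share
#' 0.45). Configuration-overridable.
#'
#' @param SMV,SV,LGV,IMV non-negative fractions summing to 1.
#' @return named numeric vector of class `flow_split`.
#' @export
flow_split <- function(SMV = 0.40, SV = 0.45, LGV = 0.05, IMV = 0.10) {
  fs <- c(SMV = SMV, SV = SV, LGV = LGV, IMV = IMV)
  if (any(fs < 0)) stop("flow split fractions must be >= 0", call. = FALSE)
  if (abs(sum(fs) - 1) > 1e-12)
    stop("flow split fractions must sum to 1", call. = FALSE)
  structure(fs, class = "flow_split")
}

#' Boundary conditions for a portal tree simulation
#'
#' @param pv_velocity cross-sectional mean portal vein velocity, m/s
#'   (ultrasound-measured, preoperative).
#' @param outlet_pressure pressure at the PV distal outlet, Pa. Default
#'   3332.9 Pa (25 mmHg, typical of portal hypertension).
#' @param split a [flow_split()].
#' @param postop_flow_mode how postoperative inflow is derived from the
#'   preoperative total: `"subtract_sv"` (default; ligated SV share removed)
#'   or `"renormalize"` (total preserved, split renormalized over the
#'   remaining inlets).
#' @return an object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(pv_velocity,
                                outlet_pressure = 3332.9,
                                split = flow_split(),
                                postop_flow_mode = c("subtract_sv",
                                                     "renormalize")) {
  if (pv_velocity <= 0) stop("pv_velocity must be > 0", call. = FALSE)
  if (outlet_pressure <= 0)
    stop("outlet_pressure must be > 0", call. = FALSE)
  structure(list(pv_velocity = pv_velocity,
                 outlet_pressure = outlet_pressure,
                 split = split,
                 postop_flow_mode = match.arg(postop_flow_mode)),
            class = "boundary_conditions")
}

#' Assign inlet volumetric flow rates
#'
#' @param tree a `portal_tree` (pre- or postoperative).
#' @param bc a [boundary_conditions()] object.
#' @return named numeric vector of inlet flows (m^3/s), one entry per
#'   inflow segment of the tree.
#' @export
assign_inlet_flows <- function(tree, bc) {
  stopifnot(inherits(tree, "portal_tree"),
            inherits(bc, "boundary_conditions"))
  d_pv <- 2 * radius_at(tree$segments$PV, 0.5)
  q_total <- bc$pv_velocity * pi * (d_pv / 2)^2
  inl <- inlet_names(tree)
  missing <- setdiff(inl, names(bc$split))
  if (length(missing))
    stop("flow split is missing inlet(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  props <- unclass(bc$split)[inl]
  if (tree$state == "postoperative" && bc$postop_flow_mode == "renormalize")
    props <- props / sum(props)
  props * q_total
}

#' Propagate flows through the tree
#'
#' Computes each segment's volumetric flow by summing its own inlet flow
#' and the flows delivered by tributaries attached along it; the flow in a
#' segment is piecewise constant in arclength, stepping up at each
#' attachment. Continuity holds exactly at every junction by construction.
#'
#' @param tree a `portal_tree`.
#' @param inlet_flows named numeric vector from [assign_inlet_flows()]
#'   (m^3/s); stump segments must be absent or zero.
#' @return an object of class `flow_solution`: per-segment base flow and
#'   attachment steps, plus `Q_outlet`.
#' @export
solve_flows <- function(tree, inlet_flows) {
  stopifnot(inherits(tree, "portal_tree"))
  if (any(inlet_flows < 0))
    stop("inlet flows must be >= 0", call. = FALSE)
  segs <- tree$segments
  bad <- setdiff(names(inlet_flows), inlet_names(tree))
  if (any(inlet_flows[bad] > 0))
    stop("flow prescribed at non-inlet segment(s): ",
         paste(bad[inlet_flows[bad] > 0], collapse = ", "), call. = FALSE)

  q_out <- new.env(parent = emptyenv())
  total_out <- function(nm) {
    if (!is.null(q_out[[nm]])) return(q_out[[nm]])
    base <- if (segs[[nm]]$role == "inlet" && nm %in% names(inlet_flows))
      inlet_flows[[nm]] else 0
    kids <- names(Filter(function(s) identical(s$parent, nm), segs))
    q <- base + sum(vapply(kids, total_out, numeric(1)))
    q_out[[nm]] <- q
    q
  }
  solution <- lapply(names(segs), function(nm) {
    base <- if (segs[[nm]]$role == "inlet" && nm %in% names(inlet_flows))
      inlet_flows[[nm]] else 0
    kids <- names(Filter(function(s) identical(s$parent, nm), segs))
    steps <- data.frame(
      s = vapply(kids, function(k) segs[[k]]$attach_s, numeric(1)),
      Q = vapply(kids, total_out, numeric(1)),
      child = kids, stringsAsFactors = FALSE, row.names = NULL
    )
    list(Q_base = base, steps = steps[order(steps$s), , drop = FALSE],
         Q_distal = total_out(nm))
  })
  names(solution) <- names(segs)
  structure(list(segments = solution, Q_outlet = total_out("PV")),
            class = "flow_solution")
}

#' Flow at a normalized position within a segment
#'
#' @param flows a `flow_solution`.
#' @param segment_id segment name.
#' @param x normalized arclength (vectorized).
#' @return flow in m^3/s at each position (piecewise constant, taken as
#'   the left limit: a tributary's flow appears strictly downstream of its
#'   attachment point, so at the attachment position itself the upstream
#'   flow is returned).
#' @export
segment_flow_at <- function(flows, segment_id, x) {
  fs <- flows$segments[[segment_id]]
  if (is.null(fs)) stop("unknown segment ", segment_id, call. = FALSE)
  vapply(x, function(xx)
    fs$Q_base + sum(fs$steps$Q[fs$steps$s < xx]), numeric(1))
}

#' Wall shear stress field over the discretized surface
#'
#' Evaluates the tube-flow wall shear stress on every surface strip from
#' the local flow and radius. Stump (ligated SV) strips use the selected
#' stump model: `"stasis"` (default) assigns zero WSS to the whole stump,
#' consistent with blood stagnation in a dead-end pouch; `"decay"` lets the
#' parent vessel's junction WSS penetrate the stump with an exponential
#' decay over one stump diameter, mimicking 3D recirculation.
#'
#' @param tree a `portal_tree`.
#' @param flows a `flow_solution` for that tree.
#' @param params a [carreau_params()] object.
#' @param dx strip width in meters (see [discretize_surface()]).
#' @param stump_model `"stasis"` or `"decay"`.
#' @return an object of class `wss_field`: the strip table with a `tau_w_pa`
#'   column.
#' @export
compute_wss_field <- function(tree, flows, params = carreau_params(),
                              dx = 0.001,
                              stump_model = c("stasis", "decay")) {
  stump_model <- match.arg(stump_model)
  strips <- discretize_surface(tree, dx)
  tau <- numeric(nrow(strips))
  cache <- new.env(parent = emptyenv())
  wss_cached <- function(Q, R) {
    key <- sprintf("%.17g|%.17g", Q, R)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- wall_shear_stress_tube(Q, R, params)
      cache[[key]] <- v
    }
    v
  }
  for (nm in names(tree$segments)) {
    seg <- tree$segments[[nm]]
    idx <- which(strips$segment_id == nm)
    if (seg$role == "stump") {
      if (stump_model == "stasis") {
        tau[idx] <- 0
      } else {
        # junction WSS from the parent vessel just downstream of the
        # attachment point
        par <- tree$segments[[seg$parent]]
        q_j <- segment_flow_at(flows, par$id, min(1, seg$attach_s + 1e-9))
        tau_j <- wss_cached(q_j, radius_at(par, seg$attach_s))
        d_stump <- 2 * radius_at(seg, 1)
        s_dist <- (1 - strips$axial_position[idx]) * seg$length
        tau[idx] <- tau_j * exp(-s_dist / d_stump)
      }
    } else {
      q <- segment_flow_at(flows, nm, strips$axial_position[idx])
      r <- strips$radius_m[idx]
      tau[idx] <- mapply(wss_cached, q, r)
    }
  }
  strips$tau_w_pa <- tau
  structure(list(strips = strips), class = "wss_field")
}

#' Node pressures by upstream integration from the outlet
#'
#' For fully developed tube flow the pressure gradient balances the wall
#' shear: the drop across a strip is `2 * tau_w * h / R`. Pressures are
#' integrated upstream from the prescribed PV outlet pressure; stump
#' segments carry no flow and contribute no drop, so the stump-tip node
#' sits at the junction pressure.
#'
#' @param tree a `portal_tree`.
#' @param flows a `flow_solution`.
#' @param params a [carreau_params()] object.
#' @param outlet_pressure outlet pressure, Pa.
#' @param dx strip width, m.
#' @param field optional precomputed [compute_wss_field()] result (must
#'   match `dx` and the stasis stump model assumption for drops).
#' @return named numeric vector of node pressures (Pa), including each
#'   segment's proximal/distal nodes.
#' @export
compute_pressures <- function(tree, flows, params = carreau_params(),
                              outlet_pressure = 3332.9, dx = 0.001,
                              field = NULL) {
  if (is.null(field))
    field <- compute_wss_field(tree, flows, params, dx, "stasis")
  strips <- field$strips
  segs <- tree$segments
  # pressure drop profile per segment: drop over strip i = 2 tau h / R
  seg_drops <- lapply(names(segs), function(nm) {
    idx <- which(strips$segment_id == nm)
    if (segs[[nm]]$role == "stump") {
      list(x = strips$axial_position[idx],
           dp = rep(0, length(idx)))
    } else {
      list(x = strips$axial_position[idx],
           dp = 2 * strips$tau_w_pa[idx] * strips$width_m[idx] /
             strips$radius_m[idx])
    }
  })
  names(seg_drops) <- names(segs)
  # pressure at position x within a segment given its distal-node pressure
  p_at <- function(nm, x, p_distal) {
    d <- seg_drops[[nm]]
    p_distal + sum(d$dp[d$x > x])
  }
  pressures <- c()
  p_distal_of <- new.env(parent = emptyenv())
  p_distal_of[["PV"]] <- outlet_pressure
  # resolve in dependency order: parent distal pressure before children
  resolve <- function(nm) {
    if (!is.null(p_distal_of[[nm]])) return(p_distal_of[[nm]])
    seg <- segs[[nm]]
    resolve(seg$parent)
    p <- p_at(seg$parent, seg$attach_s, p_distal_of[[seg$parent]])
    p_distal_of[[nm]] <- p
    p
  }
  for (nm in names(segs)) resolve(nm)
  for (nm in names(segs)) {
    seg <- segs[[nm]]
    pd <- p_distal_of[[nm]]
    pressures[seg$distal_node] <- pd
    pressures[seg$proximal_node] <- pd + sum(seg_drops[[nm]]$dp)
  }
  pressures
}

#' Check junction mass balance of a flow solution
#'
#' @param tree a `portal_tree`.
#' @param flows a `flow_solution`.
#' @return maximum relative conservation error over all junctions
#'   (0 for an exactly conservative solution).
#' @export
check_conservation <- function(tree, flows) {
  segs <- tree$segments
  err <- 0
  for (nm in names(segs)) {
    fs <- flows$segments[[nm]]
    expected <- fs$Q_base + sum(fs$steps$Q)
    got <- fs$Q_distal
    scale <- max(abs(expected), abs(got), .Machine$double.xmin)
    err <- max(err, abs(expected - got) / scale)
  }
  # outlet = sum of all inlet base flows
  total_in <- sum(vapply(flows$segments, `[[`, numeric(1), "Q_base"))
  scale <- max(abs(total_in), abs(flows$Q_outlet), .Machine$double.xmin)
  max(err, abs(total_in - flows$Q_outlet) / scale)
}
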
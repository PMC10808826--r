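#' Parametric portal venous tree geometry
#'
#' The portal venous system is modeled as a centerline network of five named
#' vessel segments: the portal vein (PV, single outflow trunk), the superior
#' mesenteric vein (SMV), the splenic vein (SV), the left gastric vein (LGV)
#' and the inferior mesenteric vein (IMV). Each segment carries a
#' piecewise-linear radius profile sampled at normalized arclength points
#' (0 = proximal/inflow end, 1 = distal end) and a tortuosity (centerline
#' path length over endpoint straight-line distance). Junctions are point
#' nodes: tributaries attach to a parent segment at a normalized arclength
#' position, and junction wall patches are attributed to the parent segment.
#'
#' The three anatomical types differ in where the LGV and IMV drain:
#' Type 1 LGV -> SV and IMV -> SV; Type 2 LGV -> PV and IMV -> SV;
#' Type 3 LGV -> SV and IMV -> SMV. Attachments to the SV are placed at its
#' distal (splenoportal confluence) end; attachments to the PV or SMV are
#' interior (mid-length), so e.g. in Type 3 the distal half of the SMV
#' carries the IMV flow in addition to its own.
#'
#' @name geometry
NULL

VEIN_NAMES <- c("PV", "SMV", "SV", "LGV", "IMV")

#' Default dimensions for veins not individually sampled per patient
#'
#' Lengths and diameters (meters) of the PV, SMV, LGV and IMV used when a
#' cohort patient record specifies only PV/SV measurements. Values are
#' plausible for adult splenomegalic portal hypertension.
#'
#' @return named list with `diameters`, `lengths`, `tortuosities` (named
#'   numeric vectors over the five veins; PV/SV entries are placeholders
#'   overridden per patient).
#' @export
default_vessel_params <- function() {
  list(
    diameters = c(PV = 0.013, SMV = 0.010, SV = 0.012, LGV = 0.005, IMV = 0.006),
    lengths = c(PV = 0.070, SMV = 0.080, SV = 0.100, LGV = 0.040, IMV = 0.060),
    tortuosities = c(PV = 1.0, SMV = 1.1, SV = 1.3, LGV = 1.1, IMV = 1.1)
  )
}

new_segment <- function(id, name, proximal_node, distal_node, length,
                        radius_x, radius_r, tortuosity, role,
                        parent = NA_character_, attach_s = NA_real_) {
  seg <- list(
    id = id, name = name, proximal_node = proximal_node,
    distal_node = distal_node, length = length,
    radius_x = radius_x, radius_r = radius_r,
    tortuosity = tortuosity, role = role,
    parent = parent, attach_s = attach_s
  )
  class(seg) <- "vessel_segment"
  seg
}

validate_segment <- function(seg) {
  if (!is.numeric(seg$length) || seg$length <= 0)
    stop("segment '", seg$name, "': length must be > 0", call. = FALSE)
  if (any(seg$radius_r <= 0))
    stop("segment '", seg$name, "': all radii must be > 0", call. = FALSE)
  if (seg$tortuosity < 1)
    stop("segment '", seg$name, "': tortuosity must be >= 1", call. = FALSE)
  if (length(seg$radius_x) != length(seg$radius_r) ||
      is.unsorted(seg$radius_x) ||
      seg$radius_x[1] != 0 || seg$radius_x[length(seg$radius_x)] != 1)
    stop("segment '", seg$name,
         "': radius profile must be sampled on sorted points spanning [0,1]",
         call. = FALSE)
  invisible(seg)
}

#' Local vessel radius at a normalized arclength position
#'
#' @param segment a vessel segment of a portal tree.
#' @param x normalized arclength in \[0,1\] (vectorized).
#' @return radius in meters, linearly interpolated between profile samples.
#' @export
radius_at <- function(segment, x) {
  approx(segment$radius_x, segment$radius_r, xout = x, rule = 2)$y
}

#' Build a preoperative portal venous tree
#'
#' Constructs the five-segment portal tree (PV, SMV, SV, LGV, IMV) with the
#' attachment topology of the requested anatomical type. All dimensions are
#' SI (meters). The returned tree is preoperative: the SMV, SV, LGV and IMV
#' are inflow segments and the distal end of the PV is the single outlet.
#'
#' @param diameters named numeric vector of vessel diameters (m) for
#'   `PV, SMV, SV, LGV, IMV`.
#' @param lengths named numeric vector of centerline lengths (m), same names.
#' @param tortuosities named numeric vector (>= 1), same names; defaults to
#'   straight vessels.
#' @param anatomy_type integer 1, 2 or 3 (LGV/IMV attachment configuration).
#' @return an object of class `portal_tree`.
#' @examples
#' p <- default_vessel_params()
#' tree <- build_tree(p$diameters, p$lengths, p$tortuosities, anatomy_type = 1)
#' @export
build_tree <- function(diameters, lengths,
                       tortuosities = setNames(rep(1, 5), VEIN_NAMES),
                       anatomy_type = 1L) {
  anatomy_type <- as.integer(anatomy_type)
  if (!anatomy_type %in% 1:3)
    stop("anatomy_type must be 1, 2 or 3", call. = FALSE)
  for (nm in VEIN_NAMES) {
    if (is.na(diameters[nm]) || diameters[nm] <= 0)
      stop("diameter of ", nm, " must be positive", call. = FALSE)
    if (is.na(lengths[nm]) || lengths[nm] <= 0)
      stop("length of ", nm, " must be positive", call. = FALSE)
  }
  tort <- setNames(rep(1, 5), VEIN_NAMES)
  tort[names(tortuosities)] <- tortuosities

  # attachment map per anatomy type (parent segment, normalized position)
  lgv_parent <- if (anatomy_type == 2L) c("PV", 0.5) else c("SV", 1.0)
  imv_parent <- if (anatomy_type == 3L) c("SMV", 0.5) else c("SV", 1.0)

  seg <- function(name, role, prox, dist, parent = NA_character_,
                  attach_s = NA_real_) {
    r <- diameters[[name]] / 2
    validate_segment(new_segment(
      id = name, name = name, proximal_node = prox, distal_node = dist,
      length = lengths[[name]], radius_x = c(0, 1), radius_r = c(r, r),
      tortuosity = tort[[name]], role = role,
      parent = parent, attach_s = attach_s
    ))
  }

  segments <- list(
    PV  = seg("PV", "internal", "confluence", "outlet"),
    SMV = seg("SMV", "inlet", "SMV_in", "confluence", parent = "PV", attach_s = 0),
    SV  = seg("SV", "inlet", "SV_in", "confluence", parent = "PV", attach_s = 0),
    LGV = seg("LGV", "inlet", "LGV_in", "J_LGV",
              parent = lgv_parent[1], attach_s = as.numeric(lgv_parent[2])),
    IMV = seg("IMV", "inlet", "IMV_in", "J_IMV",
              parent = imv_parent[1], attach_s = as.numeric(imv_parent[2]))
  )

  tree <- structure(
    list(segments = segments, anatomy_type = anatomy_type,
         state = "preoperative", outlet_node = "outlet"),
    class = "portal_tree"
  )
  validate_tree(tree)
}

#' Validate a portal tree's topology and invariants
#'
#' Checks connectivity (every segment reaches the PV outlet through parent
#' links with no cycles), the single-outlet property, the anatomy-type
#' attachment rules, and the postoperative stump contract (exactly three
#' inlets, SV closed).
#'
#' @param tree a `portal_tree`.
#' @return the tree, invisibly usable; stops with a message on violation.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "portal_tree"))
  segs <- tree$segments
  for (s in segs) validate_segment(s)
  if (!identical(sort(names(segs)), sort(VEIN_NAMES)))
    stop("tree must contain exactly the segments ",
         paste(VEIN_NAMES, collapse = ", "), call. = FALSE)
  # acyclic connectivity: walk parents to the PV
  for (nm in names(segs)) {
    seen <- character()
    cur <- nm
    while (!is.na(segs[[cur]]$parent)) {
      if (cur %in% seen) stop("cycle detected at segment ", cur, call. = FALSE)
      seen <- c(seen, cur)
      cur <- segs[[cur]]$parent
      if (is.null(segs[[cur]]))
        stop("segment ", nm, " has unknown parent", call. = FALSE)
    }
    if (cur != "PV")
      stop("segment ", nm, " does not drain to the PV outlet", call. = FALSE)
  }
  at <- tree$anatomy_type
  exp_lgv <- if (at == 2L) "PV" else "SV"
  exp_imv <- if (at == 3L) "SMV" else "SV"
  if (segs$LGV$parent != exp_lgv || segs$IMV$parent != exp_imv)
    stop("attachments inconsistent with anatomy type ", at, call. = FALSE)
  inl <- inlet_names(tree)
  if (tree$state == "preoperative") {
    if (!setequal(inl, c("SMV", "SV", "LGV", "IMV")))
      stop("preoperative tree must have 4 inlets", call. = FALSE)
  } else if (tree$state == "postoperative") {
    if (segs$SV$role != "stump")
      stop("postoperative tree must have a stump SV", call. = FALSE)
    if (!setequal(inl, c("SMV", "LGV", "IMV")))
      stop("postoperative tree must have 3 inlets (SMV, LGV, IMV)",
           call. = FALSE)
  } else stop("unknown tree state: ", tree$state, call. = FALSE)
  tree
}

#' @noRd
inlet_names <- function(tree) {
  names(Filter(function(s) s$role == "inlet", tree$segments))
}

#' Virtual splenectomy: close the splenic vein stump
#'
#' Mimics surgical ligation of the residual splenic vein near the splenic
#' hilum: the SV's proximal end is closed (role becomes `stump`, it carries
#' no inflow) and every other field of every segment is untouched, under the
#' assumption that splenectomy does not alter the morphology of the rest of
#' the portal venous system.
#'
#' @param tree a preoperative `portal_tree`.
#' @return a new postoperative `portal_tree`.
#' @export
apply_splenectomy <- function(tree) {
  stopifnot(inherits(tree, "portal_tree"))
  if (tree$state != "preoperative")
    stop("tree is already postoperative", call. = FALSE)
  tree$segments$SV$role <- "stump"
  tree$state <- "postoperative"
  validate_tree(tree)
}

#' Discretize the tree's lateral surface into strips
#'
#' Splits every segment into axial strips of width at most `dx` along the
#' centerline; each strip's area is the local perimeter `2*pi*R(x)` times
#' the axial step (midpoint rule), which is exact for constant-radius and
#' linearly tapered profiles. Inlet/outlet caps and the closed stump tip
#' have no lateral area and are not represented.
#'
#' @param tree a `portal_tree`.
#' @param dx axial strip width in meters (default 1 mm); must be smaller
#'   than the shortest segment.
#' @return a data.frame with columns `segment_id`, `axial_position`
#'   (normalized strip center), `width_m`, `radius_m`, `area_m2`.
#' @export
discretize_surface <- function(tree, dx = 0.001) {
  stopifnot(inherits(tree, "portal_tree"))
  if (dx <= 0) stop("dx must be > 0", call. = FALSE)
  min_len <- min(vapply(tree$segments, `[[`, numeric(1), "length"))
  if (dx >= min_len)
    stop("dx (", dx, " m) must be smaller than the shortest segment (",
         min_len, " m)", call. = FALSE)
  out <- lapply(tree$segments, function(seg) {
    n <- max(1L, ceiling(seg$length / dx))
    h <- seg$length / n
    x <- (seq_len(n) - 0.5) / n
    r <- radius_at(seg, x)
    data.frame(
      segment_id = seg$id, axial_position = x, width_m = h,
      radius_m = r, area_m2 = 2 * pi * r * h,
      stringsAsFactors = FALSE
    )
  })
  strips <- do.call(rbind, out)
  rownames(strips) <- NULL
  strips
}

#' Endpoint straight-line distance of a segment
#'
#' A tortuous vessel's endpoints are closer than its centerline length;
#' this scalar descriptor is the straight-line (chord) distance between the
#' segment's endpoints, `length / tortuosity`.
#'
#' @param segment a vessel segment.
#' @return distance in meters.
#' @export
distance_metric <- function(segment) {
  segment$length / segment$tortuosity
}

TREE_SCHEMA <- "portal-tree/1"

#' Write a portal tree to a JSON file
#'
#' @param tree a `portal_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  doc <- list(
    schema = TREE_SCHEMA,
    anatomy_type = tree$anatomy_type,
    state = tree$state,
    outlet_node = tree$outlet_node,
    segments = lapply(unname(tree$segments), function(s) {
      s[c("id", "name", "proximal_node", "distal_node", "length",
          "radius_x", "radius_r", "tortuosity", "role", "parent", "attach_s")]
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a portal tree from a JSON file
#'
#' @param path path to a file written by [write_tree()] (schema
#'   `portal-tree/1`).
#' @return a validated `portal_tree`.
#' @export
read_tree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (f in c("schema", "anatomy_type", "state", "segments"))
    if (is.null(doc[[f]]))
      stop("portal tree file is missing required field '", f, "'",
           call. = FALSE)
  if (!identical(doc$schema, TREE_SCHEMA))
    stop("unsupported tree schema '", doc$schema, "'", call. = FALSE)
  segments <- list()
  for (s in doc$segments) {
    for (f in c("id", "name", "proximal_node", "distal_node", "length",
                "radius_x", "radius_r", "tortuosity", "role"))
      if (is.null(s[[f]]))
        stop("segment entry is missing required field 'segments.", f, "'",
             call. = FALSE)
    segments[[s$name]] <- new_segment(
      id = s$id, name = s$name, proximal_node = s$proximal_node,
      distal_node = s$distal_node, length = s$length,
      radius_x = unlist(s$radius_x), radius_r = unlist(s$radius_r),
      tortuosity = s$tortuosity, role = s$role,
      parent = if (is.null(s$parent) || is.na(s$parent)) NA_character_
               else s$parent,
      attach_s = if (is.null(s$attach_s) || is.na(s$attach_s)) NA_real_
                 else as.numeric(s$attach_s)
    )
  }
  tree <- structure(
    list(segments = segments, anatomy_type = as.integer(doc$anatomy_type),
         state = doc$state,
         outlet_node = if (is.null(doc$outlet_node)) "outlet"
                       else doc$outlet_node),
    class = "portal_tree"
  )
  validate_tree(tree)
}

#' @export
print.portal_tree <- function(x, ...) {
  cat("Portal venous tree (anatomy type ", x$anatomy_type, ", ",
      x$state, ")\n", sep = "")
  for (s in x$segments) {
    cat(sprintf(
      "  %-3s %-8s L=%5.1f mm  D=%4.1f mm  tort=%.2f%s\n",
      s$name, s$role, s$length * 1e3, 2 * mean(s$radius_r) * 1e3,
      s$tortuosity,
      if (!is.na(s$parent))
        paste0("  -> ", s$parent, "@", format(s$attach_s)) else "  (outlet)"
    ))
  }
  invisible(x)
}
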
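# Synthetic branching-tube phantoms: ground-truth vascular trees generated in
# continuous mm space, rasterized into Doppler-like voxel grids. Generating
# geometry first and discretizing second keeps the truth record independent of
# voxel spacing, so tests can separate algorithm error from discretization
# error.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom generator configuration
#'
#' @param generations Number of binary branching generations (0 = bare tube,
#'   capped at 8 to keep volumes desk-scale).
#' @param trunk_length_mm,trunk_radius_mm Trunk geometry (mm).
#' @param length_decay,radius_decay Per-generation multipliers in (0, 1].
#' @param branch_angle_deg Angle between a child branch and its parent axis.
#' @param n_crossings Number of planted X-crossings (a perpendicular bridge
#'   through a segment midpoint; a strict binary tree cannot produce the
#'   degree-4 skeleton voxels that define crossing points).
#' @param vessel_amplitude Doppler amplitude assigned to vessel voxels.
#' @param noise_sd SD of additive Gaussian amplitude noise (clipped at 0).
#' @param seed RNG seed; fixed seed gives a bit-identical phantom and raster.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(generations = 2, trunk_length_mm = 10,
                           trunk_radius_mm = 1, length_decay = 0.75,
                           radius_decay = 0.85, branch_angle_deg = 35,
                           n_crossings = 0, vessel_amplitude = 100,
                           noise_sd = 0, seed = 1) {
  stopifnot(generations >= 0, generations <= 8, trunk_length_mm > 0,
            trunk_radius_mm > 0, length_decay > 0, length_decay <= 1,
            radius_decay > 0, radius_decay <= 1, branch_angle_deg > 0,
            branch_angle_deg < 90, n_crossings >= 0, vessel_amplitude > 0,
            noise_sd >= 0)
  structure(list(generations = as.integer(generations),
                 trunk_length_mm = trunk_length_mm,
                 trunk_radius_mm = trunk_radius_mm,
                 length_decay = length_decay, radius_decay = radius_decay,
                 branch_angle_deg = branch_angle_deg,
                 n_crossings = as.integer(n_crossings),
                 vessel_amplitude = vessel_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

unit <- function(v) v / sqrt(sum(v^2))

# orthonormal pair perpendicular to unit vector d
perp_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(pracma_cross(d, ref))
  v <- pracma_cross(d, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a ground-truth branching vascular tree
#'
#' Builds a binary tree of straight tube segments in continuous mm space:
#' the trunk points along +z and each generation splits into two children
#' rotated by the branch angle at a seeded random azimuth. Optional
#' X-crossings are planted as perpendicular bridges through segment midpoints.
#' The truth record counts the trunk origin as a tip, matching the skeleton
#' end-point convention.
#'
#' @param config A [phantom_config()].
#' @return A `tree_phantom`: `segments` data.frame (x0..z1, radius_mm, parent,
#'   generation, role) and `truth` list (n_tips, n_bifurcation_nodes,
#'   n_crossing_nodes, centerline_length_mm, mean_radius_mm).
#' @export
generate_tree <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    segs <- list()
    add_seg <- function(p0, p1, r, parent, gen, role = "tree") {
      segs[[length(segs) + 1]] <<- data.frame(
        x0 = p0[1], y0 = p0[2], z0 = p0[3],
        x1 = p1[1], y1 = p1[2], z1 = p1[3],
        radius_mm = r, parent = parent, generation = gen, role = role,
        stringsAsFactors = FALSE)
      length(segs)
    }
    trunk_tip <- c(0, 0, config$trunk_length_mm)
    trunk_id <- add_seg(c(0, 0, 0), trunk_tip, config$trunk_radius_mm, 0L, 0L)
    frontier <- list(list(id = trunk_id, tip = trunk_tip, dir = c(0, 0, 1)))
    if (config$generations >= 1) {
      for (g in seq_len(config$generations)) {
        len <- config$trunk_length_mm * config$length_decay^g
        rad <- config$trunk_radius_mm * config$radius_decay^g
        ang <- config$branch_angle_deg * pi / 180
        nxt <- list()
        for (node in frontier) {
          b <- perp_basis(node$dir)
          phi <- stats::runif(1, 0, 2 * pi)
          for (s in c(0, pi)) {
            w <- cos(phi + s) * b$u + sin(phi + s) * b$v
            cdir <- unit(cos(ang) * node$dir + sin(ang) * w)
            ctip <- node$tip + len * cdir
            cid <- add_seg(node$tip, ctip, rad, node$id, g)
            nxt[[length(nxt) + 1]] <- list(id = cid, tip = ctip, dir = cdir)
          }
        }
        frontier <- nxt
      }
    }
    n_tree <- length(segs)
    if (config$n_crossings > 0) {
      for (k in seq_len(config$n_crossings)) {
        host <- sample.int(n_tree, 1)
        h <- segs[[host]]
        a <- c(h$x0, h$y0, h$z0); bb <- c(h$x1, h$y1, h$z1)
        mid <- (a + bb) / 2
        d <- unit(bb - a)
        pb <- perp_basis(d)
        phi <- stats::runif(1, 0, 2 * pi)
        w <- cos(phi) * pb$u + sin(phi) * pb$v
        half <- sqrt(sum((bb - a)^2)) / 2
        add_seg(mid - half * w, mid + half * w, h$radius_mm, host,
                h$generation, role = "bridge")
      }
    }
    segments <- do.call(rbind, segs)
    g <- config$generations
    leaves <- 2^g
    truth <- list(
      n_tips = leaves + 1L + 2L * config$n_crossings,
      n_bifurcation_nodes = if (g >= 1) as.integer(2^g - 1) else 0L,
      n_crossing_nodes = config$n_crossings,
      centerline_length_mm = sum(segment_lengths(segments)),
      mean_radius_mm = stats::weighted.mean(segments$radius_mm,
                                            segment_lengths(segments)))
    structure(list(segments = segments, truth = truth, config = config),
              class = "tree_phantom")
  })
}

segment_lengths <- function(segments) {
  sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2 +
       (segments$z1 - segments$z0)^2)
}

#' Rasterize a tree phantom into a Doppler-like voxel grid
#'
#' Voxels whose centre lies within a segment's radius of its centreline get
#' the vessel amplitude; all voxels receive seeded additive Gaussian noise
#' clipped at zero. The mask spans the whole grid box (tree bounding region
#' plus margin).
#'
#' @param tree A [generate_tree()] result.
#' @param spacing_mm Isotropic voxel edge length (mm). Should be at most the
#'   smallest tube radius; thinner tubes trigger a provenance warning.
#' @param margin_mm Padding added around the tree bounding box.
#' @return List with `grid` ([voxel_grid()]), `mask` ([placental_mask()]) and
#'   `provenance` (spacing, seed, warnings).
#' @export
rasterize_tree <- function(tree, spacing_mm, margin_mm = NULL) {
  stopifnot(inherits(tree, "tree_phantom"), spacing_mm > 0)
  cfg <- tree$config
  segs <- tree$segments
  rmax <- max(segs$radius_mm)
  if (is.null(margin_mm)) margin_mm <- rmax + 2 * spacing_mm
  warnings <- character()
  if (min(segs$radius_mm) < spacing_mm)
    warnings <- c(warnings, sprintf(
      "tube radius %.3g mm below voxel spacing %.3g mm: tubes may be unresolved",
      min(segs$radius_mm), spacing_mm))
  pts <- rbind(as.matrix(segs[, c("x0", "y0", "z0")]),
               as.matrix(segs[, c("x1", "y1", "z1")]))
  lo <- apply(pts, 2, min) - margin_mm
  hi <- apply(pts, 2, max) + margin_mm
  dims <- pmax(3L, as.integer(ceiling((hi - lo) / spacing_mm)) + 1L)
  fg <- array(FALSE, dim = dims)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * spacing_mm)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    a <- c(s$x0, s$y0, s$z0); b <- c(s$x1, s$y1, s$z1)
    r <- s$radius_mm
    slo <- pmin(a, b) - r - spacing_mm
    shi <- pmax(a, b) + r + spacing_mm
    ix <- lapply(1:3, function(d) which(ax[[d]] >= slo[d] & ax[[d]] <= shi[d]))
    if (any(lengths(ix) == 0)) next
    gx <- expand.grid(x = ax[[1]][ix[[1]]], y = ax[[2]][ix[[2]]],
                      z = ax[[3]][ix[[3]]])
    p <- as.matrix(gx)
    ab <- b - a
    L2 <- sum(ab^2)
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
          (p[, 3] - a[3]) * ab[3]) / L2
    t <- pmin(1, pmax(0, t))
    dx <- p[, 1] - (a[1] + t * ab[1])
    dy <- p[, 2] - (a[2] + t * ab[2])
    dz <- p[, 3] - (a[3] + t * ab[3])
    hit <- (dx * dx + dy * dy + dz * dz) <= r * r
    if (!any(hit)) next
    idx <- as.matrix(expand.grid(ix[[1]], ix[[2]], ix[[3]]))[hit, , drop = FALSE]
    fg[idx] <- TRUE
  }
  values <- array(0, dim = dims)
  with_seed(cfg$seed, {
    if (cfg$noise_sd > 0)
      values[] <- stats::rnorm(prod(dims), 0, cfg$noise_sd)
  })
  values[fg] <- values[fg] + cfg$vessel_amplitude
  values <- pmax(values, 0)
  grid <- voxel_grid(values, spacing_mm, origin_mm = lo)
  mask <- placental_mask(array(TRUE, dim = dims), spacing_mm)
  list(grid = grid, mask = mask,
       provenance = list(spacing_mm = spacing_mm, seed = cfg$seed,
                         vessel_amplitude = cfg$vessel_amplitude,
                         noise_sd = cfg$noise_sd, warnings = warnings))
}

#' Expected imaging markers for a tree phantom
#'
#' Translates phantom ground truth into the marker vocabulary: tips become
#' skeleton end points, bifurcation/crossing nodes keep their names, total
#' length is the summed centreline length, mean thickness the length-weighted
#' mean radius, and the expected vascular volume is the summed analytic
#' cylinder volume (junction overlap ignored, so an approximation).
#'
#' @param tree A [generate_tree()] result.
#' @param spacing_mm Voxel spacing the phantom will be rasterized at (carried
#'   into the record for reference).
#' @return A list of expected marker values.
#' @export
truth_metrics <- function(tree, spacing_mm = NA_real_) {
  stopifnot(inherits(tree, "tree_phantom"))
  segs <- tree$segments
  len <- segment_lengths(segs)
  list(end_points = tree$truth$n_tips,
       bifurcation_points = tree$truth$n_bifurcation_nodes,
       crossing_points = tree$truth$n_crossing_nodes,
       total_length_mm = sum(len),
       mean_thickness_mm = tree$truth$mean_radius_mm,
       upvv_cm3 = sum(pi * segs$radius_mm^2 * len) / 1000,
       spacing_mm = spacing_mm)
}
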
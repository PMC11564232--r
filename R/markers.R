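# Core imaging computation: utero-placental vascular volume (uPVV) by
# thresholded voxel summation inside the placental mask, vascular skeleton
# (uPVS) by topology-preserving iterative thinning with peel-depth recording,
# skeleton-voxel classification by 26-neighbour count, and the marker summary.

#' Placental volume from a mask
#'
#' PV is the volume of the whole placental segment (trophoblast plus
#' vasculature): set-voxel count times voxel volume.
#'
#' @param mask A [placental_mask()].
#' @param spacing_mm Optional override of the mask's spacing.
#' @return Volume in cm^3.
#' @export
compute_pv <- function(mask, spacing_mm = mask$spacing_mm) {
  stopifnot(inherits(mask, "placental_mask"))
  n <- sum(mask$include)
  if (n == 0) warning("empty mask: placental volume is 0")
  n * spacing_mm^3 / 1000
}

#' Extract the utero-placental vascular volume
#'
#' Erases all Doppler signal outside the placental segment, then thresholds:
#' a voxel is vascular iff its amplitude is strictly greater than `threshold`
#' and it lies inside the mask. The uPVV is the summed volume of those voxels.
#'
#' @param grid A [voxel_grid()].
#' @param mask A [placental_mask()] of the same shape.
#' @param threshold Amplitude cutoff (strict `>`); must be supplied — the
#'   rendering threshold of the original system is unpublished, so it is an
#'   explicit, logged parameter.
#' @return A `vascular_volume`: binary `voxels` array, `upvv_cm3`,
#'   `threshold`, `spacing_mm`.
#' @export
extract_upvv <- function(grid, mask, threshold) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "placental_mask"))
  check_same_shape(grid, mask)
  if (missing(threshold) || !is.numeric(threshold) || length(threshold) != 1L)
    stop("`threshold` is mandatory (single numeric amplitude)")
  voxels <- (grid$values > threshold) & mask$include
  structure(list(voxels = voxels,
                 upvv_cm3 = sum(voxels) * grid$spacing_mm^3 / 1000,
                 threshold = threshold, spacing_mm = grid$spacing_mm),
            class = "vascular_volume")
}

#' Skeletonize a vascular volume
#'
#' Repeatedly peels the outermost voxel layer off the vascular volume until a
#' one-voxel-wide centreline network remains. The peel is realised as
#' round-based sequential thinning with six directional sub-iterations: a
#' border voxel is deleted only when deletion preserves local (26, 6)
#' topology, the voxel is not a line end, and the opposite direction has
#' foreground behind it (so one-voxel-thick structures are never consumed
#' along their axis). One-voxel background tunnels are pre-filled and
#' residual two-voxel-wide ribbons are reduced by a connectivity-preserving
#' cleanup, so the 26-connected component count is exactly preserved
#' throughout. Each surviving voxel records a peel depth: the round at which
#' it was first exposed to the background minus one, i.e. the number of
#' voxel layers peeled off before reaching it (0 for input that is already
#' one voxel wide).
#'
#' By default the raw skeleton is then canonicalized at graph level
#' (deterministically, to a fixed point): voxel-scale cycles ("bubbles"
#' around discretization tunnels) are broken, clusters of adjacent junction
#' voxels are consolidated onto a single branch-point voxel of the original
#' volume, and terminal spurs no longer than the local tube diameter are
#' pruned. Set `prune_spurs = FALSE` for the raw thinning output; see the
#' methods vignette for the full rules.
#'
#' @param vv A [extract_upvv()] result, or a 3D logical array plus
#'   `spacing_mm`.
#' @param spacing_mm Required when `vv` is a bare array.
#' @param prune_spurs Remove radius-scale terminal spurs (default TRUE).
#' @return A `skeleton`: `voxels` (logical array), `peel_depth` (integer
#'   array), `klass` (character array, filled by [classify_skeleton()]),
#'   `spacing_mm`, `n_rounds`.
#' @export
skeletonize <- function(vv, spacing_mm = NULL, prune_spurs = TRUE) {
  if (inherits(vv, "vascular_volume")) {
    voxels <- vv$voxels
    spacing_mm <- vv$spacing_mm
  } else {
    voxels <- vv
    if (is.null(spacing_mm)) stop("`spacing_mm` required for a bare array")
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!is.logical(voxels)) storage.mode(voxels) <- "logical"
  res <- thin_volume_cpp(voxels, dim(voxels))
  sk <- res$skeleton
  if (prune_spurs) sk <- tidy_skeleton(sk, res$peel_depth, voxels)
  structure(list(voxels = sk, peel_depth = res$peel_depth,
                 klass = NULL, spacing_mm = spacing_mm,
                 n_rounds = res$rounds),
            class = "skeleton")
}

NB26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
NB26 <- NB26[rowSums(abs(NB26)) > 0, ]

sk_neighbours <- function(sk, dims, i) {
  co <- arrayInd(i, dims)
  nb <- sweep(NB26, 2, as.integer(co), `+`)
  ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
    nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
  nbi <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
    dims[1] * dims[2] * (nb[ok, 3] - 1)
  nbi[sk[nbi]]
}

# bounded BFS through the skeleton, excluding voxel `excl`
sk_reachable <- function(sk, dims, from, targets, excl, max_steps) {
  if (!length(targets)) return(TRUE)
  if (!length(from) || is.na(from)) return(FALSE)
  seen <- c(from, excl)
  frontier <- from
  for (step in seq_len(max_steps)) {
    nxt <- integer()
    for (f in frontier) nxt <- c(nxt, sk_neighbours(sk, dims, f))
    nxt <- setdiff(unique(nxt), seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    if (all(targets %in% seen)) return(TRUE)
    frontier <- nxt
  }
  all(targets %in% seen)
}


adj26 <- function(dims, i, j) {
  a <- arrayInd(i, dims); b <- arrayInd(j, dims)
  all(abs(a - b) <= 1) && i != j
}

# Replace a junction cluster by a hub voxel plus one-voxel bridges so that
# exactly one voxel keeps degree >= 3. Returns the replacement voxel indices
# or NULL if no valid configuration exists in the original volume.
consolidate_hub <- function(sk, dims, orig, clv, ext) {
  eco <- arrayInd(ext, dims)
  lo <- pmax(apply(eco, 2, min) - 1L, 1L)
  hi <- pmin(apply(eco, 2, max) + 1L, dims)
  box <- integer()
  for (zz in lo[3]:hi[3]) for (yy in lo[2]:hi[2]) for (xx in lo[1]:hi[1]) {
    i <- xx + dims[1] * (yy - 1) + dims[1] * dims[2] * (zz - 1)
    if (orig[i] && !i %in% ext) box <- c(box, i)
  }
  sk0 <- sk
  sk0[clv] <- FALSE  # skeleton without the cluster
  for (h in sort(box)) {
    direct <- ext[vapply(ext, function(e) adj26(dims, h, e), logical(1))]
    need <- setdiff(ext, direct)
    bridges <- integer()
    ok <- TRUE
    for (e in need) {
      bc <- sort(setdiff(box[vapply(box, function(b)
        adj26(dims, b, e) && adj26(dims, b, h), logical(1))], c(h, bridges)))
      picked <- NA_integer_
      for (b in bc) {
        # a bridge must touch only its arm and the hub (plus no other
        # bridge), or it would create junctions elsewhere
        nb_sk <- sk_neighbours(sk0, dims, b)
        if (!all(nb_sk %in% c(e, h))) next
        if (any(vapply(bridges, function(bb) adj26(dims, b, bb), logical(1)))) next
        if (any(vapply(setdiff(ext, e), function(ee) adj26(dims, b, ee),
                       logical(1)))) next
        picked <- b
        break
      }
      if (is.na(picked)) { ok <- FALSE; break }
      bridges <- c(bridges, picked)
    }
    if (!ok) next
    # the hub itself must not touch stray skeleton voxels
    nb_h <- sk_neighbours(sk0, dims, h)
    if (!all(nb_h %in% ext)) next
    return(c(h, bridges))
  }
  NULL
}

# Canonicalize the raw thinning output at graph level. Rasterizing tubes at
# voxel scale creates three artifact classes that the voxel-degree
# classification is sensitive to:
#   (a) voxel-scale cycles ("bubbles"): doubled strands around
#       discretization tunnels; broken by deleting the longest degree-2 run
#       of any short cycle (removal from a cycle never disconnects);
#   (b) junction clusters: adjacent junction voxels that are one anatomical
#       branch point; consolidated onto a single voxel of the original
#       volume adjacent to all arms, or dropped when their neighbours stay
#       connected without them;
#   (c) terminal spurs no longer than the local tube diameter: surface
#       bumps, not resolvable branches.
# All rules are deterministic (lexicographic order, iterated to a fixed
# point). The cycle-length bound separates voxel-scale artifacts from
# genuine anastomotic loops, which are left untouched.
tidy_skeleton <- function(sk, depth, orig = NULL, max_cycle = 24L) {
  dims <- dim(sk)

  shortest_cycle <- function(sk, counts, skip) {
    # BFS from each junction/vertex edge to find one cycle of length <=
    # max_cycle; returns the cycle voxel sequence or NULL
    for (v in setdiff(which(sk & counts >= 3), skip)) {
      nbs <- sk_neighbours(sk, dims, v)
      for (a in nbs) {
        # find path a -> v avoiding the direct edge and v itself at first step
        prevmap <- new.env()
        assign(as.character(a), 0, envir = prevmap)
        frontier <- a
        found <- FALSE
        for (step in seq_len(max_cycle)) {
          nxt <- integer()
          for (f in frontier) {
            for (u in sk_neighbours(sk, dims, f)) {
              if (u == v && f == a) next  # skip the direct edge
              key <- as.character(u)
              if (!is.null(prevmap[[key]])) next
              assign(key, f, envir = prevmap)
              if (u == v) { found <- TRUE; break }
              nxt <- c(nxt, u)
            }
            if (found) break
          }
          if (found) break
          if (!length(nxt)) break
          frontier <- sort(nxt)
        }
        if (found) {
          path <- v
          cur <- get(as.character(v), envir = prevmap)
          while (cur != 0) {
            path <- c(path, cur)
            cur <- get(as.character(cur), envir = prevmap)
          }
          return(path)  # cycle: v ... a (v adjacent a closes it)
        }
      }
    }
    NULL
  }

  repeat {
    changed <- FALSE
    counts <- neighbour_counts_cpp(sk, dims)

    # (c) terminal spurs (run first: with original peel depths) no longer than the local radius
    counts <- neighbour_counts_cpp(sk, dims)
    for (e in which(sk & counts == 1)) {
      if (!sk[e]) next
      chain <- integer(); cur <- e; prev <- 0L
      repeat {
        nbi <- sk_neighbours(sk, dims, cur)
        if (cur != e && length(nbi) >= 3) {
          # shorter than the local tube diameter: unresolvable as a branch
          if (length(chain) <= 2 * (depth[cur] + 1)) {
            sk[chain] <- FALSE
            changed <- TRUE
          }
          break
        }
        chain <- c(chain, cur)
        nxt <- setdiff(nbi, c(prev, chain))
        if (length(nxt) != 1 || length(chain) > 64) break
        prev <- cur; cur <- nxt
      }
    }

    # (a) break short cycles by removing their longest degree-2 run
    counts <- neighbour_counts_cpp(sk, dims)
    skip <- integer()
    repeat {
      cyc <- shortest_cycle(sk, counts, skip)
      if (is.null(cyc)) break
      deg2 <- counts[cyc] == 2
      if (!any(deg2)) { skip <- c(skip, cyc[1]); next }
      # maximal runs of degree-2 voxels along the (circular) cycle
      n <- length(cyc)
      runs <- list(); cur <- integer()
      for (i in c(seq_len(n), seq_len(n))) {  # doubled to catch wraparound
        if (deg2[i]) cur <- c(cur, i)
        else { if (length(cur)) runs[[length(runs) + 1]] <- unique(cur); cur <- integer() }
        if (length(cur) >= n) break
      }
      if (length(cur)) runs[[length(runs) + 1]] <- unique(cur)
      if (!length(runs)) break
      lens <- vapply(runs, length, integer(1))
      pick <- which(lens == max(lens))
      mins <- vapply(runs[pick], function(r) min(cyc[r]), numeric(1))
      sk[cyc[runs[[pick[which.min(mins)]]]]] <- FALSE
      changed <- TRUE
      counts <- neighbour_counts_cpp(sk, dims)
    }

    # (b1) junction-cluster consolidation onto one original-volume voxel
    counts <- neighbour_counts_cpp(sk, dims)
    if (!is.null(orig)) {
      jx <- which(sk & counts >= 3)
      if (length(jx) >= 2) {
        jco <- arrayInd(jx, dims)
        visited <- logical(length(jx))
        for (s0 in seq_along(jx)) {
          if (visited[s0]) next
          cl <- s0; visited[s0] <- TRUE
          repeat {
            grew <- FALSE
            for (s1 in seq_along(jx)) {
              if (visited[s1]) next
              if (any(vapply(cl, function(c0)
                all(abs(jco[c0, ] - jco[s1, ]) <= 1), logical(1)))) {
                cl <- c(cl, s1); visited[s1] <- TRUE; grew <- TRUE
              }
            }
            if (!grew) break
          }
          if (length(cl) < 2) next
          clv <- jx[cl]
          ext <- setdiff(unique(unlist(lapply(clv, function(c0)
            sk_neighbours(sk, dims, c0)))), clv)
          if (length(ext) < 3) next
          eco <- arrayInd(ext, dims)
          lo <- pmax(apply(eco, 2, max) - 1L, 1L)
          hi <- pmin(apply(eco, 2, min) + 1L, dims)
          cand <- integer()
          if (all(lo <= hi)) {
            for (zz in lo[3]:hi[3]) for (yy in lo[2]:hi[2]) for (xx in lo[1]:hi[1]) {
              i <- xx + dims[1] * (yy - 1) + dims[1] * dims[2] * (zz - 1)
              if (orig[i] && !i %in% ext) cand <- c(cand, i)
            }
          }
          done <- FALSE
          if (length(cand)) {
            sk[clv] <- FALSE
            sk[min(cand)] <- TRUE
            depth[min(cand)] <- max(depth[clv])
            done <- TRUE
          } else {
            # hub + one-voxel bridges: a single voxel adjacent to all arms
            # does not exist, so look for a hub plus degree-2 bridge voxels
            # (one per unreachable arm) inside the original volume
            rep <- consolidate_hub(sk, dims, orig, clv, ext)
            if (!is.null(rep)) {
              sk[clv] <- FALSE
              sk[rep] <- TRUE
              depth[rep] <- max(depth[clv])
              done <- TRUE
            }
          }
          if (done) {
            changed <- TRUE
            counts <- neighbour_counts_cpp(sk, dims)
          }
        }
      }
    }

    # (b2) junction voxels whose neighbours stay connected without them
    counts <- neighbour_counts_cpp(sk, dims)
    for (v in which(sk & counts >= 3)) {
      if (!sk[v]) next
      nb <- sk_neighbours(sk, dims, v)
      if (length(nb) < 3) next  # degree changed since counts were taken
      sk[v] <- FALSE
      if (sk_reachable(sk, dims, nb[1], nb[-1], v, max_cycle)) {
        changed <- TRUE
        counts <- neighbour_counts_cpp(sk, dims)
      } else sk[v] <- TRUE
    }

    if (!changed) break
  }
  sk
}

#' Classify skeleton voxels by adjacency
#'
#' Each skeleton voxel gets a morphologic class from its number of 26-adjacent
#' skeleton voxels: 1 = end point, 2 = vessel point, 3 = bifurcation point,
#' 4 or more = crossing point. Isolated voxels (0 neighbours) are classed as
#' end points so the partition is exhaustive.
#'
#' @param s A [skeletonize()] result.
#' @return The skeleton with `klass` filled (character array: "end",
#'   "vessel", "bifurcation", "crossing", NA off-skeleton) and a
#'   `neighbour_count` integer array.
#' @export
classify_skeleton <- function(s) {
  stopifnot(inherits(s, "skeleton"))
  counts <- neighbour_counts_cpp(s$voxels, dim(s$voxels))
  klass <- array(NA_character_, dim = dim(s$voxels))
  on_sk <- s$voxels
  klass[on_sk & counts <= 1] <- "end"
  klass[on_sk & counts == 2] <- "vessel"
  klass[on_sk & counts == 3] <- "bifurcation"
  klass[on_sk & counts >= 4] <- "crossing"
  s$klass <- klass
  s$neighbour_count <- counts
  s
}

#' Count 26-connected components of a binary volume
#'
#' @param voxels 3D logical array.
#' @param connectivity 26 (default) or 6.
#' @return Number of connected components.
#' @export
count_components <- function(voxels, connectivity = 26) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (!is.logical(voxels)) storage.mode(voxels) <- "logical"
  label_components_cpp(voxels, dim(voxels), as.integer(connectivity))$n_components
}

#' Summarize a classified skeleton into the imaging markers
#'
#' Produces the marker set: PV, uPVV, the four voxel-class counts, total
#' vascular length (skeleton voxel count times voxel edge length), average
#' vascular thickness (mean peel depth times voxel edge length) and the three
#' branching densities (end/bifurcation/crossing points per cm^3 of uPVV).
#'
#' @param s A classified [skeletonize()] result.
#' @param vv The [extract_upvv()] result the skeleton came from.
#' @param pv_cm3 Placental volume from [compute_pv()].
#' @return One-row data.frame with columns pv_cm3, upvv_cm3, end_points,
#'   bifurcation_points, crossing_points, vessel_points, total_length_mm,
#'   avg_thickness_mm, density_end, density_bifurcation, density_crossing.
#' @export
summarize_upvs <- function(s, vv, pv_cm3) {
  stopifnot(inherits(s, "skeleton"), inherits(vv, "vascular_volume"))
  if (is.null(s$klass)) s <- classify_skeleton(s)
  n_sk <- sum(s$voxels)
  if (n_sk > 0 && vv$upvv_cm3 <= 0)
    stop("inconsistent input: non-empty skeleton with zero uPVV")
  counts <- c(end = sum(s$klass == "end", na.rm = TRUE),
              bifurcation = sum(s$klass == "bifurcation", na.rm = TRUE),
              crossing = sum(s$klass == "crossing", na.rm = TRUE),
              vessel = sum(s$klass == "vessel", na.rm = TRUE))
  stopifnot(sum(counts) == n_sk)
  avg_depth <- if (n_sk > 0) mean(s$peel_depth[s$voxels]) else 0
  dens <- function(n) if (vv$upvv_cm3 > 0) n / vv$upvv_cm3 else 0
  data.frame(pv_cm3 = pv_cm3, upvv_cm3 = vv$upvv_cm3,
             end_points = unname(counts["end"]),
             bifurcation_points = unname(counts["bifurcation"]),
             crossing_points = unname(counts["crossing"]),
             vessel_points = unname(counts["vessel"]),
             total_length_mm = n_sk * s$spacing_mm,
             avg_thickness_mm = avg_depth * s$spacing_mm,
             density_end = dens(unname(counts["end"])),
             density_bifurcation = dens(unname(counts["bifurcation"])),
             density_crossing = dens(unname(counts["crossing"])))
}

#' Run the full imaging-marker pipeline on one scan
#'
#' compute_pv -> extract_upvv -> skeletonize -> classify -> summarize.
#'
#' @inheritParams extract_upvv
#' @return The [summarize_upvs()] row, with a `provenance` attribute
#'   (threshold, spacing, voxel and skeleton counts).
#' @export
run_marker_pipeline <- function(grid, mask, threshold) {
  pv <- compute_pv(mask)
  vv <- extract_upvv(grid, mask, threshold)
  sk <- classify_skeleton(skeletonize(vv))
  out <- summarize_upvs(sk, vv, pv)
  attr(out, "provenance") <- list(threshold = threshold,
                                  spacing_mm = grid$spacing_mm,
                                  n_foreground = sum(vv$voxels),
                                  n_skeleton = sum(sk$voxels),
                                  peel_rounds = sk$n_rounds)
  out
}

#' Export a classified skeleton as a NIfTI label map
#'
#' Labels: 0 background, 1 end, 2 vessel, 3 bifurcation, 4 crossing.
#'
#' @param s A classified skeleton.
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
export_skeleton <- function(s, path) {
  stopifnot(inherits(s, "skeleton"))
  if (is.null(s$klass)) s <- classify_skeleton(s)
  lab <- array(0, dim = dim(s$voxels))
  lab[!is.na(s$klass) & s$klass == "end"] <- 1
  lab[!is.na(s$klass) & s$klass == "vessel"] <- 2
  lab[!is.na(s$klass) & s$klass == "bifurcation"] <- 3
  lab[!is.na(s$klass) & s$klass == "crossing"] <- 4
  write_volume(voxel_grid(lab, s$spacing_mm), path, dtype = "uint8")
}
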
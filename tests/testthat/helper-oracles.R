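# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: neighbour counting by explicit triple loop,
# tree-node recounting by endpoint clustering over raw segments, and
# cylinder volume in closed form.

# Brute-force 26-neighbour recount of a binary array (explicit loops).
brute_neighbour_counts <- function(v) {
  d <- dim(v)
  out <- array(0L, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!v[x, y, z]) next
    n <- 0L
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && yy >= 1 && zz >= 1 &&
          xx <= d[1] && yy <= d[2] && zz <= d[3] && v[xx, yy, zz])
        n <- n + 1L
    }
    out[x, y, z] <- n
  }
  out
}

# Independent 26-connected component count by R-level flood fill.
flood_components <- function(v) {
  d <- dim(v)
  lab <- array(0L, dim = d)
  nc <- 0L
  idx <- which(v)
  for (s in idx) {
    if (lab[s]) next
    nc <- nc + 1L
    queue <- s
    lab[s] <- nc
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xx <- co[1] + dx; yy <- co[2] + dy; zz <- co[3] + dz
        if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3])
          next
        j <- xx + d[1] * (yy - 1) + d[1] * d[2] * (zz - 1)
        if (v[j] && !lab[j]) { lab[j] <- nc; queue <- c(queue, j) }
      }
    }
  }
  nc
}

# Random blob volume: union of a few balls plus salt, guaranteed non-empty.
random_blob <- function(dim3 = c(16, 16, 16), n_balls = 3, seed = 1) {
  set.seed(seed)
  v <- array(FALSE, dim = dim3)
  for (b in seq_len(n_balls)) {
    c0 <- runif(3, 4, dim3 - 3)
    r <- runif(1, 1.5, 3.5)
    for (x in seq_len(dim3[1])) for (y in seq_len(dim3[2]))
      for (z in seq_len(dim3[3]))
        if (sum((c(x, y, z) - c0)^2) <= r^2) v[x, y, z] <- TRUE
  }
  v
}

# Recount tree-node degrees independently from the raw segment table:
# cluster segment endpoints within tolerance, count node degrees, and detect
# transversal mid-segment crossings by pairwise distance between segment
# interiors.
tree_node_recount <- function(tree, tol = 1e-6) {
  segs <- tree$segments
  pts <- rbind(as.matrix(segs[, c("x0", "y0", "z0")]),
               as.matrix(segs[, c("x1", "y1", "z1")]))
  n <- nrow(pts)
  cluster <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    nc <- nc + 1L
    hit <- which(sqrt(rowSums(sweep(pts, 2, pts[i, ])^2)) < tol)
    cluster[hit] <- nc
  }
  deg <- tabulate(cluster, nbins = nc)
  # crossings: bridge segments pass through a host mid-point; their two free
  # endpoints are already degree-1 clusters
  n_cross <- sum(segs$role == "bridge")
  list(n_tips = sum(deg == 1),
       n_bifurcations = sum(deg == 3),
       n_crossings = n_cross)
}

# tiny Y-shaped skeleton: three arms of `arm` voxels meeting at one voxel
make_voxel_y <- function(arm = 3) {
  d <- 2 * arm + 3
  v <- array(FALSE, dim = c(d, d, d))
  c0 <- arm + 2
  v[c0, c0, c0] <- TRUE
  for (k in seq_len(arm)) {
    v[c0, c0, c0 - k] <- TRUE        # stem down z
    v[c0 + k, c0, c0 + k] <- TRUE    # diagonal arm +x
    v[c0 - k, c0, c0 + k] <- TRUE    # diagonal arm -x
  }
  v
}
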
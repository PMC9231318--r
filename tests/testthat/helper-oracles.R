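# Independent oracles used across the suite.  Each deliberately uses a
# different algorithm from the implementation it checks.

# minimum-image distance by brute-force enumeration of the 27 periodic images
brute_min_image_distance <- function(a, b, box) {
  a <- a - box * floor(a / box)  # wrap into the primary cell first
  b <- b - box * floor(b / box)
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- b + c(ix, iy, iz) * box - a
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# connected components of a thresholded distance graph via boolean
# transitive closure (matrix powering), returned as a canonical partition
# label vector (labelled by smallest member)
closure_components <- function(dmat, cutoff) {
  n <- nrow(dmat)
  adj <- dmat < cutoff
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  vapply(seq_len(n), function(i) min(which(reach[i, ] > 0)), integer(1))
}

# canonical form of a partition given as a membership vector: for each
# element, the smallest index in its block
canonical_partition <- function(membership) {
  vapply(seq_along(membership), function(i)
    min(which(membership == membership[i])), integer(1))
}

# SASA by counting random surface points against all neighbours
random_point_sasa <- function(coords, radii, probe, n_pts = 1e5) {
  n <- nrow(coords)
  R <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * n_pts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * R[i], 2, coords[i, ], `+`)
    acc <- rep(TRUE, n_pts)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      acc <- acc & (d2 >= R[j]^2)
    }
    total <- total + mean(acc) * 4 * pi * R[i]^2
  }
  total
}

# minimax saddle by threshold connectivity: the smallest level t such that
# a and b are connected within {W <= t} (exact for finite grids)
threshold_minimax <- function(W, a, b, connectivity = 8) {
  nr <- nrow(W); nc <- ncol(W)
  levels <- sort(unique(as.vector(W[!is.na(W)])))
  neigh <- function(i, j) {
    if (connectivity == 8) {
      di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
    } else { di <- c(-1, 1, 0, 0); dj <- c(0, 0, -1, 1) }
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    cbind(ii[ok], jj[ok])
  }
  for (t in levels) {
    ok <- !is.na(W) & W <= t
    if (!ok[a[1], a[2]] || !ok[b[1], b[2]]) next
    seen <- matrix(FALSE, nr, nc)
    stack <- list(a)
    seen[a[1], a[2]] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      nb <- neigh(cur[1], cur[2])
      for (r in seq_len(nrow(nb))) {
        if (ok[nb[r, 1], nb[r, 2]] && !seen[nb[r, 1], nb[r, 2]]) {
          seen[nb[r, 1], nb[r, 2]] <- TRUE
          stack[[length(stack) + 1L]] <- nb[r, ]
        }
      }
    }
    if (seen[b[1], b[2]]) return(t)
  }
  Inf
}

# minimax saddle by exhaustive DFS enumeration of simple paths (small grids)
dfs_minimax <- function(W, a, b, connectivity = 8) {
  nr <- nrow(W); nc <- ncol(W)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  recurse <- function(i, j, mx) {
    mx <- max(mx, W[i, j])
    if (i == b[1] && j == b[2]) { best <<- min(best, mx); return(invisible()) }
    visited[i, j] <<- TRUE
    if (connectivity == 8) {
      di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
    } else { di <- c(-1, 1, 0, 0); dj <- c(0, 0, -1, 1) }
    for (r in seq_along(di)) {
      ii <- i + di[r]; jj <- j + dj[r]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !visited[ii, jj] && !is.na(W[ii, jj]))
        recurse(ii, jj, mx)
    }
    visited[i, j] <<- FALSE
  }
  recurse(a[1], a[2], -Inf)
  best
}
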
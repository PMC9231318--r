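# 2D free-energy landscape over (SASA, Rg) by Boltzmann inversion:
# W = -RT ln P on occupied bins, shifted so min W = 0.  Empty bins stay
# undefined (NA, conceptually +Inf); minimax paths cannot cross them.

#' 2D normalized histogram
#'
#' Counts over a regular grid, normalized to sum 1.  The default range is
#' the observed min/max of each coordinate padded by half a bin so extreme
#' points land inside bins.
#'
#' @param x,y sample coordinates, or `x` a data.frame whose first two
#'   numeric columns are used (e.g. the output of [conformation_series()],
#'   columns `sasa_nm2` and `rg_nm`).
#' @param bins integer length 2 (or 1, recycled): bins per axis.
#' @param xlim,ylim optional explicit ranges.
#' @return an object of class `mp_hist2d`: list with `P` (bins_x x bins_y
#'   matrix summing to 1), `counts`, `x_edges`, `y_edges`, `x_centers`,
#'   `y_centers`, `n`.
#' @export
histogram2d <- function(x, y = NULL, bins = c(50L, 50L),
                        xlim = NULL, ylim = NULL) {
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, logical(1))]
    y <- num[[2L]]
    x <- num[[1L]]
  }
  stopifnot(length(x) == length(y), length(x) >= 1L)
  bins <- rep_len(as.integer(bins), 2L)
  stopifnot(all(bins >= 2L))
  pad_range <- function(v, nb, lim) {
    if (!is.null(lim)) return(as.numeric(lim))
    lo <- min(v); hi <- max(v)
    w <- if (hi > lo) (hi - lo) / (nb - 1L) else 1
    c(lo - w / 2, hi + w / 2)
  }
  xr <- pad_range(x, bins[1], xlim)
  yr <- pad_range(y, bins[2], ylim)
  x_edges <- seq(xr[1], xr[2], length.out = bins[1] + 1L)
  y_edges <- seq(yr[1], yr[2], length.out = bins[2] + 1L)
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- x >= xr[1] & x <= xr[2] & y >= yr[1] & y <= yr[2]
  counts <- matrix(0L, bins[1], bins[2])
  tab <- table(factor(ix[keep], levels = seq_len(bins[1])),
               factor(iy[keep], levels = seq_len(bins[2])))
  counts[] <- as.integer(tab)
  if (sum(counts) == 0L) stop("no samples fall inside the histogram range")
  obj <- list(P = counts / sum(counts), counts = counts,
              x_edges = x_edges, y_edges = y_edges,
              x_centers = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
              y_centers = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
              n = sum(counts))
  class(obj) <- "mp_hist2d"
  obj
}

#' Boltzmann inversion of a 2D probability grid
#'
#' `W = -RT ln P` on occupied bins, shifted so the global minimum is 0.
#' Empty bins are undefined (`NA`), never zero-filled.  The pairwise
#' relation `dG = -RT ln(P2/P1)` then holds exactly for every occupied
#' bin pair.
#'
#' @param h an `mp_hist2d` (or a bare probability matrix).
#' @param temperature temperature in K.
#' @return an object of class `mp_landscape`: the histogram fields plus
#'   `W` (kcal/mol, `NA` on empty bins), `temperature`, `RT`.
#' @export
boltzmann_invert <- function(h, temperature = 310) {
  stopifnot(temperature > 0)
  if (is.matrix(h)) {
    if (sum(h) <= 0) stop("all-empty probability grid")
    h <- list(P = h / sum(h))
  }
  P <- h$P
  if (all(P == 0)) stop("all-empty probability grid")
  RT <- R_KCAL * temperature
  W <- matrix(NA_real_, nrow(P), ncol(P))
  occ <- P > 0
  W[occ] <- -RT * log(P[occ])
  W <- W - min(W, na.rm = TRUE)
  obj <- c(h[setdiff(names(h), "P")],
           list(P = P, W = W, occupied = occ,
                temperature = temperature, RT = RT))
  class(obj) <- "mp_landscape"
  obj
}

#' @export
print.mp_landscape <- function(x, ...) {
  cat(sprintf("Free-energy landscape: %d x %d bins, %d occupied, T = %g K\n",
              nrow(x$W), ncol(x$W), sum(x$occupied), x$temperature))
  cat(sprintf("  W range: 0 .. %.3f kcal/mol\n", max(x$W, na.rm = TRUE)))
  invisible(x)
}

grid_neighbours <- function(i, j, nr, nc, connectivity = 8L) {
  if (connectivity == 8L) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    di <- c(-1, 1, 0, 0); dj <- c(0, 0, -1, 1)
  }
  ii <- i + di; jj <- j + dj
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  cbind(ii[ok], jj[ok])
}

#' Locate basins (local minima) on a landscape
#'
#' Occupied bins whose W is less than or equal to that of every occupied
#' neighbour, below `max_w`.  Connected plateaus of tied minima collapse to
#' one representative, and remaining candidates within `min_separation`
#' bins (Euclidean, in bin units) of a deeper basin are dropped.
#'
#' @param ls an `mp_landscape`.
#' @param min_separation minimum bin distance between reported basins.
#' @param max_w only bins with `W < max_w` qualify (kcal/mol).
#' @param connectivity 8 (default) or 4.
#' @return data.frame sorted by W ascending: `ix`, `iy` (bin indices), `w`
#'   (kcal/mol), `x`, `y` (bin centres, when the landscape carries them).
#' @export
find_basins <- function(ls, min_separation = 3, max_w = Inf,
                        connectivity = 8L) {
  W <- ls$W
  nr <- nrow(W); nc <- ncol(W)
  cand <- which(!is.na(W) & W < max_w, arr.ind = TRUE)
  is_min <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- grid_neighbours(i, j, nr, nc, connectivity)
    wn <- W[nb]
    is_min[k] <- all(is.na(wn) | W[i, j] <= wn)
  }
  cand <- cand[is_min, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(ix = integer(0), iy = integer(0), w = numeric(0),
                      x = numeric(0), y = numeric(0)))
  # collapse connected plateaus of (numerically) tied minima
  key <- cand[, 1] + nr * (cand[, 2] - 1L)
  in_cand <- logical(nr * nc); in_cand[key] <- TRUE
  wtol <- 1e-9 * max(1, max(abs(W), na.rm = TRUE))
  assigned <- integer(nr * nc)
  group <- 0L
  for (k in seq_len(nrow(cand))) {
    if (assigned[key[k]] > 0L) next
    group <- group + 1L
    queue <- key[k]; assigned[key[k]] <- group
    w0 <- W[key[k]]
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      ci <- (cell - 1L) %% nr + 1L; cj <- (cell - 1L) %/% nr + 1L
      nb <- grid_neighbours(ci, cj, nr, nc, connectivity)
      nk <- nb[, 1] + nr * (nb[, 2] - 1L)
      nk <- nk[in_cand[nk] & assigned[nk] == 0L & abs(W[nk] - w0) <= wtol]
      if (length(nk)) { assigned[nk] <- group; queue <- c(queue, nk) }
    }
  }
  reps <- do.call(rbind, lapply(seq_len(group), function(g) {
    rows <- cand[assigned[key] == g, , drop = FALSE]
    ctr <- colMeans(rows)
    rows[which.min((rows[, 1] - ctr[1])^2 + (rows[, 2] - ctr[2])^2), ]
  }))
  reps <- matrix(reps, ncol = 2)
  w <- W[reps]
  ord <- order(w, reps[, 1], reps[, 2])
  reps <- reps[ord, , drop = FALSE]; w <- w[ord]
  keep <- logical(nrow(reps))
  for (k in seq_len(nrow(reps))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    d <- sqrt((reps[keep, 1] - reps[k, 1])^2 + (reps[keep, 2] - reps[k, 2])^2)
    keep[k] <- all(d >= min_separation)
  }
  reps <- reps[keep, , drop = FALSE]; w <- w[keep]
  data.frame(
    ix = reps[, 1], iy = reps[, 2], w = w,
    x = if (!is.null(ls$x_centers)) ls$x_centers[reps[, 1]] else NA_real_,
    y = if (!is.null(ls$y_centers)) ls$y_centers[reps[, 2]] else NA_real_
  )
}

#' Barrier between two basins by the minimax (saddle) path
#'
#' The saddle value is the minimax over connected paths of occupied bins
#' from `a` to `b`: the path whose maximum W is least.  Forward barrier is
#' `saddle - W(a)`, backward `saddle - W(b)`.  Paths cannot cross empty
#' bins; disconnected basins give an infinite barrier with a diagnostic.
#'
#' @param ls an `mp_landscape`.
#' @param a,b bin coordinates `c(ix, iy)` or single rows of the
#'   [find_basins()] data.frame.
#' @param connectivity 8 (default) or 4.
#' @return list with `saddle`, `forward`, `backward` (kcal/mol), `saddle_bin`,
#'   `path` (matrix of bin indices from a to b), `connected`, `diagnostic`.
#' @export
barrier_height <- function(ls, a, b, connectivity = 8L) {
  as_bin <- function(p) {
    if (is.data.frame(p)) c(p$ix[1], p$iy[1]) else as.integer(p[1:2])
  }
  a <- as_bin(a); b <- as_bin(b)
  W <- ls$W
  nr <- nrow(W); nc <- ncol(W)
  if (is.na(W[a[1], a[2]]) || is.na(W[b[1], b[2]]))
    stop("both basins must lie on occupied bins")
  if (all(a == b))
    return(list(saddle = W[a[1], a[2]], forward = 0, backward = 0,
                saddle_bin = a, path = matrix(a, ncol = 2),
                connected = TRUE, diagnostic = "identical basins"))
  # Dijkstra variant: path cost = maximum W along the path (incl. endpoints)
  dist <- matrix(Inf, nr, nc)
  prev <- matrix(NA_integer_, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[a[1], a[2]] <- W[a[1], a[2]]
  repeat {
    d <- dist; d[done] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    ui <- (u - 1L) %% nr + 1L; uj <- (u - 1L) %/% nr + 1L
    if (ui == b[1] && uj == b[2]) break
    nb <- grid_neighbours(ui, uj, nr, nc, connectivity)
    for (r in seq_len(nrow(nb))) {
      vi <- nb[r, 1]; vj <- nb[r, 2]
      if (is.na(W[vi, vj]) || done[vi, vj]) next
      nd <- max(dist[ui, uj], W[vi, vj])
      if (nd < dist[vi, vj]) {
        dist[vi, vj] <- nd
        prev[vi, vj] <- u
      }
    }
  }
  if (!is.finite(dist[b[1], b[2]]))
    return(list(saddle = Inf, forward = Inf, backward = Inf,
                saddle_bin = c(NA_integer_, NA_integer_),
                path = NULL, connected = FALSE,
                diagnostic = "basins not connected through occupied bins"))
  # reconstruct path b -> a
  path <- b[1] + nr * (b[2] - 1L)
  while (path[1] != a[1] + nr * (a[2] - 1L))
    path <- c(prev[path[1]], path)
  path <- cbind((path - 1L) %% nr + 1L, (path - 1L) %/% nr + 1L)
  saddle <- dist[b[1], b[2]]
  k <- which(W[path] == saddle)[1]
  list(saddle = saddle,
       forward = saddle - W[a[1], a[2]],
       backward = saddle - W[b[1], b[2]],
       saddle_bin = path[k, ],
       path = path, connected = TRUE, diagnostic = "ok")
}
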
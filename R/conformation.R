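# Conformation metrics: radius of gyration, Shrake-Rupley solvent-accessible
# surface area, and the nematic order parameter of a chain bundle.

#' Radius of gyration
#'
#' Mass-weighted RMS distance of particles from their centre of mass:
#' `sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`.
#'
#' @param coords matrix of particle coordinates (rows, nm), unwrapped.
#' @param masses particle masses (amu); equal masses if `NULL`.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n == 0L) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n, all(masses > 0))
  com <- colSums(coords * masses) / sum(masses)
  dev <- sweep(coords, 2, com)
  sqrt(sum(masses * rowSums(dev^2)) / sum(masses))
}

#' Deterministic Fibonacci-lattice points on the unit sphere
#'
#' Golden-angle spiral; the point set is deterministic so surface areas are
#' reproducible without a seed.
#'
#' @param n number of points.
#' @return an `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each particle, a deterministic unit-sphere point set is scaled to the
#' expanded radius (vdW + probe); a point is accessible if it is not inside
#' any neighbour's expanded sphere.  The accessible fraction times the
#' expanded-sphere area, summed over particles, is the SASA.  Exactly
#' coincident equal spheres count their shared surface once.
#'
#' @param coords particle coordinates (rows, nm), unwrapped.
#' @param radii van der Waals radii (nm), recycled if length 1.
#' @param probe_radius probe radius (nm), 0.14 by convention.
#' @param n_points sphere points per particle (>= 60).
#' @param occluders optional extra coordinates that occlude but contribute
#'   no area (e.g. lipid particles); `occluder_radii` must accompany it.
#' @param occluder_radii radii for `occluders`.
#' @return SASA in nm^2.
#' @export
sasa <- function(coords, radii, probe_radius = 0.14, n_points = 960L,
                 occluders = NULL, occluder_radii = NULL) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n == 0L) stop("empty selection")
  stopifnot(n_points >= 60L, probe_radius > 0)
  radii <- rep_len(radii, n)
  stopifnot(all(radii > 0))
  all_xyz <- coords
  all_R <- radii + probe_radius
  n_occ <- 0L
  if (!is.null(occluders)) {
    if (!is.matrix(occluders)) occluders <- matrix(occluders, ncol = 3)
    n_occ <- nrow(occluders)
    stopifnot(length(occluder_radii) %in% c(1L, n_occ))
    all_xyz <- rbind(coords, occluders)
    all_R <- c(all_R, rep_len(occluder_radii, n_occ) + probe_radius)
  }
  sph <- fibonacci_sphere(n_points)
  total <- 0
  m <- n + n_occ
  dmat <- as.matrix(stats::dist(all_xyz))
  tol <- 1e-10
  for (i in seq_len(n)) {
    Ri <- all_R[i]
    di <- dmat[, i]
    nb <- which(di < Ri + all_R & seq_len(m) != i)
    if (length(nb)) {
      dnb <- di[nb]; Rj <- all_R[nb]
      # complete containment buries the whole sphere; exact containment
      # ties (coincident equal spheres) yield the surface to the lower
      # index, so the shared area is counted once
      full <- dnb + Ri < Rj - tol | (abs(dnb + Ri - Rj) <= tol & nb < i)
      if (any(full)) next
      keep <- dnb + Rj > Ri + tol  # a neighbour wholly inside buries nothing
      nb <- nb[keep]; dnb <- dnb[keep]; Rj <- Rj[keep]
    }
    if (!length(nb)) { total <- total + 4 * pi * Ri^2; next }
    # a test point c_i + Ri*u is inside neighbour j iff
    # u . (c_j - c_i) > (d_ij^2 + Ri^2 - Rj^2) / (2 Ri)
    V <- t(all_xyz[nb, , drop = FALSE]) - all_xyz[i, ]
    proj <- sph %*% V                       # n_points x k dot products
    thr <- (dnb^2 + Ri^2 - Rj^2) / (2 * Ri)
    buried <- if (length(nb) == 1L) proj[, 1] > thr
      else rowSums(proj > rep(thr, each = n_points)) > 0
    total <- total + mean(!buried) * 4 * pi * Ri^2
  }
  total
}

#' Nematic order parameter of a set of axes
#'
#' Largest eigenvalue of the Q tensor `mean((3 u u' - I)/2)` over unit axes
#' `u`.  1 for perfectly parallel axes, about 0 for isotropic axes; range
#' `[-0.5, 1]`.  Invariant to flipping any axis.
#'
#' @param axes matrix of axis vectors (rows); normalised internally.
#' @return scalar S.
#' @export
nematic_order <- function(axes) {
  if (!is.matrix(axes)) axes <- matrix(axes, ncol = 3)
  if (nrow(axes) < 2L) stop("need at least 2 axes")
  nrm <- sqrt(rowSums(axes^2))
  if (any(nrm < 1e-12)) stop("degenerate (zero-length) axis")
  u <- axes / nrm
  Q <- (3 * crossprod(u) / nrow(u) - diag(3)) / 2
  max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
}

# dominant principal axis of a point cloud, sign-aligned to +z
principal_axis <- function(xyz) {
  dev <- sweep(xyz, 2, colMeans(xyz))
  cv <- crossprod(dev) / nrow(xyz)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[1] < 1e-12) stop("degenerate (zero-length) chain axis")
  ax <- e$vectors[, 1]
  if (ax[3] < 0) ax <- -ax
  ax
}

#' Channel order parameter of a peptide cluster
#'
#' Each chain's axis is the dominant principal axis of its backbone
#' particles (sign-aligned to +z); S is the largest eigenvalue of the
#' nematic Q tensor over chain axes.
#'
#' @param fr an `mp_frame`.
#' @param top an `mp_topology`.
#' @param chains integer vector of chain ids (>= 2).
#' @param unwrap rebuild chains across periodic boundaries first.
#' @return scalar S.
#' @export
order_parameter <- function(fr, top, chains, unwrap = TRUE) {
  if (length(chains) < 2L) stop("order parameter needs at least 2 chains")
  axes <- t(vapply(chains, function(id) {
    idx <- chain_particles(top, id)
    idx <- idx[top$particles$backbone[idx]]
    if (length(idx) < 2L) stop("chain ", id, " has fewer than 2 backbone particles")
    xyz <- fr$coords[idx, , drop = FALSE]
    if (unwrap) xyz <- unwrap_chain(xyz, fr$box)
    principal_axis(xyz)
  }, numeric(3)))
  nematic_order(axes)
}

#' Per-frame SASA and Rg of the peptide selection
#'
#' The reaction coordinates of the free-energy landscape: solvent-accessible
#' surface area (nm^2) and radius of gyration (nm) of the peptide particle
#' set, per frame.
#'
#' @param traj an `mp_trajectory`.
#' @param config an [analysis_config()]; `sasa_context = "with_lipids"`
#'   makes lipid particles occlude the peptide surface.
#' @param chains chain ids to include; all peptide chains by default.
#' @return data.frame with columns `time_ns`, `sasa_nm2`, `rg_nm`.
#' @export
conformation_series <- function(traj, config = analysis_config(),
                                chains = NULL) {
  top <- traj$topology
  if (is.null(chains)) chains <- chain_ids(top)
  idx <- unlist(lapply(chains, chain_particles, top = top))
  if (!length(idx)) stop("empty selection")
  masses <- top$particles$mass[idx]
  radii <- top$particles$vdw_radius[idx]
  occ_idx <- if (config$sasa_context == "with_lipids")
    which(top$particles$role %in% c("lipid_head", "lipid_tail")) else integer(0)
  rows <- lapply(traj$frames, function(fr) {
    xyz <- fr$coords[idx, , drop = FALSE]
    occ <- if (length(occ_idx)) fr$coords[occ_idx, , drop = FALSE] else NULL
    occ_r <- if (length(occ_idx)) top$particles$vdw_radius[occ_idx] else NULL
    data.frame(
      time_ns = fr$time,
      sasa_nm2 = sasa(xyz, radii, config$probe_radius, config$sasa_points,
                      occluders = occ, occluder_radii = occ_r),
      rg_nm = radius_of_gyration(xyz, masses)
    )
  })
  do.call(rbind, rows)
}

#' Per-frame order parameter of the largest cluster
#'
#' @param traj an `mp_trajectory`.
#' @param config an [analysis_config()] (cluster cutoff, COM weighting).
#' @return data.frame with columns `time_ns`, `S`, `largest_cluster_size`.
#'   S is `NA` for frames whose largest cluster has fewer than 2 chains.
#' @export
order_parameter_series <- function(traj, config = analysis_config()) {
  rows <- lapply(traj$frames, function(fr) {
    cl <- cluster_frame(fr, traj$topology, config$cluster_cutoff,
                        config$com_weighting)
    members <- cl$clusters[[cl$largest_cluster_id]]
    s <- if (length(members) >= 2L)
      order_parameter(fr, traj$topology, members) else NA_real_
    data.frame(time_ns = fr$time, S = s,
               largest_cluster_size = length(members))
  })
  do.call(rbind, rows)
}
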
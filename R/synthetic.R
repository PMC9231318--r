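# Synthetic trajectory and ensemble generators.  These provide inputs with
# the statistical structure the analyses assume -- lateral aggregation of
# membrane-bound bead chains, Boltzmann-distributed axial ensembles, and
# static pore / fiber arrangements -- so every analysis can be tested
# against a known ground truth.  No claim of physical realism is made.

#' Parameterize a synthetic aggregation scenario
#'
#' Defaults mirror the reference system: 25 bead-chain peptides of 28 beads
#' (one per residue), initial COM spacing 4.0 nm on a grid in the membrane
#' plane of a 20 x 20 x 11 nm box at 310 K.
#'
#' @param n_peptides number of chains.
#' @param beads_per_chain beads per chain.
#' @param box box edge lengths (nm).
#' @param membrane_z_center,membrane_half_thickness membrane slab (nm).
#' @param com_spacing initial COM grid spacing (nm).
#' @param diffusion_step per-frame in-plane Gaussian step s.d. (nm).
#' @param attraction dimensionless drift factor toward the nearest other
#'   cluster (0 disables aggregation).
#' @param pore_bias probability that a merged cluster anneals into a ring
#'   (pore-like) rather than a line (fiber-like).
#' @param cluster_cutoff COM distance below which clusters merge (nm).
#' @param n_frames,frame_dt number of frames and frame spacing (ns).
#' @param n_water,n_ions optional solvent particles placed uniformly
#'   outside the membrane slab.
#' @param seed integer RNG seed; identical scenarios give bit-identical
#'   trajectories.
#' @return an object of class `mp_scenario` (a named list).
#' @export
aggregation_scenario <- function(n_peptides = 25L, beads_per_chain = 28L,
                                 box = c(20, 20, 11),
                                 membrane_z_center = 5.5,
                                 membrane_half_thickness = 2.0,
                                 com_spacing = 4.0,
                                 diffusion_step = 0.05,
                                 attraction = 0.5,
                                 pore_bias = 0.6,
                                 cluster_cutoff = 1.5,
                                 n_frames = 200L, frame_dt = 25,
                                 n_water = 0L, n_ions = 0L,
                                 seed = 1L) {
  stopifnot(n_peptides >= 1L, beads_per_chain >= 1L, all(box > 0),
            com_spacing > 0, diffusion_step > 0, attraction >= 0,
            pore_bias >= 0, pore_bias <= 1, n_frames >= 1L, frame_dt > 0)
  sc <- as.list(environment())
  class(sc) <- "mp_scenario"
  sc
}

# straight vertical bead column used as the rigid chain template
chain_template <- function(beads, z_center, half_thickness) {
  dz <- min(0.15, 2 * half_thickness / max(1, beads - 1))
  z <- z_center + (seq_len(beads) - (beads + 1) / 2) * dz
  cbind(0, 0, z)
}

ring_offsets <- function(m, spacing = 0.9) {
  if (m == 1L) return(matrix(0, 1, 2))
  if (m == 2L) return(cbind(c(-spacing / 2, spacing / 2), 0))
  r <- spacing / (2 * sin(pi / m))
  th <- 2 * pi * (seq_len(m) - 1) / m
  cbind(r * cos(th), r * sin(th))
}

line_offsets <- function(m, spacing = 0.9) {
  cbind((seq_len(m) - (m + 1) / 2) * spacing, 0)
}

#' Generate a membrane-plane aggregation trajectory
#'
#' Chains start on a grid at the configured COM spacing and random-walk in
#' the membrane plane with an optional drift toward the nearest other
#' cluster.  Clusters whose chain COMs come within `cluster_cutoff` merge
#' permanently and move rigidly thereafter; on merging, the cluster anneals
#' into a ring (probability `pore_bias`) or a line.  The cluster-count
#' series is therefore non-increasing by construction.
#'
#' @param scenario an [aggregation_scenario()].
#' @return an `mp_trajectory`.
#' @export
generate_aggregation_trajectory <- function(scenario = aggregation_scenario()) {
  sc <- scenario
  n <- sc$n_peptides
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  if ((ncols - 1) * sc$com_spacing >= sc$box[1] ||
      (nrows - 1) * sc$com_spacing >= sc$box[2])
    stop("infeasible initial packing: grid of ", n,
         " chains at spacing ", sc$com_spacing, " does not fit the box")
  gx <- (seq_len(ncols) - (ncols + 1) / 2) * sc$com_spacing + sc$box[1] / 2
  gy <- (seq_len(nrows) - (nrows + 1) / 2) * sc$com_spacing + sc$box[2] / 2
  grid <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  template <- chain_template(sc$beads_per_chain, sc$membrane_z_center,
                             sc$membrane_half_thickness)

  particles <- data.frame(
    role = rep("peptide", n * sc$beads_per_chain),
    chain_id = rep(seq_len(n), each = sc$beads_per_chain),
    mass = 72, vdw_radius = 0.235,
    resname = "PEP", resid = rep(seq_len(n), each = sc$beads_per_chain),
    atom_name = "BB", backbone = TRUE, stringsAsFactors = FALSE
  )
  with_local_seed(sc$seed, {
    extra <- NULL
    if (sc$n_water > 0L || sc$n_ions > 0L) {
      n_sol <- sc$n_water + sc$n_ions
      # solvent occupies the space outside the membrane slab
      zlo <- sc$membrane_z_center - sc$membrane_half_thickness
      zhi <- sc$membrane_z_center + sc$membrane_half_thickness
      z <- numeric(n_sol)
      below <- stats::runif(n_sol) < zlo / (zlo + (sc$box[3] - zhi))
      z[below] <- stats::runif(sum(below), 0, zlo)
      z[!below] <- stats::runif(sum(!below), zhi, sc$box[3])
      extra_xyz <- cbind(stats::runif(n_sol, 0, sc$box[1]),
                         stats::runif(n_sol, 0, sc$box[2]), z)
      extra_roles <- c(rep("water", sc$n_water), rep("ion", sc$n_ions))
      extra <- list(xyz = extra_xyz, roles = extra_roles)
      particles <- rbind(particles, data.frame(
        role = extra_roles, chain_id = NA_integer_, mass = 72,
        vdw_radius = 0.235,
        resname = ifelse(extra_roles == "water", "W", "ION"),
        resid = n + seq_len(n_sol),
        atom_name = ifelse(extra_roles == "water", "W", "NA+"),
        backbone = FALSE, stringsAsFactors = FALSE))
    }
    top <- topology(particles)

    # cluster state: membership, per-chain xy offset from cluster COM
    cl_of <- seq_len(n)
    offsets <- matrix(0, n, 2)          # chain offset within its cluster
    coms <- as.matrix(grid)             # cluster COMs indexed by cluster id
    active <- rep(TRUE, n)              # which cluster ids are alive

    chain_xy <- function() coms[cl_of, , drop = FALSE] + offsets

    rearrange <- function(members) {
      m <- length(members)
      off <- if (stats::runif(1) < sc$pore_bias) ring_offsets(m)
             else line_offsets(m)
      offsets[members, ] <<- off
    }

    frames <- vector("list", sc$n_frames)
    for (t in seq_len(sc$n_frames)) {
      if (t > 1L) {
        alive <- which(active)
        ccom <- coms[alive, , drop = FALSE]
        for (a in seq_along(alive)) {
          step <- stats::rnorm(2, sd = sc$diffusion_step)
          if (sc$attraction > 0 && length(alive) > 1L) {
            others <- ccom[-a, , drop = FALSE]
            d <- minimum_image_displacement(
              cbind(ccom[a, 1], ccom[a, 2], 0)[rep(1, nrow(others)), ],
              cbind(others, 0), c(sc$box[1], sc$box[2], 1))
            k <- which.min(rowSums(d[, 1:2, drop = FALSE]^2))
            dir <- d[k, 1:2]
            nrm <- sqrt(sum(dir^2))
            if (nrm > 1e-9)
              step <- step + sc$attraction * sc$diffusion_step * dir / nrm
          }
          id <- alive[a]
          coms[id, ] <- coms[id, ] + step
          coms[id, 1] <- wrap_coord(coms[id, 1], sc$box[1])
          coms[id, 2] <- wrap_coord(coms[id, 2], sc$box[2])
        }
        # merge clusters with any chain pair below the cutoff (permanent)
        repeat {
          xy <- chain_xy()
          d <- min_image_dist_matrix(cbind(xy, 0), c(sc$box[1], sc$box[2], 1))
          close <- d < sc$cluster_cutoff
          merged_any <- FALSE
          for (i in seq_len(n - 1L)) {
            j <- which(close[i, ] & cl_of != cl_of[i])
            if (length(j)) {
              j <- j[1]
              a <- cl_of[i]; b <- cl_of[j]
              mem_a <- which(cl_of == a); mem_b <- which(cl_of == b)
              # bring b's COM to a's nearest image, merge about the mean
              shift <- minimum_image_displacement(
                c(coms[a, ], 0), c(coms[b, ], 0),
                c(sc$box[1], sc$box[2], 1))[1:2]
              wa <- length(mem_a) / (length(mem_a) + length(mem_b))
              new_com <- coms[a, ] + (1 - wa) * shift
              cl_of[mem_b] <- a
              active[b] <- FALSE
              coms[a, ] <- new_com
              rearrange(c(mem_a, mem_b))
              merged_any <- TRUE
              break
            }
          }
          if (!merged_any) break
        }
      }
      xy <- chain_xy()
      pep_xyz <- do.call(rbind, lapply(seq_len(n), function(c)
        sweep(template, 2, c(xy[c, 1], xy[c, 2], 0), `+`)))
      all_xyz <- if (is.null(extra)) pep_xyz else rbind(pep_xyz, extra$xyz)
      frames[[t]] <- traj_frame((t - 1) * sc$frame_dt, sc$box, all_xyz)
    }
    trajectory(top, frames)
  })
}

# ---- axial potentials -------------------------------------------------

new_axial_potential <- function(fun, z_lo, z_hi, type, params = list()) {
  obj <- list(fun = fun, z_lo = z_lo, z_hi = z_hi, type = type,
              params = params)
  class(obj) <- "mp_axial_potential"
  obj
}

#' Axial potentials U(z) for Boltzmann ensembles
#'
#' Constructors for the supported functional forms of `U(z)` (kcal/mol) on
#' a z interval: a constant, a Gaussian barrier
#' `baseline + height * exp(-(z - center)^2 / (2 width^2))`, and a
#' piecewise-linear table.
#'
#' @param u0,baseline constant / baseline energy (kcal/mol).
#' @param z_range domain `c(z_lo, z_hi)` (nm).
#' @param height,center,width Gaussian barrier parameters (kcal/mol, nm, nm).
#' @param z,u table nodes for the piecewise-linear form.
#' @return an `mp_axial_potential`.
#' @export
axial_potential_constant <- function(u0 = 0, z_range = c(0, 11)) {
  force(u0)
  new_axial_potential(function(z) rep(u0, length(z)),
                      z_range[1], z_range[2], "constant", list(u0 = u0))
}

#' @rdname axial_potential_constant
#' @export
axial_potential_gaussian <- function(height, center, width,
                                     z_range = c(0, 11), baseline = 0) {
  stopifnot(width > 0)
  new_axial_potential(
    function(z) baseline + height * exp(-(z - center)^2 / (2 * width^2)),
    z_range[1], z_range[2], "gaussian",
    list(height = height, center = center, width = width,
         baseline = baseline))
}

#' @rdname axial_potential_constant
#' @export
axial_potential_table <- function(z, u) {
  stopifnot(length(z) == length(u), length(z) >= 2L, !is.unsorted(z),
            all(is.finite(u)))
  new_axial_potential(function(zz) stats::approx(z, u, zz, rule = 2)$y,
                      z[1], z[length(z)], "table", list(z = z, u = u))
}

#' Evaluate an axial potential
#' @param pot an `mp_axial_potential`.
#' @param z z values (nm).
#' @return U(z) in kcal/mol.
#' @export
eval_potential <- function(pot, z) pot$fun(z)

#' Sample particles from a Boltzmann axial density
#'
#' Draws `n` particles whose z coordinates are i.i.d. samples from the
#' density proportional to `exp(-U(z)/RT)` on the potential's domain
#' (inverse-CDF on a fine grid) and whose x,y are uniform in a lateral
#' disc.  The ground truth for density-based PMF recovery.
#'
#' @param potential an `mp_axial_potential` with finite values.
#' @param n number of particles.
#' @param temperature temperature (K).
#' @param lateral_radius radius of the lateral disc (nm).
#' @param seed integer RNG seed.
#' @param species particle role (`"water"` or `"ion"`).
#' @param grid_n resolution of the inverse-CDF grid.
#' @return a single-frame `mp_trajectory`; the box is
#'   `2 lateral_radius` square laterally with the disc at its centre.
#' @export
generate_boltzmann_particles <- function(potential, n, temperature = 310,
                                         lateral_radius = 1.0, seed = 1L,
                                         species = c("water", "ion"),
                                         grid_n = 1e4) {
  stopifnot(inherits(potential, "mp_axial_potential"), n >= 1L)
  species <- match.arg(species)
  zs <- seq(potential$z_lo, potential$z_hi, length.out = grid_n)
  u <- eval_potential(potential, zs)
  if (any(!is.finite(u))) stop("non-finite potential on its domain")
  dens <- exp(-(u - min(u)) / (R_KCAL * temperature))
  dz <- zs[2] - zs[1]
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2) * dz
  cdf <- c(0, cdf) / cdf[length(cdf) - 0]
  with_local_seed(seed, {
    z <- stats::approx(cdf, zs, stats::runif(n), ties = "ordered")$y
    r <- lateral_radius * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    box <- c(2 * lateral_radius, 2 * lateral_radius,
             max(potential$z_hi, 1e-6))
    xyz <- cbind(lateral_radius + r * cos(th),
                 lateral_radius + r * sin(th), z)
    particles <- data.frame(
      role = species, chain_id = NA_integer_, mass = 72, vdw_radius = 0.235,
      resname = if (species == "water") "W" else "ION",
      resid = seq_len(n),
      atom_name = if (species == "water") "W" else "NA+",
      backbone = FALSE, stringsAsFactors = FALSE)
    trajectory(topology(particles), list(traj_frame(0, box, xyz)))
  })
}

# ---- static scenes ----------------------------------------------------

pore_chain_columns <- function(beads) {
  if (beads %% 4L == 0L) 4L else if (beads %% 2L == 0L) 2L else 1L
}

#' Generate a static pore-like arrangement
#'
#' Chains are placed vertically on a circle so that the enclosed empty
#' lumen has the requested radius: each chain's beads occupy a few
#' azimuthal columns (symmetric about the chain axis, so every chain axis
#' is exactly vertical) and adjacent columns overlap, closing the ring.
#'
#' @param n_peptides number of chains (>= 3).
#' @param lumen_radius enclosed free-lumen radius (nm).
#' @param seed kept for interface symmetry; the scene is deterministic.
#' @param beads_per_chain beads per chain.
#' @param bead_radius bead van der Waals radius (nm).
#' @param box box edge lengths (nm); the ring sits at the box centre.
#' @param z_span vertical extent of the chains (nm).
#' @return a single-frame `mp_trajectory`.
#' @export
generate_pore_scene <- function(n_peptides = 7L, lumen_radius = 0.55,
                                seed = 1L, beads_per_chain = 28L,
                                bead_radius = 0.235, box = c(20, 20, 11),
                                z_span = c(2.32, 6.55)) {
  stopifnot(n_peptides >= 3L, beads_per_chain >= 2L)
  if (lumen_radius <= 0) stop("lumen_radius must be > 0")
  cpc <- pore_chain_columns(beads_per_chain)
  n_levels <- beads_per_chain %/% cpc
  ring_r <- lumen_radius + bead_radius
  total_cols <- n_peptides * cpc
  step <- 2 * pi / total_cols
  chord <- 2 * ring_r * sin(step / 2)
  if (chord > 2 * bead_radius)
    warning("adjacent bead columns do not overlap; the ring is not closed ",
            "(increase n_peptides or bead_radius, or reduce lumen_radius)")
  zl <- seq(z_span[1], z_span[2], length.out = n_levels)
  cx <- box[1] / 2; cy <- box[2] / 2
  coords <- matrix(NA_real_, n_peptides * beads_per_chain, 3)
  row <- 0L
  for (k in seq_len(n_peptides)) {
    th0 <- 2 * pi * (k - 1) / n_peptides
    col_off <- (seq_len(cpc) - (cpc + 1) / 2) * step
    for (lev in seq_len(n_levels)) {
      for (co in col_off) {
        row <- row + 1L
        coords[row, ] <- c(cx + ring_r * cos(th0 + co),
                           cy + ring_r * sin(th0 + co), zl[lev])
      }
    }
  }
  particles <- data.frame(
    role = "peptide", chain_id = rep(seq_len(n_peptides),
                                     each = beads_per_chain),
    mass = 72, vdw_radius = bead_radius, resname = "PEP",
    resid = rep(seq_len(n_peptides), each = beads_per_chain),
    atom_name = "BB", backbone = TRUE, stringsAsFactors = FALSE)
  trajectory(topology(particles), list(traj_frame(0, box, coords)))
}

#' Generate a static fiber-like arrangement
#'
#' Chains are exactly parallel vertical bead columns with collinear COMs
#' at the given spacing (no enclosed lumen).
#'
#' @param n_peptides number of chains (>= 2).
#' @param spacing COM spacing along x (nm).
#' @param seed kept for interface symmetry; the scene is deterministic.
#' @inheritParams generate_pore_scene
#' @return a single-frame `mp_trajectory`.
#' @export
generate_fiber_scene <- function(n_peptides = 7L, spacing = 0.9, seed = 1L,
                                 beads_per_chain = 28L, bead_radius = 0.235,
                                 box = c(20, 20, 11),
                                 z_span = c(2.32, 6.55)) {
  stopifnot(n_peptides >= 2L, spacing > 0, beads_per_chain >= 2L)
  zl <- seq(z_span[1], z_span[2], length.out = beads_per_chain)
  xs <- box[1] / 2 + (seq_len(n_peptides) - (n_peptides + 1) / 2) * spacing
  coords <- do.call(rbind, lapply(xs, function(x)
    cbind(x, box[2] / 2, zl)))
  particles <- data.frame(
    role = "peptide", chain_id = rep(seq_len(n_peptides),
                                     each = beads_per_chain),
    mass = 72, vdw_radius = bead_radius, resname = "PEP",
    resid = rep(seq_len(n_peptides), each = beads_per_chain),
    atom_name = "BB", backbone = TRUE, stringsAsFactors = FALSE)
  trajectory(topology(particles), list(traj_frame(0, box, coords)))
}

# ---- two-basin reference surface for landscape recovery ----------------

#' Two-basin reference free-energy surface
#'
#' A prescribed surface with two Gaussian wells on a flat plateau: well A
#' at depth 0, well B at `depth_difference`, plateau at `barrier`, so the
#' minimax barrier from A to B is `barrier` by construction (the wells are
#' far apart relative to their width, so their overlap is negligible).
#'
#' @param depth_difference `W(B) - W(A)` (kcal/mol).
#' @param barrier plateau height above well A (kcal/mol).
#' @param centers 2x2 matrix of well centres (rows), in surface units.
#' @param sigma well width (same units).
#' @param xlim,ylim sampling domain.
#' @return an object of class `mp_fel_surface`: list with `fun(x, y)`,
#'   the construction parameters, and the domain.
#' @export
fel_reference_surface <- function(depth_difference = 1.0, barrier = 2.5,
                                  centers = rbind(c(-1, 0), c(1, 0)),
                                  sigma = 0.15,
                                  xlim = c(-1.6, 1.6), ylim = c(-0.6, 0.6)) {
  stopifnot(barrier > 0, barrier > depth_difference, sigma > 0)
  a1 <- barrier
  a2 <- barrier - depth_difference
  fun <- function(x, y) {
    g1 <- exp(-((x - centers[1, 1])^2 + (y - centers[1, 2])^2) / (2 * sigma^2))
    g2 <- exp(-((x - centers[2, 1])^2 + (y - centers[2, 2])^2) / (2 * sigma^2))
    barrier - a1 * g1 - a2 * g2
  }
  obj <- list(fun = fun, depth_difference = depth_difference,
              barrier = barrier, centers = centers, sigma = sigma,
              xlim = xlim, ylim = ylim)
  class(obj) <- "mp_fel_surface"
  obj
}

#' Sample (X, Y) points from a Boltzmann density over a surface
#'
#' Samples from the density proportional to `exp(-W0(x, y)/RT)` on the
#' surface domain, by multinomial sampling of a fine probability grid with
#' uniform jitter inside cells.
#'
#' @param surface an [fel_reference_surface()].
#' @param n number of samples.
#' @param temperature temperature (K).
#' @param seed integer RNG seed.
#' @param grid integer length 2: resolution of the sampling grid.
#' @return data.frame with columns `x`, `y`.
#' @export
sample_landscape <- function(surface, n, temperature = 310, seed = 1L,
                             grid = c(400L, 200L)) {
  stopifnot(inherits(surface, "mp_fel_surface"), n >= 1L)
  RT <- R_KCAL * temperature
  gx <- seq(surface$xlim[1], surface$xlim[2], length.out = grid[1] + 1L)
  gy <- seq(surface$ylim[1], surface$ylim[2], length.out = grid[2] + 1L)
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  W <- outer(cx, cy, surface$fun)
  p <- exp(-(W - min(W)) / RT)
  p <- as.vector(p) / sum(p)
  with_local_seed(seed, {
    cells <- sample.int(length(p), n, replace = TRUE, prob = p)
    ix <- (cells - 1L) %% grid[1] + 1L
    iy <- (cells - 1L) %/% grid[1] + 1L
    wx <- gx[2] - gx[1]; wy <- gy[2] - gy[1]
    data.frame(x = gx[ix] + stats::runif(n) * wx,
               y = gy[iy] + stats::runif(n) * wy)
  })
}
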
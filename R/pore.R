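# Axial density profiles, density-based PMF, permeation-event counting,
# pore-radius estimation and direct-contact counting.

# minimum-image lateral (xy) distance of coordinates to an axis centre
lateral_distance <- function(coords, center_xy, box) {
  dx <- coords[, 1] - center_xy[1]
  dy <- coords[, 2] - center_xy[2]
  dx <- dx - box[1] * floor(dx / box[1] + 0.5)
  dy <- dy - box[2] * floor(dy / box[2] + 0.5)
  sqrt(dx^2 + dy^2)
}

#' Axial number-density profile of a species
#'
#' Time-averaged count of species particles inside a channel-centred
#' sampling cylinder, per z bin over the channel span, divided by the bin
#' volume `pi r^2 dz`.  The bulk density comes from the slabs at least
#' `bulk_margin` nm beyond the channel span, using the full box
#' cross-section by default (`bulk_cross_section = "cylinder"` samples the
#' bulk through the same cylinder instead, appropriate when particles are
#' confined to the cylinder by construction).
#'
#' @param traj an `mp_trajectory`.
#' @param species particle role (`"water"` or `"ion"`).
#' @param z_lo,z_hi channel span (nm).
#' @param n_bins number of z bins.
#' @param cylinder_radius sampling-cylinder radius (nm).
#' @param center_xy cylinder axis position; defaults to the box centre.
#' @param bulk_margin distance beyond the span where the bulk region starts.
#' @param bulk_cross_section `"box"` or `"cylinder"`.
#' @return an object of class `mp_density_profile`: data.frame-like list
#'   with `profile` (columns `z_nm`, `rho`, `rho_over_bulk`), `rho_bulk`,
#'   `species`, and the sampling geometry.
#' @export
axial_density <- function(traj, species = "water", z_lo = 2.32, z_hi = 6.55,
                          n_bins = 30L, cylinder_radius = 1.0,
                          center_xy = NULL, bulk_margin = 1.0,
                          bulk_cross_section = c("box", "cylinder")) {
  stopifnot(z_lo < z_hi, n_bins >= 1L, cylinder_radius > 0)
  bulk_cross_section <- match.arg(bulk_cross_section)
  idx <- which(traj$topology$particles$role == species)
  if (!length(idx)) stop("no particles of species '", species, "'")
  box <- traj$frames[[1]]$box
  if (is.null(center_xy)) center_xy <- box[1:2] / 2
  edges <- seq(z_lo, z_hi, length.out = n_bins + 1L)
  dz <- diff(edges)[1]
  counts <- numeric(n_bins)
  bulk_count <- 0
  # bulk slabs clipped to the box
  lo_slab <- c(0, max(0, z_lo - bulk_margin))
  hi_slab <- c(min(box[3], z_hi + bulk_margin), box[3])
  bulk_height <- max(0, diff(lo_slab)) + max(0, diff(hi_slab))
  if (bulk_height <= 0) stop("empty bulk region: channel span fills the box")
  for (fr in traj$frames) {
    z <- wrap_coord(fr$coords[idx, 3], box[3])
    r <- lateral_distance(fr$coords[idx, , drop = FALSE], center_xy, box)
    in_cyl <- r <= cylinder_radius
    sel <- in_cyl & z >= z_lo & z <= z_hi
    if (any(sel)) {
      b <- pmin(pmax(findInterval(z[sel], edges, rightmost.closed = TRUE), 1L),
                n_bins)
      counts <- counts + tabulate(b, n_bins)
    }
    in_bulk_z <- (z >= lo_slab[1] & z < lo_slab[2]) |
      (z > hi_slab[1] & z <= hi_slab[2])
    if (bulk_cross_section == "cylinder") in_bulk_z <- in_bulk_z & in_cyl
    bulk_count <- bulk_count + sum(in_bulk_z)
  }
  nf <- length(traj$frames)
  bin_volume <- pi * cylinder_radius^2 * dz
  bulk_area <- if (bulk_cross_section == "box") box[1] * box[2]
               else pi * cylinder_radius^2
  rho <- counts / nf / bin_volume
  rho_bulk <- bulk_count / nf / (bulk_area * bulk_height)
  if (rho_bulk <= 0) stop("empty bulk region: no particles outside the channel span")
  obj <- list(
    profile = data.frame(z_nm = (edges[-1] + edges[-length(edges)]) / 2,
                         rho = rho, rho_over_bulk = rho / rho_bulk),
    rho_bulk = rho_bulk, species = species,
    z_lo = z_lo, z_hi = z_hi, cylinder_radius = cylinder_radius,
    center_xy = center_xy, bulk_margin = bulk_margin,
    bulk_cross_section = bulk_cross_section, n_frames = nf
  )
  class(obj) <- "mp_density_profile"
  obj
}

#' @export
print.mp_density_profile <- function(x, ...) {
  cat(sprintf("Axial density of %s: %d bins over %g-%g nm, rho_bulk = %.4g nm^-3\n",
              x$species, nrow(x$profile), x$z_lo, x$z_hi, x$rho_bulk))
  invisible(x)
}

#' Density-based potential of mean force
#'
#' `dG_PMF(z) = -RT ln(rho_z / rho_bulk)` on bins with nonzero density;
#' empty bins are undefined (`NA`).  The barrier is the maximum defined
#' dG over the channel span.
#'
#' @param profile an `mp_density_profile`.
#' @param temperature temperature in K.
#' @return an object of class `mp_pmf_profile`: list with `profile`
#'   (columns `z_nm`, `rho_over_bulk`, `dG_kcal_mol`), `barrier`
#'   (kcal/mol), `temperature`, `RT`, `species`.
#' @export
density_pmf <- function(profile, temperature = 310) {
  stopifnot(inherits(profile, "mp_density_profile"), temperature > 0)
  RT <- R_KCAL * temperature
  ratio <- profile$profile$rho_over_bulk
  if (all(ratio == 0)) stop("all channel bins are empty")
  dg <- ifelse(ratio > 0, -RT * log(ratio), NA_real_)
  obj <- list(
    profile = data.frame(z_nm = profile$profile$z_nm,
                         rho_over_bulk = ratio, dG_kcal_mol = dg),
    barrier = max(dg, na.rm = TRUE),
    temperature = temperature, RT = RT, species = profile$species
  )
  class(obj) <- "mp_pmf_profile"
  obj
}

#' @export
print.mp_pmf_profile <- function(x, ...) {
  cat(sprintf("Density-based PMF (%s): barrier %.3f kcal/mol at T = %g K\n",
              x$species, x$barrier, x$temperature))
  invisible(x)
}

#' Count complete permeation events through the channel slab
#'
#' A permeation event is a particle entering the slab `[z_lo, z_hi]`
#' through one face and exiting through the opposite face while remaining
#' inside the sampling cylinder for every frame spent inside the slab.
#' Re-crossings back out through the entry face are not events.  Face
#' crossings are resolved with minimum-image z steps, so the count is
#' invariant to frame-wise periodic rewrapping.
#'
#' @param traj an `mp_trajectory` with at least 2 frames.
#' @param species particle role to track.
#' @param z_lo,z_hi channel span (nm).
#' @param cylinder_radius sampling-cylinder radius (nm; `Inf` disables the
#'   lateral constraint).
#' @param center_xy cylinder axis position; defaults to the box centre.
#' @return data.frame with one row per event: `particle` (1-based index),
#'   `entry_time_ns`, `exit_time_ns`, `direction` (`"+z"` or `"-z"`).
#' @export
count_permeation_events <- function(traj, species = "water",
                                    z_lo = 2.32, z_hi = 6.55,
                                    cylinder_radius = 1.0, center_xy = NULL) {
  stopifnot(length(traj$frames) >= 2L, z_lo < z_hi)
  idx <- which(traj$topology$particles$role == species)
  if (!length(idx)) stop("no particles of species '", species, "'")
  box <- traj$frames[[1]]$box
  if (is.null(center_xy)) center_xy <- box[1:2] / 2
  nf <- length(traj$frames)
  times <- traj$times
  zmat <- vapply(traj$frames, function(fr)
    wrap_coord(fr$coords[idx, 3], box[3]), numeric(length(idx)))
  zmat <- matrix(zmat, nrow = length(idx))
  cylmat <- vapply(traj$frames, function(fr)
    lateral_distance(fr$coords[idx, , drop = FALSE], center_xy, box) <=
      cylinder_radius, logical(length(idx)))
  cylmat <- matrix(cylmat, nrow = length(idx))
  region <- function(z) ifelse(z < z_lo, -1L, ifelse(z > z_hi, 1L, 0L))
  events <- list()
  for (p in seq_along(idx)) {
    z <- zmat[p, ]
    reg <- region(z)
    side <- if (reg[1] != 0L) reg[1] else NA_integer_
    entered_from <- NA_integer_
    entry_time <- NA_real_
    valid <- FALSE
    if (reg[1] == 0L) valid <- FALSE  # started inside: traversal unattributable
    for (t in 2:nf) {
      dz <- z[t] - z[t - 1]
      dz <- dz - box[3] * floor(dz / box[3] + 0.5)
      rp <- reg[t - 1]; rc <- reg[t]
      if (rp != 0L && rc == 0L) {
        # entered the slab; face from the step direction
        entered_from <- if (dz > 0) -1L else 1L
        entry_time <- times[t - 1]
        valid <- cylmat[p, t]
      } else if (rp == 0L && rc == 0L) {
        if (!cylmat[p, t]) valid <- FALSE
      } else if (rp == 0L && rc != 0L) {
        exit_face <- if (dz > 0) 1L else -1L
        if (valid && !is.na(entered_from) && exit_face == -entered_from) {
          events[[length(events) + 1L]] <- data.frame(
            particle = idx[p], entry_time_ns = entry_time,
            exit_time_ns = times[t],
            direction = if (entered_from == -1L) "+z" else "-z")
        }
        side <- exit_face
        entered_from <- NA_integer_
        valid <- FALSE
      } else if (rp != 0L && rc != 0L && rp != rc) {
        # jumped across in one step: through the slab if the step direction
        # agrees with the region change, else through the periodic boundary
        through_slab <- (rc > rp && dz > 0) || (rc < rp && dz < 0)
        if (through_slab && cylmat[p, t - 1] && cylmat[p, t]) {
          events[[length(events) + 1L]] <- data.frame(
            particle = idx[p], entry_time_ns = times[t - 1],
            exit_time_ns = times[t],
            direction = if (rc > rp) "+z" else "-z")
        }
        side <- rc
      }
    }
  }
  if (!length(events))
    return(data.frame(particle = integer(0), entry_time_ns = numeric(0),
                      exit_time_ns = numeric(0), direction = character(0)))
  do.call(rbind, events)
}

#' Pore radius from the projected lumen area
#'
#' Projects the cluster's peptide particles, as discs of their van der
#' Waals radii, onto the x-y plane over the channel z-span, rasterizes at
#' `grid_spacing`, and flood-fills the free space from the cluster's COM
#' projection.  If that free-space component is enclosed by covered cells
#' (it does not reach the raster boundary), its area `A` gives the radius
#' `sqrt(A/pi)`; open geometries and covered COM projections report radius
#' 0 with a diagnostic.
#'
#' @param fr an `mp_frame`.
#' @param top an `mp_topology`.
#' @param cluster integer vector of chain ids (>= 3).
#' @param grid_spacing raster cell size (nm).
#' @param z_span optional channel span; only particles with z inside it are
#'   projected (all cluster particles if `NULL`).
#' @return list with `radius_nm`, `area_nm2`, `status` (`"ok"`,
#'   `"no enclosed lumen"` or `"no lumen at COM projection"`).
#' @export
pore_radius <- function(fr, top, cluster, grid_spacing = 0.02,
                        z_span = NULL) {
  if (length(cluster) < 3L) stop("pore radius needs a cluster of >= 3 chains")
  idx <- unlist(lapply(cluster, chain_particles, top = top))
  xyz <- fr$coords[idx, , drop = FALSE]
  rad <- top$particles$vdw_radius[idx]
  if (!is.null(z_span)) {
    keep <- xyz[, 3] >= z_span[1] & xyz[, 3] <= z_span[2]
    xyz <- xyz[keep, , drop = FALSE]; rad <- rad[keep]
    if (nrow(xyz) == 0L) stop("no cluster particles inside the z span")
  }
  com <- colMeans(xyz[, 1:2, drop = FALSE])
  pad <- 2 * grid_spacing
  x0 <- min(xyz[, 1] - rad) - pad; x1 <- max(xyz[, 1] + rad) + pad
  y0 <- min(xyz[, 2] - rad) - pad; y1 <- max(xyz[, 2] + rad) + pad
  nx <- ceiling((x1 - x0) / grid_spacing)
  ny <- ceiling((y1 - y0) / grid_spacing)
  xc <- x0 + (seq_len(nx) - 0.5) * grid_spacing
  yc <- y0 + (seq_len(ny) - 0.5) * grid_spacing
  covered <- matrix(FALSE, nx, ny)
  for (k in seq_len(nrow(xyz))) {
    ix <- which(abs(xc - xyz[k, 1]) <= rad[k])
    iy <- which(abs(yc - xyz[k, 2]) <= rad[k])
    if (!length(ix) || !length(iy)) next
    d2 <- outer((xc[ix] - xyz[k, 1])^2, (yc[iy] - xyz[k, 2])^2, `+`)
    covered[ix, iy] <- covered[ix, iy] | (d2 <= rad[k]^2)
  }
  ci <- pmin(pmax(1L, as.integer(ceiling((com[1] - x0) / grid_spacing))), nx)
  cj <- pmin(pmax(1L, as.integer(ceiling((com[2] - y0) / grid_spacing))), ny)
  if (covered[ci, cj])
    return(list(radius_nm = 0, area_nm2 = 0,
                status = "no lumen at COM projection"))
  # vectorized 4-connected flood fill from the COM cell
  filled <- matrix(FALSE, nx, ny)
  filled[ci, cj] <- TRUE
  frontier <- (cj - 1L) * nx + ci
  free <- !covered
  touches_edge <- FALSE
  while (length(frontier)) {
    fi <- (frontier - 1L) %% nx + 1L
    fj <- (frontier - 1L) %/% nx + 1L
    if (any(fi == 1L | fi == nx | fj == 1L | fj == ny)) touches_edge <- TRUE
    nxt <- c(frontier[fi > 1L] - 1L, frontier[fi < nx] + 1L,
             frontier[fj > 1L] - nx, frontier[fj < ny] + nx)
    nxt <- unique(nxt[free[nxt] & !filled[nxt]])
    filled[nxt] <- TRUE
    frontier <- nxt
  }
  if (touches_edge)
    return(list(radius_nm = 0, area_nm2 = 0, status = "no enclosed lumen"))
  area <- sum(filled) * grid_spacing^2
  list(radius_nm = sqrt(area / pi), area_nm2 = area, status = "ok")
}

#' Direct peptide contacts of a solvent species
#'
#' Flags every particle of the species whose minimum-image distance to any
#' peptide particle of the cluster is strictly below the cutoff (the
#' direct-contact rule, default 0.4 nm), and reports the complement within
#' the sampling cylinder (the hydrogen-bonded "water network" population).
#'
#' @param fr an `mp_frame`.
#' @param top an `mp_topology`.
#' @param cluster integer vector of chain ids.
#' @param species particle role to test.
#' @param cutoff contact distance (nm, strict `<`).
#' @param cylinder_radius,center_xy,z_span optional cylinder for the
#'   network complement (skipped if `cylinder_radius` is `NULL`).
#' @return list with `in_contact` (logical, one per species particle),
#'   `particles` (their indices), `n_contact`, and, when a cylinder is
#'   given, `n_in_cylinder` and `n_network`.
#' @export
channel_contacts <- function(fr, top, cluster, species = "water",
                             cutoff = 0.4, cylinder_radius = NULL,
                             center_xy = NULL, z_span = NULL) {
  stopifnot(cutoff > 0)
  if (!length(cluster)) stop("empty cluster")
  sp <- which(top$particles$role == species)
  if (!length(sp)) stop("no particles of species '", species, "'")
  pep <- unlist(lapply(cluster, chain_particles, top = top))
  box <- fr$box
  a <- fr$coords[sp, , drop = FALSE]
  b <- fr$coords[pep, , drop = FALSE]
  d2 <- matrix(0, length(sp), length(pep))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    dk <- dk - box[k] * floor(dk / box[k] + 0.5)
    d2 <- d2 + dk^2
  }
  in_contact <- apply(d2 < cutoff^2, 1, any)
  out <- list(in_contact = in_contact, particles = sp,
              n_contact = sum(in_contact))
  if (!is.null(cylinder_radius)) {
    if (is.null(center_xy)) center_xy <- box[1:2] / 2
    in_cyl <- lateral_distance(a, center_xy, box) <= cylinder_radius
    if (!is.null(z_span)) {
      z <- wrap_coord(a[, 3], box[3])
      in_cyl <- in_cyl & z >= z_span[1] & z <= z_span[2]
    }
    out$n_in_cylinder <- sum(in_cyl)
    out$n_network <- sum(in_cyl & !in_contact)
  }
  out
}
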
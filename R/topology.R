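# Domain containers: topology, frame, trajectory.

PARTICLE_ROLES <- c("peptide", "lipid_head", "lipid_tail", "water", "ion")

#' Build a topology
#'
#' A topology labels every particle of the system by role and, for peptide
#' particles, by chain.  Particle indices are 1-based row positions.
#'
#' @param particles a data.frame with one row per particle and columns
#'   `role` (one of peptide, lipid_head, lipid_tail, water, ion), `chain_id`
#'   (integer for peptide particles, `NA` otherwise), `mass` (amu),
#'   `vdw_radius` (nm); optional `resname`, `resid`, `atom_name`,
#'   `backbone` (logical; defaults to `TRUE` for peptide particles).
#' @return an object of class `mp_topology`.
#' @export
topology <- function(particles) {
  stopifnot(is.data.frame(particles),
            all(c("role", "chain_id", "mass", "vdw_radius") %in% names(particles)))
  n <- nrow(particles)
  if (n == 0L) stop("topology needs at least one particle")
  if (!all(particles$role %in% PARTICLE_ROLES))
    stop("unknown particle role(s): ",
         paste(unique(setdiff(particles$role, PARTICLE_ROLES)), collapse = ", "))
  if (any(particles$mass <= 0)) stop("particle masses must be > 0")
  if (any(particles$vdw_radius <= 0)) stop("particle radii must be > 0")
  pep <- particles$role == "peptide"
  if (any(pep & is.na(particles$chain_id)))
    stop("every peptide particle must carry a chain_id")
  if (is.null(particles$backbone)) particles$backbone <- pep
  if (is.null(particles$resname))
    particles$resname <- ifelse(pep, "PEP",
                                toupper(substr(particles$role, 1, 4)))
  if (is.null(particles$atom_name))
    particles$atom_name <- ifelse(pep, "BB", "X")
  if (is.null(particles$resid)) {
    particles$resid <- ifelse(pep, particles$chain_id, NA_integer_)
    nonp <- which(!pep)
    if (length(nonp)) {
      base <- if (any(pep)) max(particles$chain_id[pep]) else 0L
      particles$resid[nonp] <- base + seq_along(nonp)
    }
  }
  chains <- split(which(pep), particles$chain_id[pep])
  obj <- list(particles = particles, chains = chains)
  class(obj) <- "mp_topology"
  obj
}

#' @export
print.mp_topology <- function(x, ...) {
  tab <- table(x$particles$role)
  cat(sprintf("Topology: %d particles, %d peptide chains\n",
              nrow(x$particles), length(x$chains)))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Peptide chain ids of a topology
#' @param top an `mp_topology`.
#' @return integer vector of chain ids.
#' @export
chain_ids <- function(top) as.integer(names(top$chains))

#' Particle indices of one peptide chain
#' @param top an `mp_topology`.
#' @param chain_id a chain id present in the topology.
#' @return integer vector of 1-based particle indices, in bonded order.
#' @export
chain_particles <- function(top, chain_id) {
  key <- as.character(chain_id)
  if (!key %in% names(top$chains)) stop("unknown chain id: ", chain_id)
  top$chains[[key]]
}

#' Build a single frame
#'
#' @param time frame time (ns).
#' @param box orthorhombic box edge lengths (nm, length 3, all > 0).
#' @param coords numeric matrix, one particle per row, columns x/y/z (nm).
#' @return an object of class `mp_frame`.
#' @export
traj_frame <- function(time, box, coords) {
  stopifnot(length(box) == 3L, all(box > 0), is.matrix(coords), ncol(coords) == 3L)
  obj <- list(time = as.numeric(time), box = as.numeric(box), coords = coords)
  class(obj) <- "mp_frame"
  obj
}

#' Build a trajectory
#'
#' @param top an `mp_topology`.
#' @param frames list of `mp_frame` objects with strictly increasing times
#'   and coordinate counts matching the topology.
#' @return an object of class `mp_trajectory`.
#' @export
trajectory <- function(top, frames) {
  stopifnot(inherits(top, "mp_topology"), length(frames) >= 1L)
  n <- nrow(top$particles)
  for (f in frames) {
    if (!inherits(f, "mp_frame")) stop("frames must be mp_frame objects")
    if (nrow(f$coords) != n)
      stop(sprintf("particle-count mismatch: topology has %d, frame has %d",
                   n, nrow(f$coords)))
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  obj <- list(topology = top, frames = frames, times = times)
  class(obj) <- "mp_trajectory"
  obj
}

#' @export
print.mp_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, t = %g .. %g ns, %d particles\n",
              length(x$frames), x$times[1], x$times[length(x$times)],
              nrow(x$topology$particles)))
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mp_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)
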
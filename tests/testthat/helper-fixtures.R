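# Programmatic fixtures: small topologies, frames and scripted
# trajectories built in code at test time.

# topology of n_chains point-like chains (beads beads each, unit masses
# unless given) plus optional solvent particles
make_chain_topology <- function(n_chains, beads = 1L, masses = NULL,
                                radius = 0.235, n_water = 0L, n_ion = 0L) {
  n <- n_chains * beads
  df <- data.frame(
    role = rep("peptide", n),
    chain_id = rep(seq_len(n_chains), each = beads),
    mass = if (is.null(masses)) 72 else masses,
    vdw_radius = radius, stringsAsFactors = FALSE)
  if (n_water + n_ion > 0L)
    df <- rbind(df, data.frame(
      role = c(rep("water", n_water), rep("ion", n_ion)),
      chain_id = NA_integer_, mass = 72, vdw_radius = radius,
      stringsAsFactors = FALSE))
  topology(df)
}

# frame with one bead per chain at the given COM positions (n x 3)
make_com_frame <- function(coms, box = c(20, 20, 11), time = 0) {
  traj_frame(time, box, as.matrix(coms))
}

# single-bead-per-chain trajectory from a list of COM matrices
make_com_trajectory <- function(com_frames, box = c(20, 20, 11),
                                times = NULL) {
  n_chains <- nrow(com_frames[[1]])
  top <- make_chain_topology(n_chains)
  if (is.null(times)) times <- seq_along(com_frames) - 1
  trajectory(top, Map(function(xy, t) traj_frame(t, box, as.matrix(xy)),
                      com_frames, times))
}

# trajectory of water particles following prescribed z-paths; xy sits on
# the cylinder axis unless in_cyl[i, t] is FALSE, in which case the
# particle is displaced laterally out of the cylinder for that frame
make_scripted_water_trajectory <- function(z_paths, in_cyl = NULL,
                                           box = c(10, 10, 10),
                                           cylinder_radius = 1.0) {
  np <- nrow(z_paths); nt <- ncol(z_paths)
  if (is.null(in_cyl)) in_cyl <- matrix(TRUE, np, nt)
  top <- make_chain_topology(0L + 1L, beads = 1L, n_water = np)
  # one dummy peptide chain far away so the topology is valid
  frames <- lapply(seq_len(nt), function(t) {
    xy <- matrix(rep(box[1:2] / 2, each = np), np, 2)
    xy[!in_cyl[, t], 1] <- box[1] / 2 + cylinder_radius + 1.5
    coords <- rbind(c(0.5, 0.5, 0.5),
                    cbind(xy, z_paths[, t]))
    traj_frame(t - 1, box, coords)
  })
  trajectory(top, frames)
}

expect_same_partition <- function(cl, membership_oracle) {
  got <- canonical_partition(as.integer(cl$membership))
  want <- canonical_partition(membership_oracle)
  expect_identical(got, want)
}
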
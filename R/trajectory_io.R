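# Trajectory reading/writing.  Frames use a plain-text multi-frame GRO
# dialect (concatenated GRO blocks whose title lines carry "t= <ns>"); the
# topology is taken from the first block of the topology file, with roles
# inferred from residue/atom names through the config role map.  PDB
# topologies are supported through bio3d when installed.

parse_gro_blocks <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("malformed GRO block at line ", i + 1L)
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]
    box <- as.numeric(box_line)
    if (length(box) > 3L) {
      if (any(abs(box[-(1:3)]) > 1e-9)) stop("triclinic boxes are not supported")
      box <- box[1:3]
    }
    tm <- NA_real_
    m <- regmatches(title, regexec("t=\\s*([0-9eE+.\\-]+)", title))[[1]]
    if (length(m) == 2L) tm <- as.numeric(m[2])
    blocks[[length(blocks) + 1L]] <- list(
      time = tm,
      natoms = natoms,
      resid = as.integer(substr(atom_lines, 1, 5)),
      resname = trimws(substr(atom_lines, 6, 10)),
      atom_name = trimws(substr(atom_lines, 11, 15)),
      coords = cbind(as.numeric(substr(atom_lines, 21, 28)),
                     as.numeric(substr(atom_lines, 29, 36)),
                     as.numeric(substr(atom_lines, 37, 44))),
      box = box
    )
    i <- i + 3L + natoms
  }
  if (!length(blocks)) stop("no GRO blocks found in ", path)
  blocks
}

infer_roles <- function(resname, atom_name, role_map) {
  role <- rep(NA_character_, length(resname))
  up <- toupper(resname)
  role[up %in% toupper(role_map$peptide)] <- "peptide"
  role[up %in% toupper(role_map$water)] <- "water"
  role[up %in% toupper(role_map$ion)] <- "ion"
  lip <- up %in% toupper(role_map$lipid)
  head <- toupper(atom_name) %in% toupper(role_map$lipid_head_atoms)
  role[lip & head] <- "lipid_head"
  role[lip & !head] <- "lipid_tail"
  if (anyNA(role))
    stop("cannot infer a role for residue name(s): ",
         paste(unique(resname[is.na(role)]), collapse = ", "),
         " (extend config$role_map)")
  role
}

topology_from_atoms <- function(resid, resname, atom_name, config) {
  role <- infer_roles(resname, atom_name, config$role_map)
  particles <- data.frame(
    role = role,
    chain_id = ifelse(role == "peptide", resid, NA_integer_),
    mass = config$bead_mass,
    vdw_radius = config$bead_radius,
    resname = resname,
    resid = resid,
    atom_name = atom_name,
    backbone = role == "peptide",
    stringsAsFactors = FALSE
  )
  topology(particles)
}

read_pdb_atoms <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB topologies requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  list(resid = as.integer(a$resno), resname = a$resid, atom_name = a$elety,
       coords = cbind(a$x, a$y, a$z) / 10)  # Angstrom -> nm
}

#' Load a trajectory from topology and frame files
#'
#' The topology file is a GRO (or PDB) structure whose residue and atom
#' names identify particle roles through `config$role_map`; its coordinates
#' double as frame 0 when no separate frames file is given.  The frames
#' file is a concatenation of GRO blocks, one per frame, with frame times
#' in the title lines (`t= <ns>`).
#'
#' @param topology_path GRO or PDB file defining the particles.
#' @param frames_path multi-frame GRO file; defaults to `topology_path`.
#' @param config an [analysis_config()].
#' @return an `mp_trajectory`.
#' @export
load_trajectory <- function(topology_path, frames_path = topology_path,
                            config = analysis_config()) {
  if (!file.exists(topology_path)) stop("missing file: ", topology_path)
  if (!file.exists(frames_path)) stop("missing file: ", frames_path)
  is_pdb <- grepl("\\.pdb$", topology_path, ignore.case = TRUE)
  if (is_pdb) {
    at <- read_pdb_atoms(topology_path)
    top <- topology_from_atoms(at$resid, at$resname, at$atom_name, config)
    if (identical(topology_path, frames_path))
      stop("a PDB topology needs a separate frames file")
  } else {
    tb <- parse_gro_blocks(topology_path)[[1L]]
    top <- topology_from_atoms(tb$resid, tb$resname, tb$atom_name, config)
  }
  blocks <- parse_gro_blocks(frames_path)
  n <- nrow(top$particles)
  frames <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (b$natoms != n)
      stop(sprintf("particle-count mismatch: topology has %d, frame %d has %d",
                   n, k, b$natoms))
    tm <- if (is.na(b$time)) k - 1 else b$time
    frames[[k]] <- traj_frame(tm, b$box, b$coords)
  }
  trajectory(top, frames)
}

format_gro_block <- function(top, fr) {
  p <- top$particles
  n <- nrow(p)
  resid <- p$resid %% 100000L
  atnum <- seq_len(n) %% 100000L
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   resid, substr(p$resname, 1, 5), substr(p$atom_name, 1, 5),
                   atnum, fr$coords[, 1], fr$coords[, 2], fr$coords[, 3])
  c(sprintf("mempore frame t= %.6f ns", fr$time),
    sprintf("%5d", n),
    lines,
    sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]))
}

#' Write a trajectory to the multi-frame GRO dialect
#'
#' Writes every frame as a GRO block (coordinates at 0.001 nm precision).
#' When `topology_path` differs from `frames_path`, the first frame is
#' additionally written there as a standalone structure file.
#'
#' @param traj an `mp_trajectory`.
#' @param frames_path output file for the frame series.
#' @param topology_path optional separate structure file.
#' @return invisibly, `frames_path`.
#' @export
write_trajectory <- function(traj, frames_path, topology_path = NULL) {
  stopifnot(inherits(traj, "mp_trajectory"))
  if (length(traj$frames) == 0L) stop("nothing to write: trajectory has no frames")
  out <- unlist(lapply(traj$frames, function(fr)
    format_gro_block(traj$topology, fr)))
  writeLines(out, frames_path)
  if (!is.null(topology_path) && !identical(topology_path, frames_path))
    writeLines(format_gro_block(traj$topology, traj$frames[[1L]]), topology_path)
  invisible(frames_path)
}
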
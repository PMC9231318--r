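# Analysis configuration: every tunable the analyses share, with the
# defaults used throughout (310 K, 1.5 nm cluster rule, 0.4 nm contact rule,
# channel span 2.32-6.55 nm, 0.14 nm probe).

default_role_map <- function() {
  list(
    peptide = c("PEP", "AMB", "ABET"),
    water   = c("W", "SOL", "WAT", "TIP3"),
    ion     = c("ION", "NA", "NA+", "CL", "CL-", "SOD", "CLA"),
    lipid   = c("DPPC", "POPC"),
    lipid_head_atoms = c("NC3", "PO4", "N", "P", "GL1", "GL2")
  )
}

#' Analysis configuration
#'
#' Collects the shared parameters of the pipeline.  Energies are in
#' kcal/mol, lengths in nm, times in ns, temperature in K.
#'
#' @param temperature simulation temperature (K).
#' @param cluster_cutoff centre-of-mass distance below which two peptides
#'   belong to the same cluster (nm, strict `<`).
#' @param contact_cutoff direct-contact distance between a solvent particle
#'   and any peptide particle (nm, strict `<`).
#' @param channel_z numeric length 2: the z-span of the channel (nm).
#' @param probe_radius solvent probe radius for accessible surface area (nm).
#' @param fel_bins integer length 2: bins per axis of the 2D free-energy
#'   landscape.
#' @param cylinder_radius radius of the axial sampling cylinder for density
#'   profiles and permeation counting (nm).
#' @param bulk_margin distance beyond the channel span at which the bulk
#'   region starts (nm).
#' @param bulk_cross_section `"box"` (full box cross-section, the default)
#'   or `"cylinder"` (same sampling cylinder as the channel) for the bulk
#'   density normalisation.
#' @param sasa_points number of deterministic sphere points per particle for
#'   the Shrake-Rupley estimate.
#' @param sasa_context `"peptides_only"` (only peptide particles occlude) or
#'   `"with_lipids"` (lipid particles occlude as well, but only peptide area
#'   is summed).
#' @param com_weighting `"mass"` or `"geometric"` centre of mass.
#' @param connectivity 8 or 4: grid connectivity for basins and minimax
#'   paths on the landscape.
#' @param role_map named list mapping residue names to particle roles, plus
#'   `lipid_head_atoms` (atom names counted as lipid head particles).
#' @param bead_mass default particle mass (amu) for coarse-grained beads.
#' @param bead_radius default van der Waals radius (nm) for coarse-grained
#'   beads (half the common 0.47 nm bead diameter).
#' @return an object of class `mp_config` (a named list).
#' @export
analysis_config <- function(temperature = 310,
                            cluster_cutoff = 1.5,
                            contact_cutoff = 0.4,
                            channel_z = c(2.32, 6.55),
                            probe_radius = 0.14,
                            fel_bins = c(50L, 50L),
                            cylinder_radius = 1.0,
                            bulk_margin = 1.0,
                            bulk_cross_section = c("box", "cylinder"),
                            sasa_points = 960L,
                            sasa_context = c("peptides_only", "with_lipids"),
                            com_weighting = c("mass", "geometric"),
                            connectivity = 8L,
                            role_map = default_role_map(),
                            bead_mass = 72,
                            bead_radius = 0.235) {
  stopifnot(temperature > 0, cluster_cutoff > 0, contact_cutoff > 0,
            length(channel_z) == 2L, channel_z[1] < channel_z[2],
            probe_radius > 0, all(fel_bins >= 2),
            cylinder_radius > 0, bulk_margin >= 0,
            connectivity %in% c(4L, 8L), bead_mass > 0, bead_radius > 0)
  cfg <- list(
    temperature = temperature,
    cluster_cutoff = cluster_cutoff,
    contact_cutoff = contact_cutoff,
    channel_z = as.numeric(channel_z),
    probe_radius = probe_radius,
    fel_bins = as.integer(fel_bins),
    cylinder_radius = cylinder_radius,
    bulk_margin = bulk_margin,
    bulk_cross_section = match.arg(bulk_cross_section),
    sasa_points = as.integer(sasa_points),
    sasa_context = match.arg(sasa_context),
    com_weighting = match.arg(com_weighting),
    connectivity = as.integer(connectivity),
    role_map = role_map,
    bead_mass = bead_mass,
    bead_radius = bead_radius
  )
  class(cfg) <- "mp_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Keys missing from the file keep their [analysis_config()] defaults.
#'
#' @param path YAML file.
#' @return an `mp_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.mp_config <- function(x, ...) {
  cat("Analysis configuration (mempore)\n")
  cat(sprintf("  temperature      : %g K\n", x$temperature))
  cat(sprintf("  cluster cutoff   : %g nm\n", x$cluster_cutoff))
  cat(sprintf("  contact cutoff   : %g nm\n", x$contact_cutoff))
  cat(sprintf("  channel z-span   : %g - %g nm\n", x$channel_z[1], x$channel_z[2]))
  cat(sprintf("  probe radius     : %g nm\n", x$probe_radius))
  cat(sprintf("  FEL bins         : %d x %d\n", x$fel_bins[1], x$fel_bins[2]))
  invisible(x)
}

# run a block with a locally set RNG seed, restoring global state after
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
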
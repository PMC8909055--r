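# Fixtures built in code: voxel-based DVHs for oracle comparisons, small
# registries and cohorts.

# Bin a vector of simulated voxel doses into a differential structure_dvh
# (equal-volume voxels, bin mass at the bin center).
voxel_dvh <- function(doses, bin_width = 0.1, volume_cc = 10,
                      structure_id = "oracle") {
  edges <- seq(0, max(doses) + bin_width, by = bin_width)
  idx <- findInterval(doses, edges, rightmost.closed = FALSE)
  centers <- edges[-length(edges)] + bin_width / 2
  frac <- tabulate(idx, nbins = length(centers)) / length(doses)
  # keep empty bins: the grid spacing, not the occupied-bin spacing, bounds
  # the interpolation error of the Dx% lookup
  structure_dvh(structure_id, volume_cc, centers, frac, "differential")
}

uniform_dvh <- function(dose, volume_cc = 10, structure_id = "uniform") {
  structure_dvh(structure_id, volume_cc, dose, 1, "differential")
}

# random differential DVH on an 0.1-Gy-spaced grid
random_dvh <- function(n_bins = 10, volume_cc = 10, structure_id = "rand") {
  dose <- sort(sample(seq(0.5, 70, by = 0.1), n_bins))
  frac <- stats::runif(n_bins)
  frac <- frac / sum(frac)
  structure_dvh(structure_id, volume_cc, dose, frac, "differential")
}

# one-structure plan around a single DVH
plan_of <- function(dvh, patient_id = "P001", modality = "photon") {
  structs <- list(dvh)
  names(structs) <- dvh$structure_id
  plan_record(patient_id, modality, structs)
}

# minimal fast generator config (coarse bins, few structures)
small_config <- function(n = 6, seed = 1, structures = NULL, ...) {
  generator_config(n_patients = n, seed = seed, structures = structures,
                   bin_width = 0.5, ...)
}

# zero delta vector over the default registry
zero_delta <- function(registry = default_registry()) {
  stats::setNames(rep(0, length(registry$models)), names(registry$models))
}
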
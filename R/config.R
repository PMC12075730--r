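#' Screening and search configuration
#'
#' Collects every tunable threshold of the pipeline in one object. The
#' defaults are the published cutoffs of the screening protocol (resolution,
#' S-N distance, occupancy, RSRZ) together with the embedding/clustering
#' policy used by the descriptor-subset search.
#'
#' @param max_resolution Maximum crystallographic resolution retained
#'   (Angstrom, inclusive). Default 2.0.
#' @param max_sn_dist Maximum S-N contact distance (Angstrom, inclusive).
#'   Default 3.2, the covalent-interaction cutoff for Lys/Cys NOS bridges.
#' @param min_occupancy Occupancy threshold for the two target atoms
#'   (strict: occupancy must exceed this). Default 0.8.
#' @param max_rsrz Per-residue RSRZ threshold (strict: RSRZ must be below
#'   this). Default 2.0.
#' @param neighbor_radius Radius (Angstrom, inclusive) around a residue's
#'   C-alpha used by the packing descriptors Ngb^N / Ngb^S. Default 4.0.
#' @param sasa_probe_radius Solvent probe radius (Angstrom). Default 1.4.
#' @param sasa_points Number of deterministic sphere points per atom in the
#'   Shrake-Rupley quadrature. Default 960.
#' @param sasa_default_radius Van der Waals radius (Angstrom) used, with a
#'   warning, for elements outside the documented radius table. Default 1.70.
#' @param min_silhouette Silhouette acceptance gate for a descriptor subset.
#'   Default 0.5.
#' @param min_clusters,max_clusters Acceptable cluster-count range for a
#'   descriptor subset. Defaults 2 and 3.
#' @param ref_leak_tolerance Maximum number of reference linkages allowed
#'   outside the probable clusters. Default 2.
#' @param umap_n_neighbors,umap_min_dist,umap_n_epochs UMAP embedding
#'   parameters. Defaults 15, 0.1 and 200.
#' @param seed Integer seed used for the embedding whenever no explicit seed
#'   is passed downstream. Default 42.
#' @param ms_quantile Neighbourhood quantile of the mean-shift bandwidth
#'   heuristic (average distance to the `floor(n * quantile)`-th nearest
#'   neighbour). Default 0.3, the conventional mean-shift default; smaller
#'   values fragment diffuse embedded clusters.
#' @param covalent_max Maximum distance (Angstrom, inclusive) at which a
#'   carbon counts as covalently bound to the target S or N. Default 1.9.
#' @param dist_epsilon Numerical guard (Angstrom) added to inclusive distance
#'   cutoffs so that text-format round-off at a boundary cannot flip the
#'   decision. Default 1e-4, below the precision of any coordinate format
#'   read by the package.
#' @param include_met Keep methionine SD as a sulfur donor in the default
#'   target classes? Default FALSE (Met contacts are enumerated and
#'   tabulated, but the candidate classes use cysteine only).
#' @param include_excluded_classes Keep Cys-Cys backbone and His-Cys classes
#'   in the default target classes? Default FALSE (disulfide bridges and
#'   metal-coordinating histidines dominate those contacts).
#' @param water_residues Residue names treated as water and excluded from
#'   SASA and packing computations.
#'
#' @return A list of class `"nos_config"`.
#' @export
#' @examples
#' cfg <- screening_config()
#' cfg$max_sn_dist
screening_config <- function(max_resolution = 2.0,
                             max_sn_dist = 3.2,
                             min_occupancy = 0.8,
                             max_rsrz = 2.0,
                             neighbor_radius = 4.0,
                             sasa_probe_radius = 1.4,
                             sasa_points = 960,
                             sasa_default_radius = 1.70,
                             min_silhouette = 0.5,
                             min_clusters = 2,
                             max_clusters = 3,
                             ref_leak_tolerance = 2,
                             umap_n_neighbors = 15,
                             umap_min_dist = 0.1,
                             umap_n_epochs = 200,
                             seed = 42L,
                             ms_quantile = 0.3,
                             covalent_max = 1.9,
                             dist_epsilon = 1e-4,
                             include_met = FALSE,
                             include_excluded_classes = FALSE,
                             water_residues = c("HOH", "WAT", "DOD")) {
  cfg <- list(
    max_resolution = max_resolution, max_sn_dist = max_sn_dist,
    min_occupancy = min_occupancy, max_rsrz = max_rsrz,
    neighbor_radius = neighbor_radius,
    sasa_probe_radius = sasa_probe_radius, sasa_points = sasa_points,
    sasa_default_radius = sasa_default_radius,
    min_silhouette = min_silhouette,
    min_clusters = min_clusters, max_clusters = max_clusters,
    ref_leak_tolerance = ref_leak_tolerance,
    umap_n_neighbors = umap_n_neighbors, umap_min_dist = umap_min_dist,
    umap_n_epochs = umap_n_epochs, seed = as.integer(seed),
    ms_quantile = ms_quantile, covalent_max = covalent_max,
    dist_epsilon = dist_epsilon,
    include_met = include_met,
    include_excluded_classes = include_excluded_classes,
    water_residues = water_residues
  )
  thr <- c("max_resolution", "max_sn_dist", "min_occupancy", "max_rsrz",
           "neighbor_radius", "sasa_probe_radius", "covalent_max")
  bad <- thr[vapply(cfg[thr], function(x) !is.numeric(x) || x <= 0, logical(1))]
  if (length(bad) > 0)
    stop("screening_config: thresholds must be positive: ",
         paste(bad, collapse = ", "))
  if (min_clusters > max_clusters)
    stop("screening_config: min_clusters must be <= max_clusters")
  class(cfg) <- "nos_config"
  cfg
}
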
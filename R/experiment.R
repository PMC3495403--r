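# End-to-end recovery experiment ---------------------------------------------
#
# Simulates two populations whose genomes differ by a planted rearrangement
# set, maps both from pedigree genotypes, and compares the recovered maps.
# The reference population plays the role of the published map: its
# recovered groups are relabelled and oriented against its truth table
# (published maps carry the field's chromosome nomenclature and orientation
# convention), exactly as a new map is compared against a published one.

#' Simulate, map and compare two populations differing by planted events
#'
#' The default planted set mirrors the three rearrangements separating the
#' two Atlantic salmon karyotypes: a whole-arm translocation of the p arm of
#' a metacentric onto an acrocentric (leaving the q-arm residue), a
#' head-to-head Robertsonian fusion of two acrocentrics, and a tail-to-head
#' tandem fusion of an acrocentric onto a metacentric's q arm.
#'
#' @param seed RNG seed driving the whole experiment.
#' @param n_chromosomes,markers_per_chromosome,female_length_cM,male_length_cM,shared_fraction,telomere_window,telomere_mass,arm_split
#'   passed to [simulate_truth_maps()].
#' @param metacentric metacentric reference chromosomes.
#' @param events planted [rearrangement_event()] list (`NULL` for the
#'   default three-event set, which uses chromosomes `chr01`, `chr08`,
#'   `chr23`, `chr26`, `chr28` and `chr29` of the default 29-chromosome
#'   reference, leaving the query with 27 groups).
#' @param n_families,offspring_per_family,half_sib_fraction,missing_rate
#'   pedigree parameters per population.
#' @param lod_threshold,mapping_function,min_shared,max_interlopers mapping
#'   and comparison parameters.
#' @return List: `sim` (truth), `map_reference`, `map_query` (recovered map
#'   tables), `comparison` ([compare_maps()] result).
#' @export
run_comparison_experiment <- function(seed,
                                      n_chromosomes = 29L,
                                      markers_per_chromosome = 24L,
                                      female_length_cM = 80,
                                      male_length_cM = 36,
                                      shared_fraction = 0.83,
                                      telomere_window = 0.1,
                                      telomere_mass = 0.9,
                                      arm_split = 0.45,
                                      metacentric = c("chr01", "chr08"),
                                      events = NULL,
                                      n_families = 40L,
                                      offspring_per_family = 20L,
                                      half_sib_fraction = 0.15,
                                      missing_rate = 0.02,
                                      lod_threshold = 10,
                                      mapping_function = "kosambi",
                                      min_shared = 3L,
                                      max_interlopers = 5L) {
  if (is.null(events)) {
    events <- list(
      rearrangement_event("whole_arm_translocation", c("chr01p", "chr23")),
      rearrangement_event("robertsonian_fusion", c("chr26", "chr28"),
                          polymorphic = TRUE),
      rearrangement_event("tandem_fusion", c("chr08", "chr29"),
                          polymorphic = TRUE)
    )
  }
  set.seed(seed)
  sim <- simulate_truth_maps(
    n_chromosomes = n_chromosomes,
    female_lengths_cM = female_length_cM,
    male_lengths_cM = male_length_cM,
    markers_per_chromosome = markers_per_chromosome,
    shared_fraction = shared_fraction,
    events = events, metacentric = metacentric, arm_split = arm_split,
    telomere_window = telomere_window, telomere_mass = telomere_mass)

  published_ref <- truth_to_map_table(sim$reference)

  pg_ref <- simulate_pedigree_genotypes(
    sim$reference, n_families = n_families,
    offspring_per_family = offspring_per_family,
    half_sib_fraction = half_sib_fraction, missing_rate = missing_rate)
  res_ref <- build_linkage_maps(pg_ref, lod_threshold = lod_threshold,
                                mapping_function = mapping_function,
                                reference = published_ref)
  map_ref <- relabel_groups(res_ref$map, published_ref)

  pg_qry <- simulate_pedigree_genotypes(
    sim$query, n_families = n_families,
    offspring_per_family = offspring_per_family,
    half_sib_fraction = half_sib_fraction, missing_rate = missing_rate)
  # co-segregating bins in the query map are tie-broken by the reference
  # population's map, as a new map is ordered against a published one
  res_qry <- build_linkage_maps(pg_qry, lod_threshold = lod_threshold,
                                mapping_function = mapping_function,
                                reference = map_ref)
  map_qry <- res_qry$map

  comparison <- compare_maps(map_ref, map_qry,
                             reference_karyotype = sim$reference_karyotype,
                             min_shared = min_shared,
                             max_interlopers = max_interlopers)
  list(sim = sim, map_reference = map_ref, map_query = map_qry,
       comparison = comparison,
       singletons = list(reference = res_ref$singletons,
                         query = res_qry$singletons))
}
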
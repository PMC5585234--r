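# Shared synthetic-world fixtures, built in code at test time.

# A compact world for fast unit tests: 24 cells, modest effort.
small_world <- function(seed = 1, ...) {
  simulate_world(world_config(lat_extent = 12, n_lon = 1,
                              modern_effort = 30, fossil_effort = 10,
                              seed = seed, ...))
}

# The study-scale world used by recovery checks (lat 35S-35N, 140 cells).
study_world <- function(seed = 42, ...) {
  simulate_world(world_config(seed = seed, ...))
}

toy_occurrence_path <- function() {
  system.file("extdata", "toy_occurrences.csv", package = "coralclim")
}

# A rank-r proportion matrix built from r archetype assemblages mixed with
# positive weights; rows sum to 1 by construction.
archetype_matrix <- function(n_cells, n_taxa, r = 2, seed = 1) {
  set.seed(seed)
  arch <- matrix(runif(r * n_taxa), r, n_taxa,
                 dimnames = list(NULL, sprintf("t%02d", seq_len(n_taxa))))
  arch <- arch / rowSums(arch)
  mix <- matrix(runif(n_cells * r), n_cells, r)
  mix <- mix / rowSums(mix)
  list(props = mix %*% arch, mix = mix, archetypes = arch)
}
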
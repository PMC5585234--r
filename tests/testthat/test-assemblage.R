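test_that("depth filter is boundary-inclusive and symbiont filter drops azoox", {
  rec <- data.frame(taxon = letters[1:3], genus = letters[1:3],
                    depth_m = c(59.9, 60.0, 60.1),
                    zooxanthellate = TRUE)
  out <- filter_records(rec)
  expect_equal(out$depth_m, c(59.9, 60.0))
  expect_equal(unname(attr(out, "dropped")["deep"]), 1)

  azoox <- data.frame(taxon = "a", genus = "a", depth_m = 10,
                      zooxanthellate = FALSE)
  expect_equal(nrow(filter_records(azoox)), 0)
  expect_equal(nrow(filter_records(azoox, require_zoox = FALSE)), 1)

  nadep <- data.frame(taxon = "a", genus = "a", depth_m = NA,
                      zooxanthellate = TRUE)
  expect_warning(kept <- filter_records(nadep), "missing depth")
  expect_equal(nrow(kept), 1)
  expect_equal(nrow(suppressWarnings(
    filter_records(nadep, keep_missing_depth = FALSE))), 0)
})

test_that("the packaged toy table filters to the hand-enumerated record set", {
  occ <- read_occurrences(toy_occurrence_path())
  expect_equal(nrow(occ), 10)
  out <- filter_records(occ)
  # by hand: rows 4, 9 deep; 5 azoox; 6 both -> 6 survive
  expect_equal(nrow(out), 6)
  expect_equal(sort(out$taxon),
               sort(c("Acropora_a", "Acropora_a", "Porites_b", "Favia_d",
                      "Favia_d", "Acropora_f")))
  # 3 deep and 2 azoox with 1 overlap; the overlap is tallied under azoox
  expect_equal(unname(attr(out, "dropped")), c(2, 2, 0))
})

test_that("cell assignment uses floor semantics on normalized coordinates", {
  expect_equal(assign_cell(12.7, -61.3), data.frame(lat_index = 12L,
                                                    lon_index = -62L))
  expect_equal(assign_cell(-0.2, 0.0), data.frame(lat_index = -1L,
                                                  lon_index = 0L))
  expect_equal(assign_cell(12.0, -61.0), data.frame(lat_index = 12L,
                                                    lon_index = -61L))
  # longitude wrap-around into [-180, 180)
  expect_equal(assign_cell(0.5, 190.5)$lon_index, -170L)
  expect_equal(assign_cell(0.5, 180)$lon_index, -180L)
  expect_error(assign_cell(95, 0), "\\[-90, 90\\)")
  expect_error(assign_cell(NA, 0), "finite")
})

test_that("assemblage proportions match hand-computed counts", {
  rec <- data.frame(
    taxon = c("A", "A", "B", "B", "A", "A", "A", "C", "B", "C"),
    genus = c("gA", "gA", "gB", "gB", "gA", "gA", "gA", "gC", "gB", "gC"),
    lat = c(rep(0.5, 4), rep(1.5, 3), rep(2.5, 3)),
    lon = 10.5, epoch = "modern")
  m <- build_matrix(rec, "species")
  expect_equal(dim(m$props), c(3, 3))
  # cell (0,10): {A:2, B:2} -> 0.5 / 0.5; cell (1,10): {A:3} -> 1;
  # cell (2,10): {B:1, C:2} -> 1/3, 2/3
  expect_equal(unname(m$props["0:10", ]), c(0.5, 0.5, 0))
  expect_equal(unname(m$props["1:10", ]), c(1, 0, 0))
  expect_equal(unname(m$props["2:10", ]), c(0, 1 / 3, 2 / 3))
  expect_equal(unname(rowSums(m$props)), rep(1, 3), tolerance = 1e-12)
  # order independence up to the canonical ordering
  set.seed(1)
  shuffled <- rec[sample.int(nrow(rec)), ]
  expect_equal(build_matrix(shuffled, "species")$props, m$props)
  # genus rank collapses species labels
  g <- build_matrix(rec, "genus")
  expect_equal(g$taxa, c("gA", "gB", "gC"))
  expect_equal(unname(g$props["0:10", ]), c(0.5, 0.5, 0))
  # presence-only mode counts each taxon once per cell
  pm <- build_matrix(rec, "species", presence_only = TRUE)
  expect_equal(unname(pm$props["2:10", ]), c(0, 0.5, 0.5))
})

test_that("single-genus cells are excluded and the filter is idempotent", {
  # 6 cells with genus richness 1, 1, 2, 2, 3, 5
  richness <- c(1, 1, 2, 2, 3, 5)
  rec <- do.call(rbind, lapply(seq_along(richness), function(i) {
    data.frame(taxon = paste0("sp", seq_len(richness[i])),
               genus = paste0("g", seq_len(richness[i])),
               lat = i + 0.5, lon = 0.5, epoch = "modern")
  }))
  m <- build_matrix(rec, "species")
  f <- apply_cell_filters(m, min_genera = 2)
  expect_equal(nrow(f$props), 4)
  expect_equal(nrow(attr(f, "dropped_cells")), 2)
  expect_equal(apply_cell_filters(f, 2)$props, f$props)  # idempotent
  expect_error(apply_cell_filters(m, min_genera = 10), "all cells removed")
  # species-rank matrix uses the genus map: 5 congeneric species drop
  rec2 <- data.frame(taxon = paste0("sp", 1:5), genus = "gA",
                     lat = 0.5, lon = 0.5, epoch = "modern")
  expect_error(apply_cell_filters(build_matrix(rec2, "species"), 2),
               "all cells removed")
})

test_that("taxon harmonization intersects, renormalizes and re-filters", {
  mk <- function(taxa, genera, props, epoch) {
    rec <- data.frame(taxon = rep(taxa, props), genus = rep(genera, props),
                      lat = 0.5, lon = 0.5, epoch = epoch)
    build_matrix(rec, "species")
  }
  modern <- mk(c("A", "B", "C"), c("gA", "gB", "gC"), c(5, 3, 2), "modern")
  fossil <- mk(c("B", "C", "D"), c("gB", "gC", "gD"), c(1, 1, 2), "LIG")
  h <- harmonize_taxa(modern, fossil, min_genera = 2)
  expect_equal(h$modern$taxa, c("B", "C"))
  expect_equal(h$fossil$taxa, c("B", "C"))
  # modern row (0.5, 0.3, 0.2) restricted to {B, C} -> (0.6, 0.4)
  expect_equal(unname(h$modern$props[1, ]), c(0.6, 0.4), tolerance = 1e-12)
  expect_equal(unname(rowSums(h$fossil$props)), 1, tolerance = 1e-12)

  none <- mk("Z", "gZ", 2L, "LIG")
  expect_error(harmonize_taxa(modern, none), "no taxa shared")
})

test_that("a synthetic fossil gap leaves a clean shared pool", {
  w <- small_world(seed = 9)
  modern <- build_matrix(filter_records(w$modern_occ), "species")
  # fossil sampling that misses 5 of the species
  drop <- w$pool$taxon_id[1:5]
  focc <- filter_records(w$fossil_occ)
  focc <- focc[!(focc$taxon %in% drop), ]
  fossil <- build_matrix(focc, "species")
  h <- harmonize_taxa(apply_cell_filters(modern), apply_cell_filters(fossil))
  expect_true(all(!(drop %in% h$modern$taxa)))
  expect_equal(h$modern$taxa, h$fossil$taxa)
  expect_equal(unname(rowSums(h$modern$props)),
               rep(1, nrow(h$modern$props)), tolerance = 1e-12)
  expect_equal(unname(rowSums(h$fossil$props)),
               rep(1, nrow(h$fossil$props)), tolerance = 1e-12)
})

test_that("assemblage matrices round-trip through CSV + JSON sidecar", {
  w <- small_world(seed = 2)
  m <- apply_cell_filters(build_matrix(filter_records(w$modern_occ)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_assemblage(m, path)
  m2 <- read_assemblage(path)
  expect_equal(m2$props, m$props, tolerance = 1e-12)
  expect_equal(m2$taxa, m$taxa)
  expect_equal(m2$rank, m$rank)
  expect_equal(m2$genus_map, m$genus_map)
})
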
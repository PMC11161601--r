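# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# standard noise-free organoid plus its segmentation chain
org_fixture_clean <- function() fixture("org_clean", function() {
  gen <- gen_organoid_image(synthetic_organoid_spec(noise_sd = 0, seed = 101))
  org <- segment_organoid(gen$image)[[1]]
  nuc <- detect_nuclei(get_channel(gen$image, "DAPI"), org)
  cm <- segment_cells(nuc, gen$image, org)
  list(gen = gen, org = org, nuclei = nuc, cellmap = cm)
})

# same organoid with mild noise
org_fixture_noisy <- function() fixture("org_noisy", function() {
  gen <- gen_organoid_image(synthetic_organoid_spec(noise_sd = 2, seed = 101))
  org <- segment_organoid(gen$image)[[1]]
  nuc <- detect_nuclei(get_channel(gen$image, "DAPI"), org)
  cm <- segment_cells(nuc, gen$image, org)
  list(gen = gen, org = org, nuclei = nuc, cellmap = cm)
})

# disk-shaped organoid mask at a given radius, in um
disk_mask <- function(radius_um, pixel_size_um = 0.5, dims = c(256, 256)) {
  ctr <- (dims - 1) / 2
  d <- sqrt(outer(((seq_len(dims[1]) - 1) - ctr[1])^2,
                  ((seq_len(dims[2]) - 1) - ctr[2])^2, "+"))
  mechanoquant:::new_organoid_mask(d <= radius_um / pixel_size_um,
                                   pixel_size_um)
}

# match segmented cell labels to generator truth via the true nucleus center
match_cells_to_truth <- function(cellmap, truth) {
  tc <- truth$cells
  lab <- cellmap$cells[cbind(round(tc$nucleus_row) + 1,
                             round(tc$nucleus_col) + 1)]
  data.frame(truth_cell = tc$cell, seg_label = lab)
}
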
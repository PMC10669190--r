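test_that("multi-model PDB + sidecar round-trips coordinates and topology", {
  ens <- sample_helix_coil(spec406(), helix_coil_model(0.5, n_frames = 10,
                                                       seed = 9))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_ensemble(ens, pdb, sidecar = yml)
  back <- read_ensemble(pdb, yml)
  expect_identical(n_frames(back), 10L)
  for (f in c(1, 5, 10)) {
    expect_equal(back$coords[[f]], ens$coords[[f]], tolerance = 2e-3)
  }
  expect_identical(back$topology$name, ens$topology$name)
  expect_identical(back$topology$res_index, ens$topology$res_index)
  expect_identical(back$topology$fragment, ens$topology$fragment)
  expect_identical(attr(back$topology, "spec")$center_position, 406L)
})

test_that("liganded ensembles round-trip with fragment labels intact", {
  ens <- liganded_ensemble()
  small <- split_blocks(ens, 100)[[1]]
  pdb <- withr::local_tempfile(fileext = ".pdb")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_ensemble(small, pdb, sidecar = yml)
  back <- read_ensemble(pdb, yml)
  expect_identical(back$topology$fragment, small$topology$fragment)
  expect_equal(back$coords[[1]], small$coords[[1]], tolerance = 2e-3)
})

test_that("a single-model PDB reads as a one-frame ensemble", {
  built <- helix_frame()
  ens <- pept_ensemble(built$topology, list(built$coords))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_ensemble(ens, pdb, sidecar = yml)
  expect_identical(n_frames(read_ensemble(pdb, yml)), 1L)
})

test_that("a model with a missing atom is rejected, naming the model", {
  ens <- sample_helix_coil(spec406(), helix_coil_model(0.5, n_frames = 4,
                                                       seed = 2))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_ensemble(ens, pdb, sidecar = yml)
  lines <- readLines(pdb)
  starts <- which(startsWith(lines, "MODEL"))
  drop <- starts[3] + 5  # an ATOM line inside model 3
  writeLines(lines[-drop], pdb)
  expect_error(read_ensemble(pdb, yml), "model 3")
})

test_that("the packaged registry matches the 14-system study design", {
  reg <- load_registry()
  expect_identical(nrow(reg), 14L)
  expect_identical(sum(reg$center == 406), 7L)
  expect_identical(sum(reg$center == 327), 4L)
  expect_identical(sum(reg$center == 240), 3L)
  expect_setequal(unique(reg$start), c("H", "E"))
  expect_false(anyDuplicated(reg$notation) > 0)
  expect_true("XNN_4H" %in% reg$notation)
})

test_that("registry validation flags duplicates and bad codes; empty is fine", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("notation,center,start,ligand,run_ns,ion,n_water",
               "A_4H,406,H,none,50,none,100",
               "A_4H,406,H,none,50,none,100"), f)
  expect_error(load_registry(f), "duplicate")
  writeLines(c("notation,center,start,ligand,run_ns,ion,n_water",
               "A_9H,999,H,none,50,none,100"), f)
  expect_error(load_registry(f), "centre")
  writeLines("notation,center,start,ligand,run_ns,ion,n_water", f)
  expect_identical(nrow(load_registry(f)), 0L)
})

test_that("block splitting partitions contiguously with stated tie-break", {
  ens <- sample_helix_coil(spec406(), helix_coil_model(0.9, n_frames = 101,
                                                       seed = 5))
  b <- split_blocks(ens, 2)
  expect_identical(vapply(b, n_frames, 1L), c(51L, 50L))
  expect_identical(c(b[[1]]$coords, b[[2]]$coords), ens$coords)
  one <- split_blocks(ens, 1)
  expect_identical(one[[1]]$coords, ens$coords)
  even <- split_blocks(split_blocks(ens, 101)[[1]], 1)
  expect_identical(n_frames(even[[1]]), 1L)
  expect_error(split_blocks(even[[1]], 2), "cannot split")
  b3 <- split_blocks(ens, 3)
  expect_identical(vapply(b3, n_frames, 1L), c(34L, 34L, 33L))
})

test_that("equilibration discard trims leading frames only", {
  ens <- sample_helix_coil(spec406(), helix_coil_model(0.9, n_frames = 10,
                                                       seed = 6))
  tr <- discard_equilibration(ens, 4)
  expect_identical(n_frames(tr), 6L)
  expect_identical(tr$coords[[1]], ens$coords[[5]])
  expect_error(discard_equilibration(ens, 10), "zero frames")
})
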
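test_that("contact kernel agrees exactly with the brute-force all-pairs scan", {
  ens <- mix_ensemble()
  for (f in c(1, 7, 50)) {
    fast <- contact_map(ens$coords[[f]], ens$topology)
    slow <- bf_contact_map(ens$coords[[f]], ens$topology)
    expect_identical(unclass(fast)[, ], slow)
  }
  # liganded frames: ligand atoms excluded from residue sets in both routes
  lig <- liganded_ensemble()
  for (f in c(2, 11)) {
    fast <- contact_map(lig$coords[[f]], lig$topology)
    slow <- bf_contact_map(lig$coords[[f]], lig$topology)
    expect_identical(unclass(fast)[, ], slow)
    expect_identical(nrow(fast), 23L)
  }
})

test_that("the ideal helix gives the i,i+4 band and no i,i+8 contacts", {
  built <- helix_frame()
  m <- contact_map(built$coords, built$topology)
  for (i in 3:17) expect_identical(m[i, i + 4], 1)
  for (i in 2:14) expect_identical(m[i, i + 8], 0)
  e <- extended_frame()
  me <- contact_map(e$coords, e$topology)
  long <- abs(row(me) - col(me)) >= 3
  expect_identical(sum(me[long]), 0)
})

test_that("contacts are monotone in the cutoff, frame by frame", {
  ens <- mix_ensemble()
  for (f in c(3, 90)) {
    m1 <- contact_map(ens$coords[[f]], ens$topology, cutoff = 3.5)
    m2 <- contact_map(ens$coords[[f]], ens$topology, cutoff = 4.2)
    m3 <- contact_map(ens$coords[[f]], ens$topology, cutoff = 6)
    expect_true(all(m2[m1 == 1] == 1))
    expect_true(all(m3[m2 == 1] == 1))
  }
})

test_that("mean maps average per-frame maps and stay in [0, 1]", {
  ens <- mix_ensemble()
  sub <- split_blocks(ens, 10)[[1]]  # 20 frames
  mm <- mean_contact_map(sub)
  acc <- Reduce(`+`, lapply(sub$coords, bf_contact_map,
                            topology = sub$topology)) / n_frames(sub)
  expect_equal(unclass(mm)[, ], acc, tolerance = 1e-12)
  expect_true(all(mm >= 0 & mm <= 1))
  expect_identical(unclass(mm), t(unclass(mm)))
  # identical frames: mean equals the single-frame map
  built <- helix_frame()
  ens1 <- pept_ensemble(built$topology, list(built$coords, built$coords))
  expect_identical(unclass(mean_contact_map(ens1))[, ],
                   unclass(contact_map(built$coords, built$topology))[, ])
  # stride validation
  expect_error(mean_contact_map(sub, stride = 0))
})

test_that("helix-coil mean map matches directly counted contact frequency", {
  ens <- mix_ensemble()
  mm <- mean_contact_map(ens)
  for (i in c(6, 10, 14)) {
    counted <- mean(vapply(ens$coords, function(xyz) {
      bf_contact_map(xyz, ens$topology)[i, i + 4]
    }, 1))
    expect_equal(mm[i, i + 4], counted, tolerance = 1e-12)
  }
})

test_that("vectorization obeys the n(n-1)/2 length law and round-trips", {
  for (n in 2:30) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
    m <- m + t(m)
    diag(m) <- 1
    v <- vectorize_map(m)
    expect_length(v, n * (n - 1) / 2)
    expect_equal(unvectorize_map(v, n), m, tolerance = 1e-15)
  }
  # ordering is row-major over the strict upper triangle
  m <- matrix(0, 3, 3)
  m[1, 2] <- 0.1; m[1, 3] <- 0.2; m[2, 3] <- 0.3
  m <- m + t(m); diag(m) <- 1
  expect_equal(as.numeric(vectorize_map(m)), c(0.1, 0.2, 0.3))
  expect_error(vectorize_map(matrix(0, 2, 3)), "square")
})

test_that("the 23-unit map contributes 253 contact DOFs", {
  built <- helix_frame()
  v <- vectorize_map(contact_map(built$coords, built$topology))
  expect_length(v, 253)
  vecs <- contact_vectors(pept_ensemble(built$topology, list(built$coords)))
  expect_identical(dim(vecs), c(1L, 253L))
  expect_equal(vecs[1, ], as.numeric(v))
})

test_that("fragment profiles count per-frame fragment contacts correctly", {
  lig <- liganded_ensemble()
  pr <- fragment_contact_profile(lig)
  expect_true(all(pr$contact_pct[!is.na(pr$contact_pct)] >= 0 &
                    pr$contact_pct[!is.na(pr$contact_pct)] <= 100))
  # direct per-frame count as oracle for the biased entry
  b_atoms <- which(lig$topology$fragment %in% "B-ring")
  r5 <- lig$topology$atom[lig$topology$res_index == 5 &
                            lig$topology$res_name != "LIG"]
  counted <- mean(vapply(lig$coords, function(xyz) {
    min(as.matrix(dist(xyz[c(b_atoms, r5), ]))[seq_along(b_atoms),
                                               -seq_along(b_atoms)]) <= 4.2
  }, TRUE))
  expect_equal(pr$contact_pct[pr$res_index == 5 & pr$fragment == "B-ring"],
               100 * counted, tolerance = 1e-12)
  # stem is bonded at the centre: always in contact with the Cys unit
  expect_equal(pr$contact_pct[pr$res_index == 12 & pr$fragment == "stem"],
               100)
  # the Cys fragment's own residue is not profiled against itself
  expect_true(is.na(pr$contact_pct[pr$res_index == 12 &
                                     pr$fragment == "Cys"]))
  expect_error(fragment_contact_profile(mix_ensemble()), "fragment labels")
})
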
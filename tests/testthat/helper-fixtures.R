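# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

spec406 <- function() fixture("spec406", segment_spec(406))

helix_frame <- function() fixture("helix", build_peptide(spec406(), "helix"))
extended_frame <- function() fixture("extended",
                                     build_peptide(spec406(), "extended"))

mix_ensemble <- function() {
  fixture("mix200",
          sample_helix_coil(spec406(),
                            helix_coil_model(0.7, n_frames = 200, seed = 3)))
}

liganded_ensemble <- function() {
  fixture("lig500", {
    ens <- sample_helix_coil(spec406(),
                             helix_coil_model(0.45, n_frames = 500,
                                              seed = 17))
    attach_pseudo_ligand(ens, bias = list(target = 5, fraction = 0.6),
                         seed = 18)
  })
}

frame_set_ensemble <- function(built) {
  pept_ensemble(built$topology, list(built$coords))
}

# ---- independent oracles ----

# All-pairs brute-force contact map: plain loops over residues and atoms,
# no shared code with the package kernel.
bf_contact_map <- function(coords, topology, cutoff = 4.2) {
  pep <- topology[topology$res_name != "LIG", ]
  units <- sort(unique(pep$res_index))
  n <- length(units)
  m <- diag(1, n)
  for (a in seq_len(n - 1)) {
    ia <- pep$atom[pep$res_index == units[a]]
    for (b in (a + 1):n) {
      ib <- pep$atom[pep$res_index == units[b]]
      found <- FALSE
      for (p in ia) {
        for (q in ib) {
          if (sqrt(sum((coords[p, ] - coords[q, ])^2)) <= cutoff) {
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) {
        m[a, b] <- 1
        m[b, a] <- 1
      }
    }
  }
  m
}

# Brute-force PCA: explicit covariance matrix and eigendecomposition.
bf_pca_scores <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x))
  covm <- t(xc) %*% xc / (nrow(x) - 1)
  eg <- eigen(covm, symmetric = TRUE)
  list(scores = xc %*% eg$vectors[, seq_len(k), drop = FALSE],
       values = eg$values)
}

# Reference DSSP assignments via mdtraj (python), on a written PDB.
mdtraj_dssp <- function(ensemble) {
  pdb <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".csv")
  write_ensemble(ensemble, pdb)
  script <- sprintf("
import mdtraj as md, numpy as np
t = md.load(%s)
ss = md.compute_dssp(t, simplified=False)
ss[ss == ' '] = 'C'
np.savetxt(%s, ss, fmt='%%s', delimiter=',')
", deparse(pdb), deparse(out))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("mdtraj reference run failed")
  as.matrix(utils::read.csv(out, header = FALSE,
                            colClasses = "character"))
}

# Midpoint-threshold overlap of a 1-D projection of two equal groups.
midpoint_overlap <- function(scores, n_each) {
  stopifnot(length(scores) == 2 * n_each)
  g1 <- scores[seq_len(n_each)]
  g2 <- scores[(n_each + 1):(2 * n_each)]
  mid <- (mean(g1) + mean(g2)) / 2
  side <- as.integer(scores > mid)
  if (mean(side[seq_len(n_each)]) > 0.5) side <- 1L - side
  mean(side != rep(c(0L, 1L), each = n_each))
}
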
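#' Per-residue backbone dihedral profiles
#'
#' Expands a named preset into per-residue (phi, psi) values, or validates a
#' user-supplied profile. Presets: `"helix"` is the ideal alpha-helix
#' (phi = -57, psi = -47), `"extended"` the fully extended strand
#' (phi = psi = 180), `"coil"` a marker resolved at sampling time by drawing
#' each residue's angles from broad non-helical Ramachandran basins.
#'
#' @param x a preset name, or a data frame / list with numeric `phi` and
#'   `psi` components (degrees, in (-180, 180]) of length `n_res`.
#' @param n_res number of residues the profile must cover.
#' @return a tibble with columns `phi`, `psi` and `n_res` rows.
#' @export
dihedral_profile <- function(x, n_res) {
  if (is.character(x) && length(x) == 1L) {
    x <- switch(x,
      helix = list(phi = rep(-57, n_res), psi = rep(-47, n_res)),
      extended = list(phi = rep(180, n_res), psi = rep(180, n_res)),
      coil = list(phi = rep(NA_real_, n_res), psi = rep(NA_real_, n_res)),
      stop(sprintf("unknown dihedral preset '%s'", x), call. = FALSE)
    )
  }
  prof <- tibble::tibble(phi = as.numeric(x$phi), psi = as.numeric(x$psi))
  if (nrow(prof) != n_res) {
    stop(sprintf("dihedral profile has %d rows, expected %d residues",
                 nrow(prof), n_res), call. = FALSE)
  }
  ok <- function(v) all(is.na(v) | (v > -180 & v <= 180))
  if (!ok(prof$phi) || !ok(prof$psi)) {
    stop("dihedral angles must lie in (-180, 180]", call. = FALSE)
  }
  prof
}

# Ramachandran rectangles for the coil state: a beta/PPII basin and a broad
# extended basin. Both avoid the alpha-helical region so that coil residues
# break i,i+4 hydrogen bonding.
.coil_basins <- list(
  list(phi = c(-160, -60), psi = c(100, 175), w = 0.65),
  list(phi = c(-175, -100), psi = c(-180, -150), w = 0.35)
)

sample_coil_dihedrals <- function(n) {
  which_basin <- sample.int(2L, n, replace = TRUE,
                            prob = vapply(.coil_basins, `[[`, 0, "w"))
  phi <- numeric(n)
  psi <- numeric(n)
  for (b in 1:2) {
    idx <- which(which_basin == b)
    if (!length(idx)) next
    lim <- .coil_basins[[b]]
    phi[idx] <- stats::runif(length(idx), lim$phi[1], lim$phi[2])
    psi[idx] <- stats::runif(length(idx), lim$psi[1], lim$psi[2])
  }
  tibble::tibble(phi = phi, psi = psi)
}

#' Build one conformation of a capped peptide
#'
#' Places backbone atoms (plus amide H, carbonyl O, CB and Cys SG) with
#' standard internal geometry at the requested per-residue backbone dihedrals.
#' Omega torsions are fixed trans (180 degrees). The caps are reduced
#' residues: ACE contributes CH3-C=O before the first amide nitrogen, NME
#' contributes N(-H)-CH3 after the last carbonyl.
#'
#' @param spec a [segment_spec()].
#' @param dihedrals a preset name or profile accepted by [dihedral_profile()];
#'   a `"coil"` / NA entry is drawn from the coil basins at build time.
#' @return a list of class `pept_frame_set` with `topology` (a
#'   `pept_topology`) and `coords` (atoms x 3 matrix, Angstrom).
#' @examples
#' helix <- build_peptide(segment_spec(406), "helix")
#' dim(helix$coords)
#' @export
build_peptide <- function(spec, dihedrals = "helix") {
  topology <- segment_topology(spec)
  n <- length(spec$sequence)
  prof <- dihedral_profile(dihedrals, n)
  if (anyNA(prof$phi) || anyNA(prof$psi)) {
    draw <- sample_coil_dihedrals(n)
    prof$phi[is.na(prof$phi)] <- draw$phi[is.na(prof$phi)]
    prof$psi[is.na(prof$psi)] <- draw$psi[is.na(prof$psi)]
  }
  coords <- build_coords(topology, prof)
  list(topology = topology, coords = coords)
}

# Internal: mainchain by sequential placement, then planar/tetrahedral
# decorations. `prof` has one (phi, psi) row per residue.
build_coords <- function(topology, prof) {
  g <- .bb
  n <- nrow(prof)
  # mainchain anchors per unit: ACE(CH3, C), residues (N, CA, C), NME(N, CH3)
  N <- matrix(NA_real_, n, 3)
  CA <- matrix(NA_real_, n, 3)
  C <- matrix(NA_real_, n, 3)
  ace_ch3 <- c(0, 0, 0)
  ace_c <- c(g$b_ca_c, 0, 0)
  th <- g$a_ca_c_n * pi / 180
  N[1, ] <- ace_c + g$b_c_n * c(cos(pi - th), sin(pi - th), 0)
  CA[1, ] <- place_atom(ace_ch3, ace_c, N[1, ], g$b_n_ca, g$a_c_n_ca, g$omega)
  C[1, ] <- place_atom(ace_c, N[1, ], CA[1, ], g$b_ca_c, g$a_n_ca_c,
                       prof$phi[1])
  if (n > 1) {
    for (i in 2:n) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$b_c_n,
                           g$a_ca_c_n, prof$psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], g$b_n_ca,
                            g$a_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], g$b_ca_c,
                           g$a_n_ca_c, prof$phi[i])
    }
  }
  nme_n <- place_atom(N[n, ], CA[n, ], C[n, ], g$b_c_n, g$a_ca_c_n,
                      prof$psi[n])
  nme_ch3 <- place_atom(CA[n, ], C[n, ], nme_n, g$b_n_ca, g$a_c_n_ca, g$omega)

  next_n <- rbind(N, nme_n)            # amide N following each carbonyl
  prev_c <- rbind(ace_c, C)            # carbonyl C preceding each amide N
  place_o <- function(nnext, b, c) place_atom(nnext, b, c, g$b_c_o,
                                              g$a_ca_c_o, 180)
  place_h <- function(nat, heavy1, heavy2) {
    d <- -(unit3(heavy1 - nat) + unit3(heavy2 - nat))
    nat + g$b_n_h * unit3(d)
  }

  pep <- topology[topology$res_index >= 2 & topology$res_index <= n + 1, ]
  coords <- matrix(NA_real_, nrow(topology), 3)
  for (r in seq_len(nrow(topology))) {
    at <- topology$name[r]
    ri <- topology$res_index[r]
    if (ri == 1L) {                       # ACE
      coords[r, ] <- switch(at,
        CH3 = ace_ch3, C = ace_c,
        O = place_o(N[1, ], ace_ch3, ace_c))
    } else if (ri == n + 2L) {            # NME
      coords[r, ] <- switch(at,
        N = nme_n,
        H = place_h(nme_n, nme_ch3, C[n, ]),
        CH3 = nme_ch3)
    } else {
      i <- ri - 1L
      coords[r, ] <- switch(at,
        N = N[i, ], CA = CA[i, ], C = C[i, ],
        O = place_o(next_n[i + 1, ], CA[i, ], C[i, ]),
        H = place_h(N[i, ], CA[i, ], prev_c[i, ]),
        CB = place_atom(C[i, ], N[i, ], CA[i, ], g$b_ca_cb, g$a_n_ca_cb,
                        122.6),
        SG = {
          cb <- place_atom(C[i, ], N[i, ], CA[i, ], g$b_ca_cb, g$a_n_ca_cb,
                           122.6)
          place_atom(N[i, ], CA[i, ], cb, g$b_cb_sg, g$a_ca_cb_sg, -60)
        })
    }
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  coords
}

#' Backbone dihedrals of a built frame
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param topology matching `pept_topology`.
#' @return tibble with `res_index`, `phi`, `psi` for every amino-acid residue
#'   (caps excluded; phi/psi use the flanking cap carbonyl/amide atoms).
#' @export
backbone_dihedrals <- function(coords, topology) {
  nu <- n_units(topology)
  pick <- function(ri, name) {
    j <- which(topology$res_index == ri & topology$name == name)
    if (!length(j)) return(NULL)
    coords[j[1], ]
  }
  res <- 2:(nu - 1)
  out <- purrr::map_dfr(res, function(ri) {
    c_prev <- pick(ri - 1L, "C")
    if (is.null(c_prev)) c_prev <- pick(ri - 1L, "CH3")  # never for ACE: C exists
    n_i <- pick(ri, "N"); ca_i <- pick(ri, "CA"); c_i <- pick(ri, "C")
    n_next <- pick(ri + 1L, "N")
    tibble::tibble(
      res_index = ri,
      phi = measure_dihedral(c_prev, n_i, ca_i, c_i),
      psi = measure_dihedral(n_i, ca_i, c_i, n_next)
    )
  })
  out
}
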
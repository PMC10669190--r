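#' Helix-coil sampling model
#'
#' Parameters of the two-state (helix/coil) per-residue model used by
#' [sample_helix_coil()]. Each residue is helical with marginal probability
#' `p_helix`; states along the sequence are coupled by a nearest-neighbour
#' Markov chain with persistence `rho` (the probability-scale autocorrelation
#' between adjacent residues), mimicking helix-coil cooperativity: helical
#' residues occur in runs rather than independently. With the default
#' `rho = 0.9` mean run lengths are on the order of ten residues, in line
#' with transient helical segments in disordered regions.
#'
#' @param p_helix scalar or per-residue helical probability in `[0, 1]`.
#' @param rho nearest-neighbour persistence in `[0, 1)`; 0 gives independent
#'   residues.
#' @param n_frames number of frames to draw.
#' @param seed integer seed; identical seeds give identical ensembles.
#' @return a list of class `helix_coil_model`.
#' @export
helix_coil_model <- function(p_helix = 0.85, rho = 0.9, n_frames = 1000,
                             seed = 1) {
  if (any(p_helix < 0 | p_helix > 1))
    stop("p_helix must lie in [0, 1]", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  structure(list(p_helix = p_helix, rho = rho,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "helix_coil_model")
}

# Draw one frames x residues state matrix from the chain. The chain is
# constructed so the marginal P(helix at i) equals p_i exactly:
#   P(s_i = 1 | s_{i-1} = 1) = p_i + rho * (1 - p_i)
#   P(s_i = 1 | s_{i-1} = 0) = p_i * (1 - rho)
draw_states <- function(n_res, p, rho, n_frames) {
  p <- rep_len(p, n_res)
  s <- matrix(FALSE, n_frames, n_res)
  s[, 1] <- stats::runif(n_frames) < p[1]
  if (n_res > 1) {
    for (i in 2:n_res) {
      p_on <- ifelse(s[, i - 1], p[i] + rho * (1 - p[i]), p[i] * (1 - rho))
      s[, i] <- stats::runif(n_frames) < p_on
    }
  }
  s
}

#' Sample a helix-coil conformational ensemble
#'
#' Stands in for molecular-dynamics sampling of the helix-coil transition:
#' each frame draws a per-residue helix/coil state vector from the model,
#' builds helical residues at ideal alpha-helix dihedrals and coil residues
#' at dihedrals drawn uniformly from broad non-helical Ramachandran basins,
#' then constructs coordinates with the idealised backbone builder.
#'
#' @param spec a [segment_spec()].
#' @param model a [helix_coil_model()].
#' @param stride_ps nominal time between frames in ps (bookkeeping only).
#' @return a `pept_ensemble`; the realised state matrix is kept in `$states`
#'   (frames x residues) as generator ground truth.
#' @examples
#' ens <- sample_helix_coil(segment_spec(406), helix_coil_model(0.7, n_frames = 20))
#' n_frames(ens)
#' @export
sample_helix_coil <- function(spec, model, stride_ps = 10) {
  stopifnot(inherits(spec, "segment_spec"), inherits(model, "helix_coil_model"))
  topology <- segment_topology(spec)
  n <- length(spec$sequence)
  set.seed(model$seed)
  states <- draw_states(n, model$p_helix, model$rho, model$n_frames)
  coords <- vector("list", model$n_frames)
  for (f in seq_len(model$n_frames)) {
    prof <- tibble::tibble(phi = rep(-57, n), psi = rep(-47, n))
    ncoil <- sum(!states[f, ])
    if (ncoil > 0) {
      draw <- sample_coil_dihedrals(ncoil)
      prof$phi[!states[f, ]] <- draw$phi
      prof$psi[!states[f, ]] <- draw$psi
    }
    coords[[f]] <- build_coords(topology, prof)
  }
  pept_ensemble(topology, coords, stride_ps = stride_ps, states = states,
                params = list(model = unclass(model)))
}

#' Pseudo-ligand template
#'
#' A coarse stand-in for a covalent dual-ring ligand bonded through the
#' central cysteine thiol: a three-atom `stem` (linker) leaving the sulfur,
#' and two five-atom ring groups, `A-ring` and `B-ring`. Geometry is given
#' in a local frame with the attachment point (the Cys SG) at the origin;
#' ring chemistry is not modelled atom-for-atom.
#'
#' @return a tibble of class `pseudo_ligand` with columns `name`, `element`,
#'   `fragment` and local coordinates `x`, `y`, `z` (Angstrom).
#' @export
pseudo_ligand <- function() {
  ring <- function(centre, normal, r = 1.25, n = 5) {
    normal <- unit3(normal)
    a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- unit3(cross3(normal, a))
    v <- cross3(normal, u)
    th <- 2 * pi * (seq_len(n) - 1) / n
    t(vapply(th, function(t) centre + r * (cos(t) * u + sin(t) * v),
             numeric(3)))
  }
  stem <- rbind(c(1.8, 0, 0), c(3.0, 0.7, 0), c(4.2, 0, 0))
  aring <- ring(c(5.9, 1.3, 0.4), c(0, 0.4, 1))
  bring <- ring(c(5.9, -1.6, -0.4), c(0, -0.4, 1))
  xyz <- rbind(stem, aring, bring)
  lig <- tibble::tibble(
    name = sprintf("L%02d", seq_len(nrow(xyz))),
    element = c("C", "C", "C", rep("C", 4), "N", rep("C", 4), "N"),
    fragment = c(rep("stem", 3), rep("A-ring", 5), rep("B-ring", 5)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  class(lig) <- c("pseudo_ligand", class(lig))
  lig
}

rotation_between <- function(a, b) {
  # rotation matrix sending unit vector a to unit vector b (Rodrigues)
  a <- unit3(a); b <- unit3(b)
  v <- cross3(a, b)
  s2 <- sum(v^2)
  c_ <- sum(a * b)
  if (s2 < 1e-14) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) unit3(cross3(a, c(1, 0, 0))) else
      unit3(cross3(a, c(0, 1, 0)))
    v <- perp; return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

#' Attach a fragment-labelled pseudo-ligand to an ensemble
#'
#' Adds the ligand atoms to the topology (residue `LIG`, one fragment label
#' per atom; the modified cysteine's own peptide atoms are labelled `Cys`)
#' and places the ligand in every frame. Without bias the ligand points away
#' from the peptide centroid along the S-H direction. With
#' `bias = list(target = r, fraction = f)` the `B-ring` group is placed
#' within contact range (3 Angstrom centroid offset) of residue `r`'s CA in
#' a Bernoulli-`f` subset of frames, emulating a ligand whose B-ring docks
#' against a specific upstream residue; the linker is treated as freely
#' flexible.
#'
#' @param ensemble a `pept_ensemble` whose central residue is a cysteine
#'   (must carry an SG atom).
#' @param ligand a [pseudo_ligand()] template.
#' @param bias optional list with `target` (internal residue index) and
#'   `fraction` in `[0, 1]`.
#' @param seed seed for the per-frame bias draws (default derived from the
#'   generator seed when present).
#' @return a new `pept_ensemble` with ligand atoms appended; the realised
#'   per-frame bias indicator is stored in `$params$bias_realised`.
#' @export
attach_pseudo_ligand <- function(ensemble, ligand = pseudo_ligand(),
                                 bias = NULL, seed = NULL) {
  top <- ensemble$topology
  spec <- attr(top, "spec")
  sg_row <- which(top$name == "SG" &
                    top$res_index == internal_index(spec$center_position, spec))
  if (!length(sg_row))
    stop("attachment site absent: central residue carries no SG atom",
         call. = FALSE)
  cb_row <- which(top$name == "CB" & top$res_index == top$res_index[sg_row])
  centre_unit <- top$res_index[sg_row]

  lig_top <- tibble::tibble(
    name = ligand$name, element = ligand$element,
    res_index = max(top$res_index) + 1L, res_name = "LIG",
    seq_pos = NA_integer_, fragment = ligand$fragment)
  new_tbl <- dplyr::bind_rows(
    dplyr::mutate(top, fragment = ifelse(res_index == centre_unit,
                                         "Cys", fragment)),
    lig_top)
  new_tbl$atom <- seq_len(nrow(new_tbl))
  new_top <- new_topology(new_tbl, spec)

  if (!is.null(seed)) set.seed(seed)
  else if (!is.null(ensemble$params$model$seed))
    set.seed(ensemble$params$model$seed + 7919L)
  nf <- n_frames(ensemble)
  frac <- if (is.null(bias)) 0 else bias$fraction
  if (frac < 0 || frac > 1) stop("bias fraction must be in [0, 1]",
                                 call. = FALSE)
  biased <- stats::runif(nf) < frac
  tmpl <- as.matrix(ligand[, c("x", "y", "z")])
  b_idx <- which(ligand$fragment == "B-ring")
  cutoff_clear <- 4.2

  coords <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[[f]]
    sg <- xyz[sg_row, ]
    cb <- xyz[cb_row, ]
    away <- unit3(sg - colMeans(xyz[top$name == "CA", , drop = FALSE]))
    lig_xyz <- tmpl %*% t(rotation_between(c(1, 0, 0), away))
    lig_xyz <- sweep(lig_xyz, 2, sg, `+`)
    if (biased[f]) {
      target_ca <- xyz[which(top$res_index == bias$target &
                               top$name == "CA")[1], ]
      q <- target_ca + 3.0 * unit3(sg - target_ca)
      shift <- q - colMeans(lig_xyz[b_idx, , drop = FALSE])
      lig_xyz[b_idx, ] <- sweep(lig_xyz[b_idx, , drop = FALSE], 2, shift, `+`)
    } else if (!is.null(bias)) {
      # guarantee the unbiased frames stay clear of the bias target
      t_atoms <- xyz[top$res_index == bias$target, , drop = FALSE]
      repeat {
        dmin <- min(proxy_dist(lig_xyz[b_idx, , drop = FALSE], t_atoms))
        if (dmin > cutoff_clear) break
        lig_xyz <- sweep(lig_xyz, 2, 2 * away, `+`)
      }
    }
    coords[[f]] <- rbind(xyz, lig_xyz)
  }
  params <- ensemble$params
  params$bias <- bias
  params$bias_realised <- biased
  pept_ensemble(new_top, coords, stride_ps = ensemble$stride_ps,
                states = ensemble$states, params = params)
}

# minimal cross-distance helper (euclidean, dense)
proxy_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}
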
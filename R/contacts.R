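peptide_atom_groups <- function(topology) {
  pep <- which(topology$res_name != "LIG")
  split(pep, topology$res_index[pep])
}

new_contact_map <- function(m, cutoff, type, n_frames = 1L) {
  structure(m, class = "contact_map", cutoff = cutoff, type = type,
            n_frames = n_frames)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %dx%d (%s, cutoff %g A, %d frame%s)\n",
              nrow(x), ncol(x), attr(x, "type"), attr(x, "cutoff"),
              attr(x, "n_frames"), if (attr(x, "n_frames") > 1) "s" else ""))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Per-frame residue-residue contact map
#'
#' Two indexed units j and k are in contact when any atom of j lies within
#' `cutoff` of any atom of k (boundary inclusive). All peptide atoms count,
#' hydrogens included; ligand atoms never count toward their host residue.
#' The diagonal is fixed at 1 by convention and carries no information.
#'
#' @param coords atoms x 3 coordinate matrix for one frame.
#' @param topology matching `pept_topology`.
#' @param cutoff contact distance cutoff in Angstrom (default 4.2).
#' @return an n x n binary `contact_map` (n = indexed peptide units,
#'   23 for a capped 21-mer).
#' @export
contact_map <- function(coords, topology, cutoff = 4.2) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (nrow(coords) != nrow(topology))
    stop("frame does not match topology", call. = FALSE)
  groups <- peptide_atom_groups(topology)
  if (any(lengths(groups) == 0)) stop("empty residue atom set", call. = FALSE)
  m <- contact_map_kernel(coords, groups, cutoff)
  new_contact_map(m, cutoff, "binary")
}

# Kernel shared by per-frame and ensemble-mean paths: squared-distance
# block minima over residue atom groups.
contact_map_kernel <- function(coords, groups, cutoff) {
  n <- length(groups)
  atoms <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  xyz <- coords[atoms, , drop = FALSE]
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(xyz)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  m <- diag(1, n)
  c2 <- cutoff^2
  for (j in seq_len(n - 1)) {
    rj <- starts[j]:ends[j]
    for (k in (j + 1):n) {
      if (min(d2[rj, starts[k]:ends[k]]) <= c2 + 1e-12) {
        m[j, k] <- 1
        m[k, j] <- 1
      }
    }
  }
  m
}

#' Ensemble-mean contact map
#'
#' Entrywise average of per-frame binary contact maps over every `stride`-th
#' frame; entries are contact frequencies in `[0, 1]` (the heat-map
#' statistic).
#'
#' @param ensemble a `pept_ensemble`.
#' @param cutoff contact cutoff in Angstrom.
#' @param stride analyse every `stride`-th frame (default 1 = all stored
#'   frames; stored frames are already on the ensemble's `stride_ps` grid).
#' @return an n x n real-valued `contact_map`.
#' @export
mean_contact_map <- function(ensemble, cutoff = 4.2, stride = 1) {
  idx <- seq(1, n_frames(ensemble), by = stride)
  if (!length(idx)) stop("stride leaves zero frames", call. = FALSE)
  groups <- peptide_atom_groups(ensemble$topology)
  acc <- NULL
  for (f in idx) {
    m <- contact_map_kernel(ensemble$coords[[f]], groups, cutoff)
    acc <- if (is.null(acc)) m else acc + m
  }
  new_contact_map(acc / length(idx), cutoff, "mean", length(idx))
}

#' Flatten a contact map to its contact degree-of-freedom vector
#'
#' Row-major strict upper triangle: pairs (1,2), (1,3), ..., (1,n), (2,3),
#' ... The diagonal is excluded, so an n x n map yields n(n-1)/2
#' non-redundant degrees of freedom - 253 for the 23-unit maps of capped
#' 21-mers.
#'
#' @param map a square symmetric matrix (`contact_map` or plain).
#' @return numeric vector of length n(n-1)/2 with a `pairs` attribute
#'   (two-column matrix of the (j, k) index of each entry).
#' @export
vectorize_map <- function(map) {
  m <- unclass(map)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("contact map must be a square matrix", call. = FALSE)
  n <- nrow(m)
  ut <- upper.tri(m)
  v <- t(m)[lower.tri(m)]
  pairs <- cbind(j = row(m)[ut], k = col(m)[ut])
  pairs <- pairs[order(pairs[, "j"], pairs[, "k"]), , drop = FALSE]
  structure(as.numeric(v), pairs = pairs)
}

#' Rebuild a symmetric map from a contact vector
#'
#' Inverse of [vectorize_map()]; the diagonal is restored to 1.
#'
#' @param v contact vector of length n(n-1)/2.
#' @param n map dimension.
#' @return an n x n symmetric matrix.
#' @export
unvectorize_map <- function(v, n) {
  if (length(v) != n * (n - 1) / 2)
    stop(sprintf("vector length %d does not match n(n-1)/2 = %d",
                 length(v), n * (n - 1) / 2), call. = FALSE)
  m <- diag(1, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Per-frame contact vectors for an ensemble
#'
#' @param ensemble a `pept_ensemble`.
#' @param cutoff contact cutoff in Angstrom.
#' @param stride analyse every `stride`-th frame.
#' @return a frames x n(n-1)/2 numeric matrix (one contact vector per row).
#' @export
contact_vectors <- function(ensemble, cutoff = 4.2, stride = 1) {
  idx <- seq(1, n_frames(ensemble), by = stride)
  groups <- peptide_atom_groups(ensemble$topology)
  n <- length(groups)
  out <- matrix(NA_real_, length(idx), n * (n - 1) / 2)
  for (r in seq_along(idx)) {
    m <- contact_map_kernel(ensemble$coords[[idx[r]]], groups, cutoff)
    out[r, ] <- t(m)[lower.tri(m)]
  }
  out
}

#' Fragment-resolved ligand contact profile
#'
#' For every indexed peptide unit r and every fragment f (the modified
#' cysteine's own peptide atoms, plus the ligand `A-ring`, `B-ring` and
#' `stem` groups), the percentage of analysed frames in which any atom of f
#' lies within `cutoff` of any atom of r. The Cys fragment's entry at its
#' own residue is NA (self-contact is not informative).
#'
#' @param ensemble a liganded `pept_ensemble` (topology must carry fragment
#'   labels).
#' @param cutoff contact cutoff in Angstrom.
#' @param stride analyse every `stride`-th frame.
#' @return a tibble of class `fragment_profile` with columns `res_index`,
#'   `seq_pos`, `fragment` and `contact_pct` in `[0, 100]`.
#' @export
fragment_contact_profile <- function(ensemble, cutoff = 4.2, stride = 1) {
  top <- ensemble$topology
  if (!any(!is.na(top$fragment)))
    stop("no fragment labels present; attach a pseudo-ligand first",
         call. = FALSE)
  idx <- seq(1, n_frames(ensemble), by = stride)
  frag_levels <- c("Cys", "A-ring", "B-ring", "stem")
  frag_atoms <- lapply(frag_levels, function(f) which(top$fragment %in% f))
  names(frag_atoms) <- frag_levels
  frag_atoms <- frag_atoms[lengths(frag_atoms) > 0]
  groups <- peptide_atom_groups(top)
  cys_unit <- top$res_index[which(top$fragment == "Cys")[1]]
  n <- length(groups)
  hits <- matrix(0, n, length(frag_atoms),
                 dimnames = list(NULL, names(frag_atoms)))
  for (f in idx) {
    xyz <- ensemble$coords[[f]]
    for (fr in names(frag_atoms)) {
      fa <- xyz[frag_atoms[[fr]], , drop = FALSE]
      for (r in seq_len(n)) {
        if (fr == "Cys" && r == cys_unit) next
        if (min(proxy_dist(fa, xyz[groups[[r]], , drop = FALSE])) <= cutoff)
          hits[r, fr] <- hits[r, fr] + 1
      }
    }
  }
  spec <- attr(top, "spec")
  nres <- length(spec$sequence)
  out <- tidyr::expand_grid(res_index = seq_len(n),
                            fragment = names(frag_atoms))
  out$contact_pct <- purrr::map2_dbl(out$res_index, out$fragment,
                                     ~ 100 * hits[.x, .y] / length(idx))
  out$contact_pct[out$fragment == "Cys" & out$res_index == cys_unit] <- NA
  out$seq_pos <- ifelse(out$res_index >= 2 & out$res_index <= nres + 1,
                        spec$positions[pmax(out$res_index - 1L, 1L)],
                        NA_integer_)
  out <- out[, c("res_index", "seq_pos", "fragment", "contact_pct")]
  class(out) <- c("fragment_profile", class(out))
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- length(idx)
  out
}
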
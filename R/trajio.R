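#' Construct a peptide ensemble
#'
#' An ensemble bundles one topology with an ordered list of coordinate frames
#' sharing that topology, plus the frame stride in picoseconds (bookkeeping
#' for analyses run at a coarser interval than the snapshot cadence).
#'
#' @param topology a `pept_topology`.
#' @param coords list of atoms x 3 coordinate matrices (Angstrom).
#' @param stride_ps time between stored frames in ps (default 10).
#' @param states optional frames x residues logical matrix of generator
#'   ground-truth helical states (kept by the synthetic sampler).
#' @param params optional list of generator/run parameters for provenance.
#' @return object of class `pept_ensemble`.
#' @export
pept_ensemble <- function(topology, coords, stride_ps = 10, states = NULL,
                          params = list()) {
  stopifnot(inherits(topology, "pept_topology"), is.list(coords),
            length(coords) >= 1, stride_ps > 0)
  nat <- nrow(topology)
  ok <- vapply(coords, function(m) is.matrix(m) && nrow(m) == nat &&
                 ncol(m) == 3, TRUE)
  if (!all(ok)) stop("every frame must be an atoms x 3 matrix matching the topology",
                     call. = FALSE)
  structure(list(topology = topology, coords = coords,
                 stride_ps = stride_ps, states = states, params = params),
            class = "pept_ensemble")
}

#' @export
print.pept_ensemble <- function(x, ...) {
  cat(sprintf("<pept_ensemble> %d frames x %d atoms (%d units), stride %g ps\n",
              length(x$coords), nrow(x$topology), n_units(x$topology),
              x$stride_ps))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `pept_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$coords)

#' Split an ensemble into contiguous blocks
#'
#' Used for convergence checks in the style of first/second-half trajectory
#' blocks (suffixes "_1", "_2"). The partition preserves frame order; when
#' the frame count is not divisible, earlier blocks receive the remainder.
#'
#' @param ensemble a `pept_ensemble`.
#' @param n_blocks number of blocks (>= 1, <= frame count).
#' @return list of `pept_ensemble` objects whose concatenation restores the
#'   input frame order.
#' @export
split_blocks <- function(ensemble, n_blocks = 2) {
  stopifnot(inherits(ensemble, "pept_ensemble"))
  nf <- n_frames(ensemble)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  if (nf < n_blocks) stop(sprintf("cannot split %d frames into %d blocks",
                                  nf, n_blocks), call. = FALSE)
  base <- nf %/% n_blocks
  extra <- nf %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, extra), rep(0L, n_blocks - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) {
    pept_ensemble(ensemble$topology, ensemble$coords[s:e],
                  stride_ps = ensemble$stride_ps,
                  states = if (!is.null(ensemble$states))
                    ensemble$states[s:e, , drop = FALSE],
                  params = ensemble$params)
  })
}

#' Drop leading equilibration frames
#'
#' @param ensemble a `pept_ensemble`.
#' @param n_discard number of leading frames to drop (default 0).
#' @return the truncated ensemble.
#' @export
discard_equilibration <- function(ensemble, n_discard = 0) {
  if (n_discard <= 0) return(ensemble)
  nf <- n_frames(ensemble)
  if (n_discard >= nf) stop("discard would leave zero frames", call. = FALSE)
  keep <- (n_discard + 1L):nf
  pept_ensemble(ensemble$topology, ensemble$coords[keep],
                stride_ps = ensemble$stride_ps,
                states = if (!is.null(ensemble$states))
                  ensemble$states[keep, , drop = FALSE],
                params = ensemble$params)
}

# ---- multi-model PDB ----

fmt_atom_line <- function(serial, name, resname, resseq, xyz, element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, resseq, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Fixed-column PDB v3.3 subset: one MODEL/ENDMDL block per frame, serial
#' numbering restarting at 1 in each model, single chain A, no altlocs.
#' Ligand atoms (if any) are written as residue LIG after the peptide.
#'
#' @param ensemble a `pept_ensemble`.
#' @param path output file path.
#' @param sidecar optional path for the topology sidecar (YAML); written when
#'   non-NULL so the file pair round-trips through [read_ensemble()].
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path, sidecar = NULL) {
  top <- ensemble$topology
  lines <- character(0)
  out <- vector("list", length(ensemble$coords))
  for (f in seq_along(ensemble$coords)) {
    xyz <- ensemble$coords[[f]]
    body <- vapply(seq_len(nrow(top)), function(r) {
      fmt_atom_line(r, top$name[r], top$res_name[r], top$res_index[r],
                    xyz[r, ], top$element[r])
    }, "")
    out[[f]] <- c(sprintf("MODEL     %4d", f), body, "TER", "ENDMDL")
  }
  writeLines(c(unlist(out), "END"), path)
  if (!is.null(sidecar)) write_topology(top, sidecar,
                                        stride_ps = ensemble$stride_ps)
  invisible(path)
}

#' Write a topology sidecar
#'
#' Structured-text (YAML) description of the segment: centre, flank,
#' sequence, per-atom residue membership and ligand fragment labels. Paired
#' with a multi-model PDB it fully reconstructs a `pept_ensemble`.
#'
#' @param topology a `pept_topology`.
#' @param path output path.
#' @param stride_ps frame stride recorded for the ensemble.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path, stride_ps = 10) {
  spec <- attr(topology, "spec")
  doc <- list(
    segment = list(center_position = spec$center_position,
                   flank = spec$flank,
                   sequence = paste(spec$sequence, collapse = "")),
    stride_ps = stride_ps,
    atoms = purrr::pmap(
      list(topology$name, topology$element, topology$res_index,
           topology$res_name, topology$fragment),
      function(n, e, ri, rn, fr) {
        rec <- list(name = n, element = e, res_index = ri, res_name = rn)
        if (!is.na(fr)) rec$fragment <- fr
        rec
      })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a topology sidecar
#' @param path sidecar path written by [write_topology()].
#' @return a `pept_topology` (stride recorded as attribute `stride_ps`).
#' @export
read_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  spec <- segment_spec(doc$segment$center_position, doc$segment$flank,
                       doc$segment$sequence)
  tbl <- dplyr::bind_rows(purrr::map(doc$atoms, function(a) {
    tibble::tibble(name = a$name, element = a$element,
                   res_index = as.integer(a$res_index),
                   res_name = a$res_name,
                   fragment = a$fragment %||% NA_character_)
  }))
  tbl$seq_pos <- ifelse(tbl$res_index >= 2 &
                          tbl$res_index <= length(spec$sequence) + 1,
                        spec$positions[tbl$res_index - 1L], NA_integer_)
  tbl <- tibble::add_column(tbl, atom = seq_len(nrow(tbl)), .before = 1)
  top <- new_topology(tbl[, c("atom", "name", "element", "res_index",
                              "res_name", "seq_pos", "fragment")], spec)
  attr(top, "stride_ps") <- doc$stride_ps %||% 10
  top
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multi-model PDB ensemble
#'
#' Parses the fixed-column subset written by [write_ensemble()] and validates
#' that every MODEL carries the same atom count as the sidecar topology.
#'
#' @param path multi-model PDB path.
#' @param sidecar topology sidecar path (see [write_topology()]).
#' @return a `pept_ensemble`.
#' @export
read_ensemble <- function(path, sidecar) {
  top <- read_topology(sidecar)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  nat <- nrow(top)
  if (!length(model_starts)) {
    frames <- list(seq_len(length(lines))[is_atom])
  } else {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
    frames <- purrr::map2(model_starts, model_ends, function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    })
  }
  for (f in seq_along(frames)) {
    if (length(frames[[f]]) != nat) {
      stop(sprintf("model %d has %d atoms but the topology defines %d",
                   f, length(frames[[f]]), nat), call. = FALSE)
    }
  }
  coords <- purrr::map(frames, function(idx) {
    m <- cbind(as.numeric(substr(lines[idx], 31, 38)),
               as.numeric(substr(lines[idx], 39, 46)),
               as.numeric(substr(lines[idx], 47, 54)))
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  pept_ensemble(top, coords, stride_ps = attr(top, "stride_ps") %||% 10)
}

# ---- study-design registry ----

#' Load the study-design registry
#'
#' The registry is the roster of peptide/ligand systems the analyses are
#' organised around: one record per system with its short-hand notation
#' (ligand identity, centre digit, start conformation, e.g. `XNN_4H`), the
#' centre Cys position, the starting conformation (H for alpha-helical, E for
#' extended), the attached ligand (or "none"), run length, counter ion and
#' water count. The packaged default registry describes the 14 AR AF1
#' systems.
#'
#' @param path CSV path; default the packaged registry.
#' @return a tibble of class `study_registry`.
#' @export
load_registry <- function(path = system.file("extdata",
                                             "study_registry.csv",
                                             package = "contactdof")) {
  reg <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(
                           notation = readr::col_character(),
                           center = readr::col_integer(),
                           start = readr::col_character(),
                           ligand = readr::col_character(),
                           run_ns = readr::col_integer(),
                           ion = readr::col_character(),
                           n_water = readr::col_integer()))
  if (nrow(reg) > 0) {
    if (anyDuplicated(reg$notation))
      stop("duplicate system notation in registry", call. = FALSE)
    if (!all(reg$center %in% c(406L, 327L, 240L)))
      stop("registry centre must be one of 406, 327, 240", call. = FALSE)
    if (!all(reg$start %in% c("H", "E")))
      stop("registry start conformation must be H or E", call. = FALSE)
  }
  class(reg) <- c("study_registry", class(reg))
  reg
}
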
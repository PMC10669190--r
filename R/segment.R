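#' Define a capped peptide segment
#'
#' A segment is a contiguous stretch of `2 * flank + 1` residues centred on a
#' sequence position of interest (for the androgen-receptor AF1 systems, a
#' cysteine such as C406), blocked by an N-terminal acetyl (ACE) and a
#' C-terminal N-methylamide (NME) cap. Including the caps, the segment has
#' `2 * flank + 3` indexed units; internal indices start at 1 on the ACE cap,
#' so the central residue of a 21-mer sits at internal index 12.
#'
#' @param center_position sequence position (UniProt-style, 1-based) of the
#'   central residue.
#' @param flank number of residues on each side of the centre (default 10,
#'   giving a 21-mer).
#' @param sequence one-letter residue string of length `2 * flank + 1`. When
#'   `NULL`, a synthetic poly-alanine sequence is used, anchored with the
#'   residues documented for the AR segments (W399 and A403 for the segment
#'   centred on C406; a central Cys for centres 406, 327 and 240).
#' @return an object of class `segment_spec`: a list with `center_position`,
#'   `flank`, `sequence` (character vector of one-letter codes), `positions`
#'   (sequence position of each residue) and `caps = c("ACE", "NME")`.
#' @examples
#' spec <- segment_spec(406)
#' internal_index(399, spec)
#' @export
segment_spec <- function(center_position, flank = 10, sequence = NULL) {
  stopifnot(is.numeric(center_position), length(center_position) == 1,
            is.numeric(flank), length(flank) == 1, flank >= 0)
  n <- 2L * as.integer(flank) + 1L
  if (is.null(sequence)) {
    sequence <- default_segment_sequence(center_position, flank)
  }
  seq_chr <- if (length(sequence) == 1L && nchar(sequence) > 1L) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
  if (length(seq_chr) != n) {
    stop(sprintf("sequence length %d does not match 2*flank+1 = %d",
                 length(seq_chr), n), call. = FALSE)
  }
  positions <- seq.int(center_position - flank, center_position + flank)
  structure(
    list(center_position = as.integer(center_position),
         flank = as.integer(flank),
         sequence = seq_chr,
         positions = as.integer(positions),
         caps = c("ACE", "NME")),
    class = "segment_spec"
  )
}

#' @export
print.segment_spec <- function(x, ...) {
  cat(sprintf("<segment_spec> %d-mer centred on position %d (flank %d)\n",
              length(x$sequence), x$center_position, x$flank))
  cat("  sequence: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  cat("  indexed units incl. ACE/NME caps: ", length(x$sequence) + 2L, "\n",
      sep = "")
  invisible(x)
}

# Synthetic default sequences: poly-Ala with the anchor residues that are
# documented for the AR AF1 segments (the full 21-mer sequences are not
# reproduced here; residue identity only affects naming and CB placement in
# the backbone-level model).
default_segment_sequence <- function(center_position, flank) {
  n <- 2L * flank + 1L
  s <- rep("A", n)
  positions <- seq.int(center_position - flank, center_position + flank)
  centre_idx <- flank + 1L
  if (center_position %in% c(406L, 327L, 240L)) s[centre_idx] <- "C"
  if (center_position == 406L && flank == 10L) {
    s[match(399L, positions)] <- "W"
    s[match(403L, positions)] <- "A"
  }
  s
}

#' Map a sequence position to its internal index
#'
#' Internal indices are 1-based and include the caps: the N-terminal ACE cap
#' is unit 1, the first residue of the segment unit 2, and so on. For the
#' 21-mer centred on C406 this reproduces the bookkeeping used throughout the
#' AF1 analyses: W399 is residue #5, A403 is residue #9 and the central C406
#' is residue #12.
#'
#' @param seq_position sequence position(s) to convert.
#' @param spec a [segment_spec()].
#' @return integer internal index (vectorised over `seq_position`).
#' @seealso [sequence_position()] for the inverse mapping.
#' @export
internal_index <- function(seq_position, spec) {
  stopifnot(inherits(spec, "segment_spec"))
  lo <- spec$center_position - spec$flank
  hi <- spec$center_position + spec$flank
  bad <- seq_position < lo | seq_position > hi
  if (any(bad)) {
    stop(sprintf("sequence position(s) %s outside segment [%d, %d]",
                 paste(seq_position[bad], collapse = ", "), lo, hi),
         call. = FALSE)
  }
  as.integer(seq_position - lo + 2L)
}

#' Map an internal index back to its sequence position
#'
#' @param index internal index (2 to n+1 for an n-residue segment; caps at 1
#'   and n+2 have no sequence position).
#' @param spec a [segment_spec()].
#' @return integer sequence position.
#' @export
sequence_position <- function(index, spec) {
  stopifnot(inherits(spec, "segment_spec"))
  n <- length(spec$sequence)
  bad <- index < 2L | index > n + 1L
  if (any(bad)) {
    stop(sprintf("internal index(es) %s do not map to residues (valid: 2..%d)",
                 paste(index[bad], collapse = ", "), n + 1L), call. = FALSE)
  }
  as.integer(index - 2L + spec$center_position - spec$flank)
}

aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Build the atom table for a capped segment
#'
#' The representation is backbone-centric: N, H, CA, C, O per residue plus a
#' single CB pseudo-atom on every non-glycine residue (side-chain reach for
#' contact statistics) and an SG atom on cysteines. ACE contributes CH3, C, O
#' and NME contributes N, H, CH3.
#'
#' @param spec a [segment_spec()].
#' @return a `pept_topology`: a tibble with one row per atom and columns
#'   `atom`, `name`, `element`, `res_index`, `res_name`, `seq_pos`,
#'   `fragment` (NA for peptide atoms), carrying the spec as an attribute.
#' @export
segment_topology <- function(spec) {
  stopifnot(inherits(spec, "segment_spec"))
  n <- length(spec$sequence)
  rows <- list()
  add <- function(name, element, res_index, res_name, seq_pos) {
    rows[[length(rows) + 1L]] <<- list(name = name, element = element,
                                       res_index = res_index,
                                       res_name = res_name,
                                       seq_pos = seq_pos)
  }
  add("CH3", "C", 1L, "ACE", NA_integer_)
  add("C", "C", 1L, "ACE", NA_integer_)
  add("O", "O", 1L, "ACE", NA_integer_)
  for (i in seq_len(n)) {
    code <- spec$sequence[i]
    res <- unname(aa3[code])
    if (is.na(res)) stop(sprintf("unknown residue code '%s'", code),
                         call. = FALSE)
    ri <- i + 1L
    sp <- spec$positions[i]
    add("N", "N", ri, res, sp)
    if (code != "P") add("H", "H", ri, res, sp)
    add("CA", "C", ri, res, sp)
    if (code != "G") add("CB", "C", ri, res, sp)
    if (code == "C") add("SG", "S", ri, res, sp)
    add("C", "C", ri, res, sp)
    add("O", "O", ri, res, sp)
  }
  add("N", "N", n + 2L, "NME", NA_integer_)
  add("H", "H", n + 2L, "NME", NA_integer_)
  add("CH3", "C", n + 2L, "NME", NA_integer_)
  top <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  top <- tibble::add_column(top, atom = seq_len(nrow(top)), .before = 1)
  top$fragment <- NA_character_
  new_topology(top, spec)
}

new_topology <- function(tbl, spec) {
  stopifnot(all(c("atom", "name", "element", "res_index", "res_name",
                  "seq_pos", "fragment") %in% names(tbl)))
  structure(tbl, spec = spec,
            class = c("pept_topology", class(tibble::as_tibble(tbl))))
}

#' @export
print.pept_topology <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<pept_topology> %d atoms, %d indexed units%s\n",
              nrow(x), max(x$res_index),
              if (any(!is.na(x$fragment))) " (ligand attached)" else ""))
  NextMethod()
}

#' Number of indexed units (caps included) in a topology
#' @param topology a `pept_topology`.
#' @return integer unit count (23 for a capped 21-mer).
#' @export
n_units <- function(topology) max(topology$res_index)

#' Number of peptide indexed units (caps included, ligand excluded)
#' @param topology a `pept_topology`.
#' @return integer count of non-ligand units.
#' @export
n_peptide_units <- function(topology) {
  max(topology$res_index[topology$res_name != "LIG"])
}
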
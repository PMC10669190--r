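#' The eight-state secondary-structure alphabet
#'
#' Kabsch-Sander states: `H` alpha-helix, `G` 3-10 helix, `I` pi-helix,
#' `E` extended strand, `B` isolated beta-bridge, `T` hydrogen-bonded turn,
#' `S` bend, `C` none.
#'
#' @return character vector of the 8 one-letter state codes.
#' @export
ss_states <- function() c("H", "G", "I", "E", "B", "T", "S", "C")

# Backbone H-bond detection, Kabsch-Sander electrostatic model:
# E = q1*q2*(1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) * f, bond if E < -0.5
# kcal/mol, with q1*q2*f = 0.42 * 0.20 * 332 = 27.888.
.hb_energy_cut <- -0.5
.hb_k <- 0.42 * 0.20 * 332

# Returns a units x units logical matrix: [d, a] TRUE when the amide N-H of
# unit d donates to the carbonyl C=O of unit a. Caps participate: ACE can
# accept, NME can donate; units lacking H (proline) never donate.
hbond_matrix <- function(coords, topology) {
  nu <- n_peptide_units(topology)
  pick <- function(name) {
    out <- matrix(NA_real_, nu, 3)
    rows <- which(topology$name == name & topology$res_name != "LIG")
    out[topology$res_index[rows], ] <- coords[rows, , drop = FALSE]
    out
  }
  N <- pick("N"); H <- pick("H"); C <- pick("C"); O <- pick("O")
  hb <- matrix(FALSE, nu, nu)
  dinv <- function(p, q) {
    d <- sqrt(rowSums((p - q)^2))
    ifelse(d < 0.5, 2, 1 / d)  # clamp near-overlap as in the reference scheme
  }
  for (a in seq_len(nu)) {
    if (anyNA(C[a, ]) || anyNA(O[a, ])) next
    don <- which(!is.na(N[, 1]) & !is.na(H[, 1]))
    don <- don[don != a & don != a + 1L]   # no bond to self or to the amide
                                           # nitrogen bonded to this carbonyl
    if (!length(don)) next
    e <- .hb_k * (dinv(N[don, , drop = FALSE],
                       matrix(O[a, ], length(don), 3, byrow = TRUE)) +
                  dinv(H[don, , drop = FALSE],
                       matrix(C[a, ], length(don), 3, byrow = TRUE)) -
                  dinv(H[don, , drop = FALSE],
                       matrix(O[a, ], length(don), 3, byrow = TRUE)) -
                  dinv(N[don, , drop = FALSE],
                       matrix(C[a, ], length(don), 3, byrow = TRUE)))
    hb[don[e < .hb_energy_cut], a] <- TRUE
  }
  hb
}

#' Assign eight-state secondary structure to one frame
#'
#' A Kabsch-Sander style assignment: backbone H-bonds from the electrostatic
#' energy model (threshold -0.5 kcal/mol); two consecutive n-turns define
#' helices (n = 4 alpha, 3 3-10, 5 pi); bridge patterns define strand
#' states; remaining H-bonded turns give `T` and CA-trace kinks (kappa
#' > 70 degrees) give `S`. Priority on overlap: H > E/B > G > I > T > S.
#' The ACE/NME caps act as H-bond partners but receive no state (NA).
#'
#' @param coords atoms x 3 coordinate matrix.
#' @param topology matching `pept_topology`.
#' @return character vector over indexed units (NA at caps), values from
#'   [ss_states()].
#' @export
assign_ss <- function(coords, topology) {
  nu <- n_peptide_units(topology)
  res_units <- 2:(nu - 1)                 # amino-acid residues
  need <- c("N", "CA", "C", "O")
  for (u in res_units) {
    have <- topology$name[topology$res_index == u]
    if (!all(need %in% have))
      stop(sprintf("unit %d is missing backbone atoms", u), call. = FALSE)
  }
  hb <- hbond_matrix(coords, topology)
  # Hbond(i, j) in acceptor-first convention: CO of i accepts from NH of j
  hbond <- function(i, j) {
    ok <- i >= 1 & i <= nu & j >= 1 & j <= nu
    out <- logical(length(i))
    out[ok] <- hb[cbind(j[ok], i[ok])]
    out
  }
  u <- seq_len(nu)
  turn <- sapply(3:5, function(n) hbond(u, u + n))  # n-turn at i
  colnames(turn) <- c("t3", "t4", "t5")

  helix_from_turns <- function(tcol, n) {
    flag <- logical(nu)
    start <- which(tcol)
    start <- start[start >= 2]
    start <- start[tcol[start - 1]]
    for (s in start) flag[s:min(s + n - 1, nu)] <- TRUE
    flag
  }
  isH <- helix_from_turns(turn[, "t4"], 4)
  isG <- helix_from_turns(turn[, "t3"], 3)
  isI <- helix_from_turns(turn[, "t5"], 5)

  # bridges between non-adjacent residues
  bridge <- matrix(FALSE, nu, nu)
  for (i in res_units) {
    js <- res_units[abs(res_units - i) >= 3 & res_units > i]
    for (j in js) {
      par <- (hbond(i - 1, j) && hbond(j, i + 1)) ||
             (hbond(j - 1, i) && hbond(i, j + 1))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
      if (par || anti) { bridge[i, j] <- TRUE; bridge[j, i] <- TRUE }
    }
  }
  has_bridge <- rowSums(bridge) > 0
  # extended: bridge partners of consecutive residues are themselves
  # consecutive (a ladder); otherwise isolated bridge B
  isE <- logical(nu)
  for (i in which(has_bridge)) {
    for (j in which(bridge[i, ])) {
      ladder <- (i + 1 <= nu && j + 1 <= nu && bridge[i + 1, j + 1]) ||
                (i - 1 >= 1 && j - 1 >= 1 && bridge[i - 1, j - 1]) ||
                (i + 1 <= nu && j - 1 >= 1 && bridge[i + 1, j - 1]) ||
                (i - 1 >= 1 && j + 1 <= nu && bridge[i - 1, j + 1])
      if (ladder) isE[i] <- TRUE
    }
  }
  isB <- has_bridge & !isE

  # turn T: interior residues of any n-turn
  isT <- logical(nu)
  for (n in 3:5) {
    for (i in which(turn[, n - 2])) {
      span <- (i + 1):(i + n - 1)
      span <- span[span <= nu]
      isT[span] <- TRUE
    }
  }
  # bend S: kappa angle of the CA trace
  ca <- matrix(NA_real_, nu, 3)
  rows <- which(topology$name == "CA")
  ca[topology$res_index[rows], ] <- coords[rows, , drop = FALSE]
  isS <- logical(nu)
  for (i in res_units) {
    if (i - 2 < 1 || i + 2 > nu) next
    if (anyNA(ca[c(i - 2, i, i + 2), ])) next
    v1 <- ca[i, ] - ca[i - 2, ]
    v2 <- ca[i + 2, ] - ca[i, ]
    kappa <- acos(pmin(1, pmax(-1, sum(unit3(v1) * unit3(v2))))) * 180 / pi
    if (kappa > 70) isS[i] <- TRUE
  }

  state <- rep("C", nu)
  state[isS] <- "S"
  state[isT] <- "T"
  state[isI] <- "I"
  state[isG] <- "G"
  state[isB] <- "B"
  state[isE] <- "E"
  state[isH] <- "H"
  state[c(1, nu)] <- NA_character_
  state
}

#' Per-frame secondary-structure trace for an ensemble
#'
#' @param ensemble a `pept_ensemble`.
#' @param stride analyse every `stride`-th frame.
#' @return character matrix, frames x units (NA at caps).
#' @export
ss_trace <- function(ensemble, stride = 1) {
  idx <- seq(1, n_frames(ensemble), by = stride)
  if (!length(idx)) stop("stride leaves zero frames", call. = FALSE)
  t(vapply(idx, function(f) assign_ss(ensemble$coords[[f]],
                                      ensemble$topology),
           character(n_peptide_units(ensemble$topology))))
}

#' Per-residue secondary-structure state fractions
#'
#' Aggregates the per-frame assignment to the empirical distribution over
#' the 8 states for each residue (the stacked-bar statistic).
#'
#' @param ensemble a `pept_ensemble`.
#' @param stride analyse every `stride`-th frame.
#' @return a tibble of class `ss_fractions`: `res_index`, `seq_pos`, one
#'   column per state in [ss_states()]; rows sum to 1.
#' @export
ss_fractions <- function(ensemble, stride = 1) {
  trace <- ss_trace(ensemble, stride)
  spec <- attr(ensemble$topology, "spec")
  nu <- ncol(trace)
  res_units <- 2:(nu - 1)
  states <- ss_states()
  frac <- t(vapply(res_units, function(u) {
    tab <- table(factor(trace[, u], levels = states))
    as.numeric(tab) / nrow(trace)
  }, numeric(length(states))))
  colnames(frac) <- states
  out <- tibble::as_tibble(frac)
  out <- tibble::add_column(out, res_index = res_units,
                            seq_pos = spec$positions, .before = 1)
  class(out) <- c("ss_fractions", class(out))
  attr(out, "n_frames") <- nrow(trace)
  out
}

#' Helical fraction per residue
#'
#' Sum of the three helical state fractions (alpha, 3-10, pi).
#'
#' @param fractions an [ss_fractions()] table.
#' @return tibble with `res_index`, `seq_pos`, `helical`.
#' @export
helical_fraction <- function(fractions) {
  tibble::tibble(res_index = fractions$res_index,
                 seq_pos = fractions$seq_pos,
                 helical = fractions$H + fractions$G + fractions$I)
}

#' Mean interior helical fraction
#'
#' Average helical fraction over residues away from the segment ends
#' (default trims `edge` residues on each side), where end effects of
#' helix assignment are weakest.
#'
#' @param fractions an [ss_fractions()] table.
#' @param edge residues trimmed from each end (default 3).
#' @return single numeric value.
#' @export
interior_helicity <- function(fractions, edge = 3) {
  h <- helical_fraction(fractions)
  keep <- h$res_index > (min(h$res_index) + edge - 1) &
    h$res_index < (max(h$res_index) - edge + 1)
  mean(h$helical[keep])
}
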
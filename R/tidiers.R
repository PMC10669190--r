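#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a contact map into a long pair table
#'
#' @param x a `contact_map`.
#' @param upper_only keep only the strict upper triangle (one row per DOF).
#' @param ... unused.
#' @return tibble with `j`, `k`, `value`.
#' @export
tidy.contact_map <- function(x, upper_only = FALSE, ...) {
  m <- unclass(x)
  n <- nrow(m)
  out <- tibble::tibble(j = rep(seq_len(n), each = n),
                        k = rep(seq_len(n), n),
                        value = as.numeric(t(m)))
  if (upper_only) out <- out[out$j < out$k, ]
  out
}

#' Tidy the scores of a contact-vector PCA
#'
#' @param x a `contact_pca`.
#' @param ... unused.
#' @return tibble of per-frame component scores.
#' @export
tidy.contact_pca <- function(x, ...) x$scores

#' One-row summary of a contact-vector PCA
#'
#' @param x a `contact_pca`.
#' @param ... unused.
#' @return tibble with total variance and per-retained-component explained
#'   variance fractions.
#' @export
glance.contact_pca <- function(x, ...) {
  out <- tibble::tibble(total_var = x$total_var,
                        n_frames = nrow(x$scores),
                        n_dof = nrow(x$loadings))
  ve <- x$var_explained[seq_len(x$k)]
  for (j in seq_along(ve)) out[[paste0("prop_var_PC", j)]] <- ve[j]
  out
}

#' Tidy a nonlinear contact embedding
#' @param x a `contact_embed`.
#' @param ... unused.
#' @return tibble of per-frame embedded coordinates.
#' @export
tidy.contact_embed <- function(x, ...) x$coords

#' Component loadings labelled by contact pair
#'
#' @param fit a `contact_pca` fitted on contact vectors of an n-unit map.
#' @param n map dimension (units); inferred from the DOF count when NULL.
#' @return tibble with `pair` label "(j,k)", `j`, `k` and one column per
#'   retained component.
#' @export
pca_loadings <- function(fit, n = NULL) {
  stopifnot(inherits(fit, "contact_pca"))
  ndof <- nrow(fit$loadings)
  if (is.null(n)) {
    n <- (1 + sqrt(1 + 8 * ndof)) / 2
    if (abs(n - round(n)) > 1e-9)
      stop("DOF count is not n(n-1)/2 for integer n; supply n", call. = FALSE)
    n <- as.integer(round(n))
  }
  pairs <- attr(vectorize_map(diag(1, n)), "pairs")
  out <- tibble::tibble(pair = sprintf("(%d,%d)", pairs[, 1], pairs[, 2]),
                        j = pairs[, 1], k = pairs[, 2])
  for (c_ in seq_len(ncol(fit$loadings)))
    out[[paste0("PC", c_)]] <- fit$loadings[, c_]
  out
}
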
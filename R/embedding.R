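as_vector_matrix <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    len <- unique(lengths(vectors))
    if (length(len) != 1)
      stop("contact vectors have inconsistent lengths", call. = FALSE)
    vectors <- do.call(rbind, lapply(vectors, as.numeric))
  }
  m <- as.matrix(vectors)
  storage.mode(m) <- "double"
  m
}

#' PCA embedding of contact vectors
#'
#' Mean-centred covariance principal component analysis of per-frame contact
#' degree-of-freedom vectors (no variance scaling: the DOFs share the 0/1
#' scale). Component signs follow a fixed convention - the largest-magnitude
#' loading of each component is positive - so projections are fully
#' deterministic.
#'
#' @param vectors a frames x DOFs matrix (e.g. from [contact_vectors()]) or
#'   a list of equal-length numeric vectors.
#' @param k number of components to retain (default 2).
#' @return an object of class `contact_pca`: `scores` (frames x k tibble),
#'   `loadings` (DOFs x k matrix), `sdev`, `var_explained`, `total_var`,
#'   `method = "pca"`.
#' @export
pca_embed <- function(vectors, k = 2) {
  x <- as_vector_matrix(vectors)
  if (nrow(x) < 2) stop("need at least 2 vectors", call. = FALSE)
  if (k < 1 || k > ncol(x)) stop("k must be in 1..ncol", call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(k, ncol(fit$rotation))
  load <- fit$rotation[, seq_len(nc), drop = FALSE]
  scores <- fit$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- fit$sdev^2
  sc <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(sc) <- paste0("PC", seq_len(nc))
  sc <- tibble::add_column(sc, frame = seq_len(nrow(x)), .before = 1)
  structure(list(scores = sc, loadings = load, sdev = fit$sdev,
                 var_explained = ev / max(sum(ev), .Machine$double.eps),
                 total_var = sum(ev), center = fit$center, k = nc,
                 method = "pca"),
            class = "contact_pca")
}

#' @export
print.contact_pca <- function(x, ...) {
  cat(sprintf("<contact_pca> %d frames x %d DOFs -> %d component%s\n",
              nrow(x$scores), nrow(x$loadings), x$k, if (x$k > 1) "s" else ""))
  ve <- round(100 * x$var_explained[seq_len(x$k)], 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' Nonlinear embedding of contact vectors
#'
#' Nonlinear manifold projection of contact vectors for conformation-space
#' visualisation, complementing [pca_embed()]. The default backend is
#' non-metric multidimensional scaling (vegan's monoMDS) on Euclidean
#' contact-vector distances; `method = "mds"` gives classical metric scaling
#' (principal coordinates). Runs are reproducible under the seed recorded in
#' `params`.
#'
#' @param vectors frames x DOFs matrix or list of equal-length vectors.
#' @param k embedding dimension (default 2).
#' @param method `"nmds"` (default) or `"mds"`.
#' @param params list of backend parameters; recognised: `seed` (default
#'   42), `maxit` (default 200). Recorded in the result.
#' @return object of class `contact_embed`: `coords` (frames x k tibble),
#'   `method`, `params`.
#' @export
nonlinear_embed <- function(vectors, k = 2, method = c("nmds", "mds"),
                            params = list()) {
  method <- match.arg(method)
  x <- as_vector_matrix(vectors)
  if (nrow(x) < 4) stop("need at least 4 vectors", call. = FALSE)
  params <- utils::modifyList(list(seed = 42, maxit = 200), params)
  d <- stats::dist(x)
  coords <- if (max(d) < 1e-10) {
    warning("degenerate input: all contact vectors identical; ",
            "returning coincident coordinates", call. = FALSE)
    matrix(0, nrow(x), k)
  } else if (method == "nmds") {
    set.seed(params$seed)
    fit <- vegan::monoMDS(d, k = k, maxit = params$maxit)
    fit$points
  } else {
    cm <- stats::cmdscale(d, k = k)
    if (ncol(cm) < k) cm <- cbind(cm, matrix(0, nrow(cm), k - ncol(cm)))
    cm
  }
  co <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(co) <- paste0("dim", seq_len(k))
  co <- tibble::add_column(co, frame = seq_len(nrow(x)), .before = 1)
  structure(list(coords = co, method = method, params = params, k = k),
            class = "contact_embed")
}

#' @export
print.contact_embed <- function(x, ...) {
  cat(sprintf("<contact_embed> %s, %d frames -> %d dims (seed %s)\n",
              x$method, nrow(x$coords), x$k, x$params$seed))
  invisible(x)
}

#' Joint embedding of several ensembles in one coordinate system
#'
#' Pools the per-frame contact vectors of all ensembles, fits a single
#' embedding (PCA or nonlinear) on the pooled data, and returns the
#' projected coordinates with their ensemble labels - the cross-system
#' conformation projection. Because the collective coordinates are fitted on
#' the pool, adding or removing ensembles changes the projection of every
#' system.
#'
#' @param ensembles named list of `pept_ensemble` objects.
#' @param method `"pca"`, `"nmds"` or `"mds"`.
#' @param k embedding dimension.
#' @param cutoff,stride passed to [contact_vectors()].
#' @param params nonlinear backend parameters (see [nonlinear_embed()]).
#' @return a tibble with `ensemble`, `frame` (within-ensemble index) and the
#'   embedding dimensions; the fitted object is attached as attribute
#'   `fit`.
#' @export
joint_embed <- function(ensembles, method = c("pca", "nmds", "mds"), k = 2,
                        cutoff = 4.2, stride = 1, params = list()) {
  method <- match.arg(method)
  stopifnot(is.list(ensembles), length(ensembles) >= 1,
            !is.null(names(ensembles)))
  vecs <- lapply(ensembles, contact_vectors, cutoff = cutoff,
                 stride = stride)
  dims <- unique(vapply(vecs, ncol, 1L))
  if (length(dims) != 1)
    stop("ensembles have mismatched contact-vector dimensionality",
         call. = FALSE)
  pooled <- do.call(rbind, vecs)
  labels <- rep(names(vecs), vapply(vecs, nrow, 1L))
  within <- unlist(lapply(vecs, function(v) seq_len(nrow(v))),
                   use.names = FALSE)
  if (method == "pca") {
    fit <- pca_embed(pooled, k = k)
    coords <- fit$scores[, -1, drop = FALSE]
    names(coords) <- paste0("dim", seq_len(ncol(coords)))
  } else {
    fit <- nonlinear_embed(pooled, k = k, method = method, params = params)
    coords <- fit$coords[, -1, drop = FALSE]
  }
  out <- tibble::add_column(coords, ensemble = labels, frame = within,
                            .before = 1)
  attr(out, "fit") <- fit
  out
}
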
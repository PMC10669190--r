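#' Default generator scenario for a registry system
#'
#' Maps a system record to synthetic-generator parameters emulating the
#' study conditions: unliganded systems and systems whose ligand retains
#' helicity sample a helix-stable ensemble, while systems carrying a
#' destabilising (cyanopyrazole-like) B-ring sample a destabilised ensemble
#' whose B-ring is biased toward internal residue #5 (the tryptophan
#' position of the 406 segment). Values, all fixed package-wide:
#' helix-stable p = 0.85; destabilised p = 0.45 with bias fraction 0.6 at
#' residue #5; weak-binder ligands p = 0.80 with bias fraction 0.15 at
#' residue #16.
#'
#' @param ligand ligand code from the registry (`none`, `XNN`, `XN0`,
#'   `XNB`, `XEN`).
#' @return list with `p_helix`, and for liganded systems `bias_target`,
#'   `bias_fraction`.
#' @export
scenario_defaults <- function(ligand) {
  switch(ligand,
    none = list(p_helix = 0.85),
    XNN = ,
    XN0 = list(p_helix = 0.45, bias_target = 5L, bias_fraction = 0.6),
    XNB = ,
    XEN = list(p_helix = 0.80, bias_target = 16L, bias_fraction = 0.15),
    stop(sprintf("unknown ligand code '%s'", ligand), call. = FALSE)
  )
}

#' Assemble a pipeline run configuration
#'
#' @param registry a registry tibble from [load_registry()] (or a path to
#'   one).
#' @param n_frames frames per generated system.
#' @param cutoff contact cutoff in Angstrom.
#' @param stride analysis stride over stored frames.
#' @param n_blocks number of convergence blocks.
#' @param embed_method `"pca"`, `"nmds"` or `"mds"`.
#' @param embed_k embedding dimension.
#' @param seed master seed; per-system seeds are derived from it and the
#'   system notation so systems are independent but reproducible.
#' @param outdir output directory for CSV artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(registry = load_registry(), n_frames = 500,
                       cutoff = 4.2, stride = 1, n_blocks = 2,
                       embed_method = "pca", embed_k = 2, seed = 1,
                       outdir = tempfile("contactdof_run_")) {
  if (is.character(registry)) registry <- load_registry(registry)
  structure(list(registry = registry, n_frames = as.integer(n_frames),
                 cutoff = cutoff, stride = as.integer(stride),
                 n_blocks = as.integer(n_blocks),
                 embed_method = embed_method, embed_k = as.integer(embed_k),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

system_seed <- function(config, notation) {
  # stable small-integer seed from master seed + notation (kept < 2^31)
  h <- sum(utf8ToInt(notation) * seq_along(utf8ToInt(notation)))
  as.integer((as.numeric(config$seed) * 10007 + h) %% 2147483629)
}

#' Generate the synthetic ensemble for one registry system
#'
#' @param config a [run_config()].
#' @param notation system notation present in the registry.
#' @return a `pept_ensemble` (liganded when the registry says so).
#' @export
generate_system <- function(config, notation) {
  row <- config$registry[config$registry$notation == notation, ]
  if (nrow(row) != 1)
    stop(sprintf("system '%s' not in registry", notation), call. = FALSE)
  sc <- scenario_defaults(row$ligand)
  spec <- segment_spec(row$center)
  seed <- system_seed(config, notation)
  ens <- sample_helix_coil(spec,
                           helix_coil_model(p_helix = sc$p_helix,
                                            n_frames = config$n_frames,
                                            seed = seed))
  if (row$ligand != "none") {
    ens <- attach_pseudo_ligand(ens,
                                bias = list(target = sc$bias_target,
                                            fraction = sc$bias_fraction),
                                seed = seed + 1L)
  }
  ens
}

config_hash <- function(config) {
  rlang::hash(list(unclass(config$registry), config[setdiff(names(config),
                                                            c("registry",
                                                              "outdir"))]))
}

write_csv_stamped <- function(df, path, config, notation = NULL) {
  hdr <- sprintf("# contactdof seed=%d config=%s%s", config$seed,
                 config_hash(config),
                 if (is.null(notation)) "" else paste0(" system=", notation))
  writeLines(c(hdr, readr::format_csv(df)), path)
  invisible(path)
}

matrix_as_df <- function(m) {
  df <- tibble::as_tibble(as.data.frame(unclass(m)), .name_repair = "minimal")
  names(df) <- paste0("u", seq_len(ncol(m)))
  tibble::add_column(df, res_index = seq_len(nrow(m)), .before = 1)
}

#' Run the full per-system analysis
#'
#' Generates (or accepts) the system's ensemble and produces the figure-level
#' statistics: ensemble-mean contact map, per-residue secondary-structure
#' fractions, the per-frame contact-vector matrix, the same statistics per
#' convergence block (file suffixes `_1`, `_2`, ...), and - for liganded
#' systems - the fragment-resolved contact profile. All CSVs carry the seed
#' and a configuration hash in a leading comment line.
#'
#' @param config a [run_config()].
#' @param notation system notation.
#' @param ensemble optional pre-built `pept_ensemble` (when NULL the system
#'   is generated from the registry scenario).
#' @return invisibly, a list with the computed objects and `files`, the
#'   paths written.
#' @export
run_system <- function(config, notation, ensemble = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) message(sprintf("[%s] %-28s %6.1fs", notation,
                                          what,
                                          proc.time()[["elapsed"]] - t0))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(what, expr) {
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for %s: %s", what, notation,
                   conditionMessage(e)), call. = FALSE))
    stage(what)
    out
  }
  if (is.null(ensemble))
    ensemble <- run_stage("generate", generate_system(config, notation))
  blocks <- run_stage("split blocks",
                      split_blocks(ensemble, config$n_blocks))
  files <- character(0)
  save <- function(df, name) {
    p <- file.path(config$outdir, paste0(notation, "_", name, ".csv"))
    write_csv_stamped(df, p, config, notation)
    files[[length(files) + 1]] <<- p
    p
  }
  mean_map <- run_stage("mean contact map",
                        mean_contact_map(ensemble, config$cutoff,
                                         config$stride))
  save(matrix_as_df(mean_map), "meanmap")
  fractions <- run_stage("secondary structure",
                         ss_fractions(ensemble, config$stride))
  save(tibble::as_tibble(fractions), "ssfrac")
  vectors <- run_stage("contact vectors",
                       contact_vectors(ensemble, config$cutoff,
                                       config$stride))
  vdf <- tibble::as_tibble(as.data.frame(vectors), .name_repair = "minimal")
  names(vdf) <- paste0("dof", seq_len(ncol(vdf)))
  save(tibble::add_column(vdf, frame = seq_len(nrow(vdf)), .before = 1),
       "contactvec")
  block_maps <- list()
  block_fracs <- list()
  for (b in seq_along(blocks)) {
    bm <- run_stage(sprintf("block %d contact map", b),
                    mean_contact_map(blocks[[b]], config$cutoff,
                                     config$stride))
    bf <- run_stage(sprintf("block %d secstruct", b),
                    ss_fractions(blocks[[b]], config$stride))
    save(matrix_as_df(bm), sprintf("meanmap_%d", b))
    save(tibble::as_tibble(bf), sprintf("ssfrac_%d", b))
    block_maps[[b]] <- bm
    block_fracs[[b]] <- bf
  }
  profile <- NULL
  if (any(!is.na(ensemble$topology$fragment))) {
    profile <- run_stage("fragment profile",
                         fragment_contact_profile(ensemble, config$cutoff,
                                                  config$stride))
    save(tibble::as_tibble(profile), "fragprofile")
  }
  invisible(list(ensemble = ensemble, mean_map = mean_map,
                 fractions = fractions, vectors = vectors,
                 block_maps = block_maps, block_fractions = block_fracs,
                 profile = profile, files = unlist(files)))
}

#' Cross-system comparison: joint embedding and summary report
#'
#' Pools two or more systems into one embedding (the cross-system
#' conformation projection), embeds each convergence block of the pool as
#' well, and tabulates per-system summary statistics: mean interior helical
#' fraction, mean per-frame contact count, and the strongest ligand-fragment
#' contact.
#'
#' @param config a [run_config()].
#' @param notations character vector of >= 2 system notations.
#' @param method embedding method overriding `config$embed_method` when
#'   non-NULL.
#' @return list with `embedding` (labelled tibble from [joint_embed()]),
#'   `block_embeddings`, `report` (one row per system) and `files`.
#' @export
run_comparison <- function(config, notations, method = NULL) {
  if (length(notations) < 2)
    stop("comparison needs at least two systems", call. = FALSE)
  method <- method %||% config$embed_method
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ensembles <- lapply(notations, function(nt) generate_system(config, nt))
  names(ensembles) <- notations
  emb <- joint_embed(ensembles, method = method, k = config$embed_k,
                     cutoff = config$cutoff, stride = config$stride,
                     params = list(seed = config$seed))
  files <- character(0)
  tag <- paste(notations, collapse = "-")
  p <- file.path(config$outdir, sprintf("compare_%s_embedding.csv", tag))
  write_csv_stamped(emb, p, config)
  files <- c(files, p)
  block_embs <- list()
  for (b in seq_len(config$n_blocks)) {
    blocks <- lapply(ensembles, function(e)
      split_blocks(e, config$n_blocks)[[b]])
    be <- joint_embed(blocks, method = method, k = config$embed_k,
                      cutoff = config$cutoff, stride = config$stride,
                      params = list(seed = config$seed))
    pb <- file.path(config$outdir,
                    sprintf("compare_%s_embedding_%d.csv", tag, b))
    write_csv_stamped(be, pb, config)
    files <- c(files, pb)
    block_embs[[b]] <- be
  }
  report <- purrr::map_dfr(notations, function(nt) {
    e <- ensembles[[nt]]
    fr <- ss_fractions(e, config$stride)
    mm <- mean_contact_map(e, config$cutoff, config$stride)
    v <- vectorize_map(mm)
    top_frag <- NA_character_
    top_pct <- NA_real_
    if (any(!is.na(e$topology$fragment))) {
      pr <- fragment_contact_profile(e, config$cutoff, config$stride)
      spec <- attr(e$topology, "spec")
      att <- internal_index(spec$center_position, spec)
      # specificity signal: ring-fragment contacts away from the covalent
      # tether (stem/Cys contacts at the attachment site are trivial)
      pr <- pr[pr$fragment %in% c("A-ring", "B-ring") &
                 pr$res_index != att & !is.na(pr$contact_pct), ]
      i <- which.max(pr$contact_pct)
      top_frag <- sprintf("%s@%d", pr$fragment[i], pr$res_index[i])
      top_pct <- pr$contact_pct[i]
    }
    tibble::tibble(notation = nt,
                   n_frames = n_frames(e),
                   helical_interior = interior_helicity(fr),
                   mean_contacts = sum(v),
                   top_fragment_contact = top_frag,
                   top_fragment_pct = top_pct)
  })
  pr <- file.path(config$outdir, sprintf("compare_%s_report.csv", tag))
  write_csv_stamped(report, pr, config)
  files <- c(files, pr)
  list(embedding = emb, block_embeddings = block_embs, report = report,
       files = files)
}
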
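write_run_provenance <- function(out_dir, config, inputs = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  manifest <- list(
    package = "stemspec",
    version = as.character(utils::packageVersion("stemspec")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    input_md5 = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' End-to-end bulk ATR screening pipeline
#'
#' read/accept -> truncate to the fingerprint region -> vector normalize
#' -> EMSC decomposition -> per-sample relative absorbances ->
#' compound screening against the rooting traits.
#'
#' @param table a [spectrum_table] (or path to a wide CSV).
#' @param library a [component_library] (or path to a library CSV).
#' @param reference optional reference spectrum / [spectrum_table] for the
#'   EMSC model; defaults to the batch mean of `table` (see
#'   [emsc_model()] for when a dedicated reference is needed).
#' @param lo,hi fingerprint range (cm^-1).
#' @param normalize vector-normalize before decomposition (default TRUE).
#' @param poly_order,solver EMSC settings.
#' @param rpd_thresh,alpha screening thresholds (bulk-scale defaults
#'   3 and 0.05).
#' @param seed recorded in the provenance manifest.
#' @param out_dir optional output directory: screening + correlation CSVs,
#'   relative-absorbance CSV, resolved config YAML, run manifest JSON.
#' @return list of class `bulk_run`: `fit` ([emsc_fit]), `rel_abs`,
#'   `screening`, `correlations`, `config`.
#' @export
run_bulk <- function(table, library, reference = NULL, lo = 800,
                     hi = 1800, normalize = TRUE, poly_order = 2,
                     solver = "ols", rpd_thresh = 3, alpha = 0.05,
                     seed = 1, out_dir = NULL) {
  inputs <- character()
  if (is.character(table)) {
    inputs <- c(inputs, table)
    table <- read_spectra_csv(table, "wide")
  }
  if (is.character(library)) {
    if (!file.exists(library)) {
      stop("config error: library file not found: ", library,
           call. = FALSE)
    }
    inputs <- c(inputs, library)
    library <- read_component_library(library)
  }
  stopifnot(inherits(table, "spectrum_table"),
            inherits(library, "component_library"))
  config <- list(stage = "bulk", lo = lo, hi = hi, normalize = normalize,
                 poly_order = poly_order, solver = solver,
                 rpd_thresh = rpd_thresh, alpha = alpha, seed = seed)
  table <- truncate_range(table, lo, hi)
  if (normalize) table <- vector_normalize(table)
  if (is.null(reference)) reference <- table
  model <- emsc_model(reference, library, poly_order = poly_order)
  fit <- emsc_fit(model, table, solver = solver)
  rel <- relative_absorbance(fit, "long")
  screening <- screen_compounds(rel, table$meta, rpd_thresh = rpd_thresh,
                                alpha = alpha)
  correlations <- correlation_matrix(rel, table$meta)
  if (!is.null(out_dir)) {
    write_run_provenance(out_dir, config, inputs)
    write.csv(screening, file.path(out_dir, "screening.csv"),
              row.names = FALSE)
    write.csv(correlations, file.path(out_dir, "trait_correlations.csv"),
              row.names = FALSE)
    write.csv(rel, file.path(out_dir, "relative_absorbance.csv"),
              row.names = FALSE)
  }
  structure(list(fit = fit, rel_abs = rel, screening = screening,
                 correlations = correlations, config = config),
            class = "bulk_run")
}

#' End-to-end imaging comparison between two genotype sections
#'
#' Truncates and vector-normalizes both cubes, clusters the pooled
#' unmasked fingerprints of both sections jointly (shared cluster scheme),
#' splits the labels back per cube, fits the EMSC model per pixel, and
#' compares every (cluster, component) pair between the genotypes.
#'
#' @param cube_a,cube_b [hypercube]s on the same axis (genotype A is the
#'   test group, genotype B the 100% reference).
#' @param library a [component_library].
#' @param reference reference spectrum for [emsc_model()]; defaults to the
#'   mean unmasked pixel spectrum of both cubes.
#' @param k number of tissue clusters (default 7).
#' @param lo,hi fingerprint range (cm^-1).
#' @param linkage,max_pixels,seed clustering settings ([hcluster()]).
#' @param poly_order,solver EMSC settings.
#' @param p_thresh,d_thresh,r2_thresh verdict thresholds
#'   ([compare_clusters()]; imaging defaults 0.001 / 0.8 / 0.5).
#' @param tissue_names optional character vector of length `k` naming the
#'   clusters anatomically (epidermis, root cap, ...). The mapping is the
#'   analyst's interpretation; it is echoed into the cluster summaries.
#' @param out_dir optional output directory: comparison CSV, verdict JSON
#'   summary, cluster summary CSV, component maps (ENVI + CSV), label
#'   maps (ENVI), config + manifest.
#' @return list of class `imaging_run`: `clusters_a`, `clusters_b`
#'   (shared scheme), `maps_a`, `maps_b`, `comparison`
#'   ([compare_clusters()] tibble), `config`.
#' @export
run_imaging <- function(cube_a, cube_b, library, reference = NULL,
                        k = 7, lo = 800, hi = 1800, linkage = "ward",
                        max_pixels = 20000, seed = 1, poly_order = 2,
                        solver = "ols", p_thresh = 0.001, d_thresh = 0.8,
                        r2_thresh = 0.5, tissue_names = NULL,
                        out_dir = NULL) {
  if (!is.null(tissue_names) && length(tissue_names) != k) {
    stop("tissue_names must have length k", call. = FALSE)
  }
  stopifnot(inherits(cube_a, "hypercube"), inherits(cube_b, "hypercube"),
            inherits(library, "component_library"))
  if (!isTRUE(all.equal(cube_a$axis, cube_b$axis))) {
    stop("data error: the two cubes are on different wavenumber axes",
         call. = FALSE)
  }
  config <- list(stage = "imaging", k = k, lo = lo, hi = hi,
                 linkage = linkage, max_pixels = max_pixels,
                 poly_order = poly_order, solver = solver,
                 p_thresh = p_thresh, d_thresh = d_thresh,
                 r2_thresh = r2_thresh, tissue_names = tissue_names,
                 seed = seed)
  ca <- vector_normalize(truncate_range(cube_a, lo, hi))
  cb <- vector_normalize(truncate_range(cube_b, lo, hi))
  fa <- extract_fingerprints(ca, lo, hi)
  fb <- extract_fingerprints(cb, lo, hi)
  joint <- rbind(fa, fb)
  attr(joint, "pixel_idx") <- seq_len(nrow(joint))
  attr(joint, "img_dim") <- c(nrow(joint), 1L)
  cl <- hcluster(joint, k = k, linkage = linkage,
                 max_pixels = max_pixels, seed = seed)
  lab_vec <- cl$labels[cl$pixel_idx]
  split_clusters <- function(fp, labs, template) {
    labels <- matrix(0L, attr(fp, "img_dim")[1], attr(fp, "img_dim")[2])
    labels[attr(fp, "pixel_idx")] <- labs
    res <- template
    res$labels <- labels
    res$pixel_idx <- attr(fp, "pixel_idx")
    res$cluster_areas <- tabulate(labs, nbins = template$k)
    res$pixel_size_um <- attr(fp, "pixel_size_um")
    res
  }
  na <- nrow(fa)
  clusters_a <- split_clusters(fa, lab_vec[seq_len(na)], cl)
  clusters_b <- split_clusters(fb, lab_vec[(na + 1):length(lab_vec)], cl)
  if (is.null(reference)) {
    reference <- colMeans(rbind(fa, fb))
  }
  model <- emsc_model(reference, truncate_library(library, lo, hi),
                      poly_order = poly_order)
  maps_a <- emsc_fit_cube(model, ca, solver = solver)
  maps_b <- emsc_fit_cube(model, cb, solver = solver)
  comparison <- compare_clusters(maps_a, maps_b, clusters_a, clusters_b,
                                 p_thresh = p_thresh,
                                 d_thresh = d_thresh,
                                 r2_thresh = r2_thresh)
  if (!is.null(out_dir)) {
    write_run_provenance(out_dir, config)
    write.csv(comparison, file.path(out_dir, "cluster_comparison.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(significant = comparison[
        !is.na(comparison$verdict) &
          comparison$verdict == "significant",
        c("cluster", "component")]),
      file.path(out_dir, "verdicts.json"), auto_unbox = TRUE,
      pretty = TRUE)
    for (side in c("a", "b")) {
      clr <- get(paste0("clusters_", side))
      summ <- tidy(clr)
      summ$tissue_name <- if (is.null(tissue_names)) NA_character_ else
        tissue_names[summ$cluster]
      write.csv(summ, file.path(out_dir,
                                paste0("cluster_summary_", side, ".csv")),
                row.names = FALSE)
      export_maps(get(paste0("maps_", side)), out_dir,
                  stem = paste0("component_maps_", side))
      envi_write_array(
        array(as.numeric(clr$labels), c(dim(clr$labels), 1L)),
        file.path(out_dir, paste0("labels_", side, ".envi")),
        band_names = "cluster")
    }
  }
  structure(list(clusters_a = clusters_a, clusters_b = clusters_b,
                 maps_a = maps_a, maps_b = maps_b,
                 comparison = comparison, config = config),
            class = "imaging_run")
}

truncate_library <- function(library, lo, hi) {
  keep <- truncate_idx(library$axis, lo, hi)
  if (length(keep) == length(library$axis)) return(library)
  component_library(library$spectra[, keep, drop = FALSE],
                    library$axis[keep], names = library$info$name,
                    categories = library$info$category)
}
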
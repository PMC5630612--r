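#' Pipeline configuration
#'
#' Collects every stage parameter with units and validates each against its
#' operation's preconditions. The serialized configuration (and its hash) is
#' written into every output sidecar for provenance.
#'
#' @param window_sec sliding-window length in seconds (default 60).
#' @param step_sec window step in seconds (default 3.6).
#' @param rank_M stationary-centering rank (default 50).
#' @param k_range candidate numbers of RDPs for consensus selection
#'   (default 1:30).
#' @param k_fixed override: skip consensus and use this K.
#' @param folds consensus folds (default 10).
#' @param n_init k-means restarts for the final fit (default 20).
#' @param consensus_n_init restarts per consensus fold fit (default 5).
#' @param min_region_size pruning threshold in voxels (default 20).
#' @param connectivity 26 or 6 neighborhood for contiguous regions.
#' @param band band-pass edges in Hz (default `c(0.0167, 0.15)`).
#' @param n_discard initial volumes to discard (default 10).
#' @param detrend_order polynomial detrend order (default 2).
#' @param global_signal apply global signal regression (default TRUE).
#' @param eig_mode `"magnitude"` or `"algebraic"` eigenpair selection.
#' @param eig_method `"projection"` or `"arpack"`.
#' @param seed integer seed for all stochastic stages.
#' @return An object of class `dfc_config`.
#' @export
dfc_config <- function(window_sec = 60, step_sec = 3.6, rank_M = 50L,
                       k_range = 1:30, k_fixed = NULL, folds = 10L,
                       n_init = 20L, consensus_n_init = 5L,
                       min_region_size = 20L, connectivity = 26L,
                       band = c(0.0167, 0.15), n_discard = 10L,
                       detrend_order = 2L, global_signal = TRUE,
                       eig_mode = "magnitude", eig_method = "projection",
                       seed = 1L) {
  stopifnot(window_sec > 0, step_sec > 0, rank_M >= 0,
            all(k_range >= 1), folds >= 2, n_init >= 1,
            min_region_size >= 1, connectivity %in% c(6L, 26L),
            length(band) == 2L, band[1] > 0, band[2] > band[1],
            n_discard >= 0, detrend_order >= 1)
  eig_mode <- match.arg(eig_mode, c("magnitude", "algebraic"))
  eig_method <- match.arg(eig_method, c("projection", "arpack"))
  cfg <- list(window_sec = window_sec, step_sec = step_sec,
              rank_M = as.integer(rank_M), k_range = as.integer(k_range),
              k_fixed = if (is.null(k_fixed)) NULL else as.integer(k_fixed),
              folds = as.integer(folds), n_init = as.integer(n_init),
              consensus_n_init = as.integer(consensus_n_init),
              min_region_size = as.integer(min_region_size),
              connectivity = as.integer(connectivity), band = band,
              n_discard = as.integer(n_discard),
              detrend_order = as.integer(detrend_order),
              global_signal = global_signal, eig_mode = eig_mode,
              eig_method = eig_method, seed = as.integer(seed))
  class(cfg) <- "dfc_config"
  cfg
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

#' @export
print.dfc_config <- function(x, ...) {
  cat(sprintf("<dfc_config> window %g s / step %g s, M = %d, K in [%d, %d], %d folds, prune < %d voxels (hash %s)\n",
              x$window_sec, x$step_sec, x$rank_M, min(x$k_range), max(x$k_range),
              x$folds, x$min_region_size, config_hash(x)))
  invisible(x)
}

#' End-to-end dFC parcellation pipeline
#'
#' Preprocess each subject, extract window-wise dominant patterns, pool and
#' cluster them into RDPs (with consensus selection of K unless `k_fixed` is
#' set), derive the sign-code label volume, split into contiguous regions,
#' prune, and compute symmetry and distance diagnostics. Deterministic given
#' the configuration seed.
#'
#' @param subjects list of 4D arrays, NIfTI images or [voxel_ts] objects
#'   (already-masked `voxel_ts` skip masking).
#' @param mask 3D mask (ignored for `voxel_ts` inputs).
#' @param config a [dfc_config].
#' @param tr repetition time in seconds (needed for raw arrays).
#' @param affine voxel-to-mm affine (for raw arrays; default identity * 2mm
#'   is NOT assumed — supply the true one for meaningful mm diagnostics).
#' @param confounds optional list of `T x Q` confound matrices per subject.
#' @param out_dir if non-NULL, writes atlas NIfTIs, the region TSV and JSON
#'   reports there.
#' @param verbose log stage progress.
#' @return An object of class `dfc_pipeline`: `rdps`, `consensus`, `labels`,
#'   `parcellation`, `symmetry`, `distances`, `config`, `config_hash`.
#' @export
run_pipeline <- function(subjects, mask = NULL, config = dfc_config(),
                         tr = 0.72, affine = diag(4), confounds = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "dfc_config"), length(subjects) >= 1)
  log_ <- function(...) if (verbose) message(sprintf(...))

  dp_list <- vector("list", length(subjects))
  for (s in seq_along(subjects)) {
    obj <- subjects[[s]]
    ts <- tryCatch({
      if (inherits(obj, "voxel_ts")) obj
      else mask_timeseries(obj, mask, tr = tr, affine = affine,
                           subject_id = paste0("sub-", s))
    }, error = function(e) stopf("stage preprocess, subject %d: %s", s,
                                 conditionMessage(e)))
    ts$subject_id <- ts$subject_id %||% paste0("sub-", s)
    log_("preprocessing subject %d/%d", s, length(subjects))
    ts <- tryCatch(
      preprocess_run(ts, n_discard = config$n_discard,
                     detrend_order = config$detrend_order,
                     confounds = confounds[[s]],
                     low = config$band[1], high = config$band[2],
                     global_signal = config$global_signal),
      error = function(e) stopf("stage preprocess, subject %d: %s", s,
                                conditionMessage(e)))
    log_("dominant patterns, subject %d/%d", s, length(subjects))
    dp_list[[s]] <- tryCatch(
      run_subject(ts, M = config$rank_M,
                  window_sec = config$window_sec, step_sec = config$step_sec,
                  eig_mode = config$eig_mode, method = config$eig_method),
      error = function(e) stopf("stage centrality, subject %d: %s", s,
                                conditionMessage(e)))
  }

  pool <- concatenate_patterns(dp_list)
  consensus <- NULL
  K <- config$k_fixed
  if (is.null(K)) {
    log_("consensus selection of K over %d candidates", length(config$k_range))
    consensus <- tryCatch(
      consensus_select_K(pool, K_range = config$k_range, folds = config$folds,
                         n_init = config$consensus_n_init, seed = config$seed),
      error = function(e) stopf("stage cluster (consensus): %s", conditionMessage(e)))
    K <- consensus$selected_K
  }
  log_("final clustering at K = %d", K)
  rdps <- tryCatch(
    cosine_kmeans(pool, K, n_init = config$n_init, seed = config$seed),
    error = function(e) stopf("stage cluster: %s", conditionMessage(e)))

  labels <- assign_labels(rdps)
  parc <- tryCatch(
    prune_small(connected_components(labels, config$connectivity),
                config$min_region_size),
    error = function(e) stopf("stage parcellate: %s", conditionMessage(e)))
  sym <- symmetry_index(parc)
  dists <- pattern_distances(parc)

  res <- structure(list(rdps = rdps, consensus = consensus, labels = labels,
                        parcellation = parc, symmetry = sym, distances = dists,
                        dominant_patterns = dp_list,
                        config = config, config_hash = config_hash(config)),
                   class = "dfc_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.dfc_pipeline <- function(x, ...) {
  cat(sprintf("<dfc_pipeline> K = %d RDPs -> %d labels -> %d regions (config %s)\n",
              x$rdps$K, length(unique(x$parcellation$regions$parent_label)),
              nrow(x$parcellation$regions), x$config_hash))
  invisible(x)
}

#' Write pipeline outputs
#'
#' Exports the long-range label map and fine-scale region-id map as integer
#' NIfTI volumes, the RDP centroid maps as a 4D NIfTI, the region table as
#' TSV, and symmetry/distance/consensus reports as JSON. Every file's sidecar
#' carries the configuration and its hash.
#'
#' @param res a `dfc_pipeline`.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_pipeline <- function(res, dir) {
  stopifnot(inherits(res, "dfc_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- res$parcellation
  lab_vol <- unmask(ifelse(is.na(p$labels), -1, p$labels),
                    p$mask_indices, p$dim3, background = -1)
  reg_vol <- unmask(p$region_id, p$mask_indices, p$dim3, background = 0)
  RNifti::writeNifti(RNifti::asNifti(lab_vol), file.path(dir, "labels.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(reg_vol), file.path(dir, "regions.nii.gz"))
  rdp_vol <- array(0, c(p$dim3, res$rdps$K))
  for (k in seq_len(res$rdps$K))
    rdp_vol[, , , k] <- unmask(res$rdps$centroids[, k], p$mask_indices, p$dim3, 0)
  RNifti::writeNifti(RNifti::asNifti(rdp_vol), file.path(dir, "rdps.nii.gz"))
  utils::write.table(res$parcellation$regions, file.path(dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    config = unclass(res$config), config_hash = res$config_hash,
    K = res$rdps$K, occupancy = res$rdps$occupancy,
    n_labels = length(unique(p$regions$parent_label)),
    n_regions = nrow(p$regions),
    symmetry = list(frac_symmetric = attr(res$symmetry, "frac_symmetric"),
                    per_label = as.data.frame(res$symmetry)),
    distances = list(mean_mm = res$distances$mean_mm,
                     sd_mm = res$distances$sd_mm,
                     n_pairs = res$distances$n_pairs),
    consensus = if (!is.null(res$consensus))
      list(K_values = res$consensus$K_values,
           medians = res$consensus$medians,
           selected_K = res$consensus$selected_K))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list.files(dir, full.names = TRUE))
}

#' Check that two pipeline artifacts share a configuration
#'
#' @param a,b `dfc_pipeline` objects or report lists carrying `config_hash`.
#' @return TRUE invisibly, or an error naming the mismatching hashes.
#' @export
check_same_config <- function(a, b) {
  ha <- a$config_hash; hb <- b$config_hash
  if (!identical(ha, hb))
    stopf("artifacts come from different configurations (%s vs %s); refusing to mix",
          ha, hb)
  invisible(TRUE)
}
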
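# Bundle-definition configuration files (YAML or JSON). Schema:
#
# tracts:
#   NAME:
#     include: [{path: roi1.nii.gz, tol: 2}, ...]
#     exclude: [{path: ..., tol: ...}]
#     start: start.nii.gz
#     end: end.nii.gz
#     cross_midline: true/false
#     prob_map: {path: map.nii.gz, threshold: 0.1}
#     length: {min_len: 10, max_len: 200}
#     primary_axis: {axis: "I/S", percentage: 60}
#     shape_prior: {path: refs.trk, centroid: 10}
#     qb_thresh: 10
#     mahal: {n_points: 100, distance_threshold: 3, length_threshold: 4,
#             clean_rounds: 5, min_sl: 20}
#
# Unknown keys are rejected with an error naming the key. ROI paths are
# resolved relative to the configuration file.

known_config_keys <- c("include", "exclude", "start", "end",
                       "cross_midline", "prob_map", "length",
                       "primary_axis", "shape_prior", "qb_thresh", "mahal")

#' Read a bundle-definition configuration (YAML or JSON)
#'
#' @param path configuration file; `.yml`/`.yaml` or `.json`.
#' @return a `bundle_definitions` with all referenced volumes loaded.
#' @export
read_bundle_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yml = ,
                yaml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = FALSE),
                stop(sprintf("unsupported config format '.%s'", ext)))
  if (is.null(cfg$tracts) || !length(cfg$tracts))
    stop("config must contain a nonempty 'tracts' mapping")
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  defs <- lapply(names(cfg$tracts), function(tract) {
    spec <- cfg$tracts[[tract]]
    unknown <- setdiff(names(spec), known_config_keys)
    if (length(unknown))
      stop(sprintf("unknown criterion key(s) for tract '%s': %s",
                   tract, paste(unknown, collapse = ", ")))
    roi_list <- function(entries) {
      lapply(entries, function(e)
        list(mask = read_mask_volume(resolve(e$path), "roi"),
             tol = if (is.null(e$tol)) 0 else e$tol))
    }
    bundle_criteria(
      include = if (!is.null(spec$include)) roi_list(spec$include),
      exclude = if (!is.null(spec$exclude)) roi_list(spec$exclude),
      start = if (!is.null(spec$start))
        read_mask_volume(resolve(spec$start), "roi"),
      end = if (!is.null(spec$end))
        read_mask_volume(resolve(spec$end), "roi"),
      cross_midline = spec$cross_midline,
      prob_map = if (!is.null(spec$prob_map))
        list(mask = read_mask_volume(resolve(spec$prob_map$path), "prob"),
             threshold = if (is.null(spec$prob_map$threshold)) 0
                         else spec$prob_map$threshold),
      length = spec$length,
      primary_axis = spec$primary_axis,
      shape_prior = if (!is.null(spec$shape_prior))
        list(sl = read_tractogram(resolve(spec$shape_prior$path))$streamlines,
             centroid = spec$shape_prior$centroid),
      qb_thresh = spec$qb_thresh,
      mahal = if (!is.null(spec$mahal)) {
        if (isTRUE(spec$mahal)) cleaning_params()
        else do.call(cleaning_params, spec$mahal)
      })
  })
  names(defs) <- names(cfg$tracts)
  bundle_definitions(defs)
}
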
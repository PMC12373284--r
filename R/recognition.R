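# Bundle definitions and the recognition engine.
#
# Each tract is defined by an optional set of criteria, applied to every
# candidate streamline in a fixed order:
#   (1) prob_map, (2) cross_midline, (3) start, (4) end, (5) length,
#   (6) primary_axis, (7) include, (8) exclude, (9) shape_prior,
#   (10) qb_thresh, (11) mahal.
# Criteria 1-9 are per-streamline filters; 10 and 11 clean the surviving
# set as a whole. A streamline surviving for several tracts is assigned to
# the first tract in the definition set, with a recorded warning.

criterion_order <- c("prob_map", "cross_midline", "start", "end", "length",
                     "primary_axis", "include", "exclude", "shape_prior",
                     "qb_thresh", "mahal")

#' Define the recognition criteria for one tract
#'
#' Every criterion is optional; an omitted criterion does not constrain
#' candidate streamlines.
#'
#' @param include list of `list(mask = mask_volume, tol = mm)` inclusion
#'   (waypoint) ROIs; a streamline must come within `tol` mm of every one.
#' @param exclude list of `list(mask, tol)` exclusion ROIs; a streamline
#'   must stay farther than `tol` mm from all of them.
#' @param start,end `mask_volume`s; the streamline must begin in `start`
#'   and/or terminate in `end` (after flipping if only the flipped
#'   orientation satisfies them, so accepted bundles are oriented from
#'   start to end).
#' @param cross_midline `TRUE` (must cross the x = 0 plane), `FALSE`
#'   (must not), or `NULL` (no constraint).
#' @param prob_map `list(mask = mask_volume(kind = "prob"), threshold = t)`;
#'   the mean probability sampled along the 100-node resampled streamline
#'   must be strictly greater than `threshold` (default threshold 0).
#' @param length `list(min_len, max_len)` admissible length range in mm,
#'   inclusive.
#' @param primary_axis `list(axis, percentage)` with axis one of
#'   `"L/R"`, `"P/A"`, `"I/S"`; at least `percentage` percent of the
#'   streamline's per-segment movement must lie along that axis.
#' @param shape_prior `list(sl = list of reference streamlines,
#'   centroid = mm)`; the minimum MDF distance (20 points) to a reference
#'   must not exceed `centroid`.
#' @param qb_thresh QuickBundles cleaning threshold in mm (set-level).
#' @param mahal `cleaning_params()` record or `TRUE` for defaults
#'   (set-level Mahalanobis cleaning).
#' @return an object of class `bundle_criteria`.
#' @export
bundle_criteria <- function(include = NULL, exclude = NULL, start = NULL,
                            end = NULL, cross_midline = NULL, prob_map = NULL,
                            length = NULL, primary_axis = NULL,
                            shape_prior = NULL, qb_thresh = NULL,
                            mahal = NULL) {
  if (!is.null(include)) check_roi_list(include, "include")
  if (!is.null(exclude)) check_roi_list(exclude, "exclude")
  if (!is.null(prob_map)) {
    stopifnot(inherits(prob_map$mask, "mask_volume"))
    if (is.null(prob_map$threshold)) prob_map$threshold <- 0
  }
  if (!is.null(length)) {
    stopifnot(is.numeric(length$min_len), is.numeric(length$max_len))
    if (length$min_len > length$max_len)
      stop("length: min_len must not exceed max_len")
  }
  if (!is.null(primary_axis)) {
    if (!primary_axis$axis %in% c("L/R", "P/A", "I/S"))
      stop("primary_axis: axis must be one of 'L/R', 'P/A', 'I/S'")
    p <- primary_axis$percentage
    if (!is.numeric(p) || p <= 0 || p > 100)
      stop("primary_axis: percentage must lie in (0, 100]")
  }
  if (!is.null(shape_prior)) {
    if (!base::length(shape_prior$sl))
      stop("shape_prior: at least one reference streamline required")
    if (!is.numeric(shape_prior$centroid))
      stop("shape_prior: centroid threshold (mm) required")
  }
  if (!is.null(qb_thresh) && qb_thresh <= 0)
    stop("qb_thresh must be positive")
  if (isTRUE(mahal)) mahal <- cleaning_params()
  structure(list(include = include, exclude = exclude, start = start,
                 end = end, cross_midline = cross_midline,
                 prob_map = prob_map, length = length,
                 primary_axis = primary_axis, shape_prior = shape_prior,
                 qb_thresh = qb_thresh, mahal = mahal),
            class = "bundle_criteria")
}

check_roi_list <- function(rois, what) {
  for (r in rois) {
    if (!inherits(r$mask, "mask_volume"))
      stop(sprintf("%s: each entry needs a mask_volume under $mask", what))
    if (is.null(r$tol)) stop(sprintf("%s: each entry needs a tolerance $tol", what))
    if (r$tol < 0) stop(sprintf("%s: tolerance must be >= 0", what))
  }
  invisible(rois)
}

#' Ordered set of tract definitions
#'
#' The order of entries is semantically meaningful: when a streamline
#' satisfies several tracts, the tie goes to the first tract in the set.
#'
#' @param ... named `bundle_criteria` objects, one per tract.
#' @return an object of class `bundle_definitions` (an ordered named list).
#' @export
bundle_definitions <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.null(names(defs)) && is.list(defs[[1]]) &&
      !inherits(defs[[1]], "bundle_criteria"))
    defs <- defs[[1]]
  if (length(defs) == 0L) stop("at least one tract definition required")
  if (is.null(names(defs)) || any(names(defs) == ""))
    stop("every tract definition must be named")
  if (anyDuplicated(names(defs)))
    stop("tract names must be unique")
  for (d in defs) stopifnot(inherits(d, "bundle_criteria"))
  structure(defs, class = "bundle_definitions")
}

#' Inclusion-ROI (waypoint) test
#'
#' @param sl streamline matrix.
#' @param rois list of `list(mask, tol)`.
#' @return TRUE iff the streamline passes within `tol` mm of every ROI.
#' @export
passes_include <- function(sl, rois) {
  for (r in rois) {
    if (min_distance_to_mask(sl, r$mask) > r$tol) return(FALSE)
  }
  TRUE
}

#' Exclusion-ROI test
#'
#' @param sl streamline matrix.
#' @param rois list of `list(mask, tol)`.
#' @return TRUE iff the streamline stays farther than `tol` mm from every ROI.
#' @export
passes_exclude <- function(sl, rois) {
  for (r in rois) {
    if (min_distance_to_mask(sl, r$mask) <= r$tol) return(FALSE)
  }
  TRUE
}

#' Endpoint (start/end ROI) test
#'
#' The first point must lie in the start mask and/or the last point in the
#' end mask (nearest-voxel membership, no tolerance). If only the flipped
#' orientation satisfies the configured pair, the test passes with
#' `flip = TRUE` so the caller can orient the streamline from start to end.
#'
#' @param sl streamline matrix.
#' @param start_roi,end_roi `mask_volume`s or NULL (at least one given).
#' @return list(pass = logical, flip = logical).
#' @export
passes_endpoints <- function(sl, start_roi = NULL, end_roi = NULL) {
  if (is.null(start_roi) && is.null(end_roi))
    stop("passes_endpoints: at least one of start/end must be given")
  ok_dir <- function(first, last) {
    (is.null(start_roi) || points_in_mask(first, start_roi)) &&
      (is.null(end_roi) || points_in_mask(last, end_roi))
  }
  n <- nrow(sl)
  if (ok_dir(sl[1, , drop = FALSE], sl[n, , drop = FALSE]))
    return(list(pass = TRUE, flip = FALSE))
  if (ok_dir(sl[n, , drop = FALSE], sl[1, , drop = FALSE]))
    return(list(pass = TRUE, flip = TRUE))
  list(pass = FALSE, flip = FALSE)
}

#' Probability-map test
#'
#' The streamline is resampled to 100 nodes, the map sampled trilinearly at
#' each node, and the mean must be strictly greater than the threshold.
#'
#' @param sl streamline matrix.
#' @param map probability `mask_volume`.
#' @param threshold probability threshold (default 0).
#' @return logical.
#' @export
passes_prob_map <- function(sl, map, threshold = 0) {
  pts <- resample_streamline(sl, 100L)
  mean(sample_volume(map, pts, "trilinear")) > threshold
}

#' Length-range test (inclusive bounds)
#'
#' @param sl streamline matrix.
#' @param min_len,max_len admissible length range, mm.
#' @return logical.
#' @export
passes_length <- function(sl, min_len, max_len) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  len <- streamline_length(sl)
  len >= min_len && len <= max_len
}

#' Primary-axis test
#'
#' @param sl streamline matrix.
#' @param axis one of `"L/R"`, `"P/A"`, `"I/S"`.
#' @param percentage minimum percent of movement along `axis`.
#' @return logical (FALSE for zero-movement streamlines).
#' @export
passes_primary_axis <- function(sl, axis, percentage) {
  frac <- tryCatch(primary_axis_fraction(sl), error = function(e) NULL)
  if (is.null(frac)) return(FALSE)
  frac[[axis]] * 100 >= percentage
}

#' Shape-prior test (reduced RecoBundles criterion)
#'
#' Accepts a streamline whose minimum MDF distance (20 comparison points)
#' to any reference streamline is at most the centroid threshold.
#'
#' @param sl streamline matrix.
#' @param reference list of reference streamlines.
#' @param centroid_threshold mm.
#' @return logical.
#' @export
passes_shape_prior <- function(sl, reference, centroid_threshold) {
  if (!length(reference)) stop("shape prior: empty reference set")
  for (ref in reference) {
    if (mdf_distance(sl, ref, 20L) <= centroid_threshold) return(TRUE)
  }
  FALSE
}

#' Recognize bundles in a tractogram
#'
#' Applies each tract's configured criteria to every streamline in the
#' printed order (prob_map, cross_midline, start, end, length,
#' primary_axis, include, exclude, shape_prior, qb_thresh, mahal), the last
#' two as set-level cleaning of the survivors. Rejections are tallied under
#' the first criterion that failed. A streamline surviving for multiple
#' tracts goes to the first tract in `defs` and a tie warning is recorded.
#'
#' @param tg a `tractogram`.
#' @param defs a `bundle_definitions`.
#' @return an object of class `recognition_result`: list with
#'   `assignments` (character vector, NA for unassigned), `bundles`
#'   (per tract: `indices` into the tractogram and oriented `streamlines`),
#'   `tallies` (per tract, rejection counts in criterion order plus
#'   `accepted`), and `warnings` (character vector).
#' @export
recognize <- function(tg, defs) {
  stopifnot(inherits(tg, "tractogram"), inherits(defs, "bundle_definitions"))
  n_sl <- length(tg$streamlines)
  warnings_out <- character(0)
  if (n_sl == 0L) {
    warnings_out <- "empty tractogram: nothing to recognize"
    return(structure(list(assignments = character(0), bundles = list(),
                          tallies = list(), warnings = warnings_out),
                     class = "recognition_result"))
  }
  survivors <- list()   # tract -> integer indices
  flips <- list()       # tract -> logical flip flags
  tallies <- list()
  for (tract in names(defs)) {
    cr <- defs[[tract]]
    tally <- stats::setNames(integer(length(criterion_order) + 1L),
                             c(criterion_order, "accepted"))
    alive <- seq_len(n_sl)
    flip <- logical(n_sl)
    # per-streamline criteria, printed order
    per_sl <- function(keep_fn, crit) {
      keep <- vapply(alive, keep_fn, logical(1))
      tally[[crit]] <<- tally[[crit]] + sum(!keep)
      alive <<- alive[keep]
    }
    if (!is.null(cr$prob_map))
      per_sl(function(i) passes_prob_map(tg$streamlines[[i]], cr$prob_map$mask,
                                         cr$prob_map$threshold), "prob_map")
    if (!is.null(cr$cross_midline))
      per_sl(function(i) crosses_midline(tg$streamlines[[i]]) == cr$cross_midline,
             "cross_midline")
    if (!is.null(cr$start) || !is.null(cr$end)) {
      res <- lapply(alive, function(i)
        passes_endpoints(tg$streamlines[[i]], cr$start, cr$end))
      keep <- vapply(res, `[[`, logical(1), "pass")
      flip[alive[keep]] <- vapply(res[keep], `[[`, logical(1), "flip")
      crit <- if (!is.null(cr$start)) "start" else "end"
      tally[[crit]] <- tally[[crit]] + sum(!keep)
      alive <- alive[keep]
    }
    if (!is.null(cr$length))
      per_sl(function(i) passes_length(tg$streamlines[[i]],
                                       cr$length$min_len, cr$length$max_len),
             "length")
    if (!is.null(cr$primary_axis))
      per_sl(function(i) passes_primary_axis(tg$streamlines[[i]],
                                             cr$primary_axis$axis,
                                             cr$primary_axis$percentage),
             "primary_axis")
    if (!is.null(cr$include))
      per_sl(function(i) passes_include(tg$streamlines[[i]], cr$include),
             "include")
    if (!is.null(cr$exclude))
      per_sl(function(i) passes_exclude(tg$streamlines[[i]], cr$exclude),
             "exclude")
    if (!is.null(cr$shape_prior))
      per_sl(function(i) passes_shape_prior(tg$streamlines[[i]],
                                            cr$shape_prior$sl,
                                            cr$shape_prior$centroid),
             "shape_prior")
    # set-level cleaning
    if (!is.null(cr$qb_thresh) && length(alive) > 0L) {
      kept <- qb_threshold_clean(tg$streamlines[alive], cr$qb_thresh)
      tally[["qb_thresh"]] <- tally[["qb_thresh"]] + (length(alive) - length(kept))
      alive <- alive[kept]
    }
    if (!is.null(cr$mahal) && length(alive) > 0L) {
      kept <- mahalanobis_clean(tg$streamlines[alive], cr$mahal)
      tally[["mahal"]] <- tally[["mahal"]] + (length(alive) - length(kept))
      alive <- alive[kept]
    }
    tally[["accepted"]] <- length(alive)
    survivors[[tract]] <- alive
    flips[[tract]] <- flip
    tallies[[tract]] <- tally
  }
  # first-wins tie resolution
  assignments <- rep(NA_character_, n_sl)
  for (tract in names(defs)) {
    for (i in survivors[[tract]]) {
      if (is.na(assignments[i])) {
        assignments[i] <- tract
      } else {
        warnings_out <- c(warnings_out,
          sprintf("streamline %d satisfies both '%s' and '%s'; assigned to '%s'",
                  i, assignments[i], tract, assignments[i]))
      }
    }
  }
  bundles <- list()
  for (tract in names(defs)) {
    idx <- survivors[[tract]][assignments[survivors[[tract]]] == tract]
    sls <- lapply(idx, function(i) {
      if (flips[[tract]][i]) flip_streamline(tg$streamlines[[i]])
      else tg$streamlines[[i]]
    })
    bundles[[tract]] <- list(indices = idx, streamlines = sls)
  }
  structure(list(assignments = assignments, bundles = bundles,
                 tallies = tallies, warnings = warnings_out),
            class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  cat(sprintf("recognition result: %d/%d streamlines assigned, %d warning(s)\n",
              sum(!is.na(x$assignments)), length(x$assignments),
              length(x$warnings)))
  for (tract in names(x$bundles))
    cat(sprintf("  %s: %d streamlines\n", tract,
                length(x$bundles[[tract]]$indices)))
  invisible(x)
}
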
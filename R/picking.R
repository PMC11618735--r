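# Multi-threshold peak picking: iterate intensity thresholds from PPmax down
# to PPmin, label 4-connected regions per slice, reduce each region to its
# intensity-weighted center of mass, then merge detections across slices.

#' Build the peak-picking threshold ladder
#'
#' Produces the ordered intensity thresholds the picker iterates, from
#' `pp_max` down to `pp_min` in `steps` slices. Spacing is geometric
#' (log-uniform) by default, because NMR intensities span orders of
#' magnitude; linear spacing is available via the `spacing` config key.
#'
#' @param cfg A [new_config()] object.
#' @return Numeric vector of length `cfg$steps`, strictly decreasing, first
#'   element `pp_max`, last `pp_min`.
#' @export
#' @examples
#' threshold_ladder(new_config(pp_max = 100, pp_min = 1, steps = 3))
threshold_ladder <- function(cfg) {
  cfg <- validate_config(cfg)
  if (cfg$steps == 1) {
    if (cfg$pp_max != cfg$pp_min) {
      warning("steps = 1: only PPmax (", cfg$pp_max, ") is used",
              call. = FALSE)
    }
    return(cfg$pp_max)
  }
  ladder <- if (cfg$spacing == "geometric") {
    exp(seq(log(cfg$pp_max), log(cfg$pp_min), length.out = cfg$steps))
  } else {
    seq(cfg$pp_max, cfg$pp_min, length.out = cfg$steps)
  }
  # pin the endpoints exactly
  ladder[1] <- cfg$pp_max
  ladder[cfg$steps] <- cfg$pp_min
  ladder
}

# 4-connected components of a logical mask; returns an integer label matrix
# (0 = background). Implementation route: igraph over adjacent TRUE cells.
label_regions <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(labels)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  # vertical neighbours (row r, r+1 within a column)
  v_from <- which(mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE])
  # convert back to full-matrix indices: position in (nr-1) x nc block
  v_r <- (v_from - 1L) %% (nr - 1L) + 1L
  v_c <- (v_from - 1L) %/% (nr - 1L) + 1L
  e_v <- cbind(id[cbind(v_r, v_c)], id[cbind(v_r + 1L, v_c)])
  # horizontal neighbours (col c, c+1 within a row)
  h_from <- which(mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE])
  h_r <- (h_from - 1L) %% nr + 1L
  h_c <- (h_from - 1L) %/% nr + 1L
  e_h <- cbind(id[cbind(h_r, h_c)], id[cbind(h_r, h_c + 1L)])
  edges <- rbind(e_v, e_h)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

#' Pick peaks at a single intensity threshold
#'
#' Collects all grid points with intensity at or above `threshold`, groups
#' them into 4-connected regions, and reduces each region to its
#' intensity-weighted center of mass. The region's local maximum is always a
#' member point.
#'
#' @param spec A [new_spectrum2d()] object.
#' @param threshold Positive intensity threshold.
#' @param magnitude If `TRUE`, threshold `abs(intensity)` instead.
#' @return A tibble with one row per region: `cs_direct`, `cs_dq` (ppm
#'   centers of mass), `intensity` (region maximum), `n_points`, and a
#'   `points` list-column of member grid coordinates (matrix with columns
#'   `row`, `col`).
#' @export
pick_slice <- function(spec, threshold, magnitude = FALSE) {
  stopifnot(inherits(spec, "spectrum2d"), threshold > 0)
  z <- if (magnitude) abs(spec$intensity) else spec$intensity
  mask <- z >= threshold
  labels <- label_regions(mask)
  k <- max(labels)
  if (k == 0) {
    return(tibble::tibble(cs_direct = numeric(0), cs_dq = numeric(0),
                          intensity = numeric(0), n_points = integer(0),
                          points = list()))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(mask) + 1L
  cc <- (idx - 1L) %/% nrow(mask) + 1L
  w <- z[idx]
  cs_direct <- vapply(split(seq_along(lab), lab), function(i) {
    sum(spec$direct_ppm[cc[i]] * w[i]) / sum(w[i])
  }, numeric(1))
  cs_dq <- vapply(split(seq_along(lab), lab), function(i) {
    sum(spec$dq_ppm[rr[i]] * w[i]) / sum(w[i])
  }, numeric(1))
  imax <- vapply(split(seq_along(lab), lab), function(i) max(w[i]),
                 numeric(1))
  pts <- lapply(split(seq_along(lab), lab), function(i) {
    cbind(row = rr[i], col = cc[i])
  })
  tibble::tibble(cs_direct = unname(cs_direct), cs_dq = unname(cs_dq),
                 intensity = unname(imax),
                 n_points = vapply(pts, nrow, integer(1), USE.NAMES = FALSE),
                 points = unname(pts))
}

#' Merge per-slice peak detections
#'
#' Groups detections from successive threshold slices by the transitive
#' closure of the proximity relation: two detections belong to the same peak
#' when their centers of mass are within `ppcs` ppm in the direct dimension
#' AND within `ppdq` ppm in the double-quantum dimension. Each group becomes
#' one peak positioned at the center of mass of its highest-threshold
#' (sharpest) detection — ties broken by higher intensity — with intensity
#' equal to the group maximum. Peak ids are assigned in descending intensity
#' order.
#'
#' @param per_slice List of [pick_slice()] tibbles, ordered from the highest
#'   threshold to the lowest.
#' @param ppcs,ppdq Merge tolerances (ppm), direct and DQ dimensions.
#' @param thresholds Optional numeric vector of the slice thresholds (same
#'   length as `per_slice`), recorded as each merged peak's
#'   `slice_threshold`.
#' @return A tibble of merged peaks: `id`, `cs_direct`, `cs_dq`, `intensity`,
#'   `slice_threshold`, `n_slices`, `n_points`, `points`.
#' @export
merge_peaks <- function(per_slice, ppcs, ppdq, thresholds = NULL) {
  stopifnot(is.list(per_slice), ppcs > 0, ppdq > 0)
  if (is.null(thresholds)) thresholds <- rep(NA_real_, length(per_slice))
  all <- dplyr::bind_rows(lapply(seq_along(per_slice), function(s) {
    d <- per_slice[[s]]
    if (nrow(d) == 0) return(NULL)
    d$slice <- s
    d$slice_threshold <- thresholds[s]
    d
  }))
  if (is.null(all) || nrow(all) == 0) {
    return(tibble::tibble(id = integer(0), cs_direct = numeric(0),
                          cs_dq = numeric(0), intensity = numeric(0),
                          slice_threshold = numeric(0),
                          n_slices = integer(0), n_points = integer(0),
                          points = list()))
  }
  n <- nrow(all)
  # proximity graph over detections (both conditions must hold)
  prox <- outer(all$cs_direct, all$cs_direct,
                function(a, b) abs(a - b) <= ppcs) &
          outer(all$cs_dq, all$cs_dq, function(a, b) abs(a - b) <= ppdq)
  g <- igraph::graph_from_adjacency_matrix(prox, mode = "undirected",
                                           diag = FALSE)
  grp <- igraph::components(g)$membership
  merged <- dplyr::bind_rows(lapply(split(seq_len(n), grp), function(i) {
    sub <- all[i, ]
    rep_i <- order(sub$slice, -sub$intensity)[1]
    tibble::tibble(
      cs_direct = sub$cs_direct[rep_i],
      cs_dq = sub$cs_dq[rep_i],
      intensity = max(sub$intensity),
      slice_threshold = sub$slice_threshold[rep_i],
      n_slices = length(unique(sub$slice)),
      n_points = sub$n_points[rep_i],
      points = sub$points[rep_i]
    )
  }))
  merged <- merged[order(-merged$intensity, merged$cs_direct,
                         merged$cs_dq), ]
  merged$id <- seq_len(nrow(merged))
  merged[, c("id", "cs_direct", "cs_dq", "intensity", "slice_threshold",
             "n_slices", "n_points", "points")]
}

#' Pick INADEQUATE peaks with the multi-threshold ladder
#'
#' Runs [pick_slice()] at every rung of [threshold_ladder()] and merges the
#' per-slice detections with [merge_peaks()]. Iterating thresholds from high
#' to low resolves close peaks that a single low threshold would fuse into
#' one region.
#'
#' @param spec A [new_spectrum2d()] INADEQUATE spectrum.
#' @param cfg A [new_config()] object.
#' @return The merged peak tibble (see [merge_peaks()]), with an attribute
#'   `slice_counts`: a tibble of `threshold` and `n_peaks` per slice, used by
#'   the Summary report.
#' @export
#' @examples
#' fx <- fixture_spec(noise_sd = 0)
#' sp <- render_inadequate(fx)
#' peaks <- pick_peaks(sp$spectrum, new_config(pp_max = 100, pp_min = 5,
#'                                             steps = 4))
pick_peaks <- function(spec, cfg) {
  cfg <- validate_config(cfg)
  ladder <- threshold_ladder(cfg)
  per_slice <- lapply(ladder, function(th) {
    pick_slice(spec, th, magnitude = cfg$magnitude_mode)
  })
  peaks <- merge_peaks(per_slice, cfg$ppcs, cfg$ppdq, thresholds = ladder)
  attr(peaks, "slice_counts") <- tibble::tibble(
    threshold = ladder,
    n_peaks = vapply(per_slice, nrow, integer(1))
  )
  peaks
}

#' Write a picked-peak table as TSV
#'
#' @param peaks A [pick_peaks()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_peaks_tsv <- function(peaks, path) {
  readr::write_tsv(peaks[, c("id", "cs_direct", "cs_dq", "intensity")], path)
  invisible(path)
}
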
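# JRES integration: collapse a 2D 13C-JRES spectrum to a multiplet-free 1D
# projection, pick and integrate projection peaks, and transfer the
# INADEQUATE network/compound annotations onto them.

#' Project a 2D JRES spectrum to 1D
#'
#' Skyline projection by default: the maximum over the J dimension (matrix
#' rows) for every chemical-shift column, which collapses multiplets to a
#' single apex per carbon. A sum projection is available. A 1D spectrum is
#' passed through unchanged with a notice.
#'
#' @param spec A [new_spectrum2d()] JRES spectrum (rows = J axis) or a
#'   [new_spectrum1d()] projection.
#' @param method `"max"` (skyline, default) or `"sum"`.
#' @return A `spectrum1d` projection.
#' @export
project_jres <- function(spec, method = c("max", "sum")) {
  method <- match.arg(method)
  if (inherits(spec, "spectrum1d")) {
    message("input is already 1D; returning it unchanged")
    return(spec)
  }
  stopifnot(inherits(spec, "spectrum2d"))
  proj <- if (method == "max") {
    apply(spec$intensity, 2, max)
  } else {
    colSums(spec$intensity)
  }
  new_spectrum1d(spec$direct_ppm, proj)
}

#' Pick peaks on a 1D JRES projection
#'
#' Local maxima whose apex intensity reaches `intensity_threshold_1d`. Each
#' peak is integrated (trapezoid rule) over a window of half-width
#' `peak_width_1d` ppm around the apex, clipped at the axis ends.
#'
#' @param proj A [new_spectrum1d()] projection.
#' @param cfg A [new_config()] supplying `intensity_threshold_1d` and
#'   `peak_width_1d`.
#' @return A tibble: `id`, `cs` (apex ppm), `intensity`, `area`,
#'   `bound_high`, `bound_low` (window edges in ppm).
#' @export
pick_jres_peaks <- function(proj, cfg) {
  cfg <- validate_config(cfg)
  stopifnot(inherits(proj, "spectrum1d"))
  y <- proj$intensity
  n <- length(y)
  if (n < 1) {
    return(tibble::tibble(id = integer(0), cs = numeric(0),
                          intensity = numeric(0), area = numeric(0),
                          bound_high = numeric(0), bound_low = numeric(0)))
  }
  left <- c(-Inf, y[-n]); right <- c(y[-1], -Inf)
  apex <- which(y >= left & y > right & y >= cfg$intensity_threshold_1d)
  if (length(apex) == 0) {
    return(tibble::tibble(id = integer(0), cs = numeric(0),
                          intensity = numeric(0), area = numeric(0),
                          bound_high = numeric(0), bound_low = numeric(0)))
  }
  w <- cfg$peak_width_1d
  eps <- 1e-9
  res <- lapply(apex, function(i) {
    cs <- proj$ppm[i]
    hi <- min(cs + w, max(proj$ppm))
    lo <- max(cs - w, min(proj$ppm))
    sel <- which(proj$ppm <= hi + eps & proj$ppm >= lo - eps)
    # integrate on an ascending ppm grid
    ord <- order(proj$ppm[sel])
    area <- if (length(sel) >= 2) {
      pracma::trapz(proj$ppm[sel][ord], y[sel][ord])
    } else 0
    tibble::tibble(cs = cs, intensity = y[i], area = area,
                   bound_high = hi, bound_low = lo)
  })
  out <- dplyr::bind_rows(res)
  out <- out[order(-out$intensity, out$cs), ]
  out$id <- seq_len(nrow(out))
  out[, c("id", "cs", "intensity", "area", "bound_high", "bound_low")]
}

#' Transfer INADEQUATE annotations to JRES peaks
#'
#' Assigns each network peak its nearest JRES projection peak within
#' `tolerance` ppm of the direct shift (or flags it absent). A network "has
#' JRES peaks" when at least one of its peaks is assigned. Compound names
#' from the network's database matches are propagated; unknown networks keep
#' their backbone shift signature.
#'
#' @param networks An [link_networks()] object.
#' @param match_result A [match_all()] result (list with `matches`,
#'   `unmatched`).
#' @param jres_peaks A [pick_jres_peaks()] tibble.
#' @param tolerance ppm tolerance for the INADEQUATE-to-JRES match (the
#'   `jres_match_tolerance` config key; defaults to PPCS).
#' @return A tibble, one row per network peak: `network_id`, `peak_id`,
#'   `cs_direct`, `jres_id`, `jres_cs`, `jres_intensity`, `jres_area`,
#'   `present`, `compounds` (comma-joined names, or the unknown signature).
#'   Attribute `network_presence` summarizes presence per network.
#' @export
transfer_annotations <- function(networks, match_result, jres_peaks,
                                 tolerance) {
  stopifnot(inherits(networks, "inadnet_networks"), tolerance > 0)
  np <- networks$peaks
  if (nrow(np) == 0) {
    out <- tibble::tibble(network_id = integer(0), peak_id = integer(0),
                          cs_direct = numeric(0), jres_id = integer(0),
                          jres_cs = numeric(0), jres_intensity = numeric(0),
                          jres_area = numeric(0), present = logical(0),
                          compounds = character(0))
    attr(out, "network_presence") <-
      tibble::tibble(network_id = integer(0), present = logical(0))
    return(out)
  }
  # per-network compound label
  label <- stats::setNames(rep(NA_character_,
                               length(unique(np$network_id))),
                           sort(unique(np$network_id)))
  if (nrow(match_result$matches) > 0) {
    by_net <- split(match_result$matches$name,
                    match_result$matches$network_id)
    for (nm in names(by_net)) {
      label[nm] <- paste(sort(unique(by_net[[nm]])), collapse = ",")
    }
  }
  if (nrow(match_result$unmatched) > 0) {
    for (k in seq_len(nrow(match_result$unmatched))) {
      label[as.character(match_result$unmatched$network_id[k])] <-
        match_result$unmatched$signature[k]
    }
  }
  if (nrow(jres_peaks) > 0) {
    dist <- abs(outer(np$cs_direct, jres_peaks$cs, `-`))
    nearest <- apply(dist, 1, which.min)
    dmin <- dist[cbind(seq_len(nrow(np)), nearest)]
    hit <- dmin <= tolerance
  } else {
    nearest <- rep(NA_integer_, nrow(np))
    hit <- rep(FALSE, nrow(np))
  }
  out <- tibble::tibble(
    network_id = np$network_id,
    peak_id = np$peak_id,
    cs_direct = np$cs_direct,
    jres_id = ifelse(hit, jres_peaks$id[nearest], NA_integer_),
    jres_cs = ifelse(hit, jres_peaks$cs[nearest], NA_real_),
    jres_intensity = ifelse(hit, jres_peaks$intensity[nearest], NA_real_),
    jres_area = ifelse(hit, jres_peaks$area[nearest], NA_real_),
    present = hit,
    compounds = unname(label[as.character(np$network_id)])
  )
  out <- out[order(out$network_id, out$peak_id), ]
  pres <- dplyr::summarise(dplyr::group_by(out, .data$network_id),
                           present = any(.data$present), .groups = "drop")
  attr(out, "network_presence") <- pres
  out
}
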
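# Forward simulator: renders INADEQUATE and JRES spectra from toy compound
# libraries with known ground truth, so every pipeline stage can be scored
# without any external data. Peaks are rendered as positive 2D line shapes
# (no antiphase fine structure): the pipeline consumes magnitude-like
# processed spectra.

#' Default toy compound library
#'
#' Three small metabolite-like compounds covering the structural cases the
#' pipeline must handle: a 2-carbon amino-sulfonic-acid-like compound
#' (single bond), a 3-carbon organic-acid-like chain (shared middle carbon,
#' so two horizontal pairs link vertically), and a branched 5-carbon
#' amino-acid-like compound with one ambiguous methyl pair (two alternative
#' shifts on each methyl, ambiguity score 0.4).
#'
#' @return A list of compound definitions (`name`, `entry_id`, `carbons`,
#'   `bonds`).
#' @export
toy_library <- function() {
  list(
    list(name = "taurine-like", entry_id = "fx0001",
         carbons = list(C1 = 36.4, C2 = 48.2),
         bonds = rbind(c("C1", "C2"))),
    list(name = "lactic-acid-like", entry_id = "fx0002",
         carbons = list(C1 = 183.4, C2 = 69.2, C3 = 21.0),
         bonds = rbind(c("C1", "C2"), c("C2", "C3"))),
    list(name = "valine-like", entry_id = "fx0003",
         carbons = list(C1 = 177.0, C2 = 61.2, C3 = 29.9,
                        C4 = c(17.5, 17.7), C5 = c(18.8, 19.0)),
         bonds = rbind(c("C1", "C2"), c("C2", "C3"),
                       c("C3", "C4"), c("C3", "C5")))
  )
}

#' Define a synthetic-spectrum fixture
#'
#' @param compounds List of compound definitions (default [toy_library()]).
#' @param intensities Per-compound peak amplitude (recycled).
#' @param lineshape List: `shape` (`"gaussian"` or `"lorentzian"`),
#'   `width_direct`, `width_dq`, `width_jres` — half-width-like scale
#'   parameters in ppm (Gaussian sigma / Lorentzian gamma).
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units).
#' @param axes List of grid definitions `c(min_ppm, max_ppm, n_points)` for
#'   `direct`, `dq` and `jres` axes.
#' @param seed Integer seed; the same seed reproduces spectra bit-for-bit.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(compounds = toy_library(),
                         intensities = 100,
                         lineshape = list(shape = "gaussian",
                                          width_direct = 0.12,
                                          width_dq = 0.25,
                                          width_jres = 0.1),
                         noise_sd = 0,
                         axes = list(direct = c(5, 195, 1540),
                                     dq = c(10, 390, 1540),
                                     jres = c(5, 195, 1540)),
                         seed = 1L) {
  stopifnot(noise_sd >= 0, lineshape$width_direct > 0,
            lineshape$width_dq > 0)
  fx <- list(compounds = compounds,
             intensities = rep_len(intensities, length(compounds)),
             lineshape = lineshape, noise_sd = noise_sd, axes = axes,
             seed = as.integer(seed))
  class(fx) <- "fixture_spec"
  fx
}

axis_grid <- function(def) {
  # stored high -> low ppm, matching the spectrum convention
  seq(def[2], def[1], length.out = def[3])
}

# evaluate the 1D profile of the chosen line shape
line_profile <- function(x, center, width, shape) {
  if (shape == "lorentzian") {
    width^2 / ((x - center)^2 + width^2)
  } else {
    exp(-(x - center)^2 / (2 * width^2))
  }
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_fixture_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ground-truth peak table for a fixture: one row per (bond, carbon), using
# each carbon's first assigned shift (the rendered alternative)
fixture_truth <- function(fx) {
  rows <- list()
  for (k in seq_along(fx$compounds)) {
    cmp <- fx$compounds[[k]]
    first_shift <- vapply(cmp$carbons, function(s) as.numeric(s[1]),
                          numeric(1))
    bonds <- as.matrix(cmp$bonds)
    storage.mode(bonds) <- "character"
    for (b in seq_len(nrow(bonds))) {
      a <- bonds[b, 1]; z <- bonds[b, 2]
      dq <- first_shift[[a]] + first_shift[[z]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        compound = cmp$name, entry_id = cmp$entry_id,
        bond = paste(a, z, sep = "-"),
        carbon = c(a, z),
        cs_direct = c(first_shift[[a]], first_shift[[z]]),
        cs_dq = dq,
        intensity = fx$intensities[k]
      )
    }
  }
  truth <- dplyr::bind_rows(rows)
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(compound = character(0), entry_id = character(0),
                            bond = character(0), carbon = character(0),
                            cs_direct = numeric(0), cs_dq = numeric(0),
                            intensity = numeric(0))
  }
  truth$peak <- seq_len(nrow(truth))
  truth
}

#' Render a synthetic 2D INADEQUATE spectrum
#'
#' Places, for every compound bond (a, b), two line shapes at
#' (shift_a, shift_a + shift_b) and (shift_b, shift_a + shift_b) — using
#' each carbon's first assigned shift — then adds seeded Gaussian noise.
#'
#' @param fx A [fixture_spec()].
#' @return A list: `spectrum` ([new_spectrum2d()]), `truth` (tibble of true
#'   peaks with their bond and compound), `truth_pairs` (one row per bond),
#'   `truth_networks` (compound-level partition: `entry_id`, `n_peaks`).
#' @export
#' @examples
#' sp <- render_inadequate(fixture_spec(noise_sd = 0))
#' dim(sp$spectrum$intensity)
render_inadequate <- function(fx) {
  stopifnot(inherits(fx, "fixture_spec"))
  direct <- axis_grid(fx$axes$direct)
  dq <- axis_grid(fx$axes$dq)
  truth <- fixture_truth(fx)
  out_of_grid <- truth$cs_direct > max(direct) |
    truth$cs_direct < min(direct) |
    truth$cs_dq > max(dq) | truth$cs_dq < min(dq)
  if (any(out_of_grid)) {
    stop("generation error: peak outside grid for compound(s): ",
         paste(unique(truth$compound[out_of_grid]), collapse = ", "),
         call. = FALSE)
  }
  z <- matrix(0, nrow = length(dq), ncol = length(direct))
  for (i in seq_len(nrow(truth))) {
    z <- z + truth$intensity[i] *
      outer(line_profile(dq, truth$cs_dq[i], fx$lineshape$width_dq,
                         fx$lineshape$shape),
            line_profile(direct, truth$cs_direct[i],
                         fx$lineshape$width_direct, fx$lineshape$shape))
  }
  if (fx$noise_sd > 0) {
    z <- z + with_fixture_seed(fx$seed,
      matrix(stats::rnorm(length(z), sd = fx$noise_sd),
             nrow = nrow(z)))
  }
  if (nrow(truth) > 0) {
    truth_pairs <- dplyr::summarise(
      dplyr::group_by(truth, .data$entry_id, .data$bond),
      cs_direct_left = min(.data$cs_direct),
      cs_direct_right = max(.data$cs_direct),
      dq_value = .data$cs_dq[1], .groups = "drop")
    truth_networks <- dplyr::summarise(
      dplyr::group_by(truth, .data$entry_id),
      n_peaks = dplyr::n(), .groups = "drop")
  } else {
    truth_pairs <- tibble::tibble(entry_id = character(0),
                                  bond = character(0),
                                  cs_direct_left = numeric(0),
                                  cs_direct_right = numeric(0),
                                  dq_value = numeric(0))
    truth_networks <- tibble::tibble(entry_id = character(0),
                                     n_peaks = integer(0))
  }
  list(spectrum = new_spectrum2d(direct, dq, z), truth = truth,
       truth_pairs = truth_pairs, truth_networks = truth_networks)
}

#' Render a synthetic JRES spectrum
#'
#' In 1D mode, one singlet per carbon at its (first assigned) shift on the
#' JRES axis. In 2D mode, each carbon is split into a doublet along the J
#' axis; the components collapse to a singlet under the skyline projection.
#'
#' @param fx A [fixture_spec()].
#' @param mode `"1d"` (default) or `"2d"`.
#' @param j_split Doublet half-splitting along the J axis (ppm-equivalent
#'   units of the J grid), 2D mode only.
#' @return A list: `spectrum` (`spectrum1d` or `spectrum2d`) and `truth`
#'   (tibble of carbon shifts and amplitudes).
#' @export
render_jres <- function(fx, mode = c("1d", "2d"), j_split = 0.12) {
  stopifnot(inherits(fx, "fixture_spec"))
  mode <- match.arg(mode)
  ppm <- axis_grid(fx$axes$jres)
  rows <- list()
  for (k in seq_along(fx$compounds)) {
    cmp <- fx$compounds[[k]]
    first_shift <- vapply(cmp$carbons, function(s) as.numeric(s[1]),
                          numeric(1))
    rows[[length(rows) + 1]] <- tibble::tibble(
      compound = cmp$name, entry_id = cmp$entry_id,
      carbon = names(first_shift), cs = unname(first_shift),
      intensity = fx$intensities[k])
  }
  truth <- dplyr::bind_rows(rows)
  oob <- truth$cs > max(ppm) | truth$cs < min(ppm)
  if (any(oob)) {
    stop("generation error: peak outside grid for compound(s): ",
         paste(unique(truth$compound[oob]), collapse = ", "),
         call. = FALSE)
  }
  w <- if (is.null(fx$lineshape$width_jres)) 0.15 else
    fx$lineshape$width_jres
  if (mode == "1d") {
    y <- rep(0, length(ppm))
    for (i in seq_len(nrow(truth))) {
      y <- y + truth$intensity[i] *
        line_profile(ppm, truth$cs[i], w, fx$lineshape$shape)
    }
    if (fx$noise_sd > 0) {
      y <- y + with_fixture_seed(fx$seed + 1L,
                                 stats::rnorm(length(y),
                                              sd = fx$noise_sd))
    }
    return(list(spectrum = new_spectrum1d(ppm, y), truth = truth))
  }
  j_axis <- seq(0.5, -0.5, length.out = 33)
  z <- matrix(0, nrow = length(j_axis), ncol = length(ppm))
  for (i in seq_len(nrow(truth))) {
    shift_prof <- line_profile(ppm, truth$cs[i], w, fx$lineshape$shape)
    j_prof <- line_profile(j_axis, j_split, w / 2, fx$lineshape$shape) +
      line_profile(j_axis, -j_split, w / 2, fx$lineshape$shape)
    z <- z + truth$intensity[i] * outer(j_prof, shift_prof)
  }
  if (fx$noise_sd > 0) {
    z <- z + with_fixture_seed(fx$seed + 1L,
      matrix(stats::rnorm(length(z), sd = fx$noise_sd), nrow = nrow(z)))
  }
  list(spectrum = new_spectrum2d(ppm, j_axis, z), truth = truth)
}

#' Write a fixture's compounds as a database file
#'
#' Emits the fixture's compound definitions through [build_database()] and
#' [write_database()], closing the simulate -> pick -> network -> match loop
#' in tests.
#'
#' @param fx A [fixture_spec()].
#' @param path Output JSON path.
#' @return The `inadnet_db`, invisibly; `path` is written.
#' @export
write_fixture_db <- function(fx, path) {
  db <- build_database(fx$compounds)
  write_database(db, path)
  invisible(db)
}
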
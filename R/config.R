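# Configuration: the single flat key=value file that drives every stage.

# canonical key names as they appear in config files, mapped to internal names
.config_keys <- c(
  ppmax                  = "pp_max",
  ppmin                  = "pp_min",
  steps                  = "steps",
  ppcs                   = "ppcs",
  ppdq                   = "ppdq",
  dqt                    = "dqt",
  sumxy                  = "sum_xy",
  sdt                    = "sdt",
  cst                    = "cst",
  csmt                   = "csmt",
  ncmt                   = "ncmt",
  dqmt                   = "dqmt",
  ambiguity              = "ambiguity",
  peak_width_1d          = "peak_width_1d",
  intensity_threshold_1d = "intensity_threshold_1d"
)

# optional keys with their defaults; jres_match_tolerance defaults to ppcs at
# validation time (NA marks "inherit")
.config_optional <- list(
  spacing              = "geometric",
  projection           = "max",
  magnitude_mode       = FALSE,
  jres_match_tolerance = NA_real_
)

#' Construct a pipeline configuration
#'
#' Builds the parameter set that controls every pipeline stage: the
#' peak-picking threshold ladder (`pp_max`, `pp_min`, `steps`), peak-merging
#' tolerances (`ppcs`, `ppdq`), the three horizontal-pair rules (`dqt`,
#' `sum_xy`, `sdt`), vertical linking (`cst`), database matching (`csmt`,
#' `ncmt`, `dqmt`, `ambiguity`) and JRES integration (`peak_width_1d`,
#' `intensity_threshold_1d`). All chemical-shift tolerances are in ppm;
#' intensities are in raw spectrum units.
#'
#' @param pp_max,pp_min Highest and lowest peak-picking intensity thresholds.
#' @param steps Number of threshold slices between `pp_max` and `pp_min`.
#' @param ppcs,ppdq Peak-merging tolerances (ppm) in the direct and
#'   double-quantum dimensions.
#' @param dqt Maximum double-quantum shift difference (ppm) for a horizontal
#'   pair.
#' @param sum_xy Maximum residual (ppm) between the sum of a pair's direct
#'   shifts and their mean double-quantum shift.
#' @param sdt Maximum difference (ppm) of the two peaks' absolute distances
#'   from the Y = 2X diagonal.
#' @param cst Maximum direct-dimension difference (ppm) for a vertical link.
#' @param csmt Direct-dimension tolerance (ppm) for matching a sample peak to
#'   a database peak.
#' @param ncmt Minimum number of matched sample peaks for a candidate
#'   compound to be retained (at least this many).
#' @param dqmt Double-quantum tolerance (ppm) for match confirmation.
#' @param ambiguity Maximum database-compound ambiguity score kept, in
#'   `[0, 1]`.
#' @param peak_width_1d Half-width (ppm) of the JRES 1D integration window.
#' @param intensity_threshold_1d Minimum apex intensity for a JRES
#'   projection peak.
#' @param spacing Threshold-ladder spacing, `"geometric"` (default) or
#'   `"linear"`.
#' @param projection JRES projection operator, `"max"` (skyline, default) or
#'   `"sum"`.
#' @param magnitude_mode If `TRUE`, pick peaks on `abs(intensity)`.
#' @param jres_match_tolerance ppm tolerance for transferring network
#'   annotations to JRES peaks; defaults to `ppcs`.
#'
#' @return A validated `inadnet_config` list.
#' @seealso [load_config()] to read the same parameters from a file.
#' @export
#' @examples
#' cfg <- new_config(pp_max = 100, pp_min = 5, steps = 4)
#' cfg$csmt
new_config <- function(pp_max = 100, pp_min = 5, steps = 8,
                       ppcs = 0.4, ppdq = 1.0,
                       dqt = 0.5, sum_xy = 0.5, sdt = 0.5, cst = 0.25,
                       csmt = 0.3, ncmt = 2, dqmt = 0.6, ambiguity = 1,
                       peak_width_1d = 0.3, intensity_threshold_1d = 1,
                       spacing = c("geometric", "linear"),
                       projection = c("max", "sum"),
                       magnitude_mode = FALSE,
                       jres_match_tolerance = NULL) {
  cfg <- list(
    pp_max = pp_max, pp_min = pp_min, steps = steps,
    ppcs = ppcs, ppdq = ppdq, dqt = dqt, sum_xy = sum_xy, sdt = sdt,
    cst = cst, csmt = csmt, ncmt = ncmt, dqmt = dqmt, ambiguity = ambiguity,
    peak_width_1d = peak_width_1d,
    intensity_threshold_1d = intensity_threshold_1d,
    spacing = match.arg(spacing), projection = match.arg(projection),
    magnitude_mode = isTRUE(magnitude_mode),
    jres_match_tolerance =
      if (is.null(jres_match_tolerance)) ppcs else jres_match_tolerance
  )
  validate_config(cfg)
}

#' Read a pipeline configuration file
#'
#' Parses a flat `key = value` text file (sections in `[brackets]` and
#' `#`/`;` comments are permitted and ignored). Keys are case-insensitive and
#' match the standard parameter names `PPmax`, `PPmin`, `steps`, `PPCS`,
#' `PPDQ`, `DQT`, `SumXY`, `SDT`, `CST`, `CSMT`, `NCMT`, `DQMT`,
#' `Ambiguity`, `Peak_Width_1D`, `Intensity_threshold_1D`. All fifteen are
#' required; optional keys (`spacing`, `projection`, `magnitude_mode`,
#' `jres_match_tolerance`) take documented defaults.
#'
#' @param path Path to the configuration file.
#' @param verbose If `TRUE`, echo every parameter to the console (the run
#'   log); [run_pipeline()] echoes them to `run.log` regardless.
#' @return A validated `inadnet_config` list.
#' @export
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' writeLines(c("PPmax = 100", "PPmin = 5", "steps = 4", "PPCS = 0.4",
#'              "PPDQ = 1", "DQT = 0.5", "SumXY = 0.5", "SDT = 0.5",
#'              "CST = 0.25", "CSMT = 0.3", "NCMT = 2", "DQMT = 0.6",
#'              "Ambiguity = 1", "Peak_Width_1D = 0.3",
#'              "Intensity_threshold_1D = 1"), f)
#' cfg <- load_config(f)
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[.*\\]$", lines)]

  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2
  if (any(bad)) {
    stop("configuration parse error: expected 'key = value' but got: ",
         lines[bad][1], call. = FALSE)
  }
  keys <- tolower(trimws(vapply(kv, `[[`, character(1), 1)))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))

  cfg <- .config_optional
  seen <- character(0)
  for (i in seq_along(keys)) {
    key <- keys[i]
    if (key %in% names(.config_keys)) {
      num <- suppressWarnings(as.numeric(vals[i]))
      if (is.na(num)) {
        stop("configuration parse error: non-numeric value for key '",
             key, "': ", vals[i], call. = FALSE)
      }
      cfg[[.config_keys[[key]]]] <- num
      seen <- c(seen, .config_keys[[key]])
    } else if (key %in% c("spacing", "projection")) {
      cfg[[key]] <- tolower(vals[i])
    } else if (key == "magnitude_mode") {
      cfg[[key]] <- tolower(vals[i]) %in% c("true", "1", "yes")
    } else if (key == "jres_match_tolerance") {
      cfg[[key]] <- suppressWarnings(as.numeric(vals[i]))
    } else {
      warning("unknown configuration key ignored: ", key, call. = FALSE)
    }
  }

  missing <- setdiff(unname(.config_keys), seen)
  if (length(missing) > 0) {
    # report using the canonical file-facing name
    canon <- names(.config_keys)[match(missing, .config_keys)]
    pretty <- c(ppmax = "PPmax", ppmin = "PPmin", steps = "steps",
                ppcs = "PPCS", ppdq = "PPDQ", dqt = "DQT", sumxy = "SumXY",
                sdt = "SDT", cst = "CST", csmt = "CSMT", ncmt = "NCMT",
                dqmt = "DQMT", ambiguity = "Ambiguity",
                peak_width_1d = "Peak_Width_1D",
                intensity_threshold_1d = "Intensity_threshold_1D")[canon]
    stop("configuration error: missing required key(s): ",
         paste(pretty, collapse = ", "), call. = FALSE)
  }
  if (is.na(cfg$jres_match_tolerance)) cfg$jres_match_tolerance <- cfg$ppcs
  cfg$steps <- as.integer(cfg$steps)
  cfg$ncmt <- as.integer(cfg$ncmt)
  cfg <- validate_config(cfg)
  if (verbose) {
    for (nm in names(cfg)) message("config: ", nm, " = ", cfg[[nm]])
  }
  cfg
}

#' Validate a configuration
#'
#' Checks the parameter invariants: `pp_max > pp_min > 0`, `steps >= 1`,
#' every ppm tolerance strictly positive, `ncmt >= 1`, ambiguity threshold
#' in `[0, 1]`.
#'
#' @param cfg A configuration list.
#' @return The validated `inadnet_config` (invisibly classed).
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num_fields <- unname(.config_keys)
  for (f in num_fields) {
    if (is.null(cfg[[f]]) || !is.numeric(cfg[[f]]) || !is.finite(cfg[[f]])) {
      stop("configuration error: '", f, "' missing or non-numeric",
           call. = FALSE)
    }
  }
  if (!(cfg$pp_max > cfg$pp_min) || !(cfg$pp_min > 0)) {
    stop("configuration error: require PPmax > PPmin > 0 (got PPmax = ",
         cfg$pp_max, ", PPmin = ", cfg$pp_min, ")", call. = FALSE)
  }
  if (cfg$steps < 1) {
    stop("configuration error: steps must be >= 1", call. = FALSE)
  }
  tols <- c("ppcs", "ppdq", "dqt", "sum_xy", "sdt", "cst", "csmt", "dqmt",
            "peak_width_1d", "jres_match_tolerance")
  for (f in tols) {
    if (cfg[[f]] <= 0) {
      stop("configuration error: tolerance '", f, "' must be > 0",
           call. = FALSE)
    }
  }
  if (cfg$ncmt < 1) {
    stop("configuration error: NCMT must be >= 1", call. = FALSE)
  }
  if (cfg$ambiguity < 0 || cfg$ambiguity > 1) {
    stop("configuration error: Ambiguity must lie in [0, 1]", call. = FALSE)
  }
  if (!cfg$spacing %in% c("geometric", "linear")) {
    stop("configuration error: spacing must be 'geometric' or 'linear'",
         call. = FALSE)
  }
  if (!cfg$projection %in% c("max", "sum")) {
    stop("configuration error: projection must be 'max' or 'sum'",
         call. = FALSE)
  }
  structure(cfg, class = "inadnet_config")
}

#' @export
print.inadnet_config <- function(x, ...) {
  cat("<inadnet_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# serialize a config back to the flat key=value format (used by reports)
config_lines <- function(cfg) {
  pretty <- c(pp_max = "PPmax", pp_min = "PPmin", steps = "steps",
              ppcs = "PPCS", ppdq = "PPDQ", dqt = "DQT", sum_xy = "SumXY",
              sdt = "SDT", cst = "CST", csmt = "CSMT", ncmt = "NCMT",
              dqmt = "DQMT", ambiguity = "Ambiguity",
              peak_width_1d = "Peak_Width_1D",
              intensity_threshold_1d = "Intensity_threshold_1D",
              spacing = "spacing", projection = "projection",
              magnitude_mode = "magnitude_mode",
              jres_match_tolerance = "jres_match_tolerance")
  vapply(names(pretty), function(f) {
    paste0(pretty[[f]], " = ", format(cfg[[f]], digits = 15))
  }, character(1))
}
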
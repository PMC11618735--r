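# Pipeline orchestration: stage-wise execution (load -> pick -> network ->
# match -> jres) with checkpoints after every stage, so any step can resume
# from the previous checkpoint with results identical to a monolithic run.

.stages <- c(load = "loaded", pick = "picked", network = "networked",
             match = "matched", jres = "jres_matched")
.stage_prereq <- c(pick = "load", network = "pick", match = "network",
                   jres = "match")

new_pipeline_state <- function(config) {
  structure(list(config = config, stage = NA_character_, payloads = list()),
            class = "pipeline_state")
}

#' @export
print.pipeline_state <- function(x, ...) {
  cat(sprintf("<pipeline_state> stage: %s; payloads: %s\n", x$stage,
              paste(names(x$payloads), collapse = ", ")))
  invisible(x)
}

#' Save / load pipeline state
#'
#' Checkpoints are versioned serialized containers; `load_state(save_state(x))`
#' reproduces `x` exactly (including the configuration), so any stage can
#' resume from the previous stage's checkpoint.
#'
#' @param state A `pipeline_state` object.
#' @param path Checkpoint file path.
#' @return `save_state` returns `path` invisibly; `load_state` returns the
#'   `pipeline_state`.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "pipeline_state"))
  saveRDS(list(format = "inadnet-state", version = 1L, state = state),
          path, version = 3)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  if (!file.exists(path)) {
    stop("integrity error: checkpoint not found: ", path, call. = FALSE)
  }
  doc <- tryCatch(readRDS(path), error = function(e) {
    stop("integrity error: cannot read checkpoint ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(doc) || !identical(doc$format, "inadnet-state") ||
      !inherits(doc$state, "pipeline_state")) {
    stop("integrity error: not an inadnet checkpoint: ", path,
         call. = FALSE)
  }
  doc$state
}

checkpoint_path <- function(outdir, step) {
  file.path(outdir, paste0("checkpoint_", step, ".rds"))
}

#' Run the annotation pipeline
#'
#' Executes the selected stages in order `load`, `pick`, `network`, `match`,
#' `jres`, writing a checkpoint after each stage and the report files at the
#' end. With `steps = "all"`, every stage runs (the JRES stage only when a
#' JRES input is given). A single later step resumes from the previous
#' stage's checkpoint in `outdir` and produces results identical to a
#' monolithic run.
#'
#' @param config Path to a configuration file or a [new_config()] object.
#' @param inadequate Path to the 2D INADEQUATE spectrum (text dialect or
#'   NMRPipe), or a `spectrum2d`. Required for the `load` step.
#' @param jres Optional path to a JRES spectrum (2D or 1D projection, text
#'   dialect) or a spectrum object; when absent the JRES stage is skipped.
#' @param db Path to a database JSON file or an `inadnet_db`. Required for
#'   the `match` step.
#' @param outdir Output directory (created if needed); holds checkpoints,
#'   reports and `run.log`.
#' @param steps Character vector of stages, or `"all"`.
#' @param dialect Spectrum dialect passed to [read_spectrum_2d()].
#' @return `outdir`, invisibly. Reports: `Summary.txt`, `Peaks.tsv`,
#'   `Networks.tsv`, `Matches.tsv`, `MatchJres.tsv` (when the JRES stage
#'   ran), plus `config_used.cfg`.
#' @export
run_pipeline <- function(config, inadequate = NULL, jres = NULL, db = NULL,
                         outdir, steps = "all", dialect = "auto") {
  cfg <- if (inherits(config, "inadnet_config")) config
         else load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (identical(steps, "all")) {
    steps <- c("load", "pick", "network", "match")
    if (!is.null(jres)) steps <- c(steps, "jres")
  }
  bad <- setdiff(steps, names(.stages))
  if (length(bad) > 0) {
    stop("unknown step(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(names(.stages), collapse = "|"), ")",
         call. = FALSE)
  }
  steps <- names(.stages)[names(.stages) %in% steps]  # canonical order

  state <- NULL
  if (!"load" %in% steps) {
    prereq <- .stage_prereq[[steps[1]]]
    cp <- checkpoint_path(outdir, prereq)
    if (!file.exists(cp)) {
      stop("step '", steps[1], "' requires a checkpoint from stage '",
           prereq, "' (", cp, "); run that stage first", call. = FALSE)
    }
    state <- load_state(cp)
  }

  for (step in steps) {
    state <- switch(step,
      load = {
        if (is.null(inadequate)) {
          stop("input error: the load step needs an INADEQUATE spectrum",
               call. = FALSE)
        }
        spec <- if (inherits(inadequate, "spectrum2d")) inadequate
                else read_spectrum_2d(inadequate, dialect)
        st <- new_pipeline_state(cfg)
        st$payloads$spectrum <- spec
        st$stage <- "loaded"
        st
      },
      pick = {
        peaks <- pick_peaks(state$payloads$spectrum, state$config)
        state$payloads$peaks <- peaks
        state$payloads$slice_counts <- attr(peaks, "slice_counts")
        state$stage <- "picked"
        state
      },
      network = {
        pairs <- find_horizontal_pairs(state$payloads$peaks, state$config)
        nets <- link_networks(pairs, state$config$cst,
                              peaks = state$payloads$peaks)
        state$payloads$pairs <- pairs
        state$payloads$networks <- nets
        state$stage <- "networked"
        state
      },
      match = {
        if (is.null(db)) {
          stop("input error: the match step needs a compound database",
               call. = FALSE)
        }
        dbase <- if (inherits(db, "inadnet_db")) db else read_database(db)
        res <- match_all(state$payloads$networks, dbase, state$config)
        state$payloads$matches <- res$matches
        state$payloads$unmatched <- res$unmatched
        state$stage <- "matched"
        state
      },
      jres = {
        if (is.null(jres)) {
          stop("input error: the jres step needs a JRES spectrum",
               call. = FALSE)
        }
        spec <- if (inherits(jres, "spectrum1d") ||
                    inherits(jres, "spectrum2d")) jres
                else {
                  first <- readLines(jres, n = 1, warn = FALSE)
                  if (grepl("^#inadnet-spectrum 1", first)) {
                    read_spectrum_1d(jres)
                  } else {
                    read_spectrum_2d(jres, dialect)
                  }
                }
        proj <- if (inherits(spec, "spectrum1d")) spec
                else project_jres(spec, method = state$config$projection)
        jp <- pick_jres_peaks(proj, state$config)
        assign_tbl <- transfer_annotations(
          state$payloads$networks,
          list(matches = state$payloads$matches,
               unmatched = state$payloads$unmatched),
          jp, state$config$jres_match_tolerance)
        state$payloads$jres_projection <- proj
        state$payloads$jres_peaks <- jp
        state$payloads$jres_assignments <- assign_tbl
        state$payloads$jres_presence <- attr(assign_tbl, "network_presence")
        state$stage <- "jres_matched"
        state
      }
    )
    save_state(state, checkpoint_path(outdir, step))
  }

  write_reports(state, outdir)
  log_path <- file.path(outdir, "run.log")
  cat(c(paste("run completed:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
        paste("steps:", paste(steps, collapse = ",")),
        paste("inadnet version:",
              as.character(utils::packageVersion("inadnet"))),
        config_lines(state$config)),
      file = log_path, sep = "\n", append = TRUE)
  invisible(outdir)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE,
                                scientific = FALSE))
}

#' Write the report files for a pipeline state
#'
#' Emits the reports for every completed stage: `Summary.txt` (per-stage
#' counts and the full configuration echo), `Peaks.tsv`, `Networks.tsv`,
#' `Matches.tsv` and `MatchJres.tsv`, plus `config_used.cfg`. Output is a
#' pure function of the state: re-running on the same inputs is
#' byte-identical (timestamps live in `run.log`, not in reports).
#'
#' @param state A `pipeline_state`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(state, outdir) {
  stopifnot(inherits(state, "pipeline_state"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- state$payloads

  writeLines(config_lines(state$config),
             file.path(outdir, "config_used.cfg"))

  lines <- c("inadnet Summary",
             paste0("version: ",
                    as.character(utils::packageVersion("inadnet"))),
             "", "## configuration", config_lines(state$config))
  if (!is.null(p$spectrum)) {
    lines <- c(lines, "", "## input",
               sprintf("spectrum: %d x %d points",
                       nrow(p$spectrum$intensity),
                       ncol(p$spectrum$intensity)))
  }
  if (!is.null(p$slice_counts)) {
    lines <- c(lines, "", "## peak picking",
               sprintf("slice %d (threshold = %s): %d peaks",
                       seq_len(nrow(p$slice_counts)),
                       fmt_num(p$slice_counts$threshold),
                       p$slice_counts$n_peaks),
               sprintf("merged peaks: %d", nrow(p$peaks)))
    readr::write_tsv(p$peaks[, c("id", "cs_direct", "cs_dq", "intensity",
                                 "slice_threshold", "n_slices")],
                     file.path(outdir, "Peaks.tsv"))
  }
  if (!is.null(p$networks)) {
    stats <- network_stats(p$networks)
    hist_str <- if (nrow(stats$size_histogram) > 0) {
      paste(sprintf("%d:%d", stats$size_histogram$size,
                    stats$size_histogram$n), collapse = " ")
    } else "-"
    lines <- c(lines, "", "## networks",
               sprintf("horizontal pairs: %d", nrow(p$pairs)),
               sprintf("networks: %d", stats$total),
               sprintf("size histogram: %s", hist_str),
               sprintf("max network size: %d", stats$max_size))
    np <- p$networks$peaks
    pair_of <- function(pid) {
      sel <- p$networks$pairs$left == pid | p$networks$pairs$right == pid
      if (!any(sel)) return("")
      paste(sprintf("%d-%d", p$networks$pairs$left[sel],
                    p$networks$pairs$right[sel]), collapse = ";")
    }
    link_of <- function(pid) {
      sel <- p$networks$links$peak_a == pid | p$networks$links$peak_b == pid
      if (!any(sel)) return("")
      other <- ifelse(p$networks$links$peak_a[sel] == pid,
                      p$networks$links$peak_b[sel],
                      p$networks$links$peak_a[sel])
      paste(other, collapse = ";")
    }
    nets_tbl <- tibble::tibble(
      network_id = np$network_id, peak_id = np$peak_id,
      cs_direct = np$cs_direct, cs_dq = np$cs_dq,
      pairs = vapply(np$peak_id, pair_of, character(1)),
      vertical_links = vapply(np$peak_id, link_of, character(1)))
    readr::write_tsv(nets_tbl, file.path(outdir, "Networks.tsv"))
  }
  if (!is.null(p$matches)) {
    n_nets <- length(unique(p$networks$peaks$network_id))
    n_matched_nets <- length(unique(p$matches$network_id))
    lines <- c(lines, "", "## matching",
               sprintf("matched networks: %d", n_matched_nets),
               sprintf("unmatched networks: %d", nrow(p$unmatched)),
               sprintf("network-compound matches: %d", nrow(p$matches)))
    stopifnot(n_matched_nets + nrow(p$unmatched) == n_nets)
    conn <- vapply(p$matches$matched, function(m) {
      paste(sprintf("%s-%s", m$db_carbon, m$db_partner), collapse = ";")
    }, character(1))
    match_tbl <- tibble::tibble(
      network_id = p$matches$network_id,
      entry_id = p$matches$entry_id,
      name = p$matches$name,
      ambiguity_score = p$matches$ambiguity_score,
      n_matched = p$matches$n_matched,
      hit_score = p$matches$hit_score,
      coverage_score = p$matches$coverage_score,
      connectivity = conn)
    if (nrow(p$unmatched) > 0) {
      match_tbl <- dplyr::bind_rows(match_tbl, tibble::tibble(
        network_id = p$unmatched$network_id,
        entry_id = "unknown", name = p$unmatched$signature,
        ambiguity_score = NA_real_, n_matched = NA_integer_,
        hit_score = NA_real_, coverage_score = NA_real_,
        connectivity = ""))
    }
    match_tbl <- match_tbl[order(match_tbl$network_id,
                                 match_tbl$entry_id), ]
    readr::write_tsv(match_tbl, file.path(outdir, "Matches.tsv"))
  }
  if (!is.null(p$jres_assignments)) {
    n_present <- sum(p$jres_presence$present)
    lines <- c(lines, "", "## jres integration",
               sprintf("jres projection peaks: %d", nrow(p$jres_peaks)),
               sprintf("networks with JRES peaks: %d of %d", n_present,
                       nrow(p$jres_presence)))
    readr::write_tsv(p$jres_assignments,
                     file.path(outdir, "MatchJres.tsv"))
  }
  writeLines(lines, file.path(outdir, "Summary.txt"))
  invisible(outdir)
}
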
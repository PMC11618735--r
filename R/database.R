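# Simulated INADEQUATE compound database. Each compound carries assigned
# 13C shifts (possibly several alternatives per carbon when the source
# assignment is ambiguous), a bond adjacency over carbon labels, an
# ambiguity score CA/CT, and the simulated peak list: for every bond (a, b)
# each carbon resonates at its own shift in the direct dimension and at the
# shift sum in the double-quantum dimension.

MAX_ALTERNATIVES <- 1024L

#' Construct a database compound
#'
#' @param name Compound name.
#' @param entry_id Entry identifier (e.g., a BMRB accession).
#' @param carbons Named list: carbon label -> numeric vector of assigned
#'   shift(s) in ppm. More than one shift marks the carbon as ambiguous.
#' @param bonds Two-column matrix/data frame of carbon labels (C-C bonds).
#' @return A `db_compound` object with `ambiguity_score` and `sim_peaks`
#'   populated.
#' @export
#' @examples
#' cmp <- db_compound("taurine-like", "fx0001",
#'                    carbons = list(C1 = 36.4, C2 = 48.2),
#'                    bonds = rbind(c("C1", "C2")))
#' cmp$ambiguity_score
db_compound <- function(name, entry_id, carbons, bonds) {
  if (length(carbons) == 0) {
    stop("undefined input: compound '", name, "' has zero carbons",
         call. = FALSE)
  }
  if (is.null(names(carbons)) || any(!nzchar(names(carbons)))) {
    stop("carbons must be a named list of shift vectors", call. = FALSE)
  }
  carbons <- lapply(carbons, as.numeric)
  if (any(vapply(carbons, length, integer(1)) < 1)) {
    stop("every carbon needs at least one assigned shift", call. = FALSE)
  }
  bonds <- as.matrix(bonds)
  if (ncol(bonds) != 2 && length(bonds) > 0) {
    stop("bonds must have two columns", call. = FALSE)
  }
  storage.mode(bonds) <- "character"
  unknown <- setdiff(unique(as.vector(bonds)), names(carbons))
  if (length(unknown) > 0) {
    stop("schema error: bond references unknown carbon(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(
    name = name, entry_id = entry_id, carbons = carbons, bonds = bonds,
    ambiguity_score = ambiguity_score(carbons),
    sim_peaks = simulate_compound_peaks(carbons, bonds)
  ), class = "db_compound")
}

#' @export
print.db_compound <- function(x, ...) {
  cat(sprintf(
    "<db_compound> %s (%s): %d carbons, %d bonds, ambiguity %.2f\n",
    x$name, x$entry_id, length(x$carbons), nrow(x$bonds),
    x$ambiguity_score))
  invisible(x)
}

#' Ambiguity score of a compound
#'
#' The fraction CA/CT, where CA is the number of carbons carrying more than
#' one assigned chemical shift and CT the total number of carbons. 0 means
#' every carbon is uniquely assigned; 1 means every carbon is ambiguous.
#'
#' @param compound A [db_compound()] object, or the named `carbons` list
#'   itself.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' ambiguity_score(list(C1 = 20.1, C2 = c(30.2, 30.4)))  # 0.5
ambiguity_score <- function(compound) {
  carbons <- if (inherits(compound, "db_compound")) compound$carbons
             else compound
  if (length(carbons) == 0) {
    stop("undefined input: ambiguity score needs at least one carbon",
         call. = FALSE)
  }
  ca <- sum(vapply(carbons, function(s) length(s) > 1, logical(1)))
  ca / length(carbons)
}

# enumerate global assignment alternatives: the cartesian product of each
# carbon's shift list, as a data frame with one column per carbon
assignment_alternatives <- function(carbons) {
  n_alt <- prod(vapply(carbons, length, integer(1)))
  if (n_alt > MAX_ALTERNATIVES) {
    warning("compound has ", n_alt, " assignment combinations; capping ",
            "ambiguous carbons beyond ", MAX_ALTERNATIVES,
            " combinations at their first shift", call. = FALSE)
    # keep multiplicity for the most ambiguous carbons until under the cap
    lens <- vapply(carbons, length, integer(1))
    ord <- order(-lens)
    kept <- rep(1L, length(carbons))
    running <- 1
    for (k in ord) {
      if (running * lens[k] > MAX_ALTERNATIVES) break
      running <- running * lens[k]
      kept[k] <- lens[k]
    }
    carbons <- Map(function(s, m) s[seq_len(m)], carbons, kept)
  }
  expand.grid(carbons, KEEP.OUT.ATTRS = FALSE)
}

#' Simulate the INADEQUATE peak list of a compound
#'
#' For every bond (a, b) and every assigned-shift combination, emits the two
#' peaks (shift_a, shift_a + shift_b) and (shift_b, shift_a + shift_b): each
#' bonded carbon resonates at its own frequency along the direct dimension
#' and at the pair's frequency sum along the double-quantum dimension. An
#' unambiguous compound yields exactly `2 * nrow(bonds)` peaks.
#'
#' @param carbons Named list of assigned-shift vectors (ppm).
#' @param bonds Two-column character matrix of carbon labels.
#' @return A tibble: `cs_direct`, `cs_dq`, `carbon`, `partner`,
#'   `alternative_index`.
#' @export
#' @examples
#' simulate_compound_peaks(list(A = 10, B = 20), rbind(c("A", "B")))
simulate_compound_peaks <- function(carbons, bonds) {
  carbons <- lapply(carbons, as.numeric)
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "character"
  unknown <- setdiff(unique(as.vector(bonds)), names(carbons))
  if (length(unknown) > 0) {
    stop("schema error: bond references unknown carbon(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  empty <- tibble::tibble(cs_direct = numeric(0), cs_dq = numeric(0),
                          carbon = character(0), partner = character(0),
                          alternative_index = integer(0))
  if (length(bonds) == 0 || nrow(bonds) == 0) return(empty)
  alts <- assignment_alternatives(carbons)
  out <- vector("list", nrow(alts))
  for (a in seq_len(nrow(alts))) {
    shift <- stats::setNames(as.numeric(alts[a, ]), names(alts))
    da <- unname(shift[bonds[, 1]]); db <- unname(shift[bonds[, 2]])
    dq <- da + db
    out[[a]] <- tibble::tibble(
      cs_direct = c(da, db), cs_dq = c(dq, dq),
      carbon = c(bonds[, 1], bonds[, 2]),
      partner = c(bonds[, 2], bonds[, 1]),
      alternative_index = a
    )
  }
  dplyr::bind_rows(out)
}

#' Build a compound database
#'
#' Assembles [db_compound()] records from a mixed list of inputs: inline
#' definitions (lists with `name`, `entry_id`, `carbons`, `bonds`), paths to
#' tabular TSV entries, or paths to NMR-STAR files with an assigned
#' chemical-shift loop. Entries lacking bonds are skipped with a warning;
#' duplicate entry ids are suffix-disambiguated with a warning.
#'
#' The tabular format is TSV with columns `carbon`, `shifts`
#' (comma-separated ppm values), `bonded_to` (comma-separated carbon
#' labels), preceded by `# name: ...` and `# id: ...` comment lines.
#'
#' @param entries List of compound definitions and/or file paths.
#' @return An `inadnet_db` object (schema-versioned list of compounds).
#' @export
build_database <- function(entries) {
  compounds <- list()
  for (e in entries) {
    cmp <- tryCatch({
      if (is.character(e) && length(e) == 1) {
        if (grepl("\\.(str|star)$", e, ignore.case = TRUE)) {
          read_nmrstar_compound(e)
        } else {
          read_table_compound(e)
        }
      } else if (inherits(e, "db_compound")) {
        e
      } else {
        db_compound(e$name, e$entry_id, e$carbons, e$bonds)
      }
    }, error = function(err) {
      warning("skipping database entry: ", conditionMessage(err),
              call. = FALSE)
      NULL
    })
    if (is.null(cmp)) next
    if (length(cmp$bonds) == 0 || nrow(cmp$bonds) == 0) {
      warning("skipping entry '", cmp$entry_id, "': no bonds",
              call. = FALSE)
      next
    }
    id <- cmp$entry_id
    if (id %in% names(compounds)) {
      k <- 2
      while (paste0(id, "_", k) %in% names(compounds)) k <- k + 1
      warning("duplicate entry id '", id, "' renamed to '",
              paste0(id, "_", k), "'", call. = FALSE)
      id <- paste0(id, "_", k)
      cmp$entry_id <- id
    }
    compounds[[id]] <- cmp
  }
  structure(list(schema = "inadnet-db-1", compounds = compounds),
            class = "inadnet_db")
}

#' @export
print.inadnet_db <- function(x, ...) {
  cat(sprintf("<inadnet_db> %d compound(s)\n", length(x$compounds)))
  invisible(x)
}

#' Drop compounds above an ambiguity threshold
#'
#' Retains compounds whose ambiguity score is at most `threshold`; more
#' ambiguous entries are not used for matching.
#'
#' @param db An [build_database()] object.
#' @param threshold Fraction in `[0, 1]`.
#' @return The filtered `inadnet_db`.
#' @export
filter_by_ambiguity <- function(db, threshold) {
  stopifnot(inherits(db, "inadnet_db"),
            threshold >= 0, threshold <= 1)
  keep <- vapply(db$compounds, function(c) c$ambiguity_score <= threshold,
                 logical(1))
  db$compounds <- db$compounds[keep]
  db
}

#' Write / read the database as structured text (JSON)
#'
#' The on-disk schema stores `name`, `entry_id`, `carbons` (label -> shifts),
#' `bonds` and `ambiguity_score`; simulated peaks are recomputed on load.
#'
#' @param db An `inadnet_db` object.
#' @param path File path (JSON).
#' @return `path` (write) or the `inadnet_db` (read).
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "inadnet_db"))
  doc <- list(
    schema = db$schema,
    compounds = lapply(unname(db$compounds), function(c) {
      list(name = c$name, entry_id = c$entry_id, carbons = c$carbons,
           bonds = apply(c$bonds, 1, function(b) list(b[[1]], b[[2]]),
                         simplify = FALSE),
           ambiguity_score = c$ambiguity_score)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema) || !startsWith(doc$schema, "inadnet-db")) {
    stop("format error: not an inadnet database file: ", path,
         call. = FALSE)
  }
  compounds <- lapply(doc$compounds, function(c) {
    bonds <- do.call(rbind, lapply(c$bonds, function(b) {
      c(as.character(b[[1]]), as.character(b[[2]]))
    }))
    carbons <- lapply(c$carbons, function(s) as.numeric(unlist(s)))
    db_compound(c$name, c$entry_id, carbons, bonds)
  })
  names(compounds) <- vapply(compounds, `[[`, character(1), "entry_id")
  structure(list(schema = doc$schema, compounds = compounds),
            class = "inadnet_db")
}

# --- tabular entry reader -------------------------------------------------

read_table_compound <- function(path) {
  if (!file.exists(path)) stop("entry file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- function(tag, default) {
    i <- grep(paste0("^#\\s*", tag, "\\s*:"), lines)
    if (length(i) == 0) return(default)
    trimws(sub(paste0("^#\\s*", tag, "\\s*:"), "", lines[i[1]]))
  }
  name <- meta("name", basename(path))
  id <- meta("id", tools::file_path_sans_ext(basename(path)))
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  need <- c("carbon", "shifts", "bonded_to")
  if (!all(need %in% names(tab))) {
    stop("table entry must have columns carbon, shifts, bonded_to: ", path,
         call. = FALSE)
  }
  carbons <- stats::setNames(lapply(tab$shifts, function(s) {
    as.numeric(strsplit(as.character(s), "[,;]")[[1]])
  }), tab$carbon)
  bonds <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    to <- trimws(strsplit(as.character(tab$bonded_to[i]), "[,;]")[[1]])
    to <- to[nzchar(to)]
    if (length(to) == 0) return(NULL)
    cbind(tab$carbon[i], to)
  }))
  if (!is.null(bonds)) {
    # each bond once, endpoints sorted
    bonds <- unique(t(apply(bonds, 1, sort)))
  } else {
    bonds <- matrix(character(0), ncol = 2)
  }
  db_compound(name, id, carbons, bonds)
}

# --- minimal NMR-STAR reader ---------------------------------------------
# Parses loop_ blocks; extracts the assigned chemical-shift loop
# (_Atom_chem_shift.*: Atom_ID, Atom_type, Val) and the bond loop
# (_Chem_comp_bond.*: Atom_ID_1/2 or Comp_atom_ID_1/2). Carbons only.

parse_star_loops <- function(lines) {
  lines <- trimws(lines)
  loops <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, lines[i])
        i <- i + 1
      }
      rows <- list()
      while (i <= n && lines[i] != "stop_" && lines[i] != "loop_") {
        if (nzchar(lines[i]) && !startsWith(lines[i], "#")) {
          vals <- scan(text = lines[i], what = character(), quiet = TRUE)
          rows[[length(rows) + 1]] <- vals
        }
        i <- i + 1
      }
      if (length(rows) > 0) {
        width <- length(tags)
        flat <- unlist(rows)
        if (length(flat) %% width == 0) {
          m <- matrix(flat, ncol = width, byrow = TRUE)
          colnames(m) <- tags
          loops[[length(loops) + 1]] <- m
        }
      }
    }
    i <- i + 1
  }
  loops
}

star_col <- function(loop, suffix) {
  hit <- grep(paste0("\\.", suffix, "$"), colnames(loop))
  if (length(hit) == 0) return(NULL)
  loop[, hit[1]]
}

read_nmrstar_compound <- function(path) {
  if (!file.exists(path)) stop("entry file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  grab_scalar <- function(tag) {
    i <- grep(paste0("^\\s*", tag, "\\s"), lines)
    if (length(i) == 0) return(NULL)
    val <- trimws(sub(paste0("^\\s*", tag, "\\s+"), "", lines[i[1]]))
    gsub("^['\"]|['\"]$", "", val)
  }
  name <- grab_scalar("_Entry.Title")
  if (is.null(name)) name <- grab_scalar("_Chem_comp.Name")
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  id <- grab_scalar("_Entry.ID")
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))

  loops <- parse_star_loops(lines)
  shifts_loop <- NULL; bonds_loop <- NULL
  for (lp in loops) {
    if (any(grepl("^_Atom_chem_shift\\.", colnames(lp)))) shifts_loop <- lp
    if (any(grepl("^_Chem_comp_bond\\.", colnames(lp)))) bonds_loop <- lp
  }
  if (is.null(shifts_loop)) {
    stop("no _Atom_chem_shift loop in NMR-STAR file: ", path, call. = FALSE)
  }
  atom <- star_col(shifts_loop, "Atom_ID")
  type <- star_col(shifts_loop, "Atom_type")
  val <- as.numeric(star_col(shifts_loop, "Val"))
  keep <- if (!is.null(type)) toupper(type) == "C" else grepl("^C", atom)
  atom <- atom[keep]; val <- val[keep]
  carbons <- split(val, atom)
  carbons <- lapply(carbons, function(s) sort(unique(s)))

  bonds <- matrix(character(0), ncol = 2)
  if (!is.null(bonds_loop)) {
    a1 <- star_col(bonds_loop, "Atom_ID_1")
    if (is.null(a1)) a1 <- star_col(bonds_loop, "Comp_atom_ID_1")
    a2 <- star_col(bonds_loop, "Atom_ID_2")
    if (is.null(a2)) a2 <- star_col(bonds_loop, "Comp_atom_ID_2")
    if (!is.null(a1) && !is.null(a2)) {
      cc <- a1 %in% names(carbons) & a2 %in% names(carbons)
      if (any(cc)) bonds <- unique(t(apply(cbind(a1[cc], a2[cc]), 1, sort)))
    }
  }
  db_compound(name, id, carbons, bonds)
}
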
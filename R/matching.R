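# Network-to-database matching. Stage 1: sample peaks match database peaks
# when their direct shifts agree within CSMT (injective, nearest-first
# greedy). Stage 2: a candidate is retained when at least NCMT distinct
# sample peaks matched. Stage 3: every matched pair must also agree in the
# double-quantum dimension within DQMT. Hit score = matched sample peaks /
# network peaks; coverage score = matched database peaks / compound peaks
# (within one assignment alternative).

# Greedy injective matching on direct-shift distance. A shared chain carbon
# puts two database peaks at the same direct shift on different DQ rows, so
# candidates already consistent in DQ (within dqmt) are preferred; remaining
# ties break by distance, then lower db peak index.
greedy_direct_match <- function(sample_cs, sample_dq, db_cs, db_dq, csmt,
                                dqmt = Inf) {
  ns <- length(sample_cs); nd <- length(db_cs)
  if (ns == 0 || nd == 0) {
    return(tibble::tibble(sample_row = integer(0), db_row = integer(0),
                          d_direct = numeric(0), d_dq = numeric(0)))
  }
  d <- abs(outer(sample_cs, db_cs, `-`))
  cand <- which(d <= csmt, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(sample_row = integer(0), db_row = integer(0),
                          d_direct = numeric(0), d_dq = numeric(0)))
  }
  ddq <- abs(outer(sample_dq, db_dq, `-`))
  dq_ok <- ddq[cand] <= dqmt
  ord <- order(!dq_ok, d[cand], cand[, 2], cand[, 1])
  cand <- cand[ord, , drop = FALSE]
  used_s <- logical(ns); used_d <- logical(nd)
  keep <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_s[i] && !used_d[j]) {
      used_s[i] <- TRUE; used_d[j] <- TRUE
      keep <- c(keep, k)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble::tibble(sample_row = cand[, 1], db_row = cand[, 2],
                 d_direct = d[cand],
                 d_dq = abs(sample_dq[cand[, 1]] - db_dq[cand[, 2]]))
}

#' Match one network against one database compound
#'
#' Evaluates the three-stage matching rule against every assignment
#' alternative of the compound and keeps the alternative maximizing the hit
#' score (ties: lower alternative index). Returns `NULL` when fewer than
#' `ncmt` sample peaks match or when any matched pair disagrees in the
#' double-quantum dimension by more than `dqmt`.
#'
#' @param network_peaks Tibble of one network's peaks (`peak_id`,
#'   `cs_direct`, `cs_dq`), e.g. one group of `link_networks()$peaks`.
#' @param compound A [db_compound()] (must already have passed the ambiguity
#'   filter).
#' @param cfg A [new_config()] supplying `csmt`, `ncmt`, `dqmt`.
#' @return A one-row tibble (`entry_id`, `name`, `ambiguity_score`,
#'   `alternative_index`, `n_matched`, `hit_score`, `coverage_score`,
#'   `dq_consistent`, list-column `matched`) or `NULL`.
#' @export
match_network <- function(network_peaks, compound, cfg) {
  cfg <- validate_config(cfg)
  stopifnot(inherits(compound, "db_compound"))
  sim <- compound$sim_peaks
  if (nrow(sim) == 0 || nrow(network_peaks) == 0) return(NULL)
  n_net <- nrow(network_peaks)
  best <- NULL
  for (a in sort(unique(sim$alternative_index))) {
    dbp <- sim[sim$alternative_index == a, ]
    m <- greedy_direct_match(network_peaks$cs_direct, network_peaks$cs_dq,
                             dbp$cs_direct, dbp$cs_dq, cfg$csmt, cfg$dqmt)
    if (nrow(m) < cfg$ncmt) next
    if (any(m$d_dq > cfg$dqmt)) next
    hit <- nrow(m) / n_net
    coverage <- length(unique(m$db_row)) / nrow(dbp)
    if (is.null(best) || hit > best$hit_score) {
      matched <- tibble::tibble(
        peak_id = network_peaks$peak_id[m$sample_row],
        sample_cs_direct = network_peaks$cs_direct[m$sample_row],
        sample_cs_dq = network_peaks$cs_dq[m$sample_row],
        db_cs_direct = dbp$cs_direct[m$db_row],
        db_cs_dq = dbp$cs_dq[m$db_row],
        db_carbon = dbp$carbon[m$db_row],
        db_partner = dbp$partner[m$db_row]
      )
      best <- tibble::tibble(
        entry_id = compound$entry_id, name = compound$name,
        ambiguity_score = compound$ambiguity_score,
        alternative_index = a, n_matched = nrow(m),
        hit_score = hit, coverage_score = coverage,
        dq_consistent = TRUE, matched = list(matched)
      )
    }
  }
  best
}

# compact backbone signature, e.g. "C(28.0)-C(60.9)-C(182.2)": distinct
# carbon shifts of a network (direct-shift clusters within cst), ascending
network_signature <- function(network_peaks, cst) {
  cs <- sort(network_peaks$cs_direct)
  if (length(cs) == 0) return("")
  grp <- cumsum(c(TRUE, diff(cs) > cst))
  centers <- tapply(cs, grp, mean)
  paste(sprintf("C(%.1f)", centers), collapse = "-")
}

#' Match all networks against a compound database
#'
#' Exhaustively evaluates every (network, compound) combination — a network
#' may match several similar compounds, and a compound may appear in several
#' networks. Compounds above the configured ambiguity threshold are excluded
#' first. Networks with no matching compound are reported with their
#' backbone shift signature so unknown compounds remain trackable.
#'
#' @param networks An [link_networks()] object.
#' @param db An [build_database()] database.
#' @param cfg A [new_config()] object.
#' @return A list: `matches` (tibble, one row per retained
#'   network-compound match, ordered by network then entry id) and
#'   `unmatched` (tibble `network_id`, `signature`).
#' @export
match_all <- function(networks, db, cfg) {
  cfg <- validate_config(cfg)
  stopifnot(inherits(networks, "inadnet_networks"),
            inherits(db, "inadnet_db"))
  db <- filter_by_ambiguity(db, cfg$ambiguity)
  net_ids <- sort(unique(networks$peaks$network_id))
  entry_ids <- sort(names(db$compounds))
  rows <- list()
  unmatched <- list()
  for (nid in net_ids) {
    np <- networks$peaks[networks$peaks$network_id == nid, ]
    found <- FALSE
    for (eid in entry_ids) {
      m <- match_network(np, db$compounds[[eid]], cfg)
      if (!is.null(m)) {
        m$network_id <- nid
        rows[[length(rows) + 1]] <- m
        found <- TRUE
      }
    }
    if (!found) {
      unmatched[[length(unmatched) + 1]] <- tibble::tibble(
        network_id = nid, signature = network_signature(np, cfg$cst))
    }
  }
  matches <- if (length(rows) > 0) {
    out <- dplyr::bind_rows(rows)
    out <- out[order(out$network_id, out$entry_id), ]
    out[, c("network_id", "entry_id", "name", "ambiguity_score",
            "alternative_index", "n_matched", "hit_score",
            "coverage_score", "dq_consistent", "matched")]
  } else {
    tibble::tibble(network_id = integer(0), entry_id = character(0),
                   name = character(0), ambiguity_score = numeric(0),
                   alternative_index = integer(0), n_matched = integer(0),
                   hit_score = numeric(0), coverage_score = numeric(0),
                   dq_consistent = logical(0), matched = list())
  }
  unmatched <- if (length(unmatched) > 0) dplyr::bind_rows(unmatched)
               else tibble::tibble(network_id = integer(0),
                                   signature = character(0))
  list(matches = matches, unmatched = unmatched)
}
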
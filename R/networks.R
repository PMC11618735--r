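# Network assembly. In INADEQUATE, two directly bonded carbons resonate at
# the same double-quantum (DQ) value -- the sum of their shifts -- giving a
# pair of peaks symmetric about the Y = 2X diagonal. Horizontal pairs are
# screened by three rules (DQT, SumXY, SDT); pairs sharing a carbon are then
# linked vertically (CST) into connected networks.

#' Find horizontal bonded-carbon peak pairs
#'
#' Screens all unordered peak pairs with the three pairing rules:
#' \itemize{
#'   \item DQ alignment: `|cs_dq_L - cs_dq_R| <= dqt`;
#'   \item sum rule: the sum of the two direct shifts must equal the pair's
#'     mean DQ shift to within `sum_xy`;
#'   \item diagonal symmetry: the two peaks' absolute distances from the
#'     Y = 2X line (`|cs_dq - 2 cs_direct|`) must agree to within `sdt`.
#' }
#' All inequalities are inclusive (`<=`). `left` is the peak with the
#' smaller direct shift; a peak may participate in several pairs (chain
#' carbons must).
#'
#' @param peaks A [pick_peaks()] tibble with distinct `id`s.
#' @param cfg A [new_config()] object supplying `dqt`, `sum_xy`, `sdt`.
#' @return A tibble: `left`, `right` (peak ids), `cs_direct_left`,
#'   `cs_direct_right`, `dq_value` (mean of the two DQ shifts),
#'   `sum_residual`, `symmetry_residual`.
#' @export
find_horizontal_pairs <- function(peaks, cfg) {
  cfg <- validate_config(cfg)
  if (anyDuplicated(peaks$id)) {
    stop("peak ids must be distinct", call. = FALSE)
  }
  n <- nrow(peaks)
  empty <- tibble::tibble(left = integer(0), right = integer(0),
                          cs_direct_left = numeric(0),
                          cs_direct_right = numeric(0),
                          dq_value = numeric(0), sum_residual = numeric(0),
                          symmetry_residual = numeric(0))
  if (n < 2) return(empty)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  # order within each pair by direct shift
  swap <- peaks$cs_direct[i] > peaks$cs_direct[j]
  li <- ifelse(swap, j, i); ri <- ifelse(swap, i, j)
  dql <- peaks$cs_dq[li]; dqr <- peaks$cs_dq[ri]
  dl <- peaks$cs_direct[li]; dr <- peaks$cs_direct[ri]
  dq_value <- (dql + dqr) / 2
  sum_residual <- abs(dl + dr - dq_value)
  symmetry_residual <- abs(abs(dql - 2 * dl) - abs(dqr - 2 * dr))
  keep <- abs(dql - dqr) <= cfg$dqt &
    sum_residual <= cfg$sum_xy &
    symmetry_residual <= cfg$sdt
  out <- tibble::tibble(
    left = peaks$id[li], right = peaks$id[ri],
    cs_direct_left = dl, cs_direct_right = dr,
    dq_value = dq_value, sum_residual = sum_residual,
    symmetry_residual = symmetry_residual
  )[keep, ]
  out[order(out$left, out$right), ]
}

#' Link horizontal pairs into INADEQUATE networks
#'
#' Creates a vertical link between any two peaks from different pairs whose
#' direct shifts differ by at most `cst` (a shared carbon detected in two
#' bonds), then takes connected components of the combined pair + link graph.
#' Network ids are assigned in ascending order of each network's minimum
#' direct shift, so output is reproducible run to run.
#'
#' @param pairs A [find_horizontal_pairs()] tibble.
#' @param cst Vertical-link tolerance (ppm) in the direct dimension.
#' @param peaks Optional peak tibble to carry `cs_dq`/`intensity` into the
#'   result (matched on `id`).
#' @return An `inadnet_networks` object: a list with tibbles `networks`
#'   (`network_id`, `n_peaks`, `n_pairs`, `min_cs_direct`), `peaks`
#'   (`network_id`, `peak_id`, `cs_direct`, `cs_dq`), `pairs` (the input
#'   pairs plus `network_id`), and `links` (`network_id`, `peak_a`,
#'   `peak_b`).
#' @export
link_networks <- function(pairs, cst, peaks = NULL) {
  stopifnot(cst > 0)
  empty <- structure(list(
    networks = tibble::tibble(network_id = integer(0), n_peaks = integer(0),
                              n_pairs = integer(0),
                              min_cs_direct = numeric(0)),
    peaks = tibble::tibble(network_id = integer(0), peak_id = integer(0),
                           cs_direct = numeric(0), cs_dq = numeric(0)),
    pairs = tibble::tibble(), links = tibble::tibble(
      network_id = integer(0), peak_a = integer(0), peak_b = integer(0))),
    class = "inadnet_networks")
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)

  # node table: every peak that participates in >= 1 pair
  node <- dplyr::bind_rows(
    tibble::tibble(peak_id = pairs$left, cs_direct = pairs$cs_direct_left),
    tibble::tibble(peak_id = pairs$right, cs_direct = pairs$cs_direct_right)
  )
  node <- dplyr::distinct(node, .data$peak_id, .keep_all = TRUE)
  node <- node[order(node$peak_id), ]
  nid <- stats::setNames(seq_len(nrow(node)), node$peak_id)

  pair_edges <- cbind(nid[as.character(pairs$left)],
                      nid[as.character(pairs$right)])

  # candidate vertical links: peaks (from different pairs) aligned within cst
  m <- nrow(node)
  vert <- NULL
  if (m >= 2) {
    ij <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    close_dir <- abs(node$cs_direct[ij[, 1]] - node$cs_direct[ij[, 2]]) <= cst
    vert <- ij[close_dir, , drop = FALSE]
    if (nrow(vert) > 0) {
      # drop links duplicating a pair edge (peaks already in one pair)
      pk <- paste(pmin(pair_edges[, 1], pair_edges[, 2]),
                  pmax(pair_edges[, 1], pair_edges[, 2]))
      vk <- paste(pmin(vert[, 1], vert[, 2]), pmax(vert[, 1], vert[, 2]))
      vert <- vert[!vk %in% pk, , drop = FALSE]
    }
  }

  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  g <- igraph::add_edges(g, t(pair_edges))
  if (!is.null(vert) && nrow(vert) > 0) g <- igraph::add_edges(g, t(vert))
  comp <- igraph::components(g)$membership

  # deterministic ids: ascending minimum direct shift
  min_cs <- tapply(node$cs_direct, comp, min)
  rank <- stats::setNames(rank(min_cs, ties.method = "first"),
                          names(min_cs))
  net_of_node <- as.integer(rank[as.character(comp)])

  peaks_tbl <- tibble::tibble(network_id = net_of_node,
                              peak_id = node$peak_id,
                              cs_direct = node$cs_direct)
  if (!is.null(peaks)) {
    cols <- intersect(c("cs_dq", "intensity"), names(peaks))
    extra <- peaks[match(peaks_tbl$peak_id, peaks$id), cols, drop = FALSE]
    for (col in cols) peaks_tbl[[col]] <- extra[[col]]
  } else {
    dq_lookup <- c(stats::setNames(pairs$dq_value, pairs$left),
                   stats::setNames(pairs$dq_value, pairs$right))
    peaks_tbl$cs_dq <- unname(dq_lookup[as.character(peaks_tbl$peak_id)])
  }
  peaks_tbl <- peaks_tbl[order(peaks_tbl$network_id, peaks_tbl$peak_id), ]

  pairs_out <- pairs
  pairs_out$network_id <- net_of_node[nid[as.character(pairs$left)]]
  pairs_out <- pairs_out[order(pairs_out$network_id, pairs_out$left,
                               pairs_out$right), ]

  links_tbl <- if (!is.null(vert) && nrow(vert) > 0) {
    a <- node$peak_id[vert[, 1]]; b <- node$peak_id[vert[, 2]]
    tibble::tibble(network_id = net_of_node[vert[, 1]],
                   peak_a = pmin(a, b), peak_b = pmax(a, b))
  } else {
    tibble::tibble(network_id = integer(0), peak_a = integer(0),
                   peak_b = integer(0))
  }
  links_tbl <- links_tbl[order(links_tbl$network_id, links_tbl$peak_a,
                               links_tbl$peak_b), ]

  nets <- dplyr::summarise(
    dplyr::group_by(peaks_tbl, .data$network_id),
    n_peaks = dplyr::n(),
    min_cs_direct = min(.data$cs_direct), .groups = "drop")
  np <- table(pairs_out$network_id)
  nets$n_pairs <- as.integer(np[as.character(nets$network_id)])
  nets <- nets[order(nets$network_id),
               c("network_id", "n_peaks", "n_pairs", "min_cs_direct")]

  structure(list(networks = nets, peaks = peaks_tbl, pairs = pairs_out,
                 links = links_tbl),
            class = "inadnet_networks")
}

#' @export
print.inadnet_networks <- function(x, ...) {
  cat(sprintf("<inadnet_networks> %d network(s), %d peak(s), %d pair(s)\n",
              nrow(x$networks), nrow(x$peaks), nrow(x$pairs)))
  if (nrow(x$networks) > 0) print(utils::head(x$networks, 10))
  invisible(x)
}

#' Summary counts for a set of networks
#'
#' @param networks An [link_networks()] object.
#' @return A list: `total` networks, `size_histogram` (tibble of network
#'   `size` and count `n`), `max_size`.
#' @export
#' @examples
#' network_stats(link_networks(tibble::tibble(), cst = 0.1))
network_stats <- function(networks) {
  stopifnot(inherits(networks, "inadnet_networks"))
  if (nrow(networks$networks) == 0) {
    return(list(total = 0L,
                size_histogram = tibble::tibble(size = integer(0),
                                                n = integer(0)),
                max_size = 0L))
  }
  sizes <- networks$networks$n_peaks
  tab <- table(sizes)
  list(total = nrow(networks$networks),
       size_histogram = tibble::tibble(size = as.integer(names(tab)),
                                       n = as.integer(tab)),
       max_size = max(sizes))
}
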
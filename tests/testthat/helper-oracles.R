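# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (loops, BFS, explicit union-find) and share
# no code with the implementation paths they check.

# --- naive BFS flood fill: connected-component labels of a logical mask ----
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (mask[r0, c0] && lab[r0, c0] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(r0, c0))
        lab[r0, c0] <- nxt
        while (length(queue) > 0) {
          cur <- queue[[1]]; queue <- queue[-1]
          r <- cur[1]; c <- cur[2]
          for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1),
                         c(r, c + 1))) {
            if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc &&
                mask[d[1], d[2]] && lab[d[1], d[2]] == 0L) {
              lab[d[1], d[2]] <- nxt
              queue[[length(queue) + 1]] <- d
            }
          }
        }
      }
    }
  }
  lab
}

# --- explicit union-find ----------------------------------------------------
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

# grouping of detections by transitive closure of the proximity relation,
# via explicit union-find over all O(n^2) pairs
oracle_merge_groups <- function(cs_direct, cs_dq, ppcs, ppdq) {
  n <- length(cs_direct)
  parent <- uf_new(n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(cs_direct[i] - cs_direct[j]) <= ppcs &&
            abs(cs_dq[i] - cs_dq[j]) <= ppdq) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# --- exhaustive O(n^2) triple-predicate pair oracle -------------------------
oracle_pairs <- function(peaks, dqt, sum_xy, sdt) {
  out <- list()
  n <- nrow(peaks)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- peaks[i, ]; b <- peaks[j, ]
        if (a$cs_direct > b$cs_direct) { tmp <- a; a <- b; b <- tmp }
        dq_value <- (a$cs_dq + b$cs_dq) / 2
        ok <- abs(a$cs_dq - b$cs_dq) <= dqt &&
          abs(a$cs_direct + b$cs_direct - dq_value) <= sum_xy &&
          abs(abs(a$cs_dq - 2 * a$cs_direct) -
              abs(b$cs_dq - 2 * b$cs_direct)) <= sdt
        if (ok) {
          out[[length(out) + 1]] <- data.frame(left = a$id, right = b$id)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(left = integer(0), right = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$left, res$right), , drop = FALSE]
}

# --- fixture builders -------------------------------------------------------

# a small fast config consistent with the default fixture conditions:
# amplitudes ~100, PPmin above overlap saddles and the noise floor
test_config <- function(...) {
  new_config(pp_max = 90, pp_min = 10, steps = 6, ...)
}

# random compound library for round-trip trials: k compounds, chain lengths
# 2..4, carbon shifts in 12..188 ppm with guaranteed separation so that the
# study conditions (linewidths, tolerances) can resolve every peak
random_library <- function(k = 2, min_sep_direct = 4, min_sep_dq = 3) {
  repeat {
    n_carbons <- sample(2:4, k, replace = TRUE)
    shifts <- numeric(0)
    cmps <- list()
    ok <- TRUE
    for (m in seq_len(k)) {
      cs <- numeric(0)
      for (j in seq_len(n_carbons[m])) {
        cand <- stats::runif(1, 12, 188)
        tries <- 0
        while (any(abs(c(shifts, cs) - cand) < min_sep_direct)) {
          cand <- stats::runif(1, 12, 188)
          tries <- tries + 1
          if (tries > 200) { ok <- FALSE; break }
        }
        if (!ok) break
        cs <- c(cs, cand)
      }
      if (!ok) break
      labels <- paste0("C", seq_along(cs))
      bonds <- cbind(labels[-length(labels)], labels[-1])
      cmps[[m]] <- list(name = sprintf("rand-%d", m),
                        entry_id = sprintf("rx%04d", m),
                        carbons = stats::setNames(as.list(cs), labels),
                        bonds = bonds)
      shifts <- c(shifts, cs)
    }
    if (!ok) next
    # all bond DQ values must also be separated
    dqs <- unlist(lapply(cmps, function(cmp) {
      s <- vapply(cmp$carbons, `[[`, numeric(1), 1)
      b <- cmp$bonds
      s[b[, 1]] + s[b[, 2]]
    }))
    if (length(dqs) < 2 || min(dist(dqs)) >= min_sep_dq) {
      return(cmps)
    }
  }
}

# render + pick + network + match on a fixture, returning all intermediates
run_fixture_pipeline <- function(fx, cfg = test_config()) {
  sp <- render_inadequate(fx)
  peaks <- pick_peaks(sp$spectrum, cfg)
  pairs <- find_horizontal_pairs(peaks, cfg)
  nets <- link_networks(pairs, cfg$cst, peaks = peaks)
  db <- build_database(fx$compounds)
  res <- match_all(nets, db, cfg)
  list(sim = sp, peaks = peaks, pairs = pairs, nets = nets, db = db,
       matches = res$matches, unmatched = res$unmatched)
}

write_test_config <- function(path, overrides = list()) {
  vals <- list(PPmax = 90, PPmin = 10, steps = 6, PPCS = 0.4, PPDQ = 1,
               DQT = 0.5, SumXY = 0.5, SDT = 0.5, CST = 0.25, CSMT = 0.3,
               NCMT = 2, DQMT = 0.6, Ambiguity = 1, Peak_Width_1D = 0.3,
               Intensity_threshold_1D = 1)
  vals[names(overrides)] <- overrides
  writeLines(paste(names(vals), "=", unlist(vals)), path)
  path
}
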
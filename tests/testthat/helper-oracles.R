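# Independent oracles used across tests.

# Exhaustive order-preserving frame-pair matcher: enumerates every mapping
# in which each current cell maps to one next-frame cell, two adjacent
# next-frame cells, or none, and leftover next-frame cells appear as new
# tracks. Costs re-implement the documented tracking contract from scratch
# (no dynamic programming, no shared code) and the minimum is found by
# brute force. Termination penalties are priced after the full mapping is
# known: a terminated cell with a surviving distal neighbour is a lysis
# (pen_lys), one without is an eviction (pen_term).
oracle_match_cost <- function(LA, cA, LB, cB, ahat = 0, dt = 1,
                              div_tol = 0.15, gamma = 0.001,
                              pen_term = 4, pen_div = 3, pen_new = 12,
                              pen_shrink = 6, sigma = 0.02,
                              pen_lys = 6) {
  g <- exp(ahat * dt)
  n <- length(LA); m <- length(LB)
  log_tol <- log(1 + div_tol)
  s2 <- max(sigma, 1e-3)^2
  match_cost <- function(i, j) {
    lr <- log(LB[j] / (LA[i] * g))
    if (lr < -log_tol)  # hidden division: other daughter vanished unseen
      return(pen_shrink + (lr - log(0.5))^2 / (2 * (0.085^2 + 2 * s2)) +
               gamma * abs(cB[j] - cA[i] * g))
    lr^2 / (4 * s2) + gamma * abs(cB[j] - cA[i] * g)
  }
  div_cost <- function(i, j1, j2) {
    sumd <- LB[j1] + LB[j2]
    lr <- log(sumd / (LA[i] * g))
    if (abs(lr) > log_tol) return(Inf)
    mid <- (cB[j1] * LB[j1] + cB[j2] * LB[j2]) / sumd
    lr^2 / (3 * s2) + gamma * abs(mid - cA[i] * g) + pen_div
  }
  term_total <- function(terms, nonterms) {
    if (!length(terms)) return(0)
    last_nonterm <- if (length(nonterms)) max(nonterms) else 0L
    sum(ifelse(terms < last_nonterm, pen_lys, pen_term))
  }
  best <- Inf
  rec <- function(i, j, cost, terms, nonterms) {
    if (cost >= best) return()
    if (i > n) {
      total <- cost + (m - j + 1) * pen_new + term_total(terms, nonterms)
      if (total < best) best <<- total
      return()
    }
    rec(i + 1, j, cost, c(terms, i), nonterms)
    if (j <= m) {
      rec(i + 1, j + 1, cost + match_cost(i, j), terms, c(nonterms, i))
      rec(i, j + 1, cost + pen_new, terms, nonterms)
      if (j + 1 <= m)
        rec(i + 1, j + 2, cost + div_cost(i, j, j + 1), terms,
            c(nonterms, i))
    }
  }
  rec(1, 1, 0, integer(0), integer(0))
  best
}

# cost of the assignment the package's DP actually chose, priced with the
# oracle's own cost functions
dp_assignment_cost <- function(LA, cA, LB, cB, ahat = 0, dt = 1,
                               div_tol = 0.15, gamma = 0.001,
                               pen_term = 4, pen_div = 3, pen_new = 12,
                               pen_shrink = 6, sigma = 0.02,
                               pen_lys = 6) {
  res <- helmamp:::.match_frames(LA, cA, LB, cB, ahat, dt, div_tol, gamma,
                                 pen_term, pen_div, pen_new, pen_shrink,
                                 sigma, pen_lys)
  g <- exp(ahat * dt)
  m <- length(LB)
  log_tol <- log(1 + div_tol)
  s2 <- max(sigma, 1e-3)^2
  types <- vapply(res$assign, `[[`, character(1), "type")
  nonterms <- which(types != "term")
  last_nonterm <- if (length(nonterms)) max(nonterms) else 0L
  cost <- length(res$appeared) * pen_new
  for (i in seq_along(res$assign)) {
    a <- res$assign[[i]]
    if (a$type == "term") {
      cost <- cost + if (i < last_nonterm) pen_lys else pen_term
    } else if (a$type == "match") {
      lr <- log(LB[a$j] / (LA[i] * g))
      cost <- cost + if (lr < -log_tol) {
        pen_shrink + (lr - log(0.5))^2 / (2 * (0.085^2 + 2 * s2)) +
          gamma * abs(cB[a$j] - cA[i] * g)
      } else lr^2 / (4 * s2) + gamma * abs(cB[a$j] - cA[i] * g)
    } else {
      sumd <- sum(LB[a$j])
      mid <- sum(cB[a$j] * LB[a$j]) / sumd
      cost <- cost + log(sumd / (LA[i] * g))^2 / (3 * s2) +
        gamma * abs(mid - cA[i] * g) + pen_div
    }
  }
  cost
}

# observation table for a hand-specified stack of cell lengths per frame;
# centroids follow from stacking at the dead end
make_obs <- function(lengths_by_frame, trench_id = 1L, frame0 = 0L,
                     frames = NULL) {
  if (is.null(frames)) frames <- frame0 + seq_along(lengths_by_frame) - 1L
  rows <- lapply(seq_along(lengths_by_frame), function(k) {
    L <- lengths_by_frame[[k]]
    if (!length(L)) return(NULL)
    data.frame(trench_id = trench_id, frame = frames[k],
               time_min = as.numeric(frames[k]),
               rank = seq_along(L) - 1L, length_um = L,
               centroid_um = cumsum(L) - L / 2)
  })
  do.call(rbind, rows)
}

# brute-force maximum-cardinality, minimum-total-distance matching of
# candidate disulfide pairs (each cysteine in at most one bond)
oracle_disulfide_matching <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  best <- NULL
  n <- nrow(pairs)
  for (sel in 0:(2^n - 1)) {
    idx <- which(bitwAnd(sel, 2^(seq_len(n) - 1)) > 0)
    res <- c(pairs$residue_a[idx], pairs$residue_b[idx])
    if (anyDuplicated(res)) next
    cand <- list(k = length(idx), w = sum(pairs$distance[idx]), idx = idx)
    if (is.null(best) || cand$k > best$k ||
        (cand$k == best$k && cand$w < best$w)) best <- cand
  }
  pairs[best$idx, , drop = FALSE]
}
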
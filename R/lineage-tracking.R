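#' Reconstruct cell lineages from per-frame trench observations
#'
#' `track_trench()` rebuilds the lineage forest of a single trench from its
#' tidy observation table; `track_trenches()` applies it per trench. For
#' each consecutive frame pair an order-preserving assignment is computed
#' in which every current cell maps to one next-frame cell (growth), two
#' adjacent next-frame cells (division) or none (lysis/eviction), and
#' unexplained next-frame cells appear as new parentless tracks (heavily
#' penalised; in a dead-end trench nothing enters from the open end). The
#' optimal assignment minimises a negative log-likelihood by dynamic
#' programming over the rank-ordered cells: Gaussian length residuals
#' `log(L_next / L_pred)^2` (scaled by the measurement-noise variance,
#' estimated on the fly unless `sigma` is given) plus a centroid term
#' `gamma * |delta centroid|`, with `L_pred = L * exp(alpha_hat * dt)`
#' using a running growth-rate estimate, and prior penalties for each
#' structural move (division, termination, hidden division, appearance).
#' An apparent shrink beyond `div_tol` is interpreted as a division whose
#' second daughter vanished within the frame interval (evicted at the
#' open end or lysed at birth); the track continues through the surviving
#' daughter. Ties are broken toward growth, then division, then
#' termination (the most parsimonious history).
#'
#' Terminated tracks are classified by [classify_fate()]: a cell that
#' disappears while cells distal to it survive can only have lysed (cells
#' leave the trench at the open end only); a disappearing cell with no
#' surviving distal neighbour is evicted if its distal edge was within
#' `eviction_margin` of the open end, and lysed otherwise. Tracks reaching
#' the final frame are censored; missing frames split tracks with fate
#' `censored` at the gap.
#'
#' @param observations Observation data.frame in the [simulate_trench()]
#'   dialect (`trench_id`, `frame`, `time_min`, `rank`, `length_um`,
#'   `centroid_um`), sorted by frame with valid within-frame ranks.
#' @param trench_len Trench length (µm).
#' @param eviction_margin Distance from the open end (µm) within which a
#'   disappearing distal cell is classified as evicted. Default: one mean
#'   cell length.
#' @param div_tol Relative tolerance on (daughter length sum) vs predicted
#'   parent length for a division to be admissible.
#' @param gamma Weight (1/µm) of the centroid-displacement cost term.
#' @param pen_term,pen_div,pen_new Prior penalties (negative log scale)
#'   for terminating a track at the open end (eviction), accepting a
#'   division, and creating a parentless track.
#' @param pen_shrink Prior penalty for a hidden division (shrink
#'   continuation).
#' @param pen_lys Prior penalty for an interior termination (lysis);
#'   larger than `pen_term` because lysis is rarer than eviction in a
#'   packed trench.
#' @param sigma Per-measurement length-noise scale on the log scale;
#'   `NULL` (default) estimates it adaptively from match residuals.
#' @param t_final Last frame of the movie; defaults to the maximum frame in
#'   `observations`. Tracks alive at `t_final` are censored.
#' @param alpha_init Initial growth-rate estimate (1/min) for length
#'   prediction before any frame pair has been matched.
#'
#' @return A list with
#' \describe{
#'   \item{records}{data.frame `cell_id`, `trench_id`, `parent_id`,
#'     `birth_frame`, `last_frame`, `fate` (one of `divided`, `lysed`,
#'     `evicted`, `censored`).}
#'   \item{assignments}{data.frame `trench_id`, `frame`, `rank`, `cell_id`
#'     mapping every observation row to its track.}
#' }
#' @examples
#' p <- sim_params(n_trenches = 1, t_total = 90, obs_noise_sd = 0, seed = 3)
#' sim <- simulate_trench(p)
#' trk <- track_trench(sim$observations)
#' table(trk$records$fate)
#' @export
track_trench <- function(observations, trench_len = 75, eviction_margin = 6,
                         div_tol = 0.15, gamma = 0.001, pen_term = 4,
                         pen_div = 3, pen_new = 12, pen_shrink = 6,
                         pen_lys = 6, sigma = NULL, t_final = NULL,
                         alpha_init = 0) {
  stopifnot(is.data.frame(observations))
  if (length(unique(observations$trench_id)) > 1L)
    stop("`track_trench()` expects a single trench; use `track_trenches()`.",
         call. = FALSE)
  if (is.null(t_final)) t_final <- max(observations$frame)
  .track_one(observations, trench_len, eviction_margin, div_tol, gamma,
             pen_term, pen_div, pen_new, pen_shrink, sigma, pen_lys,
             t_final, alpha_init)
}

#' @rdname track_trench
#' @export
track_trenches <- function(observations, trench_len = 75,
                           eviction_margin = 6, div_tol = 0.15,
                           gamma = 0.001, pen_term = 4, pen_div = 3,
                           pen_new = 12, pen_shrink = 6, pen_lys = 6,
                           sigma = NULL, t_final = NULL,
                           alpha_init = 0) {
  if (is.null(t_final)) t_final <- max(observations$frame)
  parts <- split(observations, observations$trench_id)
  res <- lapply(parts, .track_one, trench_len, eviction_margin, div_tol,
                gamma, pen_term, pen_div, pen_new, pen_shrink, sigma,
                pen_lys, t_final, alpha_init)
  list(records = do.call(rbind, c(lapply(res, `[[`, "records"),
                                  make.row.names = FALSE)),
       assignments = do.call(rbind, c(lapply(res, `[[`, "assignments"),
                                      make.row.names = FALSE)))
}

#' Classify the fate of a terminated track
#'
#' A disappearing cell with a surviving distal neighbour must have lysed:
#' in a dead-end trench cells exit only via the open end, so eviction can
#' only affect the distal-most cells. A disappearing cell with no
#' surviving distal neighbour is evicted if its distal edge was within
#' `eviction_margin` of the open end, otherwise it lysed.
#'
#' @param distal_edge_um Distance of the cell's distal (open-end-facing)
#'   edge from the dead end at the last frame it was seen.
#' @param has_distal_survivor Logical: did any cell distal to this one
#'   survive into the next frame?
#' @param trench_len,eviction_margin Geometry, as in [track_trench()].
#' @return `"lysed"` or `"evicted"`.
#' @export
classify_fate <- function(distal_edge_um, has_distal_survivor,
                          trench_len = 75, eviction_margin = 6) {
  if (has_distal_survivor) return("lysed")
  if (distal_edge_um >= trench_len - eviction_margin) "evicted" else "lysed"
}

# Order-preserving frame-pair assignment by dynamic programming.
# Costs are negative log-likelihoods: length residuals are Gaussian on the
# log scale (variance from the measurement-noise scale `sigma`), and each
# structural move carries a prior penalty. The DP runs over the sequences
# reversed (distal end first) so that a termination before any next-frame
# cell has been consumed -- i.e. with no surviving distal neighbour -- can
# be priced as an eviction (pen_term) while interior terminations are
# priced as lyses (pen_lys), which are rarer. Returns per-A moves and
# appeared-B indices in original (dead-end-first) indexing.
.match_frames <- function(LA, cA, LB, cB, ahat, dt, div_tol, gamma,
                          pen_term, pen_div, pen_new, pen_shrink = 6,
                          sigma = 0.02, pen_lys = 6) {
  n <- length(LA); m <- length(LB)
  g <- exp(ahat * dt)
  LAr <- rev(LA); cAr <- rev(cA)
  LBr <- rev(LB); cBr <- rev(cB)
  Lpred <- LAr * g
  cpred <- cAr * g  # uniform growth advects the whole column distally
  log_tol <- log(1 + div_tol)
  s2 <- max(sigma, 1e-3)^2
  sf2 <- 0.085^2  # spread of log daughter fraction around log(1/2)

  if (m > 0L && n > 0L) {
    lr <- log(outer(1 / Lpred, LBr))
    # growth: both lengths carry measurement noise, lr ~ N(0, 2 sigma^2)
    cpen <- lr^2 / (4 * s2)
    # a cell cannot shrink: an apparent shrink beyond the division
    # tolerance signals a hidden division whose other daughter vanished
    # within the same interval (evicted at the open end, or lysed right
    # after birth); the track continues through the surviving daughter,
    # matching the observable-forest collapse. The residual is the implied
    # daughter fraction's distance from an even split.
    shrink <- lr < -log_tol
    cpen[shrink] <- pen_shrink +
      (lr[shrink] - log(0.5))^2 / (2 * (sf2 + 2 * s2))
    cmatch <- cpen + gamma * abs(outer(-cpred, cBr, `+`))
  }
  if (m > 1L && n > 0L) {
    sumd <- LBr[-m] + LBr[-1]
    mid <- (cBr[-m] * LBr[-m] + cBr[-1] * LBr[-1]) / sumd
    lrd <- log(outer(1 / Lpred, sumd))
    cdiv <- lrd^2 / (3 * s2)  # summed daughters have ~sigma^2/2 variance
    cdiv[abs(lrd) > log_tol] <- Inf
    cdiv <- cdiv + gamma * abs(outer(-cpred, mid, `+`)) + pen_div
  }

  M <- matrix(0L, n + 1L, m + 1L)  # 1 term, 2 match, 3 div, 4 appear
  row_prev <- c(0, cumsum(rep(pen_new, m)))
  M[1L, -1L] <- 4L
  for (i in seq_len(n)) {
    v_match <- c(Inf, if (m > 0L) row_prev[1:m] + cmatch[i, ] else numeric(0))
    v_div <- if (m > 1L) c(Inf, Inf, row_prev[1:(m - 1L)] + cdiv[i, ])
             else rep(Inf, m + 1L)
    v_term <- row_prev + pen_lys
    v_term[1L] <- row_prev[1L] + pen_term  # no distal survivor: eviction
    row <- v_match; mv <- rep(2L, m + 1L)
    upd <- v_div < row
    row[upd] <- v_div[upd]; mv[upd] <- 3L
    upd <- v_term < row
    row[upd] <- v_term[upd]; mv[upd] <- 1L
    if (m > 0L) for (k in 2:(m + 1L)) {
      if (row[k - 1L] + pen_new < row[k]) {
        row[k] <- row[k - 1L] + pen_new
        mv[k] <- 4L
      }
    }
    M[i + 1L, ] <- mv
    row_prev <- row
  }

  # backtrack (reversed indices), mapping back to dead-end-first order
  assign <- vector("list", n)
  appeared <- integer(0)
  i <- n; k <- m + 1L
  while (i > 0L || k > 1L) {
    mv <- M[i + 1L, k]
    if (i == 0L) mv <- 4L
    if (mv == 1L) {
      assign[[n + 1L - i]] <- list(type = "term")
      i <- i - 1L
    } else if (mv == 2L) {
      assign[[n + 1L - i]] <- list(type = "match", j = m + 2L - k)
      i <- i - 1L; k <- k - 1L
    } else if (mv == 3L) {
      assign[[n + 1L - i]] <- list(type = "div",
                                   j = c(m + 2L - k, m + 3L - k))
      i <- i - 1L; k <- k - 2L
    } else {
      appeared <- c(appeared, m + 2L - k)
      k <- k - 1L
    }
  }
  list(assign = assign, appeared = sort(appeared))
}

.track_one <- function(obs, trench_len, eviction_margin, div_tol, gamma,
                       pen_term, pen_div, pen_new, pen_shrink, sigma,
                       pen_lys, t_final, alpha_init) {
  tr <- obs$trench_id[1L]
  obs <- obs[order(obs$frame, obs$rank), , drop = FALSE]
  frames <- sort(unique(obs$frame))
  by_frame <- split(obs, factor(obs$frame, levels = frames))

  rec_id <- integer(0); rec_parent <- integer(0)
  rec_birth <- integer(0); rec_last <- integer(0); rec_fate <- character(0)
  next_id <- 1L
  new_track <- function(parent, birth_frame) {
    id <- next_id; next_id <<- next_id + 1L
    rec_id[id] <<- id; rec_parent[id] <<- parent
    rec_birth[id] <<- birth_frame; rec_last[id] <<- birth_frame
    rec_fate[id] <<- NA_character_
    id
  }

  asg_frame <- integer(0); asg_rank <- integer(0); asg_cell <- integer(0)
  push_asg <- function(frame, ranks, ids) {
    asg_frame <<- c(asg_frame, rep(as.integer(frame), length(ranks)))
    asg_rank <<- c(asg_rank, as.integer(ranks))
    asg_cell <<- c(asg_cell, ids)
  }

  # active state, ordered by rank
  f0 <- by_frame[[1L]]
  act_id <- vapply(seq_len(nrow(f0)), function(i) new_track(NA_integer_,
                                                            frames[1L]),
                   integer(1))
  act_len <- f0$length_um
  act_cen <- f0$centroid_um
  push_asg(frames[1L], f0$rank, act_id)

  ahat <- alpha_init
  adaptive_sigma <- is.null(sigma)
  shat <- if (adaptive_sigma) 0.02 else sigma

  terminate_all <- function(at_frame, censor) {
    for (i in seq_along(act_id)) {
      rec_last[act_id[i]] <<- as.integer(at_frame)
      rec_fate[act_id[i]] <<- if (censor) "censored" else
        classify_fate(act_cen[i] + act_len[i] / 2, FALSE, trench_len,
                      eviction_margin)
    }
    act_id <<- integer(0); act_len <<- numeric(0); act_cen <<- numeric(0)
  }

  fidx <- 1L
  while (fidx <= length(frames)) {
    f <- frames[fidx]
    if (fidx == length(frames)) {
      # no further data: end of movie -> censored, else all disappeared
      terminate_all(f, censor = f >= t_final)
      break
    }
    fn <- frames[fidx + 1L]
    if (fn != f + 1L) {  # data gap: split with censoring, restart fresh
      terminate_all(f, censor = TRUE)
      fB <- by_frame[[fidx + 1L]]
      act_id <- vapply(seq_len(nrow(fB)), function(i)
        new_track(NA_integer_, fn), integer(1))
      act_len <- fB$length_um
      act_cen <- fB$centroid_um
      push_asg(fn, fB$rank, act_id)
      fidx <- fidx + 1L
      next
    }

    fB <- by_frame[[fidx + 1L]]
    dt <- fB$time_min[1L] - by_frame[[fidx]]$time_min[1L]
    res <- .match_frames(act_len, act_cen, fB$length_um, fB$centroid_um,
                         ahat, dt, div_tol, gamma, pen_term, pen_div,
                         pen_new, pen_shrink, shat, pen_lys)

    n <- length(act_id)
    types <- vapply(res$assign, `[[`, character(1), "type")
    survives <- types != "term"
    new_id <- rep(NA_integer_, nrow(fB))
    new_from <- rep(NA_integer_, nrow(fB))  # index into act for ahat update
    for (i in seq_len(n)) {
      a <- res$assign[[i]]
      if (a$type == "term") {
        rec_last[act_id[i]] <- f
        has_surv <- i < n && any(survives[(i + 1L):n])
        rec_fate[act_id[i]] <- classify_fate(act_cen[i] + act_len[i] / 2,
                                             has_surv, trench_len,
                                             eviction_margin)
      } else if (a$type == "match") {
        new_id[a$j] <- act_id[i]
        new_from[a$j] <- i
        rec_last[act_id[i]] <- fn
      } else {  # division
        rec_last[act_id[i]] <- f
        rec_fate[act_id[i]] <- "divided"
        new_id[a$j[1L]] <- new_track(act_id[i], fn)
        new_id[a$j[2L]] <- new_track(act_id[i], fn)
      }
    }
    for (j in res$appeared) new_id[j] <- new_track(NA_integer_, fn)

    matched <- !is.na(new_from)
    if (any(matched) && dt > 0) {
      r <- log(fB$length_um[matched] / act_len[new_from[matched]]) / dt
      r <- r[r > -log(1 + div_tol) / dt]  # exclude hidden-division drops
      if (length(r)) ahat <- 0.7 * ahat + 0.3 * stats::median(r)
      if (adaptive_sigma && length(r) >= 5L) {
        # robust per-measurement noise scale from match residuals
        est <- stats::mad(r * dt, center = stats::median(r) * dt) / sqrt(2)
        shat <- max(0.7 * shat + 0.3 * est, 1e-3)
      }
    }

    push_asg(fn, fB$rank, new_id)
    act_id <- new_id
    act_len <- fB$length_um
    act_cen <- fB$centroid_um
    fidx <- fidx + 1L
  }

  n_rec <- next_id - 1L
  list(
    records = data.frame(
      cell_id = rec_id[seq_len(n_rec)], trench_id = tr,
      parent_id = rec_parent[seq_len(n_rec)],
      birth_frame = rec_birth[seq_len(n_rec)],
      last_frame = rec_last[seq_len(n_rec)],
      fate = rec_fate[seq_len(n_rec)]
    ),
    assignments = data.frame(trench_id = tr, frame = asg_frame,
                             rank = asg_rank, cell_id = asg_cell)
  )
}

# per-row predecessor keys: which (frame-1) observation each row descends
# from under a forest ("none" for births without a linked parent row)
.pred_keys <- function(forest) {
  asg <- forest$assignments
  rec <- forest$records
  row_key <- paste(asg$trench_id, asg$frame, asg$rank)
  rank_lookup <- stats::setNames(asg$rank,
                                 paste(asg$trench_id, asg$cell_id,
                                       asg$frame))
  prev_rank <- rank_lookup[paste(asg$trench_id, asg$cell_id,
                                 asg$frame - 1)]
  need_parent <- is.na(prev_rank)
  if (any(need_parent)) {
    parent_lookup <- stats::setNames(rec$parent_id,
                                     paste(rec$trench_id, rec$cell_id))
    par <- parent_lookup[paste(asg$trench_id[need_parent],
                               asg$cell_id[need_parent])]
    prev_rank[need_parent] <- rank_lookup[paste(asg$trench_id[need_parent],
                                                par,
                                                asg$frame[need_parent] - 1)]
  }
  pred <- ifelse(is.na(prev_rank), "none",
                 paste(asg$trench_id, asg$frame - 1, prev_rank))
  stats::setNames(pred, row_key)
}

#' Frame-to-frame assignment accuracy of a tracking result
#'
#' For every observation row (after the first frame of its trench) both
#' forests imply a predecessor row in the previous frame: the same track's
#' row, the parent track's row for a newborn daughter, or none. Accuracy is
#' the fraction of rows whose predecessor agrees with the reference
#' (typically the [observable_forest()] of the simulator ground truth).
#'
#' @param tracked,reference Lists with `records` and `assignments` as
#'   returned by [track_trenches()] and [observable_forest()].
#' @return Fraction in `[0, 1]`.
#' @export
assignment_accuracy <- function(tracked, reference) {
  pt <- .pred_keys(tracked)
  pr <- .pred_keys(reference)
  stopifnot(length(pt) == length(pr))
  pr <- pr[names(pt)]
  asg <- tracked$assignments
  first_frame <- tapply(asg$frame, asg$trench_id, min)
  eval_rows <- asg$frame > first_frame[as.character(asg$trench_id)]
  keys <- paste(asg$trench_id, asg$frame, asg$rank)[eval_rows]
  mean(pt[keys] == pr[keys])
}

#' Compare two lineage forests for structural identity
#'
#' Two forests are identical when they partition the observation rows into
#' the same tracks, assign each track the same fate, and link corresponding
#' tracks to corresponding parents (track identifiers themselves are
#' arbitrary).
#'
#' @inheritParams assignment_accuracy
#' @return A list with logicals `same_partition`, `same_fates`,
#'   `same_parents` and `identical`.
#' @export
compare_forests <- function(tracked, reference) {
  sig <- function(forest) {
    asg <- forest$assignments
    keys <- paste(asg$trench_id, asg$frame, asg$rank)
    grp <- split(keys, paste(asg$trench_id, asg$cell_id))
    members <- vapply(grp, function(k) paste(sort(k), collapse = "|"),
                      character(1))
    first_key <- vapply(grp, function(k) sort(k)[1L], character(1))
    rec_key <- paste(forest$records$trench_id, forest$records$cell_id)
    fates <- stats::setNames(forest$records$fate, rec_key)[names(grp)]
    parents <- stats::setNames(paste(forest$records$trench_id,
                                     forest$records$parent_id),
                               rec_key)[names(grp)]
    # express parent as the parent's first row key (id-free)
    parent_first <- stats::setNames(first_key, names(grp))[parents]
    data.frame(track_sig = unname(members), first = unname(first_key),
               fate = unname(fates),
               parent_sig = ifelse(is.na(parents) |
                                     !(parents %in% names(grp)),
                                   "root", unname(parent_first)))
  }
  a <- sig(tracked); b <- sig(reference)
  a <- a[order(a$first), ]; b <- b[order(b$first), ]
  same_partition <- identical(a$track_sig[order(a$track_sig)],
                              b$track_sig[order(b$track_sig)])
  if (same_partition) {
    m <- match(a$track_sig, b$track_sig)
    same_fates <- all(a$fate == b$fate[m])
    same_parents <- all(a$parent_sig == b$parent_sig[m])
  } else {
    same_fates <- FALSE
    same_parents <- FALSE
  }
  list(same_partition = same_partition, same_fates = same_fates,
       same_parents = same_parents,
       identical = same_partition && same_fates && same_parents)
}

#' Read and write lineage record tables
#'
#' CSV schema identical to the simulator's observable ground-truth lineage
#' table, enabling direct diffing.
#'
#' @param records Lineage records data.frame.
#' @param path CSV file path.
#' @export
write_lineage <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lineage
#' @export
read_lineage <- function(path) {
  rec <- utils::read.csv(path)
  need <- c("cell_id", "trench_id", "parent_id", "birth_frame",
            "last_frame", "fate")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("lineage file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec
}
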
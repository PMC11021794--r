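#' @title Continuous-time simulation of mother-machine trenches
#'
#' @description
#' `simulate_trench()` runs one dead-end trench; `simulate_trenches()` runs
#' `params$n_trenches` independent trenches. Cells are single-file segments
#' stacked from the dead end. Each cell elongates exponentially at the
#' phase-appropriate rate (reduced by `inhibition` inside the treatment
#' window), divides when it reaches a per-cell threshold drawn at birth
#' (sizer model, lognormal threshold), lyses after an exponential waiting
#' time at the phase-appropriate rate, and is evicted when its distal edge
#' is pushed past the open end of the trench. Event scheduling is exact in
#' continuous time; discretisation happens only when observations are
#' sampled every `frame_interval` minutes with multiplicative lognormal
#' length noise. Ground truth (noise-free per-frame states, the lineage
#' forest and the event log) is returned alongside the observations and is
#' the oracle the downstream tracking and statistics modules are tested
#' against.
#'
#' @param params A [sim_params()] object.
#' @param trench_id Integer identifier stamped on the output rows.
#'
#' @return A list with elements
#' \describe{
#'   \item{observations}{data.frame with columns `trench_id`, `frame`,
#'     `time_min`, `rank` (0 = dead-end mother), `length_um`, `centroid_um`
#'     (cell centre distance from the dead end, stacked from observed
#'     lengths).}
#'   \item{truth}{list with `lineage` (`cell_id`, `trench_id`, `parent_id`,
#'     `birth_time`, `death_time`, `fate`), `events` (`trench_id`,
#'     `time_min`, `cell_id`, `event`), and `cell_frames` (noise-free
#'     per-frame state with true cell identities).}
#'   \item{params}{the input parameters.}
#' }
#' @seealso [observable_forest()], [track_trench()]
#' @examples
#' p <- sim_params(n_trenches = 1, t_total = 60, seed = 42)
#' sim <- simulate_trench(p)
#' head(sim$observations)
#' @export
simulate_trench <- function(params, trench_id = 1L) {
  validate_sim_params(params)
  withr::with_seed(params$seed, .simulate_trench_core(params, trench_id))
}

#' @rdname simulate_trench
#' @export
simulate_trenches <- function(params) {
  validate_sim_params(params)
  seeds <- withr::with_seed(params$seed,
                            sample.int(.Machine$integer.max - 1L,
                                       params$n_trenches))
  runs <- lapply(seq_len(params$n_trenches), function(i) {
    withr::with_seed(seeds[i], .simulate_trench_core(params, i))
  })
  list(
    observations = do.call(rbind, lapply(runs, `[[`, "observations")),
    truth = list(
      lineage = do.call(rbind, lapply(runs, function(r) r$truth$lineage)),
      events = do.call(rbind, lapply(runs, function(r) r$truth$events)),
      cell_frames = do.call(rbind,
                            lapply(runs, function(r) r$truth$cell_frames))
    ),
    params = params
  )
}

# threshold redraw keeps thresholds comfortably above birth length so a cell
# never divides within a fraction of a frame of being born
.draw_thr <- function(birth_len, p) {
  if (p$div_len_cv == 0) {
    thr <- p$div_len_mean
    if (thr <= 1.2 * birth_len) thr <- 1.2 * birth_len
    return(thr)
  }
  ml <- log(p$div_len_mean / sqrt(1 + p$div_len_cv^2))
  sl <- sqrt(log(1 + p$div_len_cv^2))
  for (k in 1:100) {
    thr <- stats::rlnorm(1, ml, sl)
    if (thr > 1.2 * birth_len) return(thr)
  }
  1.2 * birth_len
}

.alpha_at <- function(p, t) {
  if (t >= p$treat_start && t < p$treat_end) p$alpha0 * (1 - p$inhibition)
  else p$alpha0
}

# lysis rate in events per cell per minute
.lambda_at <- function(p, t) {
  (if (t >= p$treat_start && t < p$treat_end) p$lambda_treat else p$lambda0) / 60
}

.simulate_trench_core <- function(p, trench_id) {
  trench_id <- as.integer(trench_id)

  ## founder cells (ordered from the dead end)
  if (!is.null(p$init_lengths)) {
    len <- as.numeric(p$init_lengths)
    thr <- vapply(len, function(L) {
      if (p$alpha0 == 0) {
        ml <- log(p$div_len_mean / sqrt(1 + p$div_len_cv^2))
        sl <- sqrt(log(1 + max(p$div_len_cv, 0)^2))
        t0 <- if (p$div_len_cv == 0) p$div_len_mean else stats::rlnorm(1, ml, sl)
        if (t0 <= L)
          stop("degenerate parameters: alpha0 = 0 with a division threshold ",
               "below the initial cell length.", call. = FALSE)
        t0
      } else .draw_thr(L, p)
    }, numeric(1))
  } else {
    draw_founder <- function() {
      mb <- p$div_len_mean / 2
      lb <- if (p$div_len_cv == 0) mb else
        stats::rlnorm(1, log(mb / sqrt(1 + p$div_len_cv^2)),
                      sqrt(log(1 + p$div_len_cv^2)))
      th <- .draw_thr(lb, p)
      # stationary size distribution of an exponentially growing sizer
      # population (density ~ 1/L^2 between birth and division size)
      u <- stats::runif(1)
      c(len = lb / (1 - u * (1 - lb / th)), thr = th)
    }
    f1 <- draw_founder()
    len <- f1[["len"]]; thr <- f1[["thr"]]
    target <- p$init_fill * p$trench_len
    while (sum(len) < target) {
      fi <- draw_founder()
      if (sum(len) + fi[["len"]] > 0.95 * p$trench_len) break
      len <- c(len, fi[["len"]]); thr <- c(thr, fi[["thr"]])
    }
    if (p$alpha0 == 0 && any(len >= thr))
      stop("degenerate parameters: alpha0 = 0 with a division threshold ",
           "below the initial cell length.", call. = FALSE)
  }
  n0 <- length(len)
  id <- seq_len(n0)
  hz <- stats::rexp(n0)

  ## per-cell records (indexed by id)
  cap <- 1024L
  rec_parent <- rep(NA_integer_, cap)
  rec_birth <- rep(NA_real_, cap)
  rec_death <- rep(NA_real_, cap)
  rec_fate <- rep(NA_character_, cap)
  rec_birth[id] <- 0
  next_id <- n0 + 1L
  grow_rec <- function(need) {
    while (need > length(rec_parent)) {
      rec_parent <<- c(rec_parent, rep(NA_integer_, length(rec_parent)))
      rec_birth <<- c(rec_birth, rep(NA_real_, length(rec_birth)))
      rec_death <<- c(rec_death, rep(NA_real_, length(rec_death)))
      rec_fate <<- c(rec_fate, rep(NA_character_, length(rec_fate)))
    }
  }

  ev_time <- numeric(0); ev_cell <- integer(0); ev_type <- character(0)

  ft_seq <- seq(0, p$t_total, by = p$frame_interval)
  fi_ptr <- 1L
  obs_acc <- vector("list", length(ft_seq))
  tru_acc <- vector("list", length(ft_seq))

  emit_frame <- function(ftt, lens_t) {
    n <- length(lens_t)
    if (n == 0L) return(invisible())
    mult <- if (p$obs_noise_sd > 0) exp(stats::rnorm(n, 0, p$obs_noise_sd))
            else rep(1, n)
    lo <- lens_t * mult
    fr <- as.integer(round(ftt / p$frame_interval))
    obs_acc[[fi_ptr]] <<- list(frame = rep(fr, n), time = rep(ftt, n),
                               rank = 0:(n - 1L), len = lo,
                               cen = cumsum(lo) - lo / 2)
    tru_acc[[fi_ptr]] <<- list(frame = rep(fr, n), time = rep(ftt, n),
                               rank = 0:(n - 1L), cell = id,
                               len = lens_t, cen = cumsum(lens_t) - lens_t / 2)
  }

  bounds <- c(p$treat_start, p$treat_end)
  t <- 0
  repeat {
    if (length(len) == 0L) break  # trench extinct
    a <- .alpha_at(p, t)
    lam <- .lambda_at(p, t)
    td <- if (a > 0) t + pmax(log(thr / len), 0) / a else rep(Inf, length(len))
    tl <- if (lam > 0) t + hz / lam else rep(Inf, length(len))
    tev <- if (a > 0 && sum(len) < p$trench_len)
      t + log(p$trench_len / sum(len)) / a else Inf
    nb <- bounds[bounds > t + 1e-9]
    tb <- if (length(nb)) min(nb) else Inf
    cand <- c(div = min(td), lys = min(tl), ev = tev, phase = tb)
    te <- min(cand, p$t_total)
    type <- if (te >= p$t_total) "end" else names(cand)[which.min(cand)]
    if (type == "end") te <- p$t_total

    while (fi_ptr <= length(ft_seq) && ft_seq[fi_ptr] <= te + 1e-9) {
      ftt <- ft_seq[fi_ptr]
      emit_frame(ftt, len * exp(a * (ftt - t)))
      fi_ptr <- fi_ptr + 1L
    }

    len <- len * exp(a * (te - t))
    hz <- hz - lam * (te - t)
    t <- te

    if (type == "end") break
    if (type == "phase") next
    if (type == "div") {
      i <- which.min(td)
      len[i] <- thr[i]
      f <- min(max(stats::rnorm(1, 0.5, p$div_asym_sd), 0.25), 0.75)
      l1 <- f * len[i]; l2 <- len[i] - l1
      grow_rec(next_id + 1L)
      id1 <- next_id; id2 <- next_id + 1L; next_id <- next_id + 2L
      rec_parent[c(id1, id2)] <- id[i]
      rec_birth[c(id1, id2)] <- t
      rec_death[id[i]] <- t; rec_fate[id[i]] <- "divided"
      ev_time <- c(ev_time, t); ev_cell <- c(ev_cell, id[i])
      ev_type <- c(ev_type, "division")
      thr1 <- .draw_thr(l1, p); hz1 <- stats::rexp(1)
      thr2 <- .draw_thr(l2, p); hz2 <- stats::rexp(1)
      keep_pre <- seq_len(i - 1L)
      keep_post <- if (i < length(len)) (i + 1L):length(len) else integer(0)
      id <- c(id[keep_pre], id1, id2, id[keep_post])
      len <- c(len[keep_pre], l1, l2, len[keep_post])
      thr <- c(thr[keep_pre], thr1, thr2, thr[keep_post])
      hz <- c(hz[keep_pre], hz1, hz2, hz[keep_post])
    } else if (type == "lys") {
      i <- which.min(tl)
      rec_death[id[i]] <- t; rec_fate[id[i]] <- "lysed"
      ev_time <- c(ev_time, t); ev_cell <- c(ev_cell, id[i])
      ev_type <- c(ev_type, "lysis")
      id <- id[-i]; len <- len[-i]; thr <- thr[-i]; hz <- hz[-i]
    } else if (type == "ev") {
      i <- length(len)  # only the distal-most cell can protrude
      rec_death[id[i]] <- t; rec_fate[id[i]] <- "evicted"
      ev_time <- c(ev_time, t); ev_cell <- c(ev_cell, id[i])
      ev_type <- c(ev_type, "eviction")
      id <- id[-i]; len <- len[-i]; thr <- thr[-i]; hz <- hz[-i]
    }
  }

  if (length(id)) {
    rec_death[id] <- p$t_total
    rec_fate[id] <- "censored"
  }

  n_cells <- next_id - 1L
  cat_fields <- function(acc, field) unlist(lapply(acc, `[[`, field),
                                            use.names = FALSE)
  obs <- data.frame(
    trench_id = trench_id,
    frame = as.integer(cat_fields(obs_acc, "frame")),
    time_min = cat_fields(obs_acc, "time"),
    rank = as.integer(cat_fields(obs_acc, "rank")),
    length_um = cat_fields(obs_acc, "len"),
    centroid_um = cat_fields(obs_acc, "cen")
  )
  cf <- data.frame(
    trench_id = trench_id,
    frame = as.integer(cat_fields(tru_acc, "frame")),
    time_min = cat_fields(tru_acc, "time"),
    rank = as.integer(cat_fields(tru_acc, "rank")),
    cell_id = as.integer(cat_fields(tru_acc, "cell")),
    length_true_um = cat_fields(tru_acc, "len"),
    centroid_true_um = cat_fields(tru_acc, "cen")
  )
  lineage <- data.frame(
    cell_id = seq_len(n_cells),
    trench_id = trench_id,
    parent_id = rec_parent[seq_len(n_cells)],
    birth_time = rec_birth[seq_len(n_cells)],
    death_time = rec_death[seq_len(n_cells)],
    fate = rec_fate[seq_len(n_cells)]
  )
  events <- data.frame(
    trench_id = if (length(ev_time)) trench_id else integer(0),
    time_min = ev_time, cell_id = ev_cell, event = ev_type
  )
  list(observations = obs,
       truth = list(lineage = lineage, events = events, cell_frames = cf),
       params = p)
}

#' Collapse simulator ground truth to its observable lineage forest
#'
#' Exact continuous-time dynamics can create cells that are never observed:
#' a daughter born and evicted between two consecutive frames leaves no
#' trace in the sampled data. No tracker can recover such cells, so
#' tracking is evaluated against the *observable* forest: unobserved cells
#' are dropped, a division whose second daughter was never observed is
#' collapsed into a single continuing track, and a division with no
#' observed daughter is reported as an eviction of the parent (the parent
#' simply vanishes at the open end between frames).
#'
#' A second observability limit concerns fates: a distal-most cell that
#' lyses while the column reaches close to the open end leaves exactly the
#' same observable trace as an eviction (in neither case do surviving
#' cells move). The pipeline's declared fate taxonomy resolves this band
#' to `evicted` (see [classify_fate()]); passing `eviction_margin` applies
#' the same convention to the reference forest so that tracking is
#' compared at the information ceiling. With `eviction_margin = NULL` the
#' exact simulator fates are kept.
#'
#' @param truth The `truth` element returned by [simulate_trench()] or
#'   [simulate_trenches()].
#' @param eviction_margin Optional margin (µm) for resolving the ambiguous
#'   distal lysis band, as in [track_trench()].
#' @param trench_len Trench length (µm), used with `eviction_margin`.
#' @return A list with `records` (schema of [track_trench()] records:
#'   `cell_id`, `trench_id`, `parent_id`, `birth_frame`, `last_frame`,
#'   `fate`) and `assignments` (`trench_id`, `frame`, `rank`, `cell_id`
#'   linking every observation row to its track).
#' @export
observable_forest <- function(truth, eviction_margin = NULL,
                              trench_len = 75) {
  lin <- truth$lineage
  cf <- truth$cell_frames
  rec_list <- list()
  asg_list <- list()
  for (tr in unique(lin$trench_id)) {
    ltr <- lin[lin$trench_id == tr, , drop = FALSE]
    ctr <- cf[cf$trench_id == tr, , drop = FALSE]
    first_fr <- tapply(ctr$frame, ctr$cell_id, min)
    last_fr <- tapply(ctr$frame, ctr$cell_id, max)
    observed <- as.integer(names(first_fr))
    kids <- split(ltr$cell_id, factor(ltr$parent_id, levels = ltr$cell_id))

    track_of <- integer(0)  # cell_id -> track id (id of first cell in chain)
    track_parent <- integer(0)  # track id -> parent track id (NA root)
    ord <- ltr$cell_id[order(ltr$birth_time, ltr$cell_id)]
    fate_of_cell <- stats::setNames(ltr$fate, ltr$cell_id)
    for (cid in ord) {
      if (!(cid %in% observed)) next
      key <- as.character(cid)
      if (!is.null(track_of[key]) && !is.na(track_of[key])) next
      par <- ltr$parent_id[ltr$cell_id == cid]
      if (is.na(par)) {
        track_of[key] <- cid
        track_parent[as.character(cid)] <- NA_integer_
      } else {
        sib <- setdiff(kids[[as.character(par)]], cid)
        sib_obs <- length(sib) && sib %in% observed
        par_track <- track_of[as.character(par)]
        if (is.na(par_track))  # parent itself unobserved; treat as root
          par_track <- NA_integer_
        if (sib_obs || is.na(par_track)) {
          track_of[key] <- cid
          track_parent[as.character(cid)] <-
            if (is.na(par_track)) NA_integer_ else par_track
        } else {
          track_of[key] <- par_track  # unobserved sibling: continuation
        }
      }
    }

    # track-level summaries
    cells_by_track <- split(as.integer(names(track_of)), track_of)
    recs <- lapply(names(cells_by_track), function(tk) {
      cells <- cells_by_track[[tk]]
      bt <- ltr$birth_time[match(cells, ltr$cell_id)]
      terminal <- cells[which.max(bt)]
      fate <- fate_of_cell[[as.character(terminal)]]
      if (fate == "divided") {
        k <- kids[[as.character(terminal)]]
        k_obs <- k[k %in% observed]
        if (length(k_obs) == 0L) {
          kf <- fate_of_cell[as.character(k)]
          fate <- if (any(kf == "evicted")) "evicted" else "lysed"
        }
        # one observed daughter would have continued the chain, so terminal
        # with fate "divided" here implies both daughters observed
      }
      data.frame(cell_id = as.integer(tk), trench_id = tr,
                 parent_id = track_parent[[tk]],
                 birth_frame = min(first_fr[as.character(cells)]),
                 last_frame = max(last_fr[as.character(cells)]),
                 fate = fate)
    })
    rec_list[[length(rec_list) + 1L]] <- do.call(rbind, recs)
    asg_list[[length(asg_list) + 1L]] <- data.frame(
      trench_id = tr, frame = ctr$frame, rank = ctr$rank,
      cell_id = track_of[as.character(ctr$cell_id)]
    )
  }
  records <- do.call(rbind, rec_list)
  records <- records[order(records$trench_id, records$birth_frame,
                           records$cell_id), , drop = FALSE]
  rownames(records) <- NULL
  asg <- do.call(rbind, asg_list)

  if (!is.null(eviction_margin)) {
    # resolve the ambiguous distal lysis band to "evicted", mirroring the
    # tracker's taxonomy: a lysed cell with no surviving distal neighbour
    # whose distal edge lay within the margin of the open end leaves the
    # same observable trace as an eviction
    edge <- stats::setNames(cf$centroid_true_um + cf$length_true_um / 2,
                            paste(cf$trench_id, cf$frame, cf$rank))
    trk_rank <- stats::setNames(asg$rank,
                                paste(asg$trench_id, asg$cell_id,
                                      asg$frame))
    for (k in which(records$fate == "lysed")) {
      tr_k <- records$trench_id[k]
      f_k <- records$last_frame[k]
      r <- trk_rank[[paste(tr_k, records$cell_id[k], f_k)]]
      if (edge[[paste(tr_k, f_k, r)]] < trench_len - eviction_margin)
        next
      distal_ids <- cf$cell_id[cf$trench_id == tr_k & cf$frame == f_k &
                                 cf$rank > r]
      next_ids <- cf$cell_id[cf$trench_id == tr_k & cf$frame == f_k + 1L]
      if (!any(distal_ids %in% next_ids)) records$fate[k] <- "evicted"
    }
  }
  list(records = records, assignments = asg)
}

#' Well-mixed agent-based population simulation
#'
#' Simulates a batch-culture population under the same single-cell laws as
#' the trench simulator (exponential elongation with treatment-window
#' inhibition, sizer division, Poisson lysis) but without spatial
#' confinement: no trench, no eviction. Used to cross-validate the
#' closed-form birth-death solution of [predict_ratio()].
#'
#' @param params A [sim_params()] object (geometry fields are ignored).
#' @param n0 Initial number of cells (>= 1). Founders get random sizes and
#'   cell-cycle phases, approximating a desynchronised steady-state culture.
#' @return data.frame with `time_min`, `n_cells` and `total_length_um`
#'   sampled every `frame_interval` minutes.
#' @examples
#' p <- sim_params(t_total = 60, seed = 7)
#' tail(simulate_population(p, n0 = 20))
#' @export
simulate_population <- function(params, n0) {
  validate_sim_params(params)
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 1)
    stop("`n0` must be >= 1.", call. = FALSE)
  n0 <- as.integer(n0)
  withr::with_seed(params$seed, .simulate_population_core(params, n0))
}

.simulate_population_core <- function(p, n0) {
  mb <- p$div_len_mean / 2
  lb <- if (p$div_len_cv == 0) rep(mb, n0) else
    stats::rlnorm(n0, log(mb / sqrt(1 + p$div_len_cv^2)),
                  sqrt(log(1 + p$div_len_cv^2)))
  thr <- vapply(lb, .draw_thr, numeric(1), p = p)
  # stationary size distribution (see draw_founder in the trench simulator)
  u <- stats::runif(n0)
  len <- lb / (1 - u * (1 - lb / thr))
  hz <- stats::rexp(n0)

  ft_seq <- seq(0, p$t_total, by = p$frame_interval)
  fi_ptr <- 1L
  out_n <- integer(length(ft_seq)); out_b <- numeric(length(ft_seq))

  bounds <- c(p$treat_start, p$treat_end)
  t <- 0
  repeat {
    n <- length(len)
    a <- .alpha_at(p, t); lam <- .lambda_at(p, t)
    td <- if (a > 0 && n) t + pmax(log(thr / len), 0) / a else rep(Inf, max(n, 1))
    tl <- if (lam > 0 && n) t + hz / lam else rep(Inf, max(n, 1))
    nb <- bounds[bounds > t + 1e-9]
    tb <- if (length(nb)) min(nb) else Inf
    cand <- c(div = if (n) min(td) else Inf,
              lys = if (n) min(tl) else Inf, phase = tb)
    te <- min(cand, p$t_total)
    type <- if (te >= p$t_total) "end" else names(cand)[which.min(cand)]
    if (type == "end") te <- p$t_total

    while (fi_ptr <= length(ft_seq) && ft_seq[fi_ptr] <= te + 1e-9) {
      g <- exp(a * (ft_seq[fi_ptr] - t))
      out_n[fi_ptr] <- n
      out_b[fi_ptr] <- sum(len) * g
      fi_ptr <- fi_ptr + 1L
    }
    if (n) {
      len <- len * exp(a * (te - t))
      hz <- hz - lam * (te - t)
    }
    t <- te
    if (type == "end") break
    if (type == "phase") next
    if (type == "div") {
      i <- which.min(td)
      len[i] <- thr[i]
      f <- min(max(stats::rnorm(1, 0.5, p$div_asym_sd), 0.25), 0.75)
      l1 <- f * len[i]; l2 <- len[i] - l1
      thr1 <- .draw_thr(l1, p); thr2 <- .draw_thr(l2, p)
      len <- c(len[-i], l1, l2)
      thr <- c(thr[-i], thr1, thr2)
      hz <- c(hz[-i], stats::rexp(2))
    } else if (type == "lys") {
      i <- which.min(tl)
      len <- len[-i]; thr <- thr[-i]; hz <- hz[-i]
    }
  }
  data.frame(time_min = ft_seq[seq_len(fi_ptr - 1L)],
             n_cells = out_n[seq_len(fi_ptr - 1L)],
             total_length_um = out_b[seq_len(fi_ptr - 1L)])
}

#' Read and write trench observation tables
#'
#' Tidy CSV with one row per segmented cell per frame; the dialect produced
#' by [simulate_trench()] and consumed by [track_trench()].
#'
#' @param observations Observation data.frame.
#' @param path CSV file path.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path)
  need <- c("trench_id", "frame", "time_min", "rank", "length_um",
            "centroid_um")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  obs
}
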
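# Value-modulated rise-to-threshold simulator: generates whole chamber
# sessions (trajectory, egg events, latent decision variable) with seeded
# randomness.  The latent variable is a linear drift-diffusion with
# substrate-dependent drift, exponential relative-value re-adaptation and
# an absorbing threshold; locomotion is a two-state walk/pause Markov
# process with reflective chamber walls.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# reflect an unbounded coordinate into [lo, hi] (triangle-wave folding)
fold_reflect <- function(z, lo, hi) {
  L <- hi - lo
  zz <- (z - lo) %% (2 * L)
  lo + pmin(zz, 2 * L - zz)
}

#' Effective drift rate along a substrate track
#'
#' Implements the relative-value re-adaptation rule: on the favoured
#' substrate the effective drift is `drift_rate_high` and the adaptation
#' clock resets; on the disfavoured substrate the drift relaxes
#' exponentially from `drift_rate_low` toward `drift_rate_high` with
#' timescale `value_adapt_tau`, measured from the last visit to the
#' favoured substrate.
#'
#' @param substrate_track Character vector of per-frame substrate labels.
#' @param params A [drift_params()].
#' @param favoured Label of the higher-relative-value substrate, or `NA`
#'   when the two options are equivalent (constant `drift_rate_high`).
#' @param disfavoured Label of the other substrate (used to validate the
#'   track; defaults to any non-favoured label present).
#' @param dt Frame interval in seconds.
#' @param t0 Time of the first frame.
#' @param last_favoured_t Time of the most recent favoured visit before
#'   the track starts; defaults to `t0` (session start is the reference
#'   when the favoured substrate has never been visited).
#' @return Numeric vector of per-frame effective drift rates (latent
#'   units per second), with the final adaptation-clock state in
#'   attribute `"last_favoured_t"`.
#' @export
simulate_value_trace <- function(substrate_track, params, favoured,
                                 disfavoured = NULL, dt = 0.5, t0 = 0,
                                 last_favoured_t = t0) {
  stopifnot(inherits(params, "drift_params"))
  if (length(substrate_track) == 0) stop("substrate_track must be non-empty")
  hi <- params$drift_rate_high
  if (is.na(favoured)) {
    out <- rep(hi, length(substrate_track))
    attr(out, "last_favoured_t") <- last_favoured_t
    return(out)
  }
  known <- c(favoured, disfavoured)
  if (!is.null(disfavoured)) {
    bad <- setdiff(unique(substrate_track), known)
    if (length(bad))
      stop("unknown substrate label: ", paste(bad, collapse = ", "))
  }
  tt <- t0 + (seq_along(substrate_track) - 1) * dt
  fav <- substrate_track == favoured
  last <- cummax(ifelse(fav, tt, -Inf))
  last <- pmax(last, last_favoured_t)
  delta <- tt - last
  lo <- params$drift_rate_low
  out <- ifelse(fav, hi, hi - (hi - lo) * exp(-delta / params$value_adapt_tau))
  attr(out, "last_favoured_t") <- last[length(last)]
  out
}

# one vectorised locomotion segment; returns positions and updated state
gen_loco_segment <- function(k, st, loco, chamber, dt) {
  w <- logical(k)
  pos <- 1L
  cur <- st$walking
  while (pos <= k) {
    p <- if (cur) loco$p_walk_to_pause else loco$p_pause_to_walk
    run <- stats::rgeom(1L, p) + 1L
    end <- min(k, pos + run - 1L)
    w[pos:end] <- cur
    if (pos + run - 1L <= k) cur <- !cur
    pos <- end + 1L
  }
  h <- st$heading + cumsum(stats::rnorm(k, 0, loco$turn_sd_rad))
  step <- loco$walk_speed_mm_s * dt
  x <- fold_reflect(st$x + cumsum(step * cos(h) * w), 0, chamber$width)
  y <- fold_reflect(st$y + cumsum(step * sin(h) * w), 0, chamber$height)
  list(x = x, y = y, walking = w,
       state = list(x = x[k], y = y[k], heading = h[k], walking = cur))
}

#' Simulate one egg-laying session in a two-substrate chamber
#'
#' Runs the full generative model: the fly alternates walking bouts and
#' pauses; periodically it ovulates (a standstill of roughly
#' `ovulation_duration_mean` seconds), after which the latent decision
#' variable integrates the substrate-dependent drift plus diffusion noise
#' until it crosses threshold (abdomen bend); the egg is deposited
#' `bend_to_deposit_delay` seconds later, deferred while the fly is on
#' the plastic barrier strip, and an inter-egg refractory period follows.
#' Identical seeds reproduce identical sessions.
#'
#' @param params A [drift_params()].
#' @param chamber A [chamber_spec()].
#' @param duration Session duration in seconds.
#' @param seed Integer seed.
#' @param locomotion A [locomotion_params()].
#' @param hold_at Optional `c(x, y)` position; when given the fly is held
#'   stationary there for the whole session (no locomotion).
#' @return A `sim_session` object: list with `trajectory`
#'   (`t_s, x_mm, y_mm`), `labels` (per-frame substrate), `walking`,
#'   `latent_trace`, `value_trace`, `egg_events` (one row per deposited
#'   egg with the annotated event times), plus the generating parameter
#'   objects and seed.
#' @export
simulate_session <- function(params, chamber, duration, seed,
                             locomotion = locomotion_params(),
                             hold_at = NULL) {
  stopifnot(inherits(params, "drift_params"), inherits(chamber, "chamber_spec"))
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a positive number of seconds")
  if (params$noise_sd == 0 && params$drift_rate_high <= 0)
    stop("unreachable threshold: zero noise with non-positive drift")
  dt <- 1 / chamber$frame_rate
  n <- floor(duration / dt)
  if (n < 10) stop("duration too short for a session")
  fav <- favoured_substrate(chamber)
  fav_is_lower <- !is.na(fav) && fav == chamber$labels[["lower"]]
  tvec <- (seq_len(n) - 1) * dt

  with_seed(seed, {
    x <- numeric(n); y <- numeric(n); walking <- logical(n)
    latent <- rep(params$reset_level, n)
    st <- list(x = stats::runif(1, 0, chamber$width),
               y = stats::runif(1, 0, chamber$height),
               heading = stats::runif(1, 0, 2 * pi), walking = TRUE)
    if (!is.null(hold_at)) { st$x <- hold_at[1]; st$y <- hold_at[2] }
    g <- 0L  # frames generated so far
    # searching flies walk with only brief pauses; the walk/pause chain
    # switches parameter sets with the behavioural phase
    loco_search <- locomotion
    loco_search$p_walk_to_pause <- locomotion$search_p_walk_to_pause
    loco_search$p_pause_to_walk <- locomotion$search_p_pause_to_walk
    cur_loco <- locomotion

    gen_upto <- function(j) {
      if (j <= g) return(invisible())
      idx <- (g + 1L):j
      if (is.null(hold_at)) {
        seg <- gen_loco_segment(length(idx), st, cur_loco, chamber, dt)
        x[idx] <<- seg$x; y[idx] <<- seg$y; walking[idx] <<- seg$walking
        st <<- seg$state
      } else {
        x[idx] <<- st$x; y[idx] <<- st$y; walking[idx] <<- FALSE
      }
      g <<- j
      invisible()
    }
    # standstill: position frozen at the last pre-standstill frame; any
    # frames speculatively generated beyond it are discarded (g rewinds)
    freeze <- function(i0, j) {
      px <- if (i0 > 1L) x[i0 - 1L] else st$x
      py <- if (i0 > 1L) y[i0 - 1L] else st$y
      x[i0:j] <<- px; y[i0:j] <<- py; walking[i0:j] <<- FALSE
      st <<- list(x = px, y = py, heading = st$heading, walking = TRUE)
      g <<- j
      invisible()
    }
    fav_frames <- function(i0, j) {
      if (is.na(fav)) return(rep(FALSE, j - i0 + 1))
      lower <- y[i0:j] <= chamber$midline_y
      if (fav_is_lower) lower else !lower
    }
    # adaptation clock: time of last favoured visit (session start = 0 ref)
    carry <- 0
    bump_carry <- function(i0, j) {
      ft <- tvec[i0:j][fav_frames(i0, j)]
      if (length(ft)) carry <<- max(carry, ft[length(ft)])
      invisible()
    }

    nr <- round(params$inter_egg_refractory / dt)
    nd <- round(params$bend_to_deposit_delay / dt)
    gshape <- 8  # Gamma shape for ovulation durations (strictly positive, unimodal)
    eggs <- list()
    i <- 1L
    repeat {
      if (nr > 0) {
        j <- min(n, i + nr - 1L)
        gen_upto(j); bump_carry(i, j); i <- j + 1L
        if (i > n) break
      }
      ovu_dur <- stats::rgamma(1, shape = gshape,
                               rate = gshape / params$ovulation_duration_mean)
      no <- max(1L, round(ovu_dur / dt))
      ovu_start_t <- tvec[i] - dt
      j <- min(n, i + no - 1L)
      freeze(i, j); bump_carry(i, j); i <- j + 1L
      if (i > n) break
      search_start_t <- tvec[i] - dt
      A <- params$reset_level
      ib <- NA_integer_
      cur_loco <- loco_search
      st$walking <- TRUE
      while (i <= n) {
        j <- min(n, i + 239L)
        gen_upto(j)
        k <- j - i + 1L
        labs <- ifelse(y[i:j] <= chamber$midline_y,
                       chamber$labels[["lower"]], chamber$labels[["upper"]])
        dr <- simulate_value_trace(labs, params, fav, dt = dt,
                                   t0 = tvec[i], last_favoured_t = carry)
        dA <- dr * dt
        if (params$noise_sd > 0)
          dA <- dA + stats::rnorm(k, 0, params$noise_sd * sqrt(dt))
        Avec <- A + cumsum(dA)
        cr <- match(TRUE, Avec >= params$threshold_level - 1e-9)
        if (!is.na(cr)) {
          latent[i:(i + cr - 1L)] <- Avec[seq_len(cr)]
          bump_carry(i, i + cr - 1L)
          ib <- i + cr - 1L
          i <- ib + 1L
          break
        }
        latent[i:j] <- Avec
        A <- Avec[k]
        carry <- attr(dr, "last_favoured_t")
        i <- j + 1L
      }
      cur_loco <- locomotion
      if (is.na(ib)) break  # session ended mid-search; incomplete egg dropped
      dep <- ib + nd
      if (dep > n) { gen_upto(n); break }
      # the egg-deposition motor programme is stationary: the fly stands
      # at the bend location until the egg is deposited
      if (dep >= ib + 1L) { freeze(ib + 1L, dep); bump_carry(ib + 1L, dep) }
      # no eggs on the plastic barrier: defer deposition until off the strip
      while (abs(y[dep] - chamber$midline_y) <= chamber$barrier_halfwidth) {
        if (dep + 1L > n) { dep <- NA_integer_; break }
        dep <- dep + 1L
        gen_upto(dep); bump_carry(dep, dep)
      }
      if (is.na(dep)) { gen_upto(n); break }
      sub <- if (y[dep] <= chamber$midline_y) chamber$labels[["lower"]]
             else chamber$labels[["upper"]]
      eggs[[length(eggs) + 1L]] <- data.frame(
        ovulation_start_s = max(0, ovu_start_t),
        search_start_s = max(0, search_start_t),
        bend_complete_s = tvec[ib],
        deposition_s = tvec[dep],
        substrate = sub,
        stringsAsFactors = FALSE)
      i <- dep + 1L
      if (i > n) break
    }
    gen_upto(n)

    labels <- ifelse(y <= chamber$midline_y,
                     chamber$labels[["lower"]], chamber$labels[["upper"]])
    value <- simulate_value_trace(
      labels, params, fav,
      disfavoured = setdiff(unname(chamber$labels), fav),
      dt = dt, t0 = 0)
    egg_df <- if (length(eggs)) do.call(rbind, eggs) else
      data.frame(ovulation_start_s = numeric(0), search_start_s = numeric(0),
                 bend_complete_s = numeric(0), deposition_s = numeric(0),
                 substrate = character(0), stringsAsFactors = FALSE)
    egg_df <- cbind(egg_id = seq_len(nrow(egg_df)), egg_df)
    structure(list(
      trajectory = data.frame(t_s = tvec, x_mm = x, y_mm = y),
      labels = labels,
      walking = walking,
      latent_trace = data.frame(t_s = tvec, A = latent),
      value_trace = data.frame(t_s = tvec, drift_eff = as.numeric(value)),
      egg_events = egg_df,
      params = params, chamber = chamber, locomotion = locomotion,
      rng_seed = seed, favoured = fav
    ), class = "sim_session")
  })
}

#' @export
print.sim_session <- function(x, ...) {
  cat("<sim_session>", nrow(x$trajectory), "frames,",
      nrow(x$egg_events), "eggs, favoured =",
      ifelse(is.na(x$favoured), "(none)", x$favoured),
      ", seed =", x$rng_seed, "\n")
  invisible(x)
}

#' Per-frame locomotor speed of a trajectory
#'
#' Displacement between consecutive frames times the frame rate; the
#' first frame gets speed 0.
#'
#' @param trajectory Data frame with `t_s`, `x_mm`, `y_mm`.
#' @param frame_rate Frames per second.
#' @return Numeric vector of speeds in mm/s.
#' @export
trajectory_speed <- function(trajectory, frame_rate = 2) {
  n <- nrow(trajectory)
  if (n == 0) return(numeric(0))
  d <- sqrt(diff(trajectory$x_mm)^2 + diff(trajectory$y_mm)^2)
  c(0, d * frame_rate)
}

#' Simulate a pooled-fluorescence recording from a latent trace
#'
#' F_cell(t) = baseline_F * (1 + gain * A(t)) + background_F + drift +
#' noise and F_background(t) = background_F + noise, sampled at the
#' volumetric imaging rate with each volume timestamped at half-volume
#' completion.  Seeded for reproducibility.
#'
#' @param latent Data frame with columns `t_s` and `A` on a uniform grid
#'   (e.g. `sim_session$latent_trace`).
#' @param spec A [fluorescence_sim_spec()].
#' @param seed Integer seed.
#' @return Data frame `volume_t_s, F_cell, F_background`.
#' @export
simulate_fluorescence <- function(latent, spec, seed) {
  stopifnot(inherits(spec, "fluor_sim_spec"))
  tt <- latent$t_s
  if (length(tt) < 2) stop("latent trace too short")
  grid_dt <- tt[2] - tt[1]
  if (spec$volume_rate > 1 / grid_dt + 1e-9)
    stop("volume_rate exceeds the latent grid rate")
  vt <- seq(0.5 / spec$volume_rate, max(tt), by = 1 / spec$volume_rate)
  idx <- findInterval(vt, tt)
  A <- latent$A[pmax(idx, 1L)]
  with_seed(seed, {
    m <- length(vt)
    drift <- if (spec$baseline_drift_sd > 0)
      cumsum(stats::rnorm(m, 0, spec$baseline_drift_sd)) else numeric(m)
    noise1 <- if (spec$photon_noise_sd > 0)
      stats::rnorm(m, 0, spec$photon_noise_sd) else numeric(m)
    noise2 <- if (spec$photon_noise_sd > 0)
      stats::rnorm(m, 0, spec$photon_noise_sd) else numeric(m)
    data.frame(volume_t_s = vt,
               F_cell = spec$baseline_F * (1 + spec$gain * A) +
                 spec$background_F + drift + noise1,
               F_background = spec$background_F + noise2)
  })
}

#' Synthetic synapse table with a planted recurrent motif
#'
#' Builds a connectome-style synapse table containing a planted motif
#' around two seed-class (`oviEN`) cells, one per hemisphere: three
#' single-intermediary cross-hemisphere loops (one `groupG`, one
#' `groupU`, one `oviIN` intermediary, each receiving from and projecting
#' to the seed class on both sides), a reciprocal `oviIN`-`oviIN` pair,
#' and one-way `oviEN` to `oviDN` edges.  All planted edges have synapse
#' counts in `planted_weights`; they are embedded among at least
#' `n_distractors` random cells whose edges have counts 1-9, so a
#' ten-synapse threshold isolates the plant exactly.  One planted edge is
#' split across two rows to exercise duplicate aggregation.
#'
#' @param seed Integer seed.
#' @param n_distractors Number of random background cells.
#' @param n_distractor_edges Number of random background edges.
#' @param planted_weights Range of planted synapse counts.
#' @return List with `table` (the synapse data frame:
#'   `pre_id, post_id, pre_class, post_class, pre_side, post_side,
#'   n_synapses`) and `truth` (planted seed cells, intermediaries,
#'   reciprocal pair and edges).
#' @export
make_synapse_fixture <- function(seed, n_distractors = 200,
                                 n_distractor_edges = 600,
                                 planted_weights = c(10, 15)) {
  with_seed(seed, {
    cells <- data.frame(
      id = c("oviDN_L", "oviDN_R", "oviEN_L", "oviEN_R",
             "grpG_R", "grpU_L", "oviIN_L", "oviIN_R",
             sprintf("dist%03d", seq_len(n_distractors))),
      class = c("oviDN", "oviDN", "oviEN", "oviEN",
                "groupG", "groupU", "oviIN", "oviIN",
                rep("other", n_distractors)),
      side = c("L", "R", "L", "R", "R", "L", "L", "R",
               sample(c("L", "R"), n_distractors, replace = TRUE)),
      stringsAsFactors = FALSE)
    pw <- function(k) sample(seq(planted_weights[1], planted_weights[2]), k,
                             replace = TRUE)
    intermediaries <- c("grpG_R", "grpU_L", "oviIN_L")
    pre <- character(0); post <- character(0)
    for (x in intermediaries) {
      pre <- c(pre, "oviEN_L", x, "oviEN_R", x)
      post <- c(post, x, "oviEN_R", x, "oviEN_L")
    }
    pre <- c(pre, "oviIN_L", "oviIN_R", "oviEN_L", "oviEN_R")
    post <- c(post, "oviIN_R", "oviIN_L", "oviDN_L", "oviDN_R")
    planted <- data.frame(pre_id = pre, post_id = post,
                          n_synapses = pw(length(pre)),
                          stringsAsFactors = FALSE)
    # split the first planted edge into two rows (same total)
    w1 <- planted$n_synapses[1]
    split_rows <- data.frame(pre_id = rep(planted$pre_id[1], 2),
                             post_id = rep(planted$post_id[1], 2),
                             n_synapses = c(w1 - w1 %/% 2, w1 %/% 2),
                             stringsAsFactors = FALSE)
    planted_rows <- rbind(split_rows, planted[-1, ])

    # distinct random ordered pairs, none duplicating a planted pair
    npair <- nrow(cells)
    key_planted <- paste(planted$pre_id, planted$post_id)
    picked <- character(0)
    rows <- list()
    while (length(rows) < n_distractor_edges) {
      a <- sample.int(npair, n_distractor_edges, replace = TRUE)
      b <- sample.int(npair, n_distractor_edges, replace = TRUE)
      ok <- a != b
      k <- paste(cells$id[a], cells$id[b])
      ok <- ok & !(k %in% c(key_planted, picked))
      ok <- ok & !duplicated(k)
      a <- a[ok]; b <- b[ok]; k <- k[ok]
      take <- seq_len(min(length(a), n_distractor_edges - length(rows)))
      for (j in take)
        rows[[length(rows) + 1L]] <- c(cells$id[a[j]], cells$id[b[j]])
      picked <- c(picked, k[take])
    }
    dmat <- do.call(rbind, rows)
    distractor <- data.frame(pre_id = dmat[, 1], post_id = dmat[, 2],
                             n_synapses = sample(1:9, nrow(dmat),
                                                 replace = TRUE),
                             stringsAsFactors = FALSE)
    tab <- rbind(planted_rows, distractor)
    cls <- stats::setNames(cells$class, cells$id)
    sde <- stats::setNames(cells$side, cells$id)
    tab <- data.frame(pre_id = tab$pre_id, post_id = tab$post_id,
                      pre_class = unname(cls[tab$pre_id]),
                      post_class = unname(cls[tab$post_id]),
                      pre_side = unname(sde[tab$pre_id]),
                      post_side = unname(sde[tab$post_id]),
                      n_synapses = tab$n_synapses,
                      stringsAsFactors = FALSE)
    tab <- tab[sample.int(nrow(tab)), ]
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(
           seed_class = "oviEN",
           seed_cells = c(L = "oviEN_L", R = "oviEN_R"),
           intermediaries = data.frame(
             id = intermediaries,
             class = c("groupG", "groupU", "oviIN"),
             stringsAsFactors = FALSE),
           reciprocal_pair = c("oviIN_L", "oviIN_R"),
           planted_edges = planted))
  })
}
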
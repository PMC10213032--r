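#' Sample spontaneous-curvature turning angles
#'
#' Turning angles of a growing tip, applied once per `step_length` of
#' advance, follow the density
#' \eqn{p(\theta) \propto (\theta_0 - \theta)^a \, (\theta + \theta_0)^b}
#' on \eqn{(-\theta_0, \theta_0)}. This is a shifted Beta law: with
#' \eqn{U \sim Beta(b+1, a+1)}, \eqn{\theta = \theta_0 (2U - 1)}, giving
#' the closed-form mean \eqn{\theta_0 (b - a)/(a + b + 2)}. Chirality is
#' broken when `a != b`; with `a == b` the mean turning angle is zero and
#' growth has no preferred handedness.
#'
#' @param n number of draws.
#' @param params a [curvature_params()] block.
#' @return Angles in radians, strictly inside `(-theta0, theta0)`.
#' @examples
#' mean(sample_curvature_angle(1e4, curvature_params(a = 2, b = 1, theta0 = 1)))
#' @export
sample_curvature_angle <- function(n, params) {
  stopifnot(inherits(params, "curvature_params"))
  u <- stats::rbeta(n, params$b + 1, params$a + 1)
  params$theta0 * (2 * u - 1)
}

#' Tip elongation velocity ramp
#'
#' Hyphal tips accelerate from rest to an asymptotic velocity of
#' 4.5 µm min^-1 (270 µm h^-1). The ramp is
#' \eqn{v(t) = v_\infty (1 - 2^{-t/\tau})} with the timescale \eqn{\tau}
#' fixed by the constraint that the cumulative length reaches 500 µm after
#' 7 h of growth (\eqn{\tau \approx 7.47} h), the time at which hyphae
#' first exceed the lateral dominance length and densification can begin.
#'
#' @param t time since germination (h), vectorised.
#' @param params a [germination_params()] block.
#' @return Velocity in µm h^-1.
#' @export
elongation_velocity <- function(t, params = germination_params()) {
  stopifnot(all(t >= 0))
  v_h <- params$v_asym * 60
  tau <- ramp_timescale(params)
  v_h * (1 - 2^(-t / tau))
}

#' @rdname elongation_velocity
#' @export
ramp_timescale <- function(params = germination_params()) {
  v_h <- params$v_asym * 60
  Tt <- params$ramp_hours
  f <- function(tau) v_h * (Tt - tau / log(2) * (1 - 2^(-Tt / tau))) - params$ramp_length
  stats::uniroot(f, c(0.1, 200), tol = 1e-10)$root
}

#' Draw the distance to the next apical branch point
#'
#' The arc distance between consecutive apical branch points on a hypha is
#' the apical dominance length plus a memoryless base-2 exponential tail:
#' \eqn{L = L_0 + X}, with \eqn{P(X > x) = 2^{-\alpha x}}. The median is
#' \eqn{L_0 + 1/\alpha}.
#'
#' @param n number of draws.
#' @param params an [apical_params()] block.
#' @return Distances in µm, all at least `L0`.
#' @export
schedule_apical_branch <- function(n, params = apical_params()) {
  params$L0 + stats::rexp(n, rate = params$alpha_rate * log(2))
}

# subapical offset, Normal(41, 11) truncated at zero
draw_subapical_offset <- function(n, params) {
  x <- stats::rnorm(n, params$L_api_mean, params$L_api_sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), params$L_api_mean, params$L_api_sd)
  }
  x
}

#' Choose the emergence side of a new branch
#'
#' A new branch emerges preferentially on the side opposite the local
#' curvature of the mother hypha. The curvature sign convention is that
#' positive curvature bends the hypha to the right, so with
#' `p_opposite = 1` and positive curvature the branch always goes left.
#' When the local curvature sign is zero (no recorded turn yet) the side
#' is chosen uniformly. Because turning angles are sampled symmetrically,
#' the global clockwise/counterclockwise branch frequency stays at 1/2:
#' the preference is local, and no global chirality is generated.
#'
#' @param local_curvature_sign +1 (bending right), -1 (bending left) or 0.
#' @param p_opposite probability of emerging opposite the curvature.
#' @return `"left"` or `"right"`.
#' @export
branch_side <- function(local_curvature_sign, p_opposite) {
  stopifnot(p_opposite >= 0, p_opposite <= 1)
  if (local_curvature_sign == 0) {
    return(if (stats::runif(1) < 0.5) "left" else "right")
  }
  bend <- if (local_curvature_sign > 0) "right" else "left"
  opp <- if (bend == "right") "left" else "right"
  if (stats::runif(1) < p_opposite) opp else bend
}

#' Run the lattice-free growth simulation
#'
#' Grows a two-dimensional mycelium from germinating hyphae as a binary
#' tree with lateral branches. Each tip advances along its heading at the
#' shared colony-time velocity ramp, its direction perturbed by a
#' spontaneous-curvature turning angle once per `step_length` of advance.
#' Apical (subapical) branch points are placed at exact sampled arc
#' distances \eqn{L_0 + Exp_2(\alpha)} along each hypha, the branch point
#' sitting behind the tip by a truncated-normal subapical offset; the new
#' (operating) branch leaves at the widest angle from the mother
#' projection while the continuing tip (exploratory) deflects by the
#' smallest. Lateral branches nucleate on the newly eligible flank at
#' least `L_dominance` behind the owning apex, as a superposition of
#' isolated events (uniform in position within an aging window) and burst
#' trains whose spacings and waiting times follow base-2 exponential laws.
#' Branch sides follow the opposite-curvature preference
#' ([branch_side()]).
#'
#' @param config a [growth_config()].
#' @return An object of class `growth_trajectory` with elements
#'   `config`, `snapshots` (list of per-cadence apex clouds with columns
#'   `t_h`, `x_um`, `y_um`, `apex_class`), `events` (data.frame of branch
#'   events), `graph` (the final [network_graph()]) and `n_apexes`.
#' @examples
#' traj <- run_growth(growth_config(t_end = 5, seed = 1))
#' traj
#' @export
run_growth <- function(config) {
  stopifnot(inherits(config, "growth_config"))
  set.seed(config$seed)
  ap <- config$apical
  lp <- config$lateral
  gp <- config$germination
  dt <- config$dt
  deg2rad <- pi / 180

  # --- growable node / edge storage ---------------------------------------
  cap_n <- 4096L
  nx <- numeric(cap_n); ny <- numeric(cap_n); nt <- numeric(cap_n)
  ntsign <- numeric(cap_n); nprov <- character(cap_n); nbranch <- logical(cap_n)
  nn <- 0L
  cap_e <- 4096L
  ea <- integer(cap_e); eb <- integer(cap_e); etype <- character(cap_e)
  ne <- 0L
  grow_nodes <- function(k) {
    while (nn + k > cap_n) {
      cap_n <<- cap_n * 2L
      length(nx) <<- cap_n; length(ny) <<- cap_n; length(nt) <<- cap_n
      length(ntsign) <<- cap_n; length(nprov) <<- cap_n; length(nbranch) <<- cap_n
    }
  }
  grow_edges <- function(k) {
    while (ne + k > cap_e) {
      cap_e <<- cap_e * 2L
      length(ea) <<- cap_e; length(eb) <<- cap_e; length(etype) <<- cap_e
    }
  }

  # --- apex state ----------------------------------------------------------
  n_init <- gp$n_initial_hyphae
  base_head <- 2 * pi * (seq_len(n_init) - 1) / n_init +
    stats::rnorm(n_init, 0, 10 * deg2rad)
  n_ap <- n_init
  a_x <- numeric(n_ap); a_y <- numeric(n_ap)
  a_head <- base_head
  a_s <- numeric(n_ap)              # arc grown since hypha birth
  a_bp_prev <- numeric(n_ap)        # arc of previous branch point
  a_next_bp <- schedule_apical_branch(n_ap, ap)
  a_lapi <- draw_subapical_offset(n_ap, ap)
  a_sturn <- numeric(n_ap)
  a_tsign <- numeric(n_ap)          # sign of the most recent turn
  a_axis <- base_head               # growth axis the heading reverts to
  a_type <- rep("germination", n_ap)
  a_node <- integer(n_ap)

  grow_nodes(if (n_init <= 2) 1L else n_init)
  if (n_init <= 2) {
    nn <- 1L; nx[1] <- 0; ny[1] <- 0; nt[1] <- 0
    nprov[1] <- "germination"
    a_node[] <- 1L
    origin_nodes <- rep(1L, n_ap)
  } else {
    for (i in seq_len(n_init)) {
      nn <- nn + 1L; nx[nn] <- 0; ny[nn] <- 0; nt[nn] <- 0
      nprov[nn] <- "germination"
      a_node[i] <- nn
    }
    origin_nodes <- a_node
  }
  p_node <- lapply(a_node, function(k) k)
  p_arc <- rep(list(0), n_ap)

  # --- pending burst-train events ------------------------------------------
  q_time <- numeric(0); q_apex <- integer(0); q_arc <- numeric(0)

  # --- event log -----------------------------------------------------------
  ev <- list(type = character(0), time = numeric(0), x = numeric(0),
             y = numeric(0), L_lat = numeric(0), L_hypha = numeric(0),
             side = character(0), side_vs_curvature = character(0),
             inter_branch = numeric(0), apex = integer(0))
  log_event <- function(type, time, x, y, L_lat, L_hypha, side, svc, inter, apex) {
    ev$type <<- c(ev$type, type); ev$time <<- c(ev$time, time)
    ev$x <<- c(ev$x, x); ev$y <<- c(ev$y, y)
    ev$L_lat <<- c(ev$L_lat, L_lat); ev$L_hypha <<- c(ev$L_hypha, L_hypha)
    ev$side <<- c(ev$side, side)
    ev$side_vs_curvature <<- c(ev$side_vs_curvature, svc)
    ev$inter_branch <<- c(ev$inter_branch, inter)
    ev$apex <<- c(ev$apex, apex)
  }

  # snap an arc position to an interior, not-yet-branched path node
  snap_to_node <- function(i, arc) {
    arcs <- p_arc[[i]]
    len <- length(arcs)
    if (len < 3) return(NA_integer_)
    j <- which.min(abs(arcs - arc))
    for (cand in unique(c(j, j - 1, j + 1, j - 2, j + 2))) {
      if (cand >= 2 && cand <= len - 1) {
        k <- p_node[[i]][cand]
        if (!nbranch[k]) return(cand)
      }
    }
    NA_integer_
  }

  local_direction <- function(i, j) {
    nodes <- p_node[[i]]
    k0 <- nodes[j - 1]; k1 <- nodes[j + 1]
    atan2(ny[k1] - ny[k0], nx[k1] - nx[k0])
  }

  spawn_apex <- function(at_node, heading, type) {
    n_ap <<- n_ap + 1L
    a_x[n_ap] <<- nx[at_node]; a_y[n_ap] <<- ny[at_node]
    a_head[n_ap] <<- heading
    a_s[n_ap] <<- 0; a_bp_prev[n_ap] <<- 0
    a_next_bp[n_ap] <<- schedule_apical_branch(1, ap)
    a_lapi[n_ap] <<- draw_subapical_offset(1, ap)
    a_sturn[n_ap] <<- 0
    a_tsign[n_ap] <<- 0
    a_axis[n_ap] <<- heading
    a_type[n_ap] <<- type
    a_node[n_ap] <<- at_node
    p_node[[n_ap]] <<- at_node
    p_arc[[n_ap]] <<- 0
    n_ap
  }

  do_branch <- function(i, j, t_now, kind) {
    # kind: "apical" (new operating branch) or "lateral"
    k <- p_node[[i]][j]
    dir0 <- local_direction(i, j)
    curv_conv <- -sign(ntsign[k])   # positive curvature = bending right
    p_opp <- if (kind == "apical") ap$p_opposite_curvature else lp$p_opposite_curvature
    side <- branch_side(curv_conv, p_opp)
    rot <- if (side == "left") 1 else -1
    jit <- if (kind == "apical") ap$angle_jitter_sd_deg else lp$angle_jitter_sd_deg
    ang_deg <- if (kind == "apical") ap$operating_angle_deg else lp$lateral_angle_deg
    ang <- (ang_deg + stats::rnorm(1, 0, jit)) * deg2rad
    heading <- dir0 + rot * ang
    nbranch[k] <<- TRUE
    nprov[k] <<- if (kind == "lateral") "lateral" else "apical"
    new_type <- if (kind == "apical") "operating" else "lateral"
    new_i <- spawn_apex(k, heading, new_type)
    svc <- if (curv_conv == 0) "same"
           else if ((curv_conv > 0) == (side == "left")) "opposite" else "same"
    list(new_apex = new_i, node = k, side = if (rot > 0) "ccw" else "cw",
         svc = svc, rot = rot)
  }

  fire_lateral <- function(i, arc, t_now) {
    j <- snap_to_node(i, arc)
    if (is.na(j)) return(FALSE)
    res <- do_branch(i, j, t_now, "lateral")
    log_event("lateral", t_now, nx[res$node], ny[res$node],
              L_lat = a_s[i] - arc, L_hypha = a_s[i],
              side = res$side, svc = res$svc, inter = NA_real_, apex = i)
    # burst-train continuation
    if (stats::runif(1) < 1 - lp$uniform_fraction) {
      dt_min <- stats::rexp(1, rate = lp$temporal_rate * log(2))
      for (try in 1:10) {
        dl <- stats::rexp(1, rate = lp$gamma1 * log(2)) *
          (if (stats::runif(1) < 0.5) 1 else -1)
        new_arc <- arc + dl
        if (new_arc >= 0) {
          q_time <<- c(q_time, t_now + dt_min / 60)
          q_apex <<- c(q_apex, i)
          q_arc <<- c(q_arc, new_arc)
          break
        }
      }
    }
    TRUE
  }

  # --- snapshots -----------------------------------------------------------
  snapshots <- list()
  take_snapshot <- function(t_now) {
    snapshots[[length(snapshots) + 1L]] <<- data.frame(
      t_h = t_now,
      x_um = a_x[seq_len(n_ap)],
      y_um = a_y[seq_len(n_ap)],
      apex_class = ifelse(a_type[seq_len(n_ap)] == "lateral", "V1l", "V1")
    )
  }
  take_snapshot(0)
  next_snap <- config$snapshot_cadence

  # --- main loop -----------------------------------------------------------
  n_steps <- ceiling(config$t_end / dt)
  window_h <- lp$aging_window / 60
  sl_map <- c(
    germination = curvature_block(config, "germination")$step_length,
    exploratory = config$curvature$exploratory$step_length,
    operating = config$curvature$operating$step_length,
    lateral = config$curvature$lateral$step_length
  )
  for (it in seq_len(n_steps)) {
    t0 <- (it - 1) * dt
    t1 <- min(it * dt, config$t_end)
    h <- t1 - t0
    if (h <= 0) break
    v <- if (gp$use_ramp) elongation_velocity((t0 + t1) / 2, gp)
         else gp$v_tip * 60
    ds <- v * h
    idx <- seq_len(n_ap)

    # curvature turns, once per step_length of advance
    a_sturn[idx] <- a_sturn[idx] + ds
    steplens <- sl_map[a_type[idx]]
    repeat {
      due <- idx[a_sturn[idx] >= steplens]
      if (length(due) == 0) break
      for (ty in unique(a_type[due])) {
        cb <- curvature_block(config, ty)
        sel <- due[a_type[due] == ty]
        dth <- sample_curvature_angle(length(sel), cb)
        dev <- wrap_angle(a_head[sel] - a_axis[sel])
        a_head[sel] <- a_head[sel] + dth - cb$axis_reversion * dev
        a_tsign[sel] <- sign(dth)
        a_sturn[sel] <- a_sturn[sel] - cb$step_length
      }
    }

    # advance tips and append nodes
    a_x[idx] <- a_x[idx] + ds * cos(a_head[idx])
    a_y[idx] <- a_y[idx] + ds * sin(a_head[idx])
    a_s[idx] <- a_s[idx] + ds
    grow_nodes(n_ap); grow_edges(n_ap)
    new_ids <- nn + idx
    nx[new_ids] <- a_x[idx]; ny[new_ids] <- a_y[idx]; nt[new_ids] <- t1
    ntsign[new_ids] <- a_tsign[idx]
    nbranch[new_ids] <- FALSE
    nprov[new_ids] <- a_type[idx]
    ea[ne + idx] <- a_node[idx]; eb[ne + idx] <- new_ids
    etype[ne + idx] <- ifelse(a_type[idx] == "germination", "germination",
                              a_type[idx])
    nn <- nn + n_ap; ne <- ne + n_ap
    for (i in idx) {
      p_node[[i]] <- c(p_node[[i]], new_ids[i])
      p_arc[[i]] <- c(p_arc[[i]], a_s[i])
      a_node[i] <- new_ids[i]
    }

    # apical branching: branch point reached when the tip is a subapical
    # offset past the scheduled branch-point arc
    due_ap <- which(a_s[seq_len(n_ap)] >= a_next_bp[seq_len(n_ap)] +
                      a_lapi[seq_len(n_ap)])
    for (i in due_ap) {
      j <- snap_to_node(i, a_next_bp[i])
      if (is.na(j)) { # cannot place yet; retry next step
        next
      }
      res <- do_branch(i, j, t1, "apical")
      log_event("apical", t1, nx[res$node], ny[res$node],
                L_lat = a_s[i] - a_next_bp[i], L_hypha = a_s[i],
                side = res$side, svc = res$svc,
                inter = a_next_bp[i] - a_bp_prev[i], apex = i)
      # continuing (exploratory) tip deflects to the other side
      a_head[i] <- a_head[i] - res$rot *
        (ap$exploratory_angle_deg + stats::rnorm(1, 0, ap$angle_jitter_sd_deg)) *
        deg2rad
      a_axis[i] <- a_head[i]
      a_bp_prev[i] <- a_next_bp[i]
      a_next_bp[i] <- a_next_bp[i] + schedule_apical_branch(1, ap)
      a_lapi[i] <- draw_subapical_offset(1, ap)
    }

    # lateral nucleation on the newly eligible flank
    if (config$lateral_enabled && lp$activity > 0) {
      elig <- a_s[seq_len(n_ap)] - lp$L_dominance
      strip <- pmin(v * window_h, elig)
      ok <- which(strip > 0)
      if (length(ok) > 0) {
        rate <- lp$activity * lp$p_isolated / window_h * strip[ok]
        n_ev <- stats::rpois(length(ok), rate * h)
        for (m in which(n_ev > 0)) {
          i <- ok[m]
          for (r in seq_len(n_ev[m])) {
            arc <- a_s[i] - lp$L_dominance - stats::runif(1) * strip[i]
            fire_lateral(i, arc, t1)
          }
        }
      }
      # pending burst events fire when due AND their site is eligible
      if (length(q_time) > 0) {
        due_q <- which(q_time <= t1 & q_arc <= a_s[q_apex] - lp$L_dominance)
        if (length(due_q) > 0) {
          for (m in due_q) fire_lateral(q_apex[m], q_arc[m], t1)
          keep <- setdiff(seq_along(q_time), due_q)
          q_time <- q_time[keep]; q_apex <- q_apex[keep]; q_arc <- q_arc[keep]
        }
      }
    }

    if (t1 + 1e-9 >= next_snap || it == n_steps) {
      take_snapshot(t1)
      next_snap <- next_snap + config$snapshot_cadence
    }
  }

  graph <- network_graph(
    nodes = data.frame(
      id = seq_len(nn), x = nx[seq_len(nn)], y = ny[seq_len(nn)],
      birth_time = nt[seq_len(nn)], class = NA_character_,
      provenance = nprov[seq_len(nn)]
    ),
    edges = data.frame(a = ea[seq_len(ne)], b = eb[seq_len(ne)],
                       branch_type = etype[seq_len(ne)]),
    snapshot_time = config$t_end
  )
  events <- data.frame(
    type = ev$type, time = ev$time, x = ev$x, y = ev$y,
    L_lat = ev$L_lat, L_hypha = ev$L_hypha, side = ev$side,
    side_vs_curvature = ev$side_vs_curvature,
    inter_branch = ev$inter_branch, apex = ev$apex
  )
  structure(
    list(config = config, snapshots = snapshots, events = events,
         graph = graph, n_apexes = n_ap),
    class = "growth_trajectory"
  )
}

wrap_angle <- function(x) atan2(sin(x), cos(x))

# curvature block for a hypha type (germination hyphae share the
# exploratory parameters)
curvature_block <- function(config, type) {
  if (type %in% names(config$curvature)) config$curvature[[type]]
  else if (type == "germination") config$curvature$exploratory
  else config$curvature$operating
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf(
    "growth_trajectory: %.1f h, %d apexes, %d branch events (%d apical, %d lateral), %d snapshots\n",
    x$config$t_end, x$n_apexes, nrow(x$events),
    sum(x$events$type == "apical"), sum(x$events$type == "lateral"),
    length(x$snapshots)
  ))
  invisible(x)
}

#' Run replicate simulations
#'
#' Runs `n_seeds` replicates of a configuration, replicate `k` using seed
#' `config$seed + k - 1`.
#'
#' @param config a [growth_config()].
#' @param n_seeds number of replicates.
#' @return List of `growth_trajectory` objects.
#' @export
run_ensemble <- function(config, n_seeds = 10) {
  lapply(seq_len(n_seeds), function(k) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    run_growth(cfg)
  })
}
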
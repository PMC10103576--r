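#' Default simulation configuration
#'
#' Parameters of the monodomain solver and the two-variable ionic model.
#' The transmembrane variable `v` is dimensionless in `[0, 1]` and is mapped
#' to millivolts as `Vm = v_rest_mV + v_span_mV * v`. Tissue-class parameter
#' sets (`normal`, `border_zone`) control the ionic time constants and the
#' longitudinal/transverse diffusivities (mm^2/ms); the border zone has
#' reduced diffusivity (slower conduction), longer recovery and reduced
#' anisotropy. Dense core is non-conducting and carries no parameters.
#'
#' Defaults were calibrated on a 1D cable so that normal tissue conducts at
#' roughly 60 cm/s along the fibre with an action-potential duration near
#' 300 ms, and border-zone conduction is roughly 40% slower.
#'
#' @param dt integration time step (ms); reduced automatically if the
#'   diffusion stability bound requires it
#' @param rec_dt recording interval (ms); 2.5 ms = 400 Hz
#' @return a named list of solver and tissue parameters
#' @export
default_sim_config <- function(dt = 0.1, rec_dt = 2.5) {
  list(
    dt = dt, rec_dt = rec_dt,
    v_thr = 0.6,                 # activation threshold, = -20 mV
    v_rest_mV = -80, v_span_mV = 100,
    tissue = list(
      normal = list(tau_in = 0.3, tau_out = 6, tau_open = 70,
                    tau_close = 130, v_gate = 0.13,
                    D_l = 0.34, aniso = 4),
      border_zone = list(tau_in = 0.3, tau_out = 6, tau_open = 150,
                         tau_close = 170, v_gate = 0.13,
                         D_l = 0.08, aniso = 2)
    ),
    stim = list(radius = 2, duration = 2, amp = 0.5)  # amp ~ 2x diastolic threshold
  )
}

# per-edge diffusion weights (1/ms): harmonic mean of the directional
# diffusivity n' D n at the two end nodes, over voxel_size^2.  Edges touching
# dense core get weight zero (excluded domain).
conduction_weights <- function(model, config) {
  edges <- model$edges
  lab <- model$label
  tis <- config$tissue
  D_l <- ifelse(lab == "border_zone", tis$border_zone$D_l, tis$normal$D_l)
  aniso <- ifelse(lab == "border_zone", tis$border_zone$aniso, tis$normal$aniso)
  D_t <- D_l / aniso
  dir <- (model$coords[edges[, 2], , drop = FALSE] -
            model$coords[edges[, 1], , drop = FALSE]) / model$voxel_size
  if (is.null(model$fibre)) {
    proj1 <- proj2 <- rep(1, nrow(edges))   # isotropic fallback
    d1 <- D_l[edges[, 1]]; d2 <- D_l[edges[, 2]]
  } else {
    proj1 <- rowSums(model$fibre[edges[, 1], , drop = FALSE] * dir)^2
    proj2 <- rowSums(model$fibre[edges[, 2], , drop = FALSE] * dir)^2
    d1 <- D_t[edges[, 1]] + (D_l - D_t)[edges[, 1]] * proj1
    d2 <- D_t[edges[, 2]] + (D_l - D_t)[edges[, 2]] * proj2
  }
  w <- 2 * d1 * d2 / pmax(d1 + d2, 1e-12) / model$voxel_size^2
  core <- lab == "dense_core"
  w[core[edges[, 1]] | core[edges[, 2]]] <- 0
  w
}

# per-node ionic parameter vectors
ionic_params <- function(model, config) {
  lab <- model$label
  tis <- config$tissue
  pick <- function(field) {
    ifelse(lab == "border_zone", tis$border_zone[[field]], tis$normal[[field]])
  }
  list(tau_in = pick("tau_in"), tau_out = pick("tau_out"),
       tau_open = pick("tau_open"), tau_close = pick("tau_close"),
       v_gate = pick("v_gate"))
}

# conducting nodes within `radius` mm of a position.  An electrode on the
# mapping surface can sit between voxel centres; when the ball is empty it
# is re-centred on the nearest myocardial node — unless that node is dense
# core, in which case the site is non-capturing by construction.
stim_node_set <- function(model, pos, radius) {
  d <- row_norms(sweep(model$coords, 2, pos))
  sel <- which(d <= radius & model$label != "dense_core")
  if (!length(sel)) {
    j <- which.min(d)
    if (model$label[j] != "dense_core") {
      dj <- row_norms(sweep(model$coords, 2, model$coords[j, ]))
      sel <- which(dj <= radius & model$label != "dense_core")
    }
  }
  sel
}

#' Run a monodomain simulation
#'
#' Integrates the monodomain reaction-diffusion system on the voxel graph of
#' `model` with anisotropic conductivity derived from the fibre field and
#' tissue labels, no-flux boundaries, and dense core excluded from the
#' conducting domain. Stimuli are intracellular current injections in a ball
#' around each stimulus site. Activation events (upstroke crossings of the
#' -20 mV threshold with positive slope) are recorded exactly at the
#' integration resolution; `v` is recorded every `rec_dt` ms.
#'
#' @param model a `ventricular_model` (or slab) with fibres and labels
#' @param protocol list with `stimuli` (list of `list(pos, start, dur, amp,
#'   radius)`; `dur`, `amp`, `radius` optional) and `t_end` (ms); optionally
#'   `state0` (list `v`, `h`) and `t0` to continue a previous run
#' @param config a [default_sim_config()] list
#' @return an object of class `vm_trace`: dimensionless `v` (nodes x
#'   samples), sample `times`, activation `events` (node, time), final state
#'   and the protocol
#' @export
run_monodomain <- function(model, protocol, config = default_sim_config()) {
  n <- nrow(model$coords)
  w <- conduction_weights(model, config)
  keep <- w > 0
  ed <- model$edges[keep, , drop = FALSE]
  w <- w[keep]
  # explicit-Euler diffusion stability: dt < 1 / max_i sum_j w_ij
  wsum <- numeric(n)
  for (k in 1:2) {
    acc <- tapply(w, ed[, k], sum)
    wsum[as.integer(names(acc))] <- wsum[as.integer(names(acc))] + acc
  }
  dt <- min(config$dt, 0.8 / max(wsum, 1e-9))
  t0 <- if (is.null(protocol$t0)) 0 else protocol$t0
  n_steps <- ceiling((protocol$t_end - t0) / dt)
  rec_every <- max(1L, round(config$rec_dt / dt))

  stims <- protocol$stimuli
  stim_nodes <- lapply(stims, function(s) {
    r <- if (is.null(s$radius)) config$stim$radius else s$radius
    stim_node_set(model, s$pos, r) - 1L
  })
  gv <- function(s, f, d) if (is.null(s[[f]])) d else s[[f]]
  ion <- ionic_params(model, config)
  state <- protocol$state0
  v0 <- if (is.null(state)) rep(0, n) else state$v
  h0 <- if (is.null(state)) rep(1, n) else state$h

  res <- monodomain_step_cpp(
    n, ed[, 1] - 1L, ed[, 2] - 1L, w,
    ion$tau_in, ion$tau_out, ion$tau_open, ion$tau_close, ion$v_gate,
    v0, h0, dt, n_steps, rec_every,
    stim_nodes,
    vapply(stims, gv, numeric(1), f = "start", d = 0),
    vapply(stims, gv, numeric(1), f = "dur", d = config$stim$duration),
    vapply(stims, gv, numeric(1), f = "amp", d = config$stim$amp),
    config$v_thr, t0)
  if (!res$stable) {
    stop("monodomain integration became unstable (|v| out of bounds); ",
         "check dt and diffusivities")
  }
  structure(list(
    v = res$v, times = res$times,
    events = data.frame(node = res$event_node, time = res$event_time),
    state_final = list(v = res$v_final, h = res$h_final),
    dt = dt, rec_dt = dt * rec_every, protocol = protocol,
    config = config, n_nodes = n,
    conducting = model$label != "dense_core"
  ), class = "vm_trace")
}

#' Transmembrane potential in millivolts
#' @param trace a `vm_trace`
#' @return matrix of Vm (mV), nodes x samples
#' @export
get_vm <- function(trace) {
  trace$config$v_rest_mV + trace$config$v_span_mV * trace$v
}

#' First activation time per node within a time window
#'
#' @param trace a `vm_trace`
#' @param window `c(start, end)` in ms; events at `start <= t < end`
#' @return numeric vector (ms), `NA` where the node did not activate
#' @export
activation_times <- function(trace, window) {
  ev <- trace$events
  ev <- ev[ev$time >= window[1] & ev$time < window[2], ]
  out <- rep(NA_real_, trace$n_nodes)
  if (nrow(ev)) {
    first <- tapply(ev$time, ev$node, min)
    out[as.integer(names(first))] <- first
  }
  out
}

#' Decide whether a delivered stimulus captured the tissue
#'
#' A stimulus captures when at least 10% of conducting nodes farther than
#' 10 mm from the pacing site activate within the beat window — i.e. the
#' excitation propagated beyond the local stimulated neighbourhood.
#'
#' @param trace a `vm_trace`
#' @param site_pos pacing-site position (mm)
#' @param window beat window `c(start, end)` in ms
#' @param model the simulated model (for node positions)
#' @return logical
#' @export
detect_capture <- function(trace, site_pos, window, model) {
  act <- activation_times(trace, window)
  far <- trace$conducting &
    row_norms(sweep(model$coords, 2, site_pos)) > 10
  if (!any(far)) return(FALSE)
  mean(!is.na(act[far])) >= 0.10
}

#' Simulate an S1 (and optional S2) paced beat from one site
#'
#' Delivers a single S1 stimulus, then optionally an extra-stimulus S2 at
#' the given coupling interval, and evaluates capture of each stimulus. Beat
#' windows are `[s1, s2)` for S1 and `[s2, end]` for S2; with no S2 the S1
#' window runs to the end of the simulation. A site inside dense core simply
#' fails to capture.
#'
#' @param model a `ventricular_model` with fibres and labels
#' @param site_pos pacing position (mm), typically a pacing-site position
#' @param s2_coupling S2 coupling interval (ms) after S1, or `NULL`
#' @param config a [default_sim_config()]
#' @param s1_time S1 delivery time (ms)
#' @param beat_ms length of the final beat window (ms)
#' @return a `vm_trace` with `beat_windows` and per-stimulus `capture`
#' @export
deliver_s1s2 <- function(model, site_pos, s2_coupling = NULL,
                         config = default_sim_config(), s1_time = 5,
                         beat_ms = 360) {
  stims <- list(list(pos = site_pos, start = s1_time))
  if (!is.null(s2_coupling)) {
    stims[[2]] <- list(pos = site_pos, start = s1_time + s2_coupling)
  }
  t_end <- s1_time + if (is.null(s2_coupling)) beat_ms else s2_coupling + beat_ms
  trace <- run_monodomain(model, list(stimuli = stims, t_end = t_end), config)
  wins <- if (is.null(s2_coupling)) {
    list(S1 = c(s1_time, t_end))
  } else {
    list(S1 = c(s1_time, s1_time + s2_coupling),
         S2 = c(s1_time + s2_coupling, t_end))
  }
  trace$beat_windows <- wins
  trace$capture <- vapply(wins, function(wn) {
    detect_capture(trace, site_pos, wn, model)
  }, logical(1))
  trace$site_pos <- site_pos
  trace
}

#' Detect re-entrant episodes after pacing has ended
#'
#' Scans activation events after `stimulus_end` for sustained periodic
#' re-activation: the reference node is the conducting node with the most
#' post-pacing activations; the cycle length is the median inter-activation
#' interval there. An episode requires at least `min_cycles` complete cycles
#' at the reference node, participation of a non-trivial fraction of the
#' tissue, and regular intervals.
#'
#' @param trace a `vm_trace`
#' @param stimulus_end time (ms) after which activity counts as self-sustained
#' @param min_cycles minimum number of re-entrant cycles (paper definition: 2)
#' @param min_fraction minimum fraction of conducting nodes re-activating
#' @return list of `vt_episode` objects (empty when none)
#' @export
detect_reentry <- function(trace, stimulus_end, min_cycles = 2,
                           min_fraction = 0.05) {
  ev <- trace$events
  ev <- ev[ev$time > stimulus_end, ]
  if (!nrow(ev)) return(list())
  counts <- tabulate(ev$node, nbins = trace$n_nodes)
  # nodes completing >= min_cycles re-activations
  recur <- sum(counts >= 2) / max(sum(trace$conducting), 1)
  ref <- which.max(counts)
  if (counts[ref] < min_cycles + 1 || recur < min_fraction) return(list())
  tt <- sort(ev$time[ev$node == ref])
  gaps <- diff(tt)
  cl <- median(gaps)
  if (cl <= 0 || (length(gaps) > 1 && mad(gaps) / cl > 0.25)) return(list())
  ep <- structure(list(
    cycle_count = length(gaps),
    cycle_length = cl,
    ref_node = ref,
    events = ev,
    stimulus_end = stimulus_end
  ), class = "vt_episode")
  list(ep)
}

#' Default programmed-stimulation protocol for VT induction
#'
#' A drive train of S1 beats followed by a downward scan of S2 coupling
#' intervals; if S2 blocks without inducing re-entry, an S3 scan is run on
#' top of the tightest capturing S2.
#'
#' @param n_drive drive-train beats
#' @param drive_cl drive cycle length (ms)
#' @param s2_scan S2 couplings to try (ms, descending)
#' @param s3_scan S3 couplings to try after each tested S2 (ms, descending)
#' @param observe_ms post-stimulus observation window for re-entry (ms)
#' @return list of protocol parameters
#' @export
default_induction_config <- function(n_drive = 6, drive_cl = 600,
                                     s2_scan = seq(400, 220, by = -10),
                                     s3_scan = seq(360, 220, by = -20),
                                     observe_ms = 2500) {
  list(n_drive = n_drive, drive_cl = drive_cl, s2_scan = s2_scan,
       s3_scan = s3_scan, observe_ms = observe_ms)
}

# farthest-point sampling over conducting volume nodes (euclidean)
induction_sites <- function(model, n_sites, seed) {
  cand <- which(model$label != "dense_core")
  set.seed(derive_seed(seed, 77L))
  chosen <- cand[sample.int(length(cand), 1)]
  mind <- row_norms(sweep(model$coords[cand, , drop = FALSE], 2,
                          model$coords[chosen, ]))
  while (length(chosen) < n_sites) {
    nxt <- cand[which.max(mind)]
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, row_norms(sweep(model$coords[cand, , drop = FALSE], 2,
                                       model$coords[nxt, ])))
  }
  chosen
}

#' Induce ventricular tachycardia by programmed stimulation
#'
#' From each of `n_induction_sites` farthest-point-sampled locations, drives
#' the tissue with an S1 train, then delivers progressively tighter
#' extra-stimuli (S2, then S2+S3) until re-entry of at least two cycles is
#' detected or the protocol is exhausted. Distinct episodes are
#' deduplicated: episodes whose exit sites lie within 10 mm of each other
#' and whose cycle lengths agree within 10% are considered one VT.
#'
#' @param model a `ventricular_model` with fibres and labels
#' @param n_induction_sites number of pacing locations to try
#' @param config a [default_sim_config()]
#' @param induction a [default_induction_config()]
#' @param seed integer seed (site sampling)
#' @param max_episodes stop early after this many distinct episodes
#' @return list of `vt_episode` objects, each annotated with the inducing
#'   site, protocol stage and exit-site node
#' @export
induce_vt <- function(model, n_induction_sites = 17,
                      config = default_sim_config(),
                      induction = default_induction_config(),
                      seed = 1, max_episodes = Inf) {
  sites <- induction_sites(model, n_induction_sites, seed)
  episodes <- list()
  for (si in seq_along(sites)) {
    pos <- model$coords[sites[si], ]
    eps <- induce_from_site(model, pos, config, induction)
    for (ep in eps) {
      ep$site_node <- sites[si]
      ep$site_pos <- pos
      ep$exit_node <- locate_exit_site(ep, model)
      dup <- any(vapply(episodes, function(e2) {
        sqrt(sum((model$coords[e2$exit_node, ] - model$coords[ep$exit_node, ])^2)) < 10 &&
          abs(e2$cycle_length - ep$cycle_length) / ep$cycle_length < 0.10
      }, logical(1)))
      if (!dup) episodes[[length(episodes) + 1L]] <- ep
    }
    if (length(episodes) >= max_episodes) break
  }
  episodes
}

# drive train once, then scan S2 (and S2+S3) couplings from the saved state
induce_from_site <- function(model, pos, config, induction) {
  nd <- induction$n_drive; cl <- induction$drive_cl
  drive <- lapply(seq_len(nd), function(b) list(pos = pos, start = (b - 1) * cl))
  t_last <- (nd - 1) * cl
  tr <- run_monodomain(model, list(stimuli = drive, t_end = t_last + 1), config)
  if (!detect_capture(tr, pos, c(t_last - cl, t_last), model)) return(list())
  state <- tr$state_final
  last_capturing_s2 <- NA_real_
  for (c2 in induction$s2_scan) {
    ep <- try_extra(model, pos, state, t_last + 1, c(c2), config, induction)
    if (is.list(ep) && length(ep$episodes)) return(ep$episodes)
    if (ep$captured) last_capturing_s2 <- c2 else break
  }
  if (!is.na(last_capturing_s2)) {
    for (c3 in induction$s3_scan) {
      ep <- try_extra(model, pos, state, t_last + 1, c(last_capturing_s2, c3),
                      config, induction)
      if (length(ep$episodes)) return(ep$episodes)
      if (!ep$captured) break
    }
  }
  list()
}

# continue from state with extra-stimuli at cumulative couplings; detect
# capture of the last extra-stimulus and re-entry after it
try_extra <- function(model, pos, state, t0, couplings, config, induction) {
  t_stim <- t0 + cumsum(couplings)
  stims <- lapply(t_stim, function(ts) list(pos = pos, start = ts))
  t_end <- max(t_stim) + induction$observe_ms
  tr <- run_monodomain(model, list(stimuli = stims, t_end = t_end,
                                   state0 = state, t0 = t0), config)
  last <- max(t_stim)
  cap <- detect_capture(tr, pos, c(last, last + 400), model)
  eps <- detect_reentry(tr, stimulus_end = last + config$stim$duration + 20)
  for (i in seq_along(eps)) eps[[i]]$stage <- paste0("S", 1 + length(couplings),
                                                     "@", paste(couplings, collapse = "/"))
  list(captured = cap, episodes = eps)
}

#' Build a rectangular tissue slab
#'
#' A homogeneous (or relabelled) box of voxels with a uniform fibre
#' direction, used for solver-validity studies such as planar conduction
#' velocity measurement and refinement tests.
#'
#' @param dims slab extents (mm), length 3
#' @param voxel_size voxel edge (mm)
#' @param fibre_dir fibre direction (unit 3-vector; default +x)
#' @param label tissue label for every node
#' @return a `ventricular_model`-compatible slab object
#' @export
build_tissue_slab <- function(dims = c(40, 8, 8), voxel_size = 1,
                              fibre_dir = c(1, 0, 0), label = "normal") {
  gx <- seq(voxel_size / 2, dims[1], by = voxel_size)
  gy <- seq(voxel_size / 2, dims[2], by = voxel_size)
  gz <- seq(voxel_size / 2, dims[3], by = voxel_size)
  coords <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  idx <- cbind(round((coords[, 1] - gx[1]) / voxel_size),
               round((coords[, 2] - gy[1]) / voxel_size),
               round((coords[, 3] - gz[1]) / voxel_size))
  storage.mode(idx) <- "integer"
  nx <- length(gx); ny <- length(gy)
  key <- idx[, 1] + nx * (idx[, 2] + ny * idx[, 3])
  edges <- voxel_edges(idx, key, nx, ny)
  fib <- matrix(rep(fibre_dir / sqrt(sum(fibre_dir^2)), each = nrow(coords)), ncol = 3)
  structure(list(voxel_size = voxel_size, coords = coords, grid_index = idx,
                 grid_key = key, grid_dims = c(nx, ny, length(gz)),
                 grid_origin = c(gx[1], gy[1], gz[1]), edges = edges,
                 label = rep(label, nrow(coords)), fibre = fib),
            class = "ventricular_model")
}

#' Measure planar conduction velocity in a slab
#'
#' Stimulates the full x = 0 face and fits activation time against x over
#' the interior of the slab; CV = 1/slope converted to cm/s.
#'
#' @param slab a slab from [build_tissue_slab()]
#' @param config a [default_sim_config()]
#' @param t_end simulation end (ms)
#' @return conduction velocity (cm/s)
#' @export
measure_planar_cv <- function(slab, config = default_sim_config(), t_end = 120) {
  face <- slab$coords[, 1] <= max(1, slab$voxel_size)
  tr <- run_monodomain_face(slab, which(face), t_end, config)
  act <- activation_times(tr, c(0, t_end))
  x <- slab$coords[, 1]
  xr <- range(x)
  mid <- x > xr[1] + 0.25 * diff(xr) & x < xr[1] + 0.85 * diff(xr) & !is.na(act)
  fit <- stats::lm(act[mid] ~ x[mid])
  100 / coef(fit)[[2]]   # mm/ms -> cm/s
}

# internal: stimulate an explicit node set (used for planar-wave studies)
run_monodomain_face <- function(model, nodes, t_end, config) {
  n <- nrow(model$coords)
  w <- conduction_weights(model, config)
  keep <- w > 0
  ed <- model$edges[keep, , drop = FALSE]
  w <- w[keep]
  wsum <- numeric(n)
  for (k in 1:2) {
    acc <- tapply(w, ed[, k], sum)
    wsum[as.integer(names(acc))] <- wsum[as.integer(names(acc))] + acc
  }
  dt <- min(config$dt, 0.8 / max(wsum, 1e-9))
  rec_every <- max(1L, round(config$rec_dt / dt))
  ion <- ionic_params(model, config)
  res <- monodomain_step_cpp(
    n, ed[, 1] - 1L, ed[, 2] - 1L, w,
    ion$tau_in, ion$tau_out, ion$tau_open, ion$tau_close, ion$v_gate,
    rep(0, n), rep(1, n), dt, ceiling(t_end / dt), rec_every,
    list(nodes - 1L), 2, config$stim$duration, config$stim$amp,
    config$v_thr, 0)
  if (!res$stable) stop("unstable planar-wave simulation")
  structure(list(v = res$v, times = res$times,
                 events = data.frame(node = res$event_node, time = res$event_time),
                 state_final = list(v = res$v_final, h = res$h_final),
                 dt = dt, rec_dt = dt * rec_every, config = config,
                 n_nodes = n, conducting = model$label != "dense_core"),
            class = "vm_trace")
}
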
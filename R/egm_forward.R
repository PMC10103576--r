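#' Precompute the unipolar forward operator for a geometry
#'
#' The extracellular potential at an observation point x is the
#' infinite-volume-conductor solution of the monodomain source model,
#'
#'   phi(x) = -(sigma_i / (4 pi sigma_e)) *
#'            integral over the myocardium of grad Vm(y) . (x - y)/|x - y|^3 dV,
#'
#' discretized as a sum over myocardial nodes with voxel-volume weights and
#' central-difference gradients of Vm on the voxel grid. Because the map
#' from nodal Vm to point potentials is linear and time-independent, it is
#' assembled once as a dense matrix (points x nodes) and reused across all
#' time samples and pacings of a geometry. Singular self-contributions are
#' regularized by excluding source nodes within one voxel of the
#' observation point.
#'
#' @param model a `ventricular_model`
#' @param surface an `eam_surface` from the same model
#' @param sigma_ratio intracellular-to-extracellular conductivity ratio
#' @return a dense matrix `P x N` mapping nodal Vm (mV) to unipolar
#'   potentials (mV) at the surface points
#' @export
egm_forward_operator <- function(model, surface, sigma_ratio = 0.4) {
  n <- nrow(model$coords)
  vs <- model$voxel_size
  k <- sigma_ratio / (4 * pi)
  vol <- vs^3
  grads <- gradient_operators(model)   # sparse N x N per axis
  pts <- surface$points
  p <- nrow(pts)
  out <- matrix(0, p, n)
  r2 <- matrix(0, p, n)
  for (dd in 1:3) r2 <- r2 + outer(pts[, dd], model$coords[, dd], "-")^2
  r <- sqrt(r2)
  denom <- pmax(r, vs / 2)^3
  near <- r < vs                        # one-voxel exclusion zone
  for (d in 1:3) {
    # kernel K[p, j] = (x_p - y_j)_d / r^3, regularized
    K <- outer(pts[, d], model$coords[, d], "-") / denom
    K[near] <- 0
    out <- out + as.matrix(K %*% grads[[d]])
  }
  -k * vol * out
}

# sparse central-difference gradient operators on the voxel grid, one-sided
# at domain boundaries (missing neighbour)
gradient_operators <- function(model) {
  n <- nrow(model$coords)
  vs <- model$voxel_size
  ord <- order(model$grid_key)
  skey <- model$grid_key[ord]
  nx <- model$grid_dims[1]; ny <- model$grid_dims[2]
  steps <- c(1, nx, nx * ny)
  find <- function(k) {
    pos <- findInterval(k, skey)
    hit <- pos > 0 & skey[pmax(pos, 1)] == k
    out <- rep(NA_integer_, length(k))
    out[hit] <- ord[pos[hit]]
    out
  }
  lapply(1:3, function(d) {
    up <- find(model$grid_key + steps[d])
    dn <- find(model$grid_key - steps[d])
    # guard against key wrap-around
    bad_up <- !is.na(up) &
      (model$grid_index[up, d] - model$grid_index[, d] != 1L |
         rowSums(abs(model$grid_index[up, , drop = FALSE] - model$grid_index)) != 1L)
    bad_dn <- !is.na(dn) &
      (model$grid_index[, d] - model$grid_index[dn, d] != 1L |
         rowSums(abs(model$grid_index[dn, , drop = FALSE] - model$grid_index)) != 1L)
    up[bad_up] <- NA; dn[bad_dn] <- NA
    i <- integer(0); j <- integer(0); x <- numeric(0)
    both <- !is.na(up) & !is.na(dn)
    i <- c(i, which(both), which(both))
    j <- c(j, up[both], dn[both])
    x <- c(x, rep(1 / (2 * vs), sum(both)), rep(-1 / (2 * vs), sum(both)))
    fwd <- !is.na(up) & is.na(dn)
    i <- c(i, which(fwd), which(fwd))
    j <- c(j, up[fwd], which(fwd))
    x <- c(x, rep(1 / vs, sum(fwd)), rep(-1 / vs, sum(fwd)))
    bwd <- is.na(up) & !is.na(dn)
    i <- c(i, which(bwd), which(bwd))
    j <- c(j, which(bwd), dn[bwd])
    x <- c(x, rep(1 / vs, sum(bwd)), rep(-1 / vs, sum(bwd)))
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  })
}

#' Compute a unipolar electrogram map for one beat
#'
#' Applies the precomputed forward operator to the transmembrane potential
#' over a beat window and resamples the signals to 400 Hz. Per-point
#' activation times are transferred from each point's linked volume node.
#'
#' @param trace a `vm_trace`
#' @param surface an `eam_surface` from the same model
#' @param operator matrix from [egm_forward_operator()] (computed on the
#'   fly when `NULL`, which is slow for repeated use)
#' @param window beat window `c(start, end)` ms (default: whole trace)
#' @param beat beat id, e.g. `"S1"` or `"S2"`
#' @param site_id pacing-site id for map keying
#' @param model required when `operator` is `NULL`
#' @return an object of class `electrogram_map`: `signals` (points x
#'   samples, mV, 400 Hz), `times`, `activation` (ms per point, NA where the
#'   linked node did not activate in the window), `beat`, `site_id`
#' @export
compute_unipolar <- function(trace, surface, operator = NULL, window = NULL,
                             beat = "S1", site_id = NA_integer_, model = NULL) {
  if (is.null(operator)) {
    if (is.null(model)) stop("model needed to build the forward operator")
    operator <- egm_forward_operator(model, surface)
  }
  if (is.null(window)) window <- range(trace$times)
  fs_dt <- 2.5                          # 400 Hz
  tq <- seq(window[1], window[2], by = fs_dt)
  vm <- get_vm(trace)
  # sample columns at the query times (trace is recorded at rec_dt)
  hit <- match(round(tq, 6), round(trace$times, 6))
  if (!anyNA(hit)) {
    vq <- vm[, hit, drop = FALSE]       # fast path: sample grid aligned
  } else {
    vq <- t(vapply(seq_len(nrow(vm)), function(i) {
      approx(trace$times, vm[i, ], xout = tq, rule = 2)$y
    }, numeric(length(tq))))
  }
  signals <- operator %*% vq
  act <- activation_times(trace, window)[surface$volume_link]
  act[surface$lid] <- NA
  structure(list(signals = signals, times = tq, activation = act,
                 beat = beat, site_id = site_id, fs = 400),
            class = "electrogram_map")
}

#' Simulate and assemble the full set of paced substrate maps
#'
#' For each pacing site and protocol, runs the S1/S2 simulation and computes
#' the corresponding electrogram maps: one S1 map per captured S1 (from the
#' S1-only protocol) and one S2 map per captured S2. Failed captures are
#' recorded as absent maps.
#'
#' @param model a labelled `ventricular_model` with fibres
#' @param surface an `eam_surface`
#' @param sites a `pacing_sites` data.frame
#' @param protocols subset of `c("S1", "S1+S2_360", "S1+S2_310")`
#' @param config a [default_sim_config()]
#' @param operator optional precomputed forward operator
#' @param progress print one line per simulation
#' @return an object of class `eam_map_set`: list of `electrogram_map`s
#'   keyed `"<site>:<beat>"` (beat one of `S1`, `S2_360`, `S2_310`), plus a
#'   `capture` data.frame with one row per (site, protocol)
#' @export
assemble_map_set <- function(model, surface, sites,
                             protocols = c("S1", "S1+S2_360", "S1+S2_310"),
                             config = default_sim_config(), operator = NULL,
                             progress = FALSE) {
  if (is.null(operator)) operator <- egm_forward_operator(model, surface)
  maps <- list()
  cap <- list()
  couplings <- c("S1" = NA, "S1+S2_360" = 360, "S1+S2_310" = 310)
  for (i in seq_len(nrow(sites))) {
    pos <- as.numeric(sites[i, c("x", "y", "z")])
    for (pr in protocols) {
      c2 <- couplings[[pr]]
      tr <- deliver_s1s2(model, pos, s2_coupling = if (is.na(c2)) NULL else c2,
                         config = config)
      if (progress) {
        message("site ", sites$id[i], " ", pr, ": capture ",
                paste(names(tr$capture), tr$capture, collapse = " "))
      }
      if (pr == "S1" && isTRUE(tr$capture[["S1"]])) {
        key <- paste0(sites$id[i], ":S1")
        maps[[key]] <- compute_unipolar(tr, surface, operator,
                                        window = tr$beat_windows$S1,
                                        beat = "S1", site_id = sites$id[i])
      }
      if (!is.na(c2) && isTRUE(tr$capture[["S2"]])) {
        beat <- paste0("S2_", c2)
        key <- paste0(sites$id[i], ":", beat)
        maps[[key]] <- compute_unipolar(tr, surface, operator,
                                        window = tr$beat_windows$S2,
                                        beat = beat, site_id = sites$id[i])
      }
      cap[[length(cap) + 1L]] <- data.frame(
        site = sites$id[i], protocol = pr,
        s1_capture = isTRUE(tr$capture[["S1"]]),
        s2_capture = if (is.na(c2)) NA else isTRUE(tr$capture[["S2"]]))
    }
  }
  structure(list(maps = maps, capture = do.call(rbind, cap),
                 protocols = protocols),
            class = "eam_map_set")
}

#' @export
print.eam_map_set <- function(x, ...) {
  cat("eam_map_set:", length(x$maps), "maps from",
      length(unique(x$capture$site)), "sites\n")
  invisible(x)
}
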
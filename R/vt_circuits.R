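#' Locate the exit site of a re-entrant episode
#'
#' The exit site is where the re-entrant wavefront leaves the protected
#' circuit into bulk myocardium. It is identified automatically from the
#' activation sequence at the remodelled boundary: an "emergence" event is
#' an activation of a normal-tissue node adjacent to border zone that is
#' immediately preceded (within `lead_ms`) by the activation of one of its
#' border-zone neighbours — the wavefront stepping out of slow tissue into
#' bulk myocardium. Each re-entrant cycle produces such events at the
#' channel mouth the wavefront exits through; the exit site is the node
#' with the most emergence events across cycles (majority vote; ties break
#' to the lowest node id). Deterministic given an episode.
#'
#' @param episode a `vt_episode` (with `events`, `ref_node`, `cycle_length`)
#' @param model the simulated `ventricular_model` (labels included)
#' @param lead_ms window within which the border-zone neighbour must lead
#' @return exit node id
#' @export
locate_exit_site <- function(episode, model, lead_ms = 40) {
  lab <- model$label
  bz <- lab == "border_zone"
  cand <- which(lab == "normal" & adjacent_to(model, which(bz)))
  ev <- episode$events
  if (!nrow(ev)) stop("episode has no activations; exit site undefined")
  adj <- adjacency_list(nrow(model$coords), model$edges)
  act_by_node <- split(ev$time, ev$node)
  votes <- integer(0)
  norm <- lab == "normal"
  for (i in cand) {
    ti <- act_by_node[[as.character(i)]]
    if (is.null(ti)) next
    nb <- adj[[i]][bz[adj[[i]]]]
    tn <- unlist(act_by_node[as.character(nb)], use.names = FALSE)
    if (is.null(tn) || !length(tn)) next
    nn <- adj[[i]][norm[adj[[i]]]]
    tm <- unlist(act_by_node[as.character(nn)], use.names = FALSE)
    hits <- sum(vapply(ti, function(t) {
      # border zone leads, and no normal neighbour led (the wavefront
      # truly arrived through the slow channel, not tangentially)
      any(tn < t & tn >= t - lead_ms) &&
        !any(tm < t & tm >= t - lead_ms)
    }, logical(1)))
    if (hits > 0) votes <- c(votes, rep(i, hits))
  }
  if (!length(votes)) {
    # fallback: earliest-activating boundary node per cycle, voted
    bnd <- which(bz & adjacent_to(model, which(lab == "normal")))
    if (!length(bnd)) bnd <- which(lab != "dense_core")
    evb <- ev[ev$node %in% bnd, ]
    if (!nrow(evb)) stop("no boundary activations; exit site undefined")
    t0 <- min(ev$time[ev$node == episode$ref_node])
    cyc <- floor((evb$time - t0) / episode$cycle_length)
    votes <- vapply(split(seq_len(nrow(evb)), cyc), function(ii) {
      evb$node[ii][which.min(evb$time[ii])]
    }, numeric(1))
  }
  tab <- table(votes)
  best <- as.integer(names(tab)[tab == max(tab)])
  min(best)
}

# logical: nodes with at least one 6-neighbour in `set`
adjacent_to <- function(model, set) {
  out <- logical(nrow(model$coords))
  in_set <- logical(nrow(model$coords))
  in_set[set] <- TRUE
  e <- model$edges
  out[e[in_set[e[, 2]], 1]] <- TRUE
  out[e[in_set[e[, 1]], 2]] <- TRUE
  out
}

#' Ventricular-coordinate window around an exit site
#'
#' The circuit window spans `ab_span` units of the apicobasal axis and
#' `rot_span` degrees of the rotational axis, centred on the exit, with the
#' full transmural extent. Apicobasal bounds are truncated at the `[0, 1]`
#' extremes (an exit at 0.1 gives the span `[0, 0.3]`); rotational bounds
#' wrap across the 0/360 seam.
#'
#' @param exit_uvc exit coordinates (named `ab`, `rot`, `tm`)
#' @param ab_span apicobasal window width (units)
#' @param rot_span rotational window width (degrees)
#' @return list with `ab = c(lo, hi)` and `rot = c(lo, hi)` (`rot` may have
#'   `lo > hi`, meaning the window crosses the seam)
#' @export
define_circuit_window <- function(exit_uvc, ab_span = 0.4, rot_span = 72) {
  ab_lo <- max(0, exit_uvc[["ab"]] - ab_span / 2)
  ab_hi <- min(1, exit_uvc[["ab"]] + ab_span / 2)
  rot_lo <- (exit_uvc[["rot"]] - rot_span / 2) %% 360
  rot_hi <- (exit_uvc[["rot"]] + rot_span / 2) %% 360
  list(ab = c(ab_lo, ab_hi), rot = c(rot_lo, rot_hi))
}

# logical: uvc rows inside a circuit window (rotational wrap-aware)
in_circuit_window <- function(uvc, window) {
  ab_ok <- uvc[, "ab"] >= window$ab[1] & uvc[, "ab"] <= window$ab[2]
  r <- uvc[, "rot"]
  rot_ok <- if (window$rot[1] <= window$rot[2]) {
    r >= window$rot[1] & r <= window$rot[2]
  } else {
    r >= window$rot[1] | r <= window$rot[2]
  }
  ab_ok & rot_ok
}

#' Decompose one VT cycle into eight isochrones over the circuit window
#'
#' Bin edges are uniform over one cycle anchored at the exit-site
#' activation: isochrone 1 begins at the exit activation and isochrone 8
#' ends at the next cycle's exit activation. Every in-window node that
#' activates in that cycle receives a bin.
#'
#' @param episode a `vt_episode`
#' @param model the `ventricular_model`
#' @param exit_node exit node id (from [locate_exit_site()])
#' @param window a [define_circuit_window()] result
#' @param n_bins number of isochrones
#' @return integer isochrone (1..n_bins) per node; NA outside the window or
#'   for nodes that did not activate in the anchored cycle
#' @export
circuit_isochrones <- function(episode, model, exit_node, window, n_bins = 8) {
  ev <- episode$events
  t_exit <- sort(ev$time[ev$node == exit_node])
  if (!length(t_exit)) stop("exit node never activates in the episode")
  cl <- episode$cycle_length
  t0 <- t_exit[1]
  inw <- in_circuit_window(model$uvc, window)
  iso <- rep(NA_integer_, nrow(model$coords))
  sub <- ev[inw[ev$node] & ev$time >= t0 & ev$time < t0 + cl, ]
  if (nrow(sub)) {
    first <- tapply(sub$time, sub$node, min)
    nodes <- as.integer(names(first))
    phase <- (first - t0) / cl
    iso[nodes] <- as.integer(pmin(floor(phase * n_bins) + 1, n_bins))
  }
  iso
}

#' Project circuit isochrones onto a mapping surface
#'
#' Each in-window surface point receives the most frequently occurring
#' isochrone among myocardial nodes within a 5 mm (Euclidean) radius; ties
#' break toward the lower (earlier) isochrone. Points with no binned node
#' in the radius stay unassigned.
#'
#' @param surface an `eam_surface`
#' @param model the `ventricular_model`
#' @param iso node isochrones from [circuit_isochrones()]
#' @param window the circuit window
#' @param radius search radius (mm)
#' @return integer isochrone per surface point (NA where unassigned)
#' @export
project_circuit <- function(surface, model, iso, window, radius = 5) {
  out <- rep(NA_integer_, nrow(surface$points))
  binned <- which(!is.na(iso))
  if (!length(binned)) return(out)
  co <- model$coords[binned, , drop = FALSE]
  inw <- in_circuit_window(surface$uvc, window) & !surface$lid
  for (i in which(inw)) {
    d2 <- (co[, 1] - surface$points[i, 1])^2 +
      (co[, 2] - surface$points[i, 2])^2 + (co[, 3] - surface$points[i, 3])^2
    sel <- d2 <= radius^2
    if (!any(sel)) next
    tab <- table(iso[binned[sel]])
    best <- max(tab)
    out[i] <- min(as.integer(names(tab)[tab == best]))  # tie -> lower index
  }
  out
}

#' Split a projected circuit into inner/outer subregions per side
#'
#' The outer circuit comprises surface points activated during isochrones
#' 1-4 (the first half of the cycle, beginning at the exit); the inner
#' circuit — which contains the critical VT site targeted by ablation —
#' comprises isochrones 5-8. Subregions are formed per side
#' (endocardium/epicardium); empty subregions are flagged, mirroring VTs
#' whose circuit lacks an endocardial or epicardial component.
#'
#' @param projection per-point isochrones from [project_circuit()]
#' @param surface the `eam_surface`
#' @return list of four subregions (`endo_outer`, `endo_inner`,
#'   `epi_outer`, `epi_inner`), each with `points` (indices) and `empty`
#' @export
split_inner_outer <- function(projection, surface) {
  halves <- list(outer = 1:4, inner = 5:8)
  out <- list()
  for (s in c("endo", "epi")) {
    for (h in names(halves)) {
      pts <- which(surface$side == s & !surface$lid &
                     projection %in% halves[[h]])
      out[[paste(s, h, sep = "_")]] <- list(points = pts,
                                            empty = length(pts) == 0L)
    }
  }
  out
}

#' Mean EAM features over circuit subregions
#'
#' @param subregions from [split_inner_outer()]
#' @param fmap a `feature_map`
#' @return data.frame: subregion, side, half, n_points and the mean of each
#'   feature over the subregion's points (NA when empty)
#' @export
subregion_feature_means <- function(subregions, fmap) {
  feats <- eam_feature_names()
  rows <- lapply(names(subregions), function(nm) {
    pts <- subregions[[nm]]$points
    mm <- vapply(feats, function(f) {
      if (!length(pts)) NA_real_ else mean(fmap[[f]][pts], na.rm = TRUE)
    }, numeric(1))
    parts <- strsplit(nm, "_")[[1]]
    cbind(data.frame(subregion = nm, side = parts[1], half = parts[2],
                     n_points = length(pts)), as.data.frame(as.list(mm)))
  })
  do.call(rbind, rows)
}

#' Rank pacing sites by distance to a VT circuit
#'
#' Each site's geodesic distance (along its own surface) to the surface
#' projection of the circuit's exit site is computed; sites are ranked from
#' most proximal (1) to most distal (P), ties broken by site id.
#'
#' @param sites a `pacing_sites` data.frame
#' @param surface the `eam_surface`
#' @param model the `ventricular_model`
#' @param exit_node circuit exit node id
#' @return the sites data.frame with `vt_distance` (mm) and `vt_rank`
#' @export
rank_sites_by_vt <- function(sites, surface, model, exit_node) {
  exit_pos <- model$coords[exit_node, ]
  d_out <- numeric(nrow(sites))
  for (s in c("endo", "epi")) {
    side_pts <- which(surface$side == s & !surface$lid)
    d2 <- rowSums(sweep(surface$points[side_pts, , drop = FALSE], 2, exit_pos)^2)
    proj <- side_pts[which.min(d2)]
    dd <- as.vector(igraph::distances(surface$graph, v = proj))
    sel <- sites$side == s
    d_out[sel] <- dd[sites$point[sel]]
  }
  sites$vt_distance <- d_out
  sites$vt_rank <- rank(d_out, ties.method = "first")
  sites
}

#' Full circuit analysis of one induced episode
#'
#' Convenience wrapper: exit site, window, 8-isochrone decomposition,
#' surface projection and inner/outer subregions.
#'
#' @param episode a `vt_episode`
#' @param model the simulated `ventricular_model`
#' @param surface an `eam_surface`
#' @param ab_span,rot_span circuit window spans
#' @return an object of class `vt_circuit`
#' @export
analyze_vt_circuit <- function(episode, model, surface,
                               ab_span = 0.4, rot_span = 72) {
  exit_node <- if (!is.null(episode$exit_node)) episode$exit_node else
    locate_exit_site(episode, model)
  exit_uvc <- model$uvc[exit_node, ]
  window <- define_circuit_window(exit_uvc, ab_span, rot_span)
  iso <- circuit_isochrones(episode, model, exit_node, window)
  projection <- project_circuit(surface, model, iso, window)
  subregions <- split_inner_outer(projection, surface)
  structure(list(episode = episode, exit_node = exit_node,
                 exit_uvc = exit_uvc, window = window, node_isochrone = iso,
                 projection = projection, subregions = subregions,
                 cycle_length = episode$cycle_length),
            class = "vt_circuit")
}

#' @export
print.vt_circuit <- function(x, ...) {
  cat("vt_circuit: exit node", x$exit_node, "cycle length",
      round(x$cycle_length, 1), "ms; projected points:",
      sum(!is.na(x$projection)), "\n")
  invisible(x)
}
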
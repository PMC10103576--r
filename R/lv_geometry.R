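#' Build an idealized voxelized left ventricle
#'
#' Constructs a truncated prolate-ellipsoid shell of myocardial voxels as a
#' stand-in for an image-derived LV. The epicardial surface is the ellipsoid
#' with semi-axes `epi_axes`; the endocardial surface is the concentric
#' ellipsoid shrunk by `wall` on every axis. The shell is cut by a base plane
#' so that a fraction `truncation` of the full long-axis extent is kept,
#' measured from the apex.
#'
#' Nodes are voxel centres on a regular grid. Only the largest 6-connected
#' component is retained so the model is a single conducting domain.
#'
#' @param epi_axes epicardial semi-axes (mm), length 3, long axis last
#' @param wall wall thickness (mm); must be at least `2 * voxel_size`
#' @param truncation fraction of the apex-to-base long-axis extent kept
#' @param voxel_size voxel edge length (mm)
#' @return an object of class `ventricular_model`: voxel coordinates,
#'   integer grid indices, 6-neighbour edge list, per-node tissue labels
#'   (all `"normal"` initially), and the shape parameters. Coordinates are in
#'   mm with the ellipsoid centre at the origin and the apex at negative z.
#' @export
build_idealized_lv <- function(epi_axes = c(34, 34, 70), wall = 10,
                               truncation = 0.7, voxel_size = 2) {
  stopifnot(length(epi_axes) == 3, all(epi_axes > 0), truncation > 0, truncation <= 1)
  if (wall < 2 * voxel_size) {
    stop("wall thickness (", wall, " mm) must be at least two voxels (",
         2 * voxel_size, " mm) to resolve transmural structure")
  }
  endo_axes <- epi_axes - wall
  if (any(endo_axes <= 0)) stop("wall thickness exceeds an epicardial semi-axis")
  c_epi <- epi_axes[3]
  z_base <- c_epi * (2 * truncation - 1)

  # voxel-centre grid covering the bounding box
  gx <- seq(-epi_axes[1], epi_axes[1], by = voxel_size)
  gy <- seq(-epi_axes[2], epi_axes[2], by = voxel_size)
  gz <- seq(-c_epi, z_base + voxel_size / 2, by = voxel_size)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  u_epi <- sqrt((grid[, 1] / epi_axes[1])^2 + (grid[, 2] / epi_axes[2])^2 +
                  (grid[, 3] / epi_axes[3])^2)
  u_endo <- sqrt((grid[, 1] / endo_axes[1])^2 + (grid[, 2] / endo_axes[2])^2 +
                   (grid[, 3] / endo_axes[3])^2)
  keep <- u_epi <= 1 & u_endo >= 1 & grid[, 3] <= z_base
  coords <- grid[keep, , drop = FALSE]
  if (nrow(coords) < 8) stop("degenerate geometry: almost no myocardial voxels")

  idx <- cbind(round((coords[, 1] - gx[1]) / voxel_size),
               round((coords[, 2] - gy[1]) / voxel_size),
               round((coords[, 3] - gz[1]) / voxel_size))
  storage.mode(idx) <- "integer"
  nx <- length(gx); ny <- length(gy)
  key <- idx[, 1] + nx * (idx[, 2] + ny * idx[, 3])
  lookup <- new.env(hash = TRUE, size = length(key))

  edges <- voxel_edges(idx, key, nx, ny)
  n <- nrow(coords)
  comp <- connected_components(n, edges)
  main <- which(comp == which.max(tabulate(comp)))
  if (length(main) < n) {
    remap <- integer(n); remap[main] <- seq_along(main)
    coords <- coords[main, , drop = FALSE]
    idx <- idx[main, , drop = FALSE]
    key <- key[main]
    edges <- edges[comp[edges[, 1]] == comp[main[1]], , drop = FALSE]
    edges <- cbind(remap[edges[, 1]], remap[edges[, 2]])
  }

  structure(list(
    voxel_size = voxel_size,
    coords = coords,
    grid_index = idx,
    grid_key = key,
    grid_dims = c(nx, ny, length(gz)),
    grid_origin = c(gx[1], gy[1], gz[1]),
    edges = edges,                      # 6-connected, each pair once (i < j)
    label = rep("normal", nrow(coords)),
    epi_axes = epi_axes, endo_axes = endo_axes,
    wall = wall, z_base = z_base, z_apex = -c_epi
  ), class = "ventricular_model")
}

# 6-neighbour edge list (i < j) from integer grid indices
voxel_edges <- function(idx, key, nx, ny) {
  ord <- order(key)
  skey <- key[ord]
  find <- function(k) {
    pos <- findInterval(k, skey)
    hit <- pos > 0 & skey[pmax(pos, 1)] == k
    out <- rep(NA_integer_, length(k))
    out[hit] <- ord[pos[hit]]
    out
  }
  res <- vector("list", 3)
  steps <- c(1L, nx, nx * ny)
  for (d in 1:3) {
    j <- find(key + steps[d])
    ok <- !is.na(j)
    i_ok <- which(ok); j_ok <- j[ok]
    # guard against key wrap-around at grid boundaries
    good <- idx[j_ok, d] - idx[i_ok, d] == 1L &
      rowSums(abs(idx[j_ok, , drop = FALSE] - idx[i_ok, , drop = FALSE])) == 1L
    res[[d]] <- cbind(i_ok[good], j_ok[good])
  }
  do.call(rbind, res)
}

# union-find over an edge list
connected_components <- function(n, edges) {
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(edges))) {
    a <- find_root(edges[e, 1]); b <- find_root(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find_root, integer(1))
}

#' Assign ventricular coordinates to every node
#'
#' Attaches the normalized coordinate triple used to compare positions across
#' hearts: apicobasal (0 at the apex, 1 at the base plane), rotational
#' (degrees around the long axis, counter-clockwise from the lateral wall,
#' in `[0, 360)`), and transmural (0 on the endocardium, 1 on the
#' epicardium). On this analytic geometry the coordinates are computed in
#' closed form from the node position relative to the two bounding
#' ellipsoids.
#'
#' @param model a `ventricular_model`
#' @return the model with an `uvc` matrix (columns `ab`, `rot`, `tm`)
#' @export
assign_uvc <- function(model) {
  co <- model$coords
  ab <- (co[, 3] - model$z_apex) / (model$z_base - model$z_apex)
  rot <- (atan2(co[, 2], co[, 1]) * 180 / pi) %% 360
  u_endo <- sqrt(rowSums(sweep(co, 2, model$endo_axes, "/")^2))
  u_epi <- sqrt(rowSums(sweep(co, 2, model$epi_axes, "/")^2))
  d_endo <- pmax(u_endo - 1, 0)
  d_epi <- pmax(1 - u_epi, 0)
  tm <- d_endo / pmax(d_endo + d_epi, 1e-12)
  model$uvc <- cbind(ab = pmin(pmax(ab, 0), 1), rot = rot, tm = pmin(pmax(tm, 0), 1))
  model
}

#' Assign a rule-based helical fibre field
#'
#' The fibre direction at each node lies in the plane tangent to the local
#' ellipsoidal shell and makes a helix angle with the circumferential
#' direction that interpolates linearly in the transmural coordinate from
#' `endo_helix` on the endocardium to `epi_helix` on the epicardium — the
#' standard rule-based construction for ventricular myofibre architecture.
#'
#' @param model a `ventricular_model` with `uvc` assigned
#' @param endo_helix,epi_helix helix angles in degrees
#' @return the model with a unit `fibre` matrix (n x 3)
#' @export
assign_fibres <- function(model, endo_helix = 60, epi_helix = -60) {
  if (is.null(model$uvc)) stop("assign_uvc() must be called before assign_fibres()")
  tm <- model$uvc[, "tm"]
  axes <- sweep(outer(tm, model$epi_axes - model$endo_axes), 2,
                model$endo_axes, "+")  # interpolated local ellipsoid
  nrm <- normalize_rows(model$coords / axes^2)
  zax <- matrix(rep(c(0, 0, 1), each = nrow(nrm)), ncol = 3)
  circ <- cross3(zax, nrm)
  deg <- row_norms(circ) < 1e-6       # apex: normal parallel to long axis
  if (any(deg)) {
    yax <- matrix(rep(c(0, 1, 0), each = sum(deg)), ncol = 3)
    circ[deg, ] <- cross3(yax, nrm[deg, , drop = FALSE])
  }
  circ <- normalize_rows(circ)
  long <- cross3(nrm, circ)
  helix <- (endo_helix + tm * (epi_helix - endo_helix)) * pi / 180
  model$fibre <- circ * cos(helix) + long * sin(helix)
  model$helix <- helix * 180 / pi
  model
}

# meridian arc-length table of an ellipse cross-section (radius a, height c),
# from apex angle 0 to theta_max
meridian_rings <- function(a, c_ax, theta_max, spacing) {
  th <- seq(0, theta_max, length.out = 4096)
  ds <- sqrt((a * cos(th))^2 + (c_ax * sin(th))^2)
  s <- c(0, cumsum((ds[-1] + ds[-length(th)]) / 2 * diff(th)))
  total <- s[length(s)]
  n_rings <- max(3L, round(total / spacing))
  targets <- seq(0, total, length.out = n_rings + 1)
  approx(s, th, xout = targets)$y
}

# triangulate the band between two rings of point indices (closed loops),
# walking both loops by azimuthal angle
band_triangles <- function(ring1, ring2, ang1, ang2) {
  n1 <- length(ring1); n2 <- length(ring2)
  tris <- matrix(0L, n1 + n2, 3)
  i <- 1L; j <- 1L; k <- 0L
  a1 <- c(ang1, ang1[1] + 2 * pi)
  a2 <- c(ang2, ang2[1] + 2 * pi)
  while (i <= n1 || j <= n2) {
    k <- k + 1L
    adv1 <- if (i > n1) FALSE else if (j > n2) TRUE else a1[i + 1] <= a2[j + 1]
    if (adv1) {
      tris[k, ] <- c(ring1[(i - 1L) %% n1 + 1L], ring1[i %% n1 + 1L],
                     ring2[(j - 1L) %% n2 + 1L])
      i <- i + 1L
    } else {
      tris[k, ] <- c(ring2[(j - 1L) %% n2 + 1L], ring1[(i - 1L) %% n1 + 1L],
                     ring2[j %% n2 + 1L])
      j <- j + 1L
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

# closed triangulated truncated ellipsoid (lateral shell + flat basal lid);
# returns points, triangles and a logical lid flag per point
triangulate_side <- function(axes, z_base, target_edge) {
  a <- axes[1]; c_ax <- axes[3]
  theta_max <- acos(pmin(pmax(-z_base / c_ax, -1), 1))
  az <- 0.95 * target_edge               # azimuthal spacing and ring spacing,
  row_h <- 0.87 * target_edge            # calibrated so the mean edge of the
  th <- meridian_rings(a, c_ax, theta_max, row_h)  # output mesh ~ target_edge
  pts <- matrix(c(0, 0, -c_ax), 1, 3)
  lid <- FALSE
  rings <- list(1L)
  angs <- list(0)
  for (t in th[-1]) {
    r <- a * sin(t); z <- -c_ax * cos(t)
    nak <- max(3L, round(2 * pi * r / az))
    ang <- 2 * pi * (seq_len(nak) - 1) / nak + (length(rings) %% 2) * pi / nak
    ring_pts <- cbind(r * cos(ang), r * sin(ang), z)
    rings[[length(rings) + 1L]] <- nrow(pts) + seq_len(nak)
    angs[[length(angs) + 1L]] <- ang
    pts <- rbind(pts, ring_pts)
    lid <- c(lid, rep(FALSE, nak))
  }
  # basal lid: rings shrinking to the lid centre at z = z_base
  r_rim <- a * sin(theta_max)
  n_lid <- max(1L, round(r_rim / row_h))
  lid_radii <- r_rim * (n_lid - seq_len(n_lid)) / n_lid
  for (r in lid_radii) {
    if (r < row_h / 2) break
    nak <- max(3L, round(2 * pi * r / az))
    ang <- 2 * pi * (seq_len(nak) - 1) / nak + (length(rings) %% 2) * pi / nak
    rings[[length(rings) + 1L]] <- nrow(pts) + seq_len(nak)
    angs[[length(angs) + 1L]] <- ang
    pts <- rbind(pts, cbind(r * cos(ang), r * sin(ang), z_base))
    lid <- c(lid, rep(TRUE, nak))
  }
  rings[[length(rings) + 1L]] <- nrow(pts) + 1L
  angs[[length(angs) + 1L]] <- 0
  pts <- rbind(pts, c(0, 0, z_base))
  lid <- c(lid, TRUE)

  tris <- list()
  # apex fan
  r2 <- rings[[2]]
  n2 <- length(r2)
  tris[[1]] <- cbind(1L, r2, r2[c(2:n2, 1L)])
  for (b in 2:(length(rings) - 2)) {
    tris[[b]] <- band_triangles(rings[[b]], rings[[b + 1]], angs[[b]], angs[[b + 1]])
  }
  # centre fan of the lid
  rl <- rings[[length(rings) - 1L]]
  nl <- length(rl)
  ctr <- rings[[length(rings)]]
  tris[[length(tris) + 1L]] <- cbind(ctr, rl[c(2:nl, 1L)], rl)
  list(points = pts, triangles = do.call(rbind, tris), lid = lid)
}

#' Extract triangulated endocardial and epicardial mapping surfaces
#'
#' Builds one closed triangulated surface per side at a target edge length,
#' mimicking the resolution of clinical electroanatomic-mapping geometries.
#' The lateral shell follows the bounding ellipsoid of each side; a flat
#' triangulated lid closes the base so each surface is a closed genus-0
#' manifold. Lid points are flagged and excluded from mapping analyses.
#' Every point is linked to its nearest myocardial node (`volume_link`) for
#' activation-time transfer and label projection.
#'
#' @param model a `ventricular_model` with `uvc` assigned
#' @param target_edge target mean triangle edge length (mm)
#' @return an object of class `eam_surface`: `points`, `triangles`, `side`
#'   (`"endo"`/`"epi"` per point), `lid` flag, `uvc`, `volume_link`,
#'   `edge_lengths`, and an igraph `graph` on surface edges for geodesics
#' @export
extract_eam_surfaces <- function(model, target_edge = 2.0) {
  if (is.null(model$uvc)) stop("assign_uvc() must be called first")
  sides <- list(endo = triangulate_side(model$endo_axes, model$z_base, target_edge),
                epi = triangulate_side(model$epi_axes, model$z_base, target_edge))
  pts <- rbind(sides$endo$points, sides$epi$points)
  off <- nrow(sides$endo$points)
  tris <- rbind(sides$endo$triangles, sides$epi$triangles + off)
  side <- rep(c("endo", "epi"), c(nrow(sides$endo$points), nrow(sides$epi$points)))
  lid <- c(sides$endo$lid, sides$epi$lid)

  for (s in c("endo", "epi")) {
    tr <- sides[[s]]$triangles
    v <- nrow(sides[[s]]$points); f <- nrow(tr)
    ed <- unique(t(apply(rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)]), 1, sort)))
    if (v - nrow(ed) + f != 2L) {
      stop("internal error: ", s, " surface is not a closed genus-0 manifold")
    }
  }

  vl <- nearest_node(model, pts)
  e <- unique(t(apply(rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)]), 1, sort)))
  el <- row_norms(pts[e[, 1], , drop = FALSE] - pts[e[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- el

  uvc <- surface_uvc(model, pts)
  structure(list(points = pts, triangles = tris, side = side, lid = lid,
                 uvc = uvc, volume_link = vl$index, link_dist = vl$dist,
                 edges = e, edge_lengths = el, graph = g,
                 target_edge = target_edge),
            class = "eam_surface")
}

# analytic ventricular coordinates of arbitrary surface points
surface_uvc <- function(model, pts) {
  ab <- (pts[, 3] - model$z_apex) / (model$z_base - model$z_apex)
  rot <- (atan2(pts[, 2], pts[, 1]) * 180 / pi) %% 360
  u_endo <- sqrt(rowSums(sweep(pts, 2, model$endo_axes, "/")^2))
  u_epi <- sqrt(rowSums(sweep(pts, 2, model$epi_axes, "/")^2))
  d_endo <- pmax(u_endo - 1, 0); d_epi <- pmax(1 - u_epi, 0)
  tm <- d_endo / pmax(d_endo + d_epi, 1e-12)
  cbind(ab = pmin(pmax(ab, 0), 1), rot = rot, tm = pmin(pmax(tm, 0), 1))
}

# nearest myocardial node per query point: local grid search widening to a
# brute-force fallback (needed for lid-interior points over the cavity)
nearest_node <- function(model, pts) {
  vs <- model$voxel_size
  org <- model$grid_origin
  nx <- model$grid_dims[1]; ny <- model$grid_dims[2]; nz <- model$grid_dims[3]
  ord <- order(model$grid_key)
  skey <- model$grid_key[ord]
  n <- nrow(pts)
  index <- integer(n); dist <- numeric(n)
  offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  for (p in seq_len(n)) {
    ijk <- round((pts[p, ] - org) / vs)
    cand <- sweep(offs, 2, ijk, "+")
    ok <- cand[, 1] >= 0 & cand[, 1] < nx & cand[, 2] >= 0 & cand[, 2] < ny &
      cand[, 3] >= 0 & cand[, 3] < nz
    keys <- cand[ok, 1] + nx * (cand[ok, 2] + ny * cand[ok, 3])
    pos <- findInterval(keys, skey)
    hit <- pos > 0 & skey[pmax(pos, 1)] == keys
    ids <- ord[pos[hit]]
    if (!length(ids)) ids <- seq_len(nrow(model$coords))  # fallback: global
    d <- row_norms(sweep(model$coords[ids, , drop = FALSE], 2, pts[p, ]))
    best <- which.min(d)
    index[p] <- ids[best]; dist[p] <- d[best]
  }
  list(index = index, dist = dist)
}

#' Select evenly spaced pacing sites on each mapping surface
#'
#' Picks `n_per_surface` sites per side by farthest-point sampling under the
#' surface geodesic metric: after a seeded random start, each new site is the
#' point whose minimum geodesic distance to all previously chosen sites on
#' its side is largest. Lid points are never selected.
#'
#' @param surface an `eam_surface`
#' @param n_per_surface number of sites per side
#' @param seed integer seed controlling the starting point
#' @return a data.frame of class `pacing_sites`: `id`, `side`, `point`
#'   (surface point index), ventricular coordinates and position
#' @export
select_pacing_sites <- function(surface, n_per_surface = 50, seed = 1) {
  out <- list()
  for (s in c("endo", "epi")) {
    cand <- which(surface$side == s & !surface$lid)
    if (n_per_surface > length(cand)) {
      stop("n_per_surface = ", n_per_surface, " exceeds the ", length(cand),
           " available ", s, " surface points")
    }
    set.seed(derive_seed(seed, if (s == "endo") 1L else 2L))
    chosen <- cand[sample.int(length(cand), 1)]
    mind <- as.vector(igraph::distances(surface$graph, v = chosen))[cand]
    while (length(chosen) < n_per_surface) {
      nxt <- cand[which.max(mind)]
      chosen <- c(chosen, nxt)
      d <- as.vector(igraph::distances(surface$graph, v = nxt))[cand]
      mind <- pmin(mind, d)
    }
    out[[s]] <- data.frame(side = s, point = chosen)
  }
  res <- do.call(rbind, out)
  res <- cbind(id = seq_len(nrow(res)), res,
               surface$uvc[res$point, , drop = FALSE],
               x = surface$points[res$point, 1],
               y = surface$points[res$point, 2],
               z = surface$points[res$point, 3])
  rownames(res) <- NULL
  class(res) <- c("pacing_sites", "data.frame")
  res
}

#' @export
print.ventricular_model <- function(x, ...) {
  cat("ventricular_model:", nrow(x$coords), "nodes at", x$voxel_size, "mm voxels;",
      "labels:", paste(names(table(x$label)), table(x$label), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.eam_surface <- function(x, ...) {
  cat("eam_surface:", nrow(x$points), "points (",
      sum(x$side == "endo"), "endo /", sum(x$side == "epi"), "epi,",
      sum(x$lid), "lid ),", nrow(x$triangles), "triangles; mean edge",
      round(mean(x$edge_lengths), 3), "mm\n")
  invisible(x)
}
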
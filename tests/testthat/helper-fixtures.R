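# Shared fixtures, memoized across test files (expensive geometry and the
# cohort run are built once per session).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# coarse LV used by most tests (3 mm voxels, ~5k nodes)
coarse_model <- function() {
  fixture("coarse_model", function() {
    assign_fibres(assign_uvc(build_idealized_lv(voxel_size = 3)))
  })
}

coarse_surface <- function() {
  fixture("coarse_surface", function() extract_eam_surfaces(coarse_model(), 4))
}

coarse_neighbors <- function() {
  fixture("coarse_neighbors", function() surface_neighbors(coarse_surface(), 10))
}

# default-resolution LV (2 mm voxels / 2 mm surface), for the geometry
# contracts stated at the default resolution
default_model <- function() {
  fixture("default_model", function() {
    assign_fibres(assign_uvc(build_idealized_lv()))
  })
}

default_surface <- function() {
  fixture("default_surface", function() extract_eam_surfaces(default_model(), 2))
}

# engineered single-channel substrate on the coarse LV
channel_substrate <- function() {
  fixture("channel_substrate", function() {
    engineered_channel_substrate(coarse_model(), rot_halfwidth = 60)
  })
}

channel_model <- function() {
  fixture("channel_model", function() {
    set_tissue_labels(coarse_model(), channel_substrate())
  })
}

# induced episodes on the engineered substrate (expensive; shared between
# the circuit unit tests and the acceptance suite)
channel_episodes <- function() {
  fixture("channel_episodes", function() {
    induce_vt(channel_model(), n_induction_sites = 6, seed = 1)
  })
}

# the 8-heart cohort experiment shared by the cohort-level acceptance checks
cohort_run <- function() {
  fixture("cohort_run", function() {
    cfg <- experiment_config("standard", seed = 1,
                             out_dir = file.path(tempdir(), "eamsim_cohort"))
    run_experiment(cfg)
  })
}

# one captured S1 electrogram + feature map on the engineered substrate
build_one_map <- function() {
  m <- channel_model()
  s <- coarse_surface()
  ps <- select_pacing_sites(s, 2, seed = 1)
  ok <- NULL
  for (i in seq_len(nrow(ps))) {
    tr <- deliver_s1s2(m, as.numeric(ps[i, c("x", "y", "z")]))
    if (tr$capture[["S1"]]) { ok <- tr; break }
  }
  em <- compute_unipolar(ok, s, model = m, window = ok$beat_windows$S1,
                         site_id = 1)
  list(em = em, fm = extract_features(em, s, neighbors = coarse_neighbors()),
       s = s)
}

one_map <- function() fixture("one_map", build_one_map)

# a flat triangulated patch posing as an eam_surface, for analytic CV tests
make_flat_patch <- function(nx = 15, ny = 15, h = 2) {
  g2 <- expand.grid(x = (seq_len(nx) - 1) * h, y = (seq_len(ny) - 1) * h)
  pts <- cbind(as.matrix(g2), z = 0)
  id <- function(i, j) (j - 1L) * nx + i
  tris <- matrix(0L, 2 * (nx - 1) * (ny - 1), 3)
  k <- 0L
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      tris[k + 1L, ] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
      tris[k + 2L, ] <- c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
      k <- k + 2L
    }
  }
  e <- unique(t(apply(rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)]), 1, sort)))
  el <- sqrt(rowSums((pts[e[, 1], ] - pts[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- el
  structure(list(points = pts, triangles = tris,
                 side = rep("endo", nrow(pts)), lid = rep(FALSE, nrow(pts)),
                 uvc = cbind(ab = rep(0.5, nrow(pts)), rot = 0, tm = 0),
                 graph = g, edges = e, edge_lengths = el, target_edge = h),
            class = "eam_surface")
}

# deterministic small random signal at 400 Hz
random_signal <- function(n = 160, seed = 1) {
  set.seed(seed)
  cumsum(rnorm(n, sd = 0.3)) + rnorm(n, sd = 0.1)
}
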
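test_that("idealized LV shell is connected, populous and matches the analytic volume", {
  m <- default_model()
  expect_gt(nrow(m$coords), 10000)
  # connectivity: union of all edges spans every node
  g <- igraph::graph_from_edgelist(m$edges, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)

  # analytic truncated-shell volume (numeric integral oracle)
  shell_vol <- function(epi, endo, z_base) {
    f <- function(z) {
      a_e <- pi * epi[1] * epi[2] * pmax(1 - (z / epi[3])^2, 0)
      a_i <- pi * endo[1] * endo[2] * pmax(1 - (z / endo[3])^2, 0)
      a_e - a_i
    }
    stats::integrate(f, -epi[3], z_base, subdivisions = 500)$value
  }
  v_true <- shell_vol(c(34, 34, 70), c(24, 24, 60), m$z_base)
  for (vx in c(2, 1)) {
    mm <- if (vx == 2) m else build_idealized_lv(voxel_size = 1)
    v_model <- nrow(mm$coords) * vx^3
    expect_lt(abs(v_model - v_true) / v_true, 0.10)
  }
})

test_that("too-thin walls are rejected", {
  expect_error(build_idealized_lv(wall = 3, voxel_size = 2), "two voxels")
})

test_that("ventricular coordinates honour their boundary conditions", {
  m <- default_model()
  uvc <- m$uvc
  expect_true(all(uvc[, "ab"] >= 0 & uvc[, "ab"] <= 1))
  expect_true(all(uvc[, "rot"] >= 0 & uvc[, "rot"] < 360))
  expect_true(all(uvc[, "tm"] >= 0 & uvc[, "tm"] <= 1))
  apex <- which.min(m$coords[, 3])
  expect_lte(uvc[apex, "ab"], 0.02)
  # a node essentially on the endocardial surface
  u_endo <- sqrt(rowSums(sweep(m$coords, 2, m$endo_axes, "/")^2))
  nd <- which.min(abs(u_endo - 1.01))
  expect_lte(uvc[nd, "tm"], 0.1)
  # opposite sides of the cavity at equal height differ by ~180 degrees
  mid <- which(abs(m$coords[, 3]) < 1 & abs(m$coords[, 2]) < m$voxel_size / 2)
  a <- mid[which.max(m$coords[mid, 1])]
  b <- mid[which.min(m$coords[mid, 1])]
  dd <- abs(uvc[a, "rot"] - uvc[b, "rot"])
  expect_lt(abs(min(dd, 360 - dd) - 180), 15)
})

test_that("rule-based fibres are unit, tangent and helical", {
  m <- default_model()
  expect_true(all(abs(sqrt(rowSums(m$fibre^2)) - 1) < 1e-6))
  # midwall helix angle ~ 0
  mid <- which(abs(m$uvc[, "tm"] - 0.5) < 0.02)
  expect_true(all(abs(m$helix[mid]) < 2 + 60 * 0.02 * 2))
  # tangency against the local transmural direction, computed here as the
  # numerical gradient of the closed-form transmural coordinate field
  tm_field <- function(p) {
    u_en <- sqrt(sum((p / m$endo_axes)^2)); u_ep <- sqrt(sum((p / m$epi_axes)^2))
    d_en <- max(u_en - 1, 0); d_ep <- max(1 - u_ep, 0)
    d_en / max(d_en + d_ep, 1e-12)
  }
  set.seed(4)
  probe <- sample(nrow(m$coords), 300)
  mis <- vapply(probe, function(i) {
    p <- m$coords[i, ]
    g <- vapply(1:3, function(d) {
      e <- numeric(3); e[d] <- 0.05
      (tm_field(p + e) - tm_field(p - e)) / 0.1
    }, numeric(1))
    ng <- sqrt(sum(g^2))
    if (ng < 1e-9) return(0)
    abs(sum(m$fibre[i, ] * g / ng))
  }, numeric(1))
  expect_lt(max(mis), 0.15)
})

test_that("EAM surfaces meet the resolution, linkage and topology contracts", {
  s <- default_surface()
  m <- default_model()
  expect_gt(mean(s$edge_lengths), 1.8)
  expect_lt(mean(s$edge_lengths), 2.2)
  # every anatomical point links to a node within one voxel diagonal
  expect_lte(max(s$link_dist[!s$lid]), sqrt(3) * m$voxel_size + 1e-9)
  # Euler characteristic 2 per closed side (recomputed from scratch)
  for (sd in c("endo", "epi")) {
    tri <- s$triangles[apply(matrix(s$side[s$triangles] == sd,
                                    ncol = 3), 1, all), , drop = FALSE]
    v <- length(unique(as.vector(tri)))
    ed <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]), 1, sort)))
    expect_identical(v - nrow(ed) + nrow(tri), 2L)
  }
  # determinism
  s2 <- extract_eam_surfaces(m, 2)
  expect_identical(s$points, s2$points)
  expect_identical(s$triangles, s2$triangles)
})

test_that("pacing-site selection returns the standardized evenly spaced set", {
  s <- default_surface()
  ps <- select_pacing_sites(s, 50, seed = 1)
  expect_identical(nrow(ps), 100L)
  expect_identical(anyDuplicated(ps$id), 0L)
  expect_identical(as.vector(table(ps$side)), c(50L, 50L))
  expect_false(any(s$lid[ps$point]))
  # reproducible under a fixed seed
  expect_identical(select_pacing_sites(s, 1, seed = 9),
                   select_pacing_sites(s, 1, seed = 9))
})

test_that("each added site is the farthest point from the chosen set", {
  s <- coarse_surface()
  ps <- select_pacing_sites(s, 6, seed = 2)
  for (sd in c("endo", "epi")) {
    sel <- ps$point[ps$side == sd]
    cand <- which(s$side == sd & !s$lid)
    d <- igraph::distances(s$graph, v = sel)[, cand]
    for (k in 2:length(sel)) {
      mind <- apply(d[seq_len(k - 1), , drop = FALSE], 2, min)
      expect_equal(mind[match(sel[k], cand)], max(mind), tolerance = 1e-9)
    }
  }
})

test_that("farthest-point spread is near the best greedy spread over all starts", {
  s <- coarse_surface()
  k <- 5
  cand <- which(s$side == "endo" & !s$lid)
  cand <- cand[seq(1, length(cand), by = 4)]   # coarsened candidate set
  dmat <- igraph::distances(s$graph, v = cand)[, cand]
  greedy_minpair <- function(start) {
    sel <- start
    repeat {
      mind <- apply(dmat[sel, , drop = FALSE], 2, min)
      if (length(sel) == k) break
      sel <- c(sel, which.max(mind))
    }
    min(dmat[sel, sel][upper.tri(diag(length(sel)))])
  }
  best <- max(vapply(seq_along(cand), greedy_minpair, numeric(1)))
  ps <- select_pacing_sites(s, k, seed = 3)
  sel <- ps$point[ps$side == "endo"]
  ours <- min(igraph::distances(s$graph, v = sel, to = sel)[upper.tri(diag(k))])
  expect_gte(ours, 0.9 * best)
})
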
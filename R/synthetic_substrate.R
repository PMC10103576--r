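#' Generate a synthetic infarct distribution
#'
#' Emulates patchy post-infarct remodelling: one or more seed foci at
#' mid-wall depth are grown by stochastic dilation on the voxel graph until
#' the remodelled set (dense core plus border zone) reaches
#' `target_fraction` of the myocardial volume. The interior of the
#' remodelled set is labelled dense core, leaving a border-zone rim of about
#' two voxels; the core is additionally capped at `core_to_bz_ratio` of the
#' remodelled volume.
#'
#' @param model a `ventricular_model` with `uvc` assigned
#' @param target_fraction fraction of nodes to remodel, in `[0, 0.8)`
#' @param core_to_bz_ratio maximum dense-core share of the remodelled set
#' @param n_foci number of infarct foci (default 1-4, seeded choice)
#' @param seed integer seed; identical seed and parameters give identical
#'   labels
#' @return an object of class `tissue_labels`: per-node `label`
#'   (`normal`/`border_zone`/`dense_core`), achieved `remodelling_fraction`,
#'   and generator metadata
#' @export
generate_infarct <- function(model, target_fraction, core_to_bz_ratio = 0.4,
                             n_foci = NULL, seed = 1) {
  stopifnot(target_fraction >= 0, target_fraction < 0.8)
  n <- nrow(model$coords)
  lab <- rep("normal", n)
  if (target_fraction > 0) {
    set.seed(derive_seed(seed, 11L))
    if (is.null(n_foci)) n_foci <- sample(1:4, 1)
    adj <- adjacency_list(n, model$edges)
    mid <- which(model$uvc[, "tm"] > 0.2 & model$uvc[, "tm"] < 0.8)
    if (!length(mid)) mid <- seq_len(n)
    target_n <- round(target_fraction * n)
    inf <- sample(mid, min(n_foci, length(mid)))
    in_set <- logical(n)
    in_set[inf] <- TRUE
    iter <- 0L
    while (sum(in_set) < target_n) {
      iter <- iter + 1L
      if (iter > 10 * n) stop("infarct growth failed to reach the target fraction")
      frontier <- unique(unlist(adj[in_set]))
      frontier <- frontier[!in_set[frontier]]
      if (!length(frontier)) {
        stop("infarct growth exhausted the connected tissue before reaching ",
             "the target fraction")
      }
      # acceptance scales with the number of already-remodelled neighbours,
      # which keeps the growing region compact (concavities fill in first)
      support <- vapply(frontier, function(i) sum(in_set[adj[[i]]]), integer(1))
      take <- frontier[runif(length(frontier)) < 0.3 * support]
      need <- target_n - sum(in_set)
      if (length(take) > need) take <- sample(take, need)
      in_set[take] <- TRUE
    }
    lab[in_set] <- "border_zone"
    # dense core: erode the remodelled set so a ~2-voxel border-zone rim remains
    core <- erode_set(in_set, adj, steps = 2)
    max_core <- round(core_to_bz_ratio * sum(in_set))
    while (sum(core) > max_core) core <- erode_set(core, adj, steps = 1)
    lab[core] <- "dense_core"
  }
  structure(list(label = lab,
                 remodelling_fraction = mean(lab != "normal"),
                 target_fraction = target_fraction,
                 core_to_bz_ratio = core_to_bz_ratio, seed = seed,
                 channel_mouths = list()),
            class = "tissue_labels")
}

# neighbour list from an (i < j) edge list
adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  spl1 <- split(edges[, 2], edges[, 1])
  spl2 <- split(edges[, 1], edges[, 2])
  for (k in names(spl1)) adj[[as.integer(k)]] <- spl1[[k]]
  for (k in names(spl2)) {
    i <- as.integer(k)
    adj[[i]] <- c(adj[[i]], spl2[[k]])
  }
  adj
}

# remove `steps` boundary layers from a logical node set
erode_set <- function(in_set, adj, steps = 1) {
  out <- in_set
  for (s in seq_len(steps)) {
    # domain boundary (endo/epi surface) does not count: scar may be transmural
    boundary <- which(out)[vapply(which(out), function(i) {
      any(!out[adj[[i]]])
    }, logical(1))]
    out[boundary] <- FALSE
    if (!any(out)) break
  }
  out
}

#' Carve border-zone conducting channels through the dense core
#'
#' Each channel is a corridor of border-zone tissue cut through the dense
#' core along a shortest path between two "mouth" nodes — normal-tissue
#' nodes adjacent to the remodelled region on roughly opposite sides of the
#' core. Channel nodes previously labelled dense core become border zone, so
#' the remodelling fraction is unchanged; the result is a slow-conducting
#' isthmus that supports re-entry.
#'
#' @param labels a `tissue_labels`
#' @param model the matching `ventricular_model`
#' @param n_channels number of channels to carve
#' @param width channel width (mm)
#' @param seed integer seed (mouth selection)
#' @return the updated `tissue_labels`, with `channel_mouths` recording the
#'   node pair of each carved channel
#' @export
carve_channels <- function(labels, model, n_channels = 1, width = 4, seed = 1) {
  if (n_channels < 1) return(labels)
  lab <- labels$label
  if (!any(lab == "dense_core")) {
    warning("no dense core present; no channel carved")
    return(labels)
  }
  set.seed(derive_seed(seed, 23L))
  n <- nrow(model$coords)
  adj <- adjacency_list(n, model$edges)
  for (ch in seq_len(n_channels)) {
    core <- which(lab == "dense_core")
    centroid <- colMeans(model$coords[core, , drop = FALSE])
    remod <- lab != "normal"
    mouths <- which(!remod & vapply(seq_len(n), function(i) {
      any(remod[adj[[i]]])
    }, logical(1)))
    if (length(mouths) < 2) break
    rel <- sweep(model$coords[mouths, , drop = FALSE], 2, centroid)
    a <- mouths[sample.int(length(mouths), 1)]
    da <- rel[match(a, mouths), ]
    # the opposite mouth: most anti-aligned with the first, then farthest
    align <- rel %*% (da / sqrt(sum(da^2)))
    b <- mouths[which.min(align + 1e-6 * seq_along(mouths))]
    # shortest path from a to b allowed only through remodelled tissue
    g <- igraph::graph_from_edgelist(model$edges, directed = FALSE)
    allowed <- remod
    allowed[c(a, b)] <- TRUE
    wts <- ifelse(allowed[model$edges[, 1]] & allowed[model$edges[, 2]], 1, 1e6)
    path <- igraph::shortest_paths(g, from = a, to = b, weights = wts)$vpath[[1]]
    path <- as.integer(path)
    if (length(path) < 2) next
    d_to_path <- apply(model$coords[path, , drop = FALSE], 1, function(p) {
      row_norms(sweep(model$coords, 2, p))
    })
    near <- apply(d_to_path, 1, min) <= width / 2
    lab[near & lab == "dense_core"] <- "border_zone"
    labels$channel_mouths[[length(labels$channel_mouths) + 1L]] <- c(a, b)
  }
  labels$label <- lab
  labels$remodelling_fraction <- mean(lab != "normal")
  labels
}

#' Deterministic single-channel test substrate
#'
#' A designed (non-random) infarct used to validate the re-entry pipeline:
#' a dense-core sector of the wall spanning `rot_halfwidth` degrees either
#' side of `rot_center` and the apicobasal band `ab`, full transmural, with
#' a single border-zone conducting channel crossing it at `channel_ab` and
#' a one-voxel border-zone rim around the core. The channel's two mouths
#' (normal-tissue nodes at the channel ends) are recorded, so tests can
#' check that the detected VT exit lies at a designed mouth.
#'
#' @param model a `ventricular_model` with `uvc`
#' @param rot_center,rot_halfwidth rotational placement of the core (deg)
#' @param ab apicobasal band of the core
#' @param channel_ab apicobasal band of the channel
#' @return a `tissue_labels` with `channel_mouths` set
#' @export
engineered_channel_substrate <- function(model, rot_center = 180,
                                         rot_halfwidth = 45,
                                         ab = c(0.30, 0.80),
                                         channel_ab = c(0.50, 0.62)) {
  uvc <- model$uvc
  drot <- (uvc[, "rot"] - rot_center + 180) %% 360 - 180
  sector <- abs(drot) <= rot_halfwidth & uvc[, "ab"] >= ab[1] & uvc[, "ab"] <= ab[2]
  channel <- sector & uvc[, "ab"] >= channel_ab[1] & uvc[, "ab"] <= channel_ab[2]
  lab <- rep("normal", nrow(model$coords))
  lab[sector] <- "dense_core"
  lab[channel] <- "border_zone"
  # one-voxel border-zone rim around the core
  adj <- adjacency_list(nrow(model$coords), model$edges)
  core_idx <- which(lab == "dense_core")
  rim <- core_idx[vapply(core_idx, function(i) any(lab[adj[[i]]] == "normal"),
                         logical(1))]
  lab[rim] <- "border_zone"
  # channel mouths: the normal-tissue openings at the two rotational ends
  # of the channel (node sets, one per end)
  mouth_cand <- which(lab == "normal" & vapply(seq_len(nrow(model$coords)),
    function(i) any(channel[adj[[i]]]), logical(1)))
  dm <- (uvc[mouth_cand, "rot"] - rot_center + 180) %% 360 - 180
  mouths <- list(mouth_cand[dm < 0], mouth_cand[dm >= 0])
  mouths <- mouths[vapply(mouths, length, integer(1)) > 0]
  structure(list(label = lab, remodelling_fraction = mean(lab != "normal"),
                 target_fraction = NA_real_, core_to_bz_ratio = NA_real_,
                 seed = NA_integer_,
                 channel_mouths = mouths),
            class = "tissue_labels")
}

#' Apply tissue labels to a model
#' @param model a `ventricular_model`
#' @param labels a `tissue_labels` for the same model
#' @return the model with its `label` field replaced
#' @export
set_tissue_labels <- function(model, labels) {
  stopifnot(length(labels$label) == nrow(model$coords))
  model$label <- labels$label
  model
}

#' Generate a synthetic cohort of infarcted hearts
#'
#' Builds `n_hearts` models sharing one idealized geometry, with per-heart
#' infarct distributions whose remodelling fractions are spread evenly over
#' `[fraction_low, fraction_high]`, each with at least one conducting
#' channel. Hearts are split at the cohort median remodelling fraction into
#' hLIR (larger remodelling) and hSIR (smaller remodelling) groups.
#'
#' @param n_hearts number of hearts (>= 2)
#' @param fraction_low,fraction_high remodelling-fraction range
#' @param seed master seed; all per-heart randomness derives from it
#' @param geometry list of arguments for [build_idealized_lv()]
#' @param n_channels channels per heart
#' @return an object of class `synthetic_cohort`: shared `model` (geometry),
#'   per-heart `labels`, achieved `fractions`, `group` assignments and seeds
#' @export
generate_cohort <- function(n_hearts, fraction_low = 0.10, fraction_high = 0.50,
                            seed = 1, geometry = list(), n_channels = 1) {
  stopifnot(n_hearts >= 2)
  if (fraction_high <= fraction_low) stop("degenerate remodelling-fraction range")
  model <- do.call(build_idealized_lv, geometry)
  model <- assign_fibres(assign_uvc(model))
  fracs <- seq(fraction_low, fraction_high, length.out = n_hearts)
  hearts <- lapply(seq_len(n_hearts), function(i) {
    s <- derive_seed(seed, i)
    lb <- generate_infarct(model, fracs[i], seed = s)
    if (n_channels > 0 && any(lb$label == "dense_core")) {
      lb <- carve_channels(lb, model, n_channels = n_channels, seed = s)
    }
    list(labels = lb, seed = s, fraction = lb$remodelling_fraction)
  })
  achieved <- vapply(hearts, `[[`, numeric(1), "fraction")
  med <- median(achieved)
  grp <- ifelse(rank(achieved, ties.method = "first") > n_hearts / 2,
                "hLIR", "hSIR")
  structure(list(model = model, hearts = hearts, fractions = achieved,
                 group = grp, seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$hearts), "hearts, remodelling fractions",
      paste(round(range(x$fractions), 3), collapse = "-"),
      "( hLIR:", sum(x$group == "hLIR"), "/ hSIR:", sum(x$group == "hSIR"), ")\n")
  invisible(x)
}
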
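#' Project infarct remodelling onto a mapping surface
#'
#' A surface point is labelled as lying over infarct remodelling when at
#' least `threshold` (default 10%) of the myocardial nodes within a
#' `radius` (default 5 mm, Euclidean) are remodelled (border zone or dense
#' core). The threshold is sweepable from 0.10 to 0.50 for sensitivity
#' analyses; raising it can only shrink the remodelled point set.
#'
#' @param surface an `eam_surface`
#' @param model the labelled `ventricular_model`
#' @param radius search radius (mm)
#' @param threshold remodelled-fraction cutoff
#' @return an object of class `remodelling_surface`: data.frame with
#'   `point`, `side`, `fraction`, `remodelled` (logical; NA on lid points),
#'   and the threshold/radius used as attributes
#' @export
project_remodelling <- function(surface, model, radius = 5, threshold = 0.10) {
  pts <- surface$points
  co <- model$coords
  remod <- model$label != "normal"
  frac <- rep(NA_real_, nrow(pts))
  for (i in which(!surface$lid)) {
    d2 <- (co[, 1] - pts[i, 1])^2 + (co[, 2] - pts[i, 2])^2 +
      (co[, 3] - pts[i, 3])^2
    sel <- d2 <= radius^2
    frac[i] <- if (any(sel)) mean(remod[sel]) else 0
  }
  out <- data.frame(point = seq_len(nrow(pts)), side = surface$side,
                    fraction = frac, remodelled = frac >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "radius") <- radius
  class(out) <- c("remodelling_surface", "data.frame")
  out
}

#' Rank pacing sites by proximity to the infarct
#'
#' For each site, geodesic distances along its surface to every remodelled
#' surface point on that side are averaged into a single infarct-proximity
#' estimate; sites are then ranked most proximal (1) to most distal (P),
#' ties broken by site id. If one side carries no remodelled points, sites
#' on that side fall back to mean Euclidean distance to all remodelled
#' points.
#'
#' @param surface an `eam_surface`
#' @param sites a `pacing_sites` data.frame
#' @param surf_labels a `remodelling_surface`
#' @return sites with `infarct_distance` (mm) and `infarct_rank`
#' @export
rank_sites_by_infarct <- function(surface, sites, surf_labels) {
  remod_pts <- which(surf_labels$remodelled %in% TRUE)
  if (!length(remod_pts)) stop("no remodelled surface points; ranking undefined")
  d_out <- numeric(nrow(sites))
  for (s in c("endo", "epi")) {
    sel <- sites$side == s
    if (!any(sel)) next
    tgt <- remod_pts[surface$side[remod_pts] == s]
    if (length(tgt)) {
      d <- igraph::distances(surface$graph, v = sites$point[sel], to = tgt)
      d_out[sel] <- rowMeans(d)
    } else {
      all_t <- surface$points[remod_pts, , drop = FALSE]
      d_out[sel] <- vapply(sites$point[sel], function(p) {
        mean(row_norms(sweep(all_t, 2, surface$points[p, ])))
      }, numeric(1))
    }
  }
  sites$infarct_distance <- d_out
  sites$infarct_rank <- rank(d_out, ties.method = "first")
  sites
}

#' Concordance of one EAM feature between two paced maps
#'
#' The correlation (Pearson by default) of a feature's values over the
#' surface points valid in both maps, optionally restricted to remodelled
#' or non-injured points.
#'
#' @param mapA,mapB `feature_map`s of the same surface
#' @param feature one of [eam_feature_names()]
#' @param subset `"all"`, `"remodelled"` or `"non_injured"`
#' @param surf_labels `remodelling_surface` (required for subsets)
#' @param method correlation type (`"pearson"` or `"spearman"`)
#' @param min_points minimum common valid points
#' @return correlation in `[-1, 1]`, or NA when too few common points or
#'   zero variance
#' @export
feature_concordance <- function(mapA, mapB, feature, subset = "all",
                                surf_labels = NULL, method = "pearson",
                                min_points = 10) {
  a <- mapA[[feature]]
  b <- mapB[[feature]]
  ok <- !is.na(a) & !is.na(b)
  if (subset != "all") {
    if (is.null(surf_labels)) stop("surf_labels needed for subset concordance")
    sel <- if (subset == "remodelled") surf_labels$remodelled %in% TRUE
           else surf_labels$remodelled %in% FALSE
    ok <- ok & sel
  }
  if (sum(ok) < min_points) return(NA_real_)
  if (sd(a[ok]) < 1e-12 || sd(b[ok]) < 1e-12) return(NA_real_)
  cor(a[ok], b[ok], method = method)
}

#' Concordance over all map pairs of one heart
#'
#' @param fmaps list of `feature_map`s (same beat) keyed by site id
#' @param sites `pacing_sites` (for inter-site distances)
#' @param surface the `eam_surface`
#' @param surf_labels optional `remodelling_surface` for subset columns
#' @return data.frame: siteA, siteB, inter-site distance (mm, geodesic on a
#'   shared side, else Euclidean), feature, r (+ r_remodelled,
#'   r_non_injured when labels given)
#' @export
concordance_table <- function(fmaps, sites, surface, surf_labels = NULL) {
  ids <- as.integer(names(fmaps))
  if (length(ids) < 2) return(NULL)
  pos <- as.matrix(sites[match(ids, sites$id), c("x", "y", "z")])
  side <- sites$side[match(ids, sites$id)]
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      same <- side[i] == side[j]
      d <- if (same) {
        igraph::distances(surface$graph,
                          v = sites$point[match(ids[i], sites$id)],
                          to = sites$point[match(ids[j], sites$id)])[1, 1]
      } else {
        sqrt(sum((pos[i, ] - pos[j, ])^2))
      }
      for (f in eam_feature_names()) {
        r <- feature_concordance(fmaps[[i]], fmaps[[j]], f)
        row <- data.frame(siteA = ids[i], siteB = ids[j], distance = d,
                          feature = f, r = r)
        if (!is.null(surf_labels)) {
          row$r_remodelled <- feature_concordance(
            fmaps[[i]], fmaps[[j]], f, "remodelled", surf_labels)
          row$r_non_injured <- feature_concordance(
            fmaps[[i]], fmaps[[j]], f, "non_injured", surf_labels)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Cohort-level concordance summary
#'
#' Per-heart mean concordance per feature (mean over map pairs), the
#' across-cohort correlation of that mean with the heart's remodelling
#' fraction, and the within-heart correlation of pairwise concordance with
#' inter-site distance.
#'
#' @param heart_tables named list of [concordance_table()] results
#' @param fractions remodelling fraction per heart (same order)
#' @return list: `per_heart` (heart, feature, mean_r), `fraction_trend`
#'   (feature, r), `distance_trend` (feature, mean within-heart r); trends
#'   are NA when variance is degenerate
#' @export
concordance_summary <- function(heart_tables, fractions) {
  per_heart <- list()
  for (h in seq_along(heart_tables)) {
    tab <- heart_tables[[h]]
    if (is.null(tab)) next
    agg <- stats::aggregate(r ~ feature, tab, mean, na.rm = TRUE)
    agg$heart <- h
    per_heart[[h]] <- agg
  }
  per_heart <- do.call(rbind, per_heart)
  feats <- eam_feature_names()
  ftrend <- vapply(feats, function(f) {
    v <- per_heart$r[per_heart$feature == f][order(per_heart$heart[per_heart$feature == f])]
    fr <- fractions[sort(unique(per_heart$heart))]
    if (length(v) < 3 || sd(v) < 1e-12 || sd(fr) < 1e-12) return(NA_real_)
    cor(fr, v)
  }, numeric(1))
  dtrend <- vapply(feats, function(f) {
    rs <- vapply(heart_tables, function(tab) {
      if (is.null(tab)) return(NA_real_)
      sub <- tab[tab$feature == f & !is.na(tab$r), ]
      if (nrow(sub) < 3 || sd(sub$distance) < 1e-12 || sd(sub$r) < 1e-12)
        return(NA_real_)
      cor(sub$distance, sub$r)
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  list(per_heart = per_heart,
       fraction_trend = data.frame(feature = feats, r = ftrend),
       distance_trend = data.frame(feature = feats, r = dtrend))
}

#' Ridge-penalized logistic regression (IRLS)
#'
#' Small in-package fitter used by the regression ladders: maximizes the
#' binomial log-likelihood with an L2 penalty on the slopes (intercept
#' unpenalized), which keeps separable fits finite as covariates
#' accumulate.
#'
#' @param X covariate matrix (no intercept column)
#' @param y 0/1 outcome
#' @param lambda ridge strength
#' @param max_iter,tol IRLS controls
#' @return list with `coef` (intercept first) and fitted probabilities `p`
#' @export
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 50, tol = 1e-8) {
  X <- cbind(1, as.matrix(X))
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wts
    XtW <- t(X * wts)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) solve(XtW %*% X + pen + diag(1e-8, p), XtW %*% z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  list(coef = drop(beta), p = 1 / (1 + exp(-eta)))
}

#' Classification metrics for a probabilistic binary model
#'
#' AUROC by exhaustive concordant-pair counting (ties count 1/2), plus F1
#' (harmonic mean of precision and recall), sensitivity and specificity at
#' a probability threshold.
#'
#' @param scores predicted probabilities or scores
#' @param labels 0/1 outcomes (both classes must be present)
#' @param threshold classification cutoff for F1/sensitivity/specificity
#' @return named list: `auroc`, `f1`, `sensitivity`, `specificity`
#' @export
evaluate_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("labels must contain both classes")
  # rank formulation == pair counting with ties = 1/2
  rk <- rank(scores, ties.method = "average")
  auroc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  list(auroc = auroc, f1 = f1, sensitivity = sens, specificity = spec)
}

#' Two-group comparison (paired or unpaired t-test)
#'
#' @param x,y numeric vectors (same length when paired)
#' @param paired paired test?
#' @return list `statistic`, `p_value`; degenerate variance gives
#'   statistic 0, p 1 when the groups are identical, else NA statistics
#' @export
group_comparisons <- function(x, y, paired = FALSE) {
  if (paired && all(abs(x - y) < 1e-15)) return(list(statistic = 0, p_value = 1))
  if (sd(x) < 1e-15 && sd(y) < 1e-15) {
    if (abs(mean(x) - mean(y)) < 1e-15) return(list(statistic = 0, p_value = 1))
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  tt <- t.test(x, y, paired = paired)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

# z-score a covariate column and mean-impute missing values
standardize_impute <- function(v) {
  mu <- mean(v, na.rm = TRUE)
  sg <- sd(v, na.rm = TRUE)
  if (!is.finite(sg) || sg < 1e-12) return(rep(0, length(v)))
  out <- (v - mu) / sg
  out[is.na(out)] <- 0
  out
}

# beats included by each protocol variant
variant_beats <- function(variant) {
  switch(variant,
         "S1" = "S1",
         "S1+S2_360" = c("S1", "S2_360"),
         "S1+S2_310" = c("S1", "S2_310"),
         "S1+both" = c("S1", "S2_360", "S2_310"),
         stop("unknown variant: ", variant))
}

#' Incremental logistic models for infarct-remodelling detection
#'
#' For one heart: fits, per EAM feature, a ladder of in-sample logistic
#' regression models over surface points. The N-th model's covariates are
#' the feature's values from the maps of the N pacing sites most proximal
#' to the infarct (plus the matching S2 maps under the decremental
#' variants). Sites without a captured map are skipped with the proximity
#' order preserved. Covariates are z-scored per map and mean-imputed;
#' a light ridge penalty keeps separable fits finite.
#'
#' @param fmaps list of `feature_map`s keyed `"<site>:<beat>"` (beats `S1`,
#'   `S2_360`, `S2_310`), e.g. from [extract_all_features()]
#' @param site_order site ids ordered most-proximal first (infarct ranks)
#' @param y 0/1 remodelling label per surface point (NA allowed; such
#'   points are dropped)
#' @param n_values numbers of maps N to evaluate
#' @param variants protocol variants (see Details)
#' @param features features to evaluate
#' @param lambda ridge strength
#' @return data.frame: feature, variant, n_maps, n_covariates, auroc, f1,
#'   sensitivity, specificity
#' @export
fit_remodelling_models <- function(fmaps, site_order, y, n_values = c(1, 8),
                                   variants = "S1",
                                   features = eam_feature_names(),
                                   lambda = 1e-3) {
  keep <- !is.na(y)
  y_use <- as.integer(y[keep])
  if (length(unique(y_use)) < 2) stop("remodelling labels are single-class")
  have_s1 <- site_order[paste0(site_order, ":S1") %in% names(fmaps)]
  out <- list()
  for (variant in variants) {
    beats <- variant_beats(variant)
    for (f in features) {
      for (N in n_values) {
        sel_sites <- head(have_s1, N)
        if (!length(sel_sites)) next
        cols <- list()
        for (s in sel_sites) {
          for (b in beats) {
            key <- paste0(s, ":", b)
            if (!key %in% names(fmaps)) next     # failed capture: skip
            cols[[key]] <- standardize_impute(fmaps[[key]][[f]][keep])
          }
        }
        if (!length(cols)) next
        X <- do.call(cbind, cols)
        fit <- ridge_logistic(X, y_use, lambda)
        met <- evaluate_metrics(fit$p, y_use)
        out[[length(out) + 1L]] <- data.frame(
          feature = f, variant = variant, n_maps = N,
          n_covariates = ncol(X), auroc = met$auroc, f1 = met$f1,
          sensitivity = met$sensitivity, specificity = met$specificity)
      }
    }
  }
  do.call(rbind, out)
}

#' Pooled observations for circuit-component classification
#'
#' Builds the long table of VT subregion observations used by
#' [fit_circuit_models()]: one row per (VT, non-empty subregion, map), with
#' the mean of each feature over the subregion's surface points, the 0/1
#' outcome (1 = inner circuit) and the map's per-VT proximity rank.
#'
#' @param circuits list of `vt_circuit`s
#' @param fmaps keyed `feature_map` list
#' @param sites_ranked list (parallel to `circuits`) of `pacing_sites` with
#'   `vt_rank` from [rank_sites_by_vt()]
#' @return data.frame: vt, subregion, label, site, beat, vt_rank, and one
#'   column per feature
#' @export
build_circuit_dataset <- function(circuits, fmaps, sites_ranked) {
  rows <- list()
  for (v in seq_along(circuits)) {
    circ <- circuits[[v]]
    ranks <- sites_ranked[[v]]
    means <- lapply(names(fmaps), function(key) {
      sm <- subregion_feature_means(circ$subregions, fmaps[[key]])
      parts <- strsplit(key, ":")[[1]]
      sm$vt <- v
      sm$site <- as.integer(parts[1])
      sm$beat <- parts[2]
      sm$vt_rank <- ranks$vt_rank[match(sm$site, ranks$id)]
      sm$label <- as.integer(sm$half == "inner")
      sm[sm$n_points > 0, ]
    })
    rows[[v]] <- do.call(rbind, means)
  }
  do.call(rbind, rows)
}

#' Incremental logistic models for inner-circuit identification
#'
#' Pooled over VTs: the observation unit is one non-empty circuit
#' subregion; the outcome is 1 for inner-circuit (isochrones 5-8) and 0
#' for outer-circuit subregions. The N-th model's covariates are one
#' feature's subregion means from the maps of the N pacing sites most
#' proximal (or most distal) to each VT's circuit, under the chosen
#' protocol variant.
#'
#' @param dataset from [build_circuit_dataset()]
#' @param n_values numbers of maps N
#' @param variants protocol variants
#' @param direction `"proximal"` (rank 1..N) or `"distal"` (rank P-N+1..P)
#' @param features features to evaluate
#' @param lambda ridge strength
#' @return data.frame like [fit_remodelling_models()]
#' @export
fit_circuit_models <- function(dataset, n_values = 1, variants = "S1",
                               direction = "proximal",
                               features = eam_feature_names(),
                               lambda = 1e-3) {
  obs <- unique(dataset[, c("vt", "subregion", "label")])
  if (length(unique(obs$label)) < 2) stop("subregion labels are single-class")
  max_rank <- max(dataset$vt_rank, na.rm = TRUE)
  out <- list()
  for (variant in variants) {
    beats <- variant_beats(variant)
    for (f in features) {
      for (N in n_values) {
        sel <- if (direction == "proximal") dataset$vt_rank <= N
               else dataset$vt_rank > max_rank - N
        sub <- dataset[sel & dataset$beat %in% beats, ]
        if (!nrow(sub)) next
        # one covariate per (rank-slot, beat): align observations
        sub$slot <- paste0("r", sub$vt_rank, ":", sub$beat)
        X <- matrix(NA_real_, nrow(obs), length(unique(sub$slot)),
                    dimnames = list(NULL, unique(sub$slot)))
        key_obs <- paste(obs$vt, obs$subregion)
        key_sub <- paste(sub$vt, sub$subregion)
        for (sl in colnames(X)) {
          rows_sl <- sub[sub$slot == sl, ]
          X[match(paste(rows_sl$vt, rows_sl$subregion), key_obs), sl] <-
            rows_sl[[f]]
        }
        X <- apply(X, 2, standardize_impute)
        if (is.null(dim(X))) X <- matrix(X, nrow = nrow(obs))
        fit <- ridge_logistic(X, obs$label, lambda)
        met <- evaluate_metrics(fit$p, obs$label)
        out[[length(out) + 1L]] <- data.frame(
          feature = f, variant = variant, n_maps = N, direction = direction,
          n_covariates = ncol(X), auroc = met$auroc, f1 = met$f1,
          sensitivity = met$sensitivity, specificity = met$specificity)
      }
    }
  }
  do.call(rbind, out)
}

#' Extract feature maps for every map in a map set
#'
#' @param map_set an `eam_map_set`
#' @param surface the `eam_surface`
#' @param neighbors optional precomputed [surface_neighbors()]
#' @return named list of `feature_map`s with the map set's keys
#' @export
extract_all_features <- function(map_set, surface, neighbors = NULL) {
  if (is.null(neighbors)) neighbors <- surface_neighbors(surface, 10)
  lapply(map_set$maps, extract_features, surface = surface,
         neighbors = neighbors)
}
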
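test_that("remodelling projection applies the 10% / 5 mm rule and recounts exactly", {
  m <- set_tissue_labels(coarse_model(),
                         generate_infarct(coarse_model(), 0.3, seed = 4))
  s <- coarse_surface()
  rs <- project_remodelling(s, m)
  expect_identical(attr(rs, "threshold"), 0.10)
  remod <- m$label != "normal"
  # direct recount oracle at random points
  set.seed(5)
  for (i in sample(which(!s$lid), 25)) {
    d2 <- rowSums(sweep(m$coords, 2, s$points[i, ])^2)
    frac <- mean(remod[d2 <= 25])
    expect_equal(rs$fraction[i], frac)
    expect_identical(rs$remodelled[i], frac >= 0.10)
  }
  expect_true(all(is.na(rs$remodelled[s$lid])))
})

test_that("infarct ranking is a deterministic permutation favouring proximity", {
  m <- set_tissue_labels(coarse_model(),
                         generate_infarct(coarse_model(), 0.3, seed = 4))
  s <- coarse_surface()
  rs <- project_remodelling(s, m)
  ps <- select_pacing_sites(s, 5, seed = 2)
  rk <- rank_sites_by_infarct(s, ps, rs)
  expect_setequal(rk$infarct_rank, seq_len(nrow(ps)))
  expect_identical(rank_sites_by_infarct(s, ps, rs)$infarct_rank,
                   rk$infarct_rank)
  # brute-force comparison: the closest site beats the farthest site
  remod_pts <- which(rs$remodelled %in% TRUE & s$side == "endo")
  dd <- igraph::distances(s$graph, v = ps$point[ps$side == "endo"],
                          to = remod_pts)
  mu <- rowMeans(dd)
  sub <- rk[rk$side == "endo", ]
  expect_lt(sub$infarct_distance[which.min(mu)],
            sub$infarct_distance[which.max(mu)])
  expect_equal(sub$infarct_distance, mu)
  # no remodelled points at all -> error
  rs0 <- rs; rs0$remodelled[] <- FALSE
  expect_error(rank_sites_by_infarct(s, ps, rs0), "no remodelled")
})

test_that("feature concordance behaves as a correlation and is symmetric", {
  fm <- one_map()$fm
  expect_equal(feature_concordance(fm, fm, "v_amp"), 1)
  neg <- fm; neg$v_amp <- -neg$v_amp
  expect_equal(feature_concordance(fm, neg, "v_amp"), -1)
  expect_equal(feature_concordance(fm, neg, "v_amp"),
               feature_concordance(neg, fm, "v_amp"))
  # white-noise maps are near-uncorrelated in >= 95% of trials
  base <- fm
  hits <- 0
  for (k in 1:100) {
    set.seed(k)
    a <- fm; a$v_amp <- rnorm(nrow(fm))
    b <- fm; b$v_amp <- rnorm(nrow(fm))
    if (abs(feature_concordance(a, b, "v_amp")) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 95)
  # insufficient common points -> NA sentinel
  few <- fm; few$v_amp[-(1:5)] <- NA
  expect_true(is.na(feature_concordance(few, fm, "v_amp")))
})

test_that("classification metrics match the worked example and brute-force oracles", {
  met <- evaluate_metrics(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(met$sensitivity, 0.5)
  expect_equal(met$specificity, 0.5)
  expect_equal(met$f1, 0.5)
  expect_equal(met$auroc, 0.75)
  expect_equal(evaluate_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auroc, 1)
  expect_equal(evaluate_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)
  expect_error(evaluate_metrics(1:4 / 4, c(1, 1, 1, 1)), "both classes")

  auroc_oracle <- function(scores, y) {     # exhaustive pair counting
    pos <- scores[y == 1]; neg <- scores[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  tally_oracle <- function(scores, y, thr = 0.5) {  # 2x2 table
    pred <- scores >= thr
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sens <- tp / (tp + fn)
    list(f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
         sens = sens, spec = tn / (tn + fp))
  }
  for (k in 1:100) {
    set.seed(k)
    n <- 10 + k %% 30
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 2)          # ties occur
    met <- evaluate_metrics(scores, y)
    expect_equal(met$auroc, auroc_oracle(scores, y), tolerance = 1e-12)
    orc <- tally_oracle(scores, y)
    expect_equal(met$f1, orc$f1, tolerance = 1e-12)
    expect_equal(met$sensitivity, orc$sens, tolerance = 1e-12)
    expect_equal(met$specificity, orc$spec, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  y <- rbinom(200, 1, 0.3)
  sc <- rnorm(200) + y
  expect_equal(evaluate_metrics(sc, y)$auroc,
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("group comparisons handle identical, shifted and degenerate inputs", {
  x <- rnorm(30)
  expect_gt(group_comparisons(x, x + rnorm(30, sd = 1e-9))$p_value, 0.9)
  expect_identical(group_comparisons(x, x, paired = TRUE)$statistic, 0)
  set.seed(1)
  a <- rnorm(30); b <- rnorm(30) + 5 * sd(a)
  expect_lt(group_comparisons(a, b)$p_value, 0.001)
  expect_identical(group_comparisons(rep(1, 5), rep(1, 5))$p_value, 1)
})

test_that("the ridge-logistic ladder is monotone under duplicated covariates", {
  set.seed(21)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x))
  f1 <- ridge_logistic(cbind(x), y)
  f2 <- ridge_logistic(cbind(x, x), y)
  expect_lt(abs(evaluate_metrics(f1$p, y)$auroc -
                  evaluate_metrics(f2$p, y)$auroc), 1e-6)
})

test_that("remodelling models recover discrimination and improve with maps", {
  # synthetic feature maps: remodelled points have lower v_amp by design
  set.seed(31)
  npt <- 600
  y <- rbinom(npt, 1, 0.3)
  fake_map <- function(noise) {
    df <- data.frame(point = 1:npt, side = "endo",
                     v_amp = 2 - y + rnorm(npt, sd = noise),
                     cv = rnorm(npt), ic = rnorm(npt), egm_dur = rnorm(npt),
                     fi = rnorm(npt), fp = rnorm(npt), activation = NA)
    class(df) <- c("feature_map", "data.frame")
    df
  }
  fmaps <- list("1:S1" = fake_map(2), "2:S1" = fake_map(2),
                "3:S1" = fake_map(2), "4:S1" = fake_map(2))
  res <- fit_remodelling_models(fmaps, 1:4, y, n_values = c(1, 4),
                                variants = "S1", features = "v_amp")
  expect_gt(res$auroc[res$n_maps == 4], res$auroc[res$n_maps == 1])
  # a feature identical to the label separates perfectly
  perfect <- fake_map(0)
  perfect$v_amp <- y
  r2 <- fit_remodelling_models(list("1:S1" = perfect), 1, y,
                               n_values = 1, features = "v_amp",
                               lambda = 1e-6)
  expect_equal(r2$auroc, 1)
  expect_equal(r2$f1, 1, tolerance = 1e-6)
  # a constant feature is uninformative
  const <- fake_map(0); const$v_amp <- rep(1, npt)
  r3 <- fit_remodelling_models(list("1:S1" = const), 1, y,
                               n_values = 1, features = "v_amp")
  expect_equal(r3$auroc, 0.5)
  # single-class labels are rejected
  expect_error(fit_remodelling_models(fmaps, 1:4, rep(1, npt)),
               "single-class")
})

test_that("the N = 1 remodelling model recovers the designed coefficient sign", {
  hits <- 0
  for (h in 1:40) {
    set.seed(200 + h)
    npt <- 400
    y <- rbinom(npt, 1, 0.35)
    v <- 2 - 1.2 * y + rnorm(npt, sd = 1)   # remodelled -> lower amplitude
    fit <- ridge_logistic(cbind(eamsim:::standardize_impute(v)), y)
    if (fit$coef[2] < 0) hits <- hits + 1
  }
  expect_gte(hits, 38)                      # >= 95%
})

test_that("circuit models separate labelled subregions and stay null under noise", {
  mk <- function(vt, sub, label, rank, beat, val) {
    data.frame(vt = vt, subregion = sub, label = label, site = rank,
               beat = beat, vt_rank = rank, n_points = 10,
               v_amp = val, cv = 0, ic = 0, fi = 0, egm_dur = 0, fp = 0)
  }
  # alternating labels with a perfectly discriminative synthetic feature
  rows <- list()
  for (v in 1:10) for (half in 0:1) {
    rows[[length(rows) + 1L]] <- mk(v, paste0("endo_", c("outer", "inner")[half + 1]),
                                    half, 1, "S1", half * 2 + rnorm(1, sd = 1e-3))
  }
  ds <- do.call(rbind, rows)
  res <- fit_circuit_models(ds, n_values = 1, features = "v_amp")
  expect_equal(res$auroc, 1)
  # label-independent random features on 200 observations: AUROC near 0.5
  set.seed(77)
  rows <- list()
  for (v in 1:100) for (half in 0:1) {
    rows[[length(rows) + 1L]] <- mk(v, paste0("endo_", c("outer", "inner")[half + 1]),
                                    half, 1, "S1", rnorm(1))
  }
  res0 <- fit_circuit_models(do.call(rbind, rows), n_values = 1,
                             features = "v_amp")
  expect_gte(res0$auroc, 0.4); expect_lte(res0$auroc, 0.6)
  # single-class labels rejected
  one <- do.call(rbind, rows); one$label <- 1
  expect_error(fit_circuit_models(one), "single-class")
})
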
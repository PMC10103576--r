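#' Build an experiment configuration
#'
#' Collects every knob of a cohort-scale mapping experiment. Resolution
#' tiers bundle sensible presets: `"test"` (coarse voxels, few sites, two
#' protocols — minutes of CPU), `"standard"` (desk-scale cohort used for
#' the package's own analyses) and `"full"` (the complete 48-heart,
#' 100-site, 3-protocol design — hours of CPU).
#'
#' @param tier `"test"`, `"standard"` or `"full"`
#' @param seed master seed; every random draw in the experiment derives
#'   from it
#' @param out_dir output directory for result tables and caches
#' @param ... overrides of any preset field
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(tier = "test", seed = 1, out_dir = tempfile("eamsim_"),
                              ...) {
  presets <- list(
    test = list(n_hearts = 4, fraction_low = 0.15, fraction_high = 0.45,
                voxel_size = 3, target_edge = 4, n_per_surface = 6,
                protocols = c("S1", "S1+S2_360"), s2_top_k = 2,
                n_values = c(1, 4), induce_vt = FALSE, n_induction_sites = 4),
    standard = list(n_hearts = 8, fraction_low = 0.10, fraction_high = 0.50,
                    voxel_size = 3, target_edge = 4, n_per_surface = 4,
                    protocols = c("S1", "S1+S2_360", "S1+S2_310"), s2_top_k = 2,
                    n_values = c(1, 2, 4, 8), induce_vt = FALSE,
                    n_induction_sites = 8),
    full = list(n_hearts = 48, fraction_low = 0.10, fraction_high = 0.50,
                voxel_size = 2, target_edge = 2, n_per_surface = 50,
                protocols = c("S1", "S1+S2_360", "S1+S2_310"), s2_top_k = NULL,
                n_values = c(1, 5, 10, 25, 50, 100), induce_vt = TRUE,
                n_induction_sites = 17))
  if (!tier %in% names(presets)) stop("unknown tier: ", tier)
  cfg <- presets[[tier]]
  cfg$tier <- tier
  cfg$seed <- as.integer(seed)
  cfg$out_dir <- out_dir
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

#' Validate an experiment configuration
#' @param cfg an `experiment_config`
#' @return the config, invisibly; errors list every offending field
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(is.numeric(cfg$n_hearts) && cfg$n_hearts >= 2, "n_hearts must be >= 2")
  chk(cfg$fraction_low < cfg$fraction_high,
      "fraction_low must be below fraction_high")
  chk(cfg$voxel_size > 0, "voxel_size must be positive")
  chk(cfg$n_per_surface >= 1, "n_per_surface must be >= 1")
  chk(all(cfg$protocols %in% c("S1", "S1+S2_360", "S1+S2_310")),
      "protocols must be among S1, S1+S2_360, S1+S2_310")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be a scalar")
  if (length(bad)) stop("invalid config: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

#' Save / load a configuration as YAML
#' @param cfg an `experiment_config`
#' @param path file path
#' @return `save_config`: the path; `load_config`: the config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  path
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$protocols <- as.character(cfg$protocols)
  cfg$n_values <- as.numeric(cfg$n_values)
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

#' Enumerate the simulation jobs of a configuration
#'
#' Deterministic cartesian enumeration heart x pacing site x protocol.
#' With `dry_run = TRUE` the jobs are printed and nothing is executed (no
#' simulation output is created).
#'
#' @param cfg an `experiment_config`
#' @param dry_run print the job list instead of returning silently
#' @return data.frame with columns heart, site, protocol (one row per job)
#' @export
enumerate_jobs <- function(cfg, dry_run = FALSE) {
  validate_config(cfg)
  jobs <- expand.grid(heart = seq_len(cfg$n_hearts),
                      site = seq_len(2 * cfg$n_per_surface),
                      protocol = cfg$protocols,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  jobs <- jobs[order(jobs$heart, jobs$site, jobs$protocol), ]
  rownames(jobs) <- NULL
  if (dry_run) {
    cat("dry run:", nrow(jobs), "jobs (",
        cfg$n_hearts, "hearts x", 2 * cfg$n_per_surface, "sites x",
        length(cfg$protocols), "protocols )\n")
  }
  jobs
}

# stage cache: compute once per (out_dir, name), reuse on resume
stage_cache <- function(cfg, name, compute) {
  dir.create(file.path(cfg$out_dir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  path <- file.path(cfg$out_dir, "cache", paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- compute()
  saveRDS(val, path)
  val
}

# deterministic CSV writer (fixed numeric formatting)
write_result_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run a full cohort mapping experiment
#'
#' Executes all stages in dependency order with per-stage caching under
#' `cfg$out_dir/cache`: cohort generation, surface extraction, pacing-site
#' selection, infarct ranking, paced-map simulation, feature extraction,
#' concordance analysis and the remodelling regression ladders (and VT
#' induction plus circuit analysis when `cfg$induce_vt`). Identical config
#' and seed give byte-identical result tables; interrupting and resuming
#' reuses the cache and produces identical outputs. Per-job failures are
#' caught, logged and skipped.
#'
#' Result tables written to `cfg$out_dir`: `capture.csv`,
#' `concordance.csv`, `concordance_summary.csv`, `remodelling_models.csv`,
#' `cohort_manifest.json` (and `circuit_models.csv` with induction).
#'
#' @param cfg an `experiment_config`
#' @param progress print per-stage progress lines
#' @return invisibly, a list with the main result tables
#' @export
run_experiment <- function(cfg, progress = FALSE) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  if (file.exists(cfg_path)) {
    prev <- try(load_config(cfg_path), silent = TRUE)
    if (inherits(prev, "try-error") ||
        !identical(unclass(prev)[order(names(prev))][setdiff(sort(names(prev)), "out_dir")],
                   unclass(cfg)[order(names(cfg))][setdiff(sort(names(cfg)), "out_dir")])) {
      unlink(file.path(cfg$out_dir, "cache"), recursive = TRUE)
    }
  }
  save_config(cfg, cfg_path)
  note <- function(...) if (progress) message(...)

  sim_cfg <- default_sim_config()
  cohort <- stage_cache(cfg, "cohort", function() {
    note("generating cohort")
    generate_cohort(cfg$n_hearts, cfg$fraction_low, cfg$fraction_high,
                    seed = cfg$seed, geometry = list(voxel_size = cfg$voxel_size))
  })
  geom <- stage_cache(cfg, "geometry", function() {
    note("extracting surfaces / operator / sites")
    surface <- extract_eam_surfaces(cohort$model, cfg$target_edge)
    list(surface = surface,
         operator = egm_forward_operator(cohort$model, surface),
         neighbors = surface_neighbors(surface, 10),
         sites = select_pacing_sites(surface, cfg$n_per_surface,
                                     seed = cfg$seed))
  })
  surface <- geom$surface

  hearts <- vector("list", cfg$n_hearts)
  for (h in seq_len(cfg$n_hearts)) {
    hearts[[h]] <- stage_cache(cfg, sprintf("heart_%02d", h), function() {
      note("heart ", h, ": simulate + features")
      model <- set_tissue_labels(cohort$model, cohort$hearts[[h]]$labels)
      surf_labels <- project_remodelling(surface, model)
      sites <- tryCatch(
        rank_sites_by_infarct(surface, geom$sites, surf_labels),
        error = function(e) { s <- geom$sites
          s$infarct_distance <- NA; s$infarct_rank <- seq_len(nrow(s)); s })
      ord <- sites$id[order(sites$infarct_rank)]
      s2_sites <- if (is.null(cfg$s2_top_k)) sites$id else head(ord, cfg$s2_top_k)
      maps <- list(); cap <- list()
      for (i in seq_len(nrow(sites))) {
        for (pr in cfg$protocols) {
          if (pr != "S1" && !sites$id[i] %in% s2_sites) next
          res <- tryCatch(
            run_one_job(model, surface, sites[i, ], pr, sim_cfg, geom$operator),
            error = function(e) {
              note("  job failed (site ", sites$id[i], " ", pr, "): ",
                   conditionMessage(e))
              NULL
            })
          if (is.null(res)) {
            cap[[length(cap) + 1L]] <- data.frame(
              heart = h, site = sites$id[i], protocol = pr,
              s1_capture = NA, s2_capture = NA, status = "failed")
            next
          }
          maps <- c(maps, res$maps)
          cap[[length(cap) + 1L]] <- cbind(heart = h, res$capture,
                                           status = "ok")
        }
      }
      fmaps <- lapply(maps, extract_features, surface = surface,
                      neighbors = geom$neighbors)
      list(sites = sites, order = ord, maps_keys = names(maps),
           fmaps = fmaps, surf_labels = surf_labels,
           capture = do.call(rbind, cap))
    })
  }

  capture_tab <- do.call(rbind, lapply(hearts, `[[`, "capture"))
  conc_tables <- list()
  remod_rows <- list()
  for (h in seq_len(cfg$n_hearts)) {
    hh <- hearts[[h]]
    s1_keys <- grep(":S1$", names(hh$fmaps), value = TRUE)
    s1 <- hh$fmaps[s1_keys]
    names(s1) <- sub(":S1$", "", s1_keys)
    conc <- concordance_table(s1, hh$sites, surface, hh$surf_labels)
    if (!is.null(conc)) conc_tables[[h]] <- conc
    y <- hh$surf_labels$remodelled
    lad <- tryCatch(
      fit_remodelling_models(hh$fmaps, hh$order, y,
                             n_values = cfg$n_values,
                             variants = intersect(
                               c("S1", sub("^S1\\+", "S1+", setdiff(cfg$protocols, "S1"))),
                               c("S1", "S1+S2_360", "S1+S2_310"))),
      error = function(e) NULL)
    if (!is.null(lad)) remod_rows[[h]] <- cbind(heart = h, lad)
  }
  conc_all <- do.call(rbind, lapply(seq_along(conc_tables), function(h) {
    if (is.null(conc_tables[[h]])) return(NULL)
    cbind(heart = h, conc_tables[[h]])
  }))
  summ <- concordance_summary(conc_tables, cohort$fractions)
  remod_tab <- do.call(rbind, remod_rows)

  results <- list(capture = capture_tab, concordance = conc_all,
                  concordance_trend = summ$fraction_trend,
                  remodelling_models = remod_tab, cohort = cohort,
                  surface = surface, hearts = hearts, geom = geom)

  write_result_csv(capture_tab, file.path(cfg$out_dir, "capture.csv"))
  if (!is.null(conc_all))
    write_result_csv(conc_all, file.path(cfg$out_dir, "concordance.csv"))
  write_result_csv(summ$fraction_trend,
                   file.path(cfg$out_dir, "concordance_summary.csv"))
  if (!is.null(remod_tab))
    write_result_csv(remod_tab, file.path(cfg$out_dir, "remodelling_models.csv"))
  jsonlite::write_json(
    list(tier = cfg$tier, seed = cfg$seed, n_hearts = cfg$n_hearts,
         fractions = round(cohort$fractions, 6),
         group = cohort$group,
         hLIR = sum(cohort$group == "hLIR"), hSIR = sum(cohort$group == "hSIR")),
    file.path(cfg$out_dir, "cohort_manifest.json"), auto_unbox = TRUE)

  if (isTRUE(cfg$induce_vt)) {
    circ_tab <- stage_cache(cfg, "circuits", function() {
      note("VT induction + circuit analysis")
      run_circuit_stage(cfg, cohort, surface, hearts, sim_cfg)
    })
    if (!is.null(circ_tab)) {
      write_result_csv(circ_tab, file.path(cfg$out_dir, "circuit_models.csv"))
      results$circuit_models <- circ_tab
    }
  }
  invisible(results)
}

# one (site, protocol) simulation -> electrogram maps + capture row
run_one_job <- function(model, surface, site, protocol, sim_cfg, operator) {
  c2 <- switch(protocol, "S1" = NULL, "S1+S2_360" = 360, "S1+S2_310" = 310)
  pos <- as.numeric(site[, c("x", "y", "z")])
  tr <- deliver_s1s2(model, pos, s2_coupling = c2, config = sim_cfg)
  maps <- list()
  if (is.null(c2) && isTRUE(tr$capture[["S1"]])) {
    maps[[paste0(site$id, ":S1")]] <- compute_unipolar(
      tr, surface, operator, window = tr$beat_windows$S1, beat = "S1",
      site_id = site$id)
  }
  if (!is.null(c2) && isTRUE(tr$capture[["S2"]])) {
    beat <- paste0("S2_", c2)
    maps[[paste0(site$id, ":", beat)]] <- compute_unipolar(
      tr, surface, operator, window = tr$beat_windows$S2, beat = beat,
      site_id = site$id)
  }
  list(maps = maps,
       capture = data.frame(site = site$id, protocol = protocol,
                            s1_capture = isTRUE(tr$capture[["S1"]]),
                            s2_capture = if (is.null(c2)) NA
                                         else isTRUE(tr$capture[["S2"]])))
}

# VT induction over the cohort and pooled circuit-model ladder
run_circuit_stage <- function(cfg, cohort, surface, hearts, sim_cfg) {
  circuits <- list(); fmaps_per_circ <- list(); ranked <- list()
  for (h in seq_len(cfg$n_hearts)) {
    model <- set_tissue_labels(cohort$model, cohort$hearts[[h]]$labels)
    eps <- tryCatch(
      induce_vt(model, cfg$n_induction_sites, sim_cfg,
                seed = derive_seed(cfg$seed, 500L + h), max_episodes = 2),
      error = function(e) list())
    for (ep in eps) {
      circ <- tryCatch(analyze_vt_circuit(ep, model, surface),
                       error = function(e) NULL)
      if (is.null(circ)) next
      circuits[[length(circuits) + 1L]] <- circ
      fmaps_per_circ[[length(circuits)]] <- hearts[[h]]$fmaps
      ranked[[length(circuits)]] <- rank_sites_by_vt(
        hearts[[h]]$sites, surface, model, circ$exit_node)
    }
  }
  if (length(circuits) < 2) return(NULL)
  # merge: per-circuit map keys may differ; build one dataset over all
  ds <- do.call(rbind, lapply(seq_along(circuits), function(v) {
    d <- build_circuit_dataset(circuits[v], fmaps_per_circ[[v]], ranked[v])
    d$vt <- v
    d
  }))
  tryCatch(
    fit_circuit_models(ds, n_values = cfg$n_values,
                       variants = intersect(
                         c("S1", setdiff(cfg$protocols, "S1")),
                         c("S1", "S1+S2_360", "S1+S2_310"))),
    error = function(e) NULL)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config [", x$tier, "]:", x$n_hearts, "hearts,",
      2 * x$n_per_surface, "sites,", length(x$protocols), "protocols, seed",
      x$seed, "\n")
  invisible(x)
}
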
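# Reproduction driver: regenerates the ensemble data characterizing the
# neighborhood-OPA model (degree distributions per checkpoint, link
# growth, degree correlation and clustering at final size) at a
# configurable scale, with theory overlays, as flat CSV files.

write_curve_csv <- function(curve, file) {
  utils::write.csv(as.data.frame(curve)[, c("k", "value", "count")],
                   file, row.names = FALSE)
}

read_curve_csv <- function(file, stat) {
  d <- utils::read.csv(file)
  new_stat_curve(d$k, d$value, d$count, stat)
}

#' Regenerate the ensemble statistics of the neighborhood-OPA model
#'
#' For each `delta` in `delta_list`, runs `trials` independent growth
#' trials to `t_max` nodes, and writes under `out_dir/delta_<delta>/`:
#' per-trial edge lists with JSON sidecars, trial-averaged degree
#' distributions at every checkpoint (`pk_t<checkpoint>.csv`), the
#' trial-averaged link-count series (`links.csv`, with the predicted
#' scaling form as an overlay column), and degree-correlation and
#' clustering curves at the final size — both a single trial's curve
#' and the trial average (`knn.csv`, `knn_trial1.csv`, `ck.csv`,
#' `ck_trial1.csv`).  A `manifest.json` at the top level records the
#' full configuration and per-trial seeds; a rerun with the same
#' arguments reproduces every file byte-for-byte.
#'
#' @param delta_list Conversion coefficients to sweep.
#' @param t_max Final node count per trial.
#' @param trials Number of trials per delta.
#' @param seed Base RNG seed.
#' @param out_dir Output directory (created if needed).
#' @param write_edgelists Write per-trial edge lists (can be bulky).
#' @return The manifest, invisibly.
#' @export
run_reproduction <- function(delta_list = c(1, sqrt(3 / 2), sqrt(2)),
                             t_max = 10000L, trials = 20L, seed = 1L,
                             out_dir = "opanet-out",
                             write_edgelists = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(model = "neighborhood_opa",
                   delta_list = delta_list, t_max = t_max,
                   trials = trials, base_seed = seed,
                   trial_seeds = seed + seq_len(trials),
                   version = as.character(utils::packageVersion("opanet")),
                   outputs = character(0))
  for (delta in delta_list) {
    dtag <- sprintf("delta_%s", format(round(delta, 6), nsmall = 0))
    ddir <- file.path(out_dir, dtag)
    dir.create(ddir, showWarnings = FALSE)
    cfg <- model_config("neighborhood_opa", delta = delta, t_max = t_max,
                        n_trials = trials, seed = seed)
    gamma <- gamma_new(delta)

    pk_by_cp <- lapply(cfg$checkpoints, function(cp) list())
    Lmat <- matrix(0, nrow = length(cfg$checkpoints), ncol = trials)
    knn_list <- vector("list", trials)
    ck_list <- vector("list", trials)

    for (i in seq_len(trials)) {
      run <- grow(cfg, trial = i, snapshots = TRUE)
      Lmat[, i] <- run$summary$L
      for (j in seq_along(cfg$checkpoints)) {
        pk_by_cp[[j]][[i]] <- degree_distribution(run$snapshots[[j]])
      }
      knn_list[[i]] <- knn_curve(run$network)
      ck_list[[i]] <- clustering_curve(run$network)
      if (write_edgelists) {
        write_edgelist(run$network,
                       file.path(ddir, sprintf("trial%03d.tsv", i)),
                       meta = list(model = cfg$model, delta = delta,
                                   seed = cfg$seed + i, trial = i))
      }
    }

    for (j in seq_along(cfg$checkpoints)) {
      write_curve_csv(average_curves(pk_by_cp[[j]]),
                      file.path(ddir, sprintf("pk_t%d.csv",
                                              cfg$checkpoints[j])))
    }
    links <- data.frame(t = cfg$checkpoints, L = rowMeans(Lmat),
                        predicted_shape =
                          predicted_link_growth(cfg$checkpoints, gamma))
    utils::write.csv(links, file.path(ddir, "links.csv"),
                     row.names = FALSE)
    write_curve_csv(average_curves(knn_list), file.path(ddir, "knn.csv"))
    write_curve_csv(knn_list[[1L]], file.path(ddir, "knn_trial1.csv"))
    write_curve_csv(average_curves(ck_list), file.path(ddir, "ck.csv"))
    write_curve_csv(ck_list[[1L]], file.path(ddir, "ck_trial1.csv"))
    theory <- list(delta = delta, gamma = gamma,
                   delta_critical = delta_critical("new"))
    jsonlite::write_json(theory, file.path(ddir, "theory.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c(manifest$outputs, ddir)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
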
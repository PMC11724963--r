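#' Default run configuration
#'
#' One nested list drives the whole pipeline; every tunable has a value
#' after resolution and the resolved config is serialized into the run
#' directory for provenance. `overrides` is merged recursively.
#'
#' @param out_dir Run directory.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param overrides Named list merged over the defaults.
#' @return Config list.
#' @export
default_config <- function(out_dir = "digitalcms_run", seed = 1L,
                           overrides = list()) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    cohorts = list(ids = c("SYN-A", "SYN-B", "SYN-C"),
                   n_patients_per_class = 20L,
                   patches_per_bag = c(80L, 120L),
                   signal_fraction = 0.3, effect_size = 2,
                   survival_hazard_ratio = 2, censoring_rate = 0.2,
                   nuclei_region_px = 512L),
    train = list(epochs = 20L, lr = 3e-3, momentum = 0.9,
                 weight_decay = 1e-4, lr_decay = 0.1,
                 lr_decay_every = 10L, hidden = 512L, patience = 3L,
                 alpha1 = 0.5, alpha2 = 0.1, n_folds = 3L),
    thresholds = list(min_tissue_fraction = 0.8,
                      tumour_rich_min_neoplastic = 50,
                      bh_level = 0.05, dab_threshold = 0.15),
    exemplars = list(k_patches = 20L, n_clusters = 9L),
    endpoints = c("dss", "dfs"))
  merge_rec <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge_rec(cfg, overrides)
}

#' Read a YAML run configuration
#'
#' Values in the file override [default_config()] defaults.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  out_dir <- if (!is.null(overrides$out_dir)) overrides$out_dir
             else "digitalcms_run"
  seed <- if (!is.null(overrides$seed)) overrides$seed else 1L
  default_config(out_dir, seed, overrides)
}

#' Run the full digital-CMS study flow
#'
#' Stages, in dependency order: synthesize (or load) the cohorts;
#' cross-cohort triplet-MIL training with stratified three-fold CV
#' (one setting per held-out cohort); score the held-out cohorts;
#' Youden-cutoff survival stratification (KM + log-rank per endpoint)
#' and multivariate Cox fits; exemplar mining (top-20 patches per
#' patient, k-means into nine patterns per class); TME profiling and
#' C1-vs-C2 group comparisons from the nuclei stores, tumour-rich
#' lymphocyte density and its Spearman correlation with the
#' digital-CMS score; CD8+ recovery on generated IHC tiles. All outputs
#' plus a provenance manifest are written under `config$out_dir`.
#'
#' @param config From [default_config()] / [read_config()].
#' @param quiet Suppress progress messages.
#' @return Invisible list of in-memory stage results.
#' @export
run_all <- function(config = default_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[digitalCMS] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(config$out_dir, "config.yaml"))
  seed <- config$seed

  # --- synth ---------------------------------------------------------
  say("stage synth: generating ", length(config$cohorts$ids), " cohorts")
  cc <- config$cohorts
  cohorts <- list()
  for (i in seq_along(cc$ids)) {
    spec <- synthetic_spec(
      n_patients_per_class = cc$n_patients_per_class,
      patches_per_bag = cc$patches_per_bag,
      signal_fraction = cc$signal_fraction,
      effect_size = cc$effect_size,
      survival_hazard_ratio = cc$survival_hazard_ratio,
      censoring_rate = cc$censoring_rate,
      seed = seed * 100L + i, signal_seed = seed)
    co <- generate_cohort(spec, cc$ids[i])
    write_synthetic_cohort(co, file.path(config$out_dir, "cohorts",
                                         cc$ids[i]),
                           nuclei_region_px = cc$nuclei_region_px)
    cohorts[[cc$ids[i]]] <- co
  }

  # --- train / score -------------------------------------------------
  say("stage train: 3-fold CV per cross-cohort setting")
  plan <- leave_one_out_plan(cc$ids, config$train$n_folds, seed)
  tr <- config$train
  results <- run_cross_cohort(
    cohorts, plan,
    params = triplet_params(tr$alpha1, tr$alpha2),
    epochs = tr$epochs, lr = tr$lr, momentum = tr$momentum,
    weight_decay = tr$weight_decay, lr_decay = tr$lr_decay,
    lr_decay_every = tr$lr_decay_every, hidden = tr$hidden,
    patience = tr$patience)
  scores_dir <- file.path(config$out_dir, "scores")
  dir.create(scores_dir, showWarnings = FALSE)
  strat <- list()
  for (res in results) {
    test_id <- res$setting$test
    roc_disc <- roc_auc(res$discovery_scores$digital_cms_score,
                        res$discovery_scores$label)
    cutoff <- youden_cutoff(roc_disc)
    res$test_scores$predicted_class <-
      as.integer(res$test_scores$digital_cms_score >= cutoff)
    write_score_table(res$test_scores,
                      file.path(scores_dir, paste0(test_id, ".csv")))
    log_path <- file.path(scores_dir, paste0(test_id, ".training.jsonl"))
    writeLines(unlist(lapply(seq_along(res$models), function(f)
      apply(res$models[[f]]$training_log, 1, function(r)
        jsonlite::toJSON(c(list(fold = f), as.list(r)),
                         auto_unbox = TRUE)))), log_path)

    # --- stratify ----------------------------------------------------
    clin <- cohorts[[test_id]]$clinical
    idx <- match(res$test_scores$patient_id, clin$patient_id)
    km <- list()
    for (ep in config$endpoints) {
      s <- stratify_survival(
        res$discovery_scores$digital_cms_score,
        res$discovery_scores$label,
        res$test_scores$digital_cms_score,
        clin[[paste0(ep, "_time")]][idx],
        clin[[paste0(ep, "_event")]][idx])
      km[[ep]] <- s
    }
    cox <- list()
    clin$digital_cms_class <- factor(
      ifelse(res$test_scores$digital_cms_score[match(clin$patient_id,
             res$test_scores$patient_id)] >= cutoff, "C2", "C1"),
      levels = c("C1", "C2"))
    for (ep in config$endpoints) {
      cox[[ep]] <- tryCatch(
        fit_coxph(clin, paste0(ep, "_time"), paste0(ep, "_event"),
                  c("hpv_type", "stage", "age", "treatment",
                    "digital_cms_class"),
                  reference_levels = list(hpv_type = "HPV16",
                                          stage = "I",
                                          treatment = "surgery")),
        error = function(e) NULL)
    }
    strat[[test_id]] <- list(cutoff = cutoff,
                             discovery_auc = roc_disc$auc,
                             val_aucs = res$val_aucs, km = km, cox = cox,
                             test_scores = res$test_scores)
  }
  surv_dir <- file.path(config$out_dir, "survival")
  dir.create(surv_dir, showWarnings = FALSE)
  for (test_id in names(strat)) {
    st <- strat[[test_id]]
    stats_json <- list(cutoff = st$cutoff,
                       discovery_auc = st$discovery_auc,
                       val_aucs = st$val_aucs)
    for (ep in config$endpoints) {
      if (!is.null(st$km[[ep]]$km)) {
        stats_json[[paste0(ep, "_logrank_p")]] <- st$km[[ep]]$km$p_value
        write.csv(st$km[[ep]]$km$curves,
                  file.path(surv_dir, paste0(test_id, ".", ep, ".km.csv")),
                  row.names = FALSE)
      }
      if (!is.null(st$cox[[ep]]))
        write.csv(st$cox[[ep]]$table,
                  file.path(surv_dir, paste0(test_id, ".", ep,
                                             ".forest.csv")),
                  row.names = FALSE)
    }
    writeLines(jsonlite::toJSON(stats_json, auto_unbox = TRUE,
                                digits = NA),
               file.path(surv_dir, paste0(test_id, ".stats.json")))
  }

  # --- exemplars (setting 1's best model on its held-out cohort) -----
  say("stage exemplars: representative patches and k-means patterns")
  best_model <- results[[1]]$models[[results[[1]]$best_fold]]
  test1 <- cohorts[[results[[1]]$setting$test]]
  sel <- select_representative_patches(test1$bags, best_model,
                                       k = config$exemplars$k_patches)
  ex_rows <- list()
  for (cls in c("C1", "C2")) {
    sub <- sel[sel$class == cls, ]
    feats <- do.call(rbind, lapply(seq_len(nrow(sub)), function(r) {
      b <- test1$bags[[match(sub$patient_id[r],
                             vapply(test1$bags, `[[`, "", "patient_id"))]]
      b$features[sub$patch_index[r], ]
    }))
    cl <- cluster_exemplars(feats, config$exemplars$n_clusters,
                            seed = seed)
    sub$cluster_id <- cl$cluster
    sub$is_medoid <- seq_len(nrow(sub)) %in% cl$medoids
    ex_rows[[cls]] <- sub
  }
  exemplars <- do.call(rbind, ex_rows)
  write.csv(exemplars, file.path(config$out_dir, "exemplars.csv"),
            row.names = FALSE)

  # --- TME profiling -------------------------------------------------
  say("stage profile: nuclei composition, comparisons, TIL density")
  th <- config$thresholds
  prof_rows <- list(V5 = list(), V6 = list())
  til <- data.frame()
  all_scores <- do.call(rbind, lapply(strat, `[[`, "test_scores"))
  for (cid in names(cohorts)) {
    man <- load_cohort(file.path(config$out_dir, "cohorts", cid,
                                 "cohort.json"))
    for (p in man$patients) {
      lab <- man$clinical$cms_label[match(p$patient_id,
                                          man$clinical$patient_id)]
      cls <- ifelse(lab == 1, "C2", "C1")
      nuc <- lapply(c(V5 = "V5", V6 = "V6"), function(voc)
        read_nuclei_store(file.path(man$dir, p$nuclei_stores[[voc]]),
                          voc))
      for (voc in c("V5", "V6")) {
        pr <- profile_region(nuc[[voc]],
                             region_area_px = cc$nuclei_region_px^2,
                             mpp = 0.5, vocabulary = voc,
                             region_id = p$patient_id)
        row <- region_profile_row(pr)
        row$class <- cls
        prof_rows[[voc]][[length(prof_rows[[voc]]) + 1L]] <- row
      }
      tr_den <- tumour_rich_lymphocyte_density(
        nuc$V5, nuc$V6, mpp = 0.5,
        min_neoplastic = th$tumour_rich_min_neoplastic)
      til <- rbind(til, data.frame(patient_id = p$patient_id,
                                   class = cls,
                                   ln_til_density = tr_den$ln_density))
    }
  }
  tme_dir <- file.path(config$out_dir, "tme")
  dir.create(tme_dir, showWarnings = FALSE)
  comparisons <- list()
  for (voc in c("V5", "V6")) {
    df <- do.call(rbind, prof_rows[[voc]])
    write.csv(df, file.path(tme_dir, paste0("profiles.", voc, ".csv")),
              row.names = FALSE)
    cmp <- compare_groups(df[df$class == "C1", ], df[df$class == "C2", ],
                          level = th$bh_level)
    write.csv(cmp, file.path(tme_dir, paste0("comparisons.", voc, ".csv")),
              row.names = FALSE)
    comparisons[[voc]] <- cmp
  }
  til$digital_cms_score <- all_scores$digital_cms_score[
    match(til$patient_id, all_scores$patient_id)]
  write.csv(til, file.path(tme_dir, "til_density.csv"), row.names = FALSE)
  til_ok <- !is.na(til$ln_til_density) & !is.na(til$digital_cms_score)
  til_cor <- if (sum(til_ok) >= 3)
    correlate_scores(til$digital_cms_score[til_ok],
                     til$ln_til_density[til_ok]) else NULL

  # --- CD8 recovery --------------------------------------------------
  say("stage cd8: DAB deconvolution recovery")
  cd8 <- do.call(rbind, lapply(c(0, 0.3, 1), function(f) {
    tile <- generate_ihc_tile(f, size_px = 128L)
    data.frame(planted = tile$positive_fraction,
               recovered = cd8_area_fraction(
                 tile$img, dab_threshold = th$dab_threshold))
  }))
  write.csv(cd8, file.path(config$out_dir, "cd8_recovery.csv"),
            row.names = FALSE)

  # --- provenance ----------------------------------------------------
  files <- list.files(config$out_dir, recursive = TRUE)
  prov <- list(package = "digitalCMS",
               version = as.character(utils::packageVersion("digitalCMS")),
               seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
               n_outputs = length(files), outputs = files)
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE),
             file.path(config$out_dir, "provenance.json"))
  say("run complete: ", config$out_dir)
  invisible(list(cohorts = cohorts, results = results, strat = strat,
                 exemplars = exemplars, comparisons = comparisons,
                 til = til, til_cor = til_cor, cd8 = cd8))
}
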
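#' Synthetic cohort specification
#'
#' Defines the statistical structure the downstream analysis assumes:
#' bags in which a known fraction of patches carries a class signal (a
#' mean shift along one fixed random unit direction in embedding
#' space), class-conditional exponential survival, and class-conditional
#' nuclei composition with the reported effect directions (higher
#' lymphocyte density and larger lymphocytes in C1; higher neutrophil
#' ratio, NLR, eosinophil ratio and larger / more variable neoplastic
#' nuclei in C2).
#'
#' @param n_patients_per_class Patients per class (default 40).
#' @param patches_per_bag Integer range c(lo, hi) of K (default
#'   100-200, a desk-scale subsample of the thousands of tissue patches
#'   a whole-slide image yields).
#' @param signal_fraction Fraction of a C2 bag's patches carrying the
#'   signal, in (0, 1\] (default 0.3).
#' @param effect_size Mean shift of signal patches along the latent
#'   direction, in units of the feature SD (default 2); 0 = null.
#' @param feature_dim Embedding dimension (1024).
#' @param survival_hazard_ratio C2 vs C1 hazard ratio (default 2).
#' @param censoring_rate Expected censoring fraction in \[0, 1)
#'   (default 0.2); censoring times are independent exponentials.
#' @param median_dss_c1 Median disease-specific survival of C1, days.
#' @param nuclei_profile Per-class, per-vocabulary rates and morphology
#'   (default [default_nuclei_profile()]).
#' @param seed Integer seed; every generator draw flows from it.
#' @param signal_seed Seed for the latent signal direction only
#'   (default `seed`). Cohorts sharing `signal_seed` share the same
#'   class-informative direction — the cross-cohort setting assumes the
#'   CMS signal is common biology — while differing in every other draw.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients_per_class = 40L,
                           patches_per_bag = c(100L, 200L),
                           signal_fraction = 0.3, effect_size = 2,
                           feature_dim = 1024L,
                           survival_hazard_ratio = 2,
                           censoring_rate = 0.2,
                           median_dss_c1 = 2000,
                           nuclei_profile = default_nuclei_profile(),
                           seed = 1L, signal_seed = seed) {
  if (signal_fraction <= 0 || signal_fraction > 1)
    stop("signal_fraction must lie in (0, 1]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (survival_hazard_ratio <= 0) stop("hazard ratio must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  structure(list(n_patients_per_class = as.integer(n_patients_per_class),
                 patches_per_bag = as.integer(patches_per_bag),
                 signal_fraction = signal_fraction,
                 effect_size = effect_size,
                 feature_dim = as.integer(feature_dim),
                 survival_hazard_ratio = survival_hazard_ratio,
                 censoring_rate = censoring_rate,
                 median_dss_c1 = median_dss_c1,
                 nuclei_profile = nuclei_profile, seed = as.integer(seed),
                 signal_seed = as.integer(signal_seed)),
            class = "synthetic_spec")
}

#' Default class-conditional nuclei profile
#'
#' Rates are expected counts per 128 x 128 um^2 patch; `area_mean` /
#' `area_sd` are nucleus areas in um^2. The directions of the
#' class differences mirror the reported tumour-microenvironment
#' contrasts: C1 denser in neoplastic/epithelial cells and lymphocytes
#' (with larger lymphocytes), C2 with more neutrophils and eosinophils
#' and enlarged, more variable neoplastic and connective nuclei.
#'
#' @return Nested list: `[[vocabulary]][[class]]` with named vectors
#'   `rate`, `area_mean`, `area_sd`.
#' @export
default_nuclei_profile <- function() {
  v5t <- nucleus_vocabulary("V5"); v6t <- nucleus_vocabulary("V6")
  nv <- function(types, ...) stats::setNames(c(...), types)
  list(
    V5 = list(
      C1 = list(rate = nv(v5t, 150, 50, 40, 5, 30),
                area_mean = nv(v5t, 35, 18, 25, 20, 28),
                area_sd = nv(v5t, 8, 4, 10, 5, 6)),
      C2 = list(rate = nv(v5t, 90, 25, 40, 10, 30),
                area_mean = nv(v5t, 50, 18, 25, 20, 28),
                area_sd = nv(v5t, 16, 4, 18, 5, 6))),
    V6 = list(
      C1 = list(rate = nv(v6t, 5, 120, 60, 10, 2, 40),
                area_mean = nv(v6t, 20, 35, 22, 24, 21, 25),
                area_sd = nv(v6t, 4, 8, 4, 5, 4, 10)),
      C2 = list(rate = nv(v6t, 15, 80, 30, 10, 6, 40),
                area_mean = nv(v6t, 20, 50, 18, 24, 21, 25),
                area_sd = nv(v6t, 4, 16, 4, 5, 4, 18))))
}

#' Generate a synthetic cohort
#'
#' Bags of standard-normal 1024-dim patch embeddings; in C2 bags a
#' known subset (`signal_fraction` of K, indices recorded for testing)
#' is shifted by `effect_size` along one fixed random unit direction.
#' Survival times are exponential with the class hazard ratio on top of
#' the C1 baseline; censoring is an independent exponential calibrated
#' to the requested censoring fraction. Clinical covariates (age,
#' stage, HPV type, treatment) are drawn independently of class.
#'
#' @param spec A [synthetic_spec()].
#' @param cohort_id Cohort identifier.
#' @param features Generate the embedding bags (default TRUE). FALSE
#'   skips them (bags NULL) for survival-only simulations; the RNG
#'   stream then differs from the full draw.
#' @return Object of class `synthetic_cohort`: `cohort_id`, `bags`
#'   (list of [cms_bag()]s), `clinical` (data frame),
#'   `signal_index` (named list of true signal patch indices),
#'   `signal_direction`, `spec`.
#' @export
generate_cohort <- function(spec, cohort_id = "SYN", features = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d <- spec$feature_dim
  set.seed(spec$signal_seed)
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  set.seed(spec$seed)
  n <- spec$n_patients_per_class
  labels <- rep(c(0, 1), each = n)
  ids <- sprintf("%s-%03d", cohort_id, seq_along(labels))
  bags <- vector("list", length(labels))
  signal_index <- stats::setNames(vector("list", length(labels)), ids)
  if (features) for (i in seq_along(labels)) {
    K <- sample(spec$patches_per_bag[1]:spec$patches_per_bag[2], 1L)
    X <- matrix(rnorm(K * d), K, d)
    sig <- integer(0)
    if (labels[i] == 1) {
      n_sig <- max(1L, round(spec$signal_fraction * K))
      sig <- sort(sample(K, n_sig))
      X[sig, ] <- X[sig, , drop = FALSE] +
        rep(spec$effect_size * u, each = length(sig))
    }
    ncol_grid <- ceiling(sqrt(K))
    coords <- data.frame(x = ((seq_len(K) - 1L) %% ncol_grid) * 256L,
                         y = ((seq_len(K) - 1L) %/% ncol_grid) * 256L,
                         width = 256L, height = 256L)
    bags[[i]] <- cms_bag(ids[i], X, labels[i], coords,
                         slide_id = paste0(ids[i], "-S1"))
    signal_index[[i]] <- sig
  }
  if (!features) bags <- NULL
  lambda1 <- log(2) / spec$median_dss_c1
  rate <- lambda1 * spec$survival_hazard_ratio^labels
  surv_pair <- function(rate) {
    t_true <- rexp(length(rate), rate)
    if (spec$censoring_rate > 0) {
      # P(C < T) = mu / (lambda + mu)  ->  mu from the mean class rate
      mu <- mean(rate) * spec$censoring_rate / (1 - spec$censoring_rate)
      cens <- rexp(length(rate), mu)
      list(time = pmin(t_true, cens), event = as.integer(t_true <= cens))
    } else list(time = t_true, event = rep(1L, length(rate)))
  }
  dss <- surv_pair(rate)
  dfs <- surv_pair(rate * 1.4)   # relapses precede deaths on average
  clinical <- data.frame(
    patient_id = ids, cms_label = labels,
    dss_time = dss$time, dss_event = dss$event,
    dfs_time = dfs$time, dfs_event = dfs$event,
    hpv_type = sample(c("HPV16", "HPV18", "other"), length(ids), TRUE,
                      prob = c(0.6, 0.2, 0.2)),
    stage = sample(c("I", "II", "III", "IV"), length(ids), TRUE,
                   prob = c(0.45, 0.25, 0.2, 0.1)),
    age = round(pmin(pmax(rnorm(length(ids), 47, 12), 21), 85)),
    treatment = sample(c("surgery", "RT", "CRT"), length(ids), TRUE),
    hiv_status = rbinom(length(ids), 1, 0.05),
    stringsAsFactors = FALSE)
  structure(list(cohort_id = cohort_id, bags = bags, clinical = clinical,
                 signal_index = signal_index, signal_direction = u,
                 spec = spec),
            class = "synthetic_cohort")
}

#' Generate nuclei records for one region
#'
#' Counts per cell type are Poisson with the class-conditional rate
#' scaled to the region area (rates are per 128 x 128 um^2). Each
#' nucleus is a regular 12-gon at a uniformly placed centroid (no two
#' coincide), rotated at random, with its area drawn from the
#' class-conditional normal (truncated at 2 um^2) — so per-nucleus area
#' and perimeter have closed-form targets given the radius.
#'
#' @param spec A [synthetic_spec()] (supplies the nuclei profile).
#' @param class_label `"C1"` or `"C2"`.
#' @param vocabulary `"V5"` or `"V6"`.
#' @param region_size_px Region side in pixels.
#' @param mpp Microns per pixel.
#' @param n_vertices Polygon vertices (default 12).
#' @return List of [nucleus_record()]s.
#' @export
generate_nuclei <- function(spec, class_label = c("C1", "C2"),
                            vocabulary = c("V5", "V6"),
                            region_size_px = 512L, mpp = 0.5,
                            n_vertices = 12L) {
  class_label <- match.arg(class_label)
  vocabulary <- match.arg(vocabulary)
  if (region_size_px <= 0) stop("region dimensions must be positive")
  prof <- spec$nuclei_profile[[vocabulary]][[class_label]]
  if (any(prof$rate < 0)) stop("negative rate in nuclei profile")
  area_um2 <- (region_size_px * mpp)^2
  scale <- area_um2 / 128^2
  out <- list(); nid <- 0L
  seen <- character()
  for (tp in names(prof$rate)) {
    count <- rpois(1L, prof$rate[tp] * scale)
    if (count == 0L) next
    for (j in seq_len(count)) {
      repeat {
        cx <- runif(1, 0, region_size_px)
        cy <- runif(1, 0, region_size_px)
        key <- paste(round(cx, 3), round(cy, 3))
        if (!key %in% seen) { seen <- c(seen, key); break }
      }
      a_um2 <- max(2, rnorm(1, prof$area_mean[tp], prof$area_sd[tp]))
      a_px2 <- a_um2 / mpp^2
      r <- sqrt(2 * a_px2 / (n_vertices * sin(2 * pi / n_vertices)))
      th <- runif(1, 0, 2 * pi) +
        2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
      contour <- cbind(cx + r * cos(th), cy + r * sin(th))
      nid <- nid + 1L
      out[[nid]] <- nucleus_record(nid, tp, contour,
                                   centroid = c(cx, cy), mpp = mpp)
    }
  }
  out
}

#' Generate a synthetic H-DAB IHC tile
#'
#' A fully-tissue tile whose pixels transmit haematoxylin except a block
#' of DAB-brown pixels occupying exactly `positive_fraction` of the
#' tissue area (Beer-Lambert transmission through the standard H-DAB
#' stain vectors), giving a known ground truth for the CD8+ area
#' fraction.
#'
#' @param positive_fraction Target DAB fraction in \[0, 1\].
#' @param size_px Tile side (default 256).
#' @param h_density,dab_density Stain optical densities of the two
#'   pixel populations.
#' @return List: `img` (H x W x 3 in \[0, 1\]), `positive_fraction`
#'   (realized ground truth).
#' @export
generate_ihc_tile <- function(positive_fraction, size_px = 256L,
                              h_density = 0.6, dab_density = 0.8) {
  if (is.na(positive_fraction) || positive_fraction < 0 ||
      positive_fraction > 1)
    stop("positive_fraction must lie in [0, 1]")
  m <- hdab_stain_matrix()
  h_rgb <- 10^(-h_density * m["h", ])
  dab_rgb <- 10^(-dab_density * m["dab", ])
  npx <- size_px * size_px
  n_pos <- round(positive_fraction * npx)
  is_dab <- c(rep(TRUE, n_pos), rep(FALSE, npx - n_pos))
  img <- array(0, dim = c(size_px, size_px, 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(ifelse(is_dab, dab_rgb[ch], h_rgb[ch]),
                          size_px, size_px)
  list(img = img, positive_fraction = n_pos / npx)
}

#' Write a synthetic cohort to disk in the cohort-directory layout
#'
#' Emits one feature store per patient, nuclei stores for both
#' detector dialects, the clinical CSV and the JSON manifest, exactly
#' as [load_cohort()] expects.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Target directory (created).
#' @param nuclei_region_px Side of the per-patient nuclei region.
#' @param write_nuclei Write nuclei stores (default TRUE).
#' @return The manifest path, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir, nuclei_region_px = 512L,
                                   write_nuclei = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  if (write_nuclei)
    dir.create(file.path(dir, "nuclei"), showWarnings = FALSE)
  patients <- list()
  for (b in cohort$bags) {
    pid <- b$patient_id
    frel <- file.path("features", paste0(pid, ".rds"))
    write_feature_store(
      feature_store(b$slide_id[1], b$coords, b$features, mpp = 0.5),
      file.path(dir, frel))
    nrel <- NULL
    if (write_nuclei) {
      cls <- ifelse(b$label == 1, "C2", "C1")
      nrel <- list()
      for (voc in c("V5", "V6")) {
        rel <- file.path("nuclei", paste0(pid, ".", voc, ".json"))
        nuc <- generate_nuclei(cohort$spec, cls, voc,
                               region_size_px = nuclei_region_px)
        write_nuclei_store(nuc, file.path(dir, rel), voc)
        nrel[[voc]] <- rel
      }
    }
    patients[[length(patients) + 1L]] <-
      list(patient_id = pid, slide_ids = b$slide_id[1],
           feature_stores = frel, nuclei_stores = nrel,
           unlabeled = is.na(b$label))
  }
  manifest <- structure(list(cohort_id = cohort$cohort_id,
                             patients = patients,
                             clinical = cohort$clinical,
                             missing_paths = character(), dir = dir),
                        class = "cohort_manifest")
  invisible(save_cohort(manifest, dir))
}

#' Rebuild MIL bags from a cohort directory
#'
#' Reads every patient's feature stores (concatenating multi-slide
#' patients into one bag) and attaches the CMS label from the clinical
#' table.
#'
#' @param manifest A [load_cohort()] result.
#' @return List of [cms_bag()]s.
#' @export
bags_from_cohort <- function(manifest) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  lapply(manifest$patients, function(p) {
    stores <- lapply(p$feature_stores, function(rel)
      read_feature_store(file.path(manifest$dir, rel)))
    X <- do.call(rbind, lapply(stores, `[[`, "features"))
    coords <- do.call(rbind, lapply(stores, `[[`, "coords"))
    slide <- unlist(lapply(stores, function(s)
      rep(s$slide_id, nrow(s$features))))
    lab <- NA
    if (!is.null(manifest$clinical)) {
      row <- match(p$patient_id, manifest$clinical$patient_id)
      if (!is.na(row)) lab <- manifest$clinical$cms_label[row]
    }
    cms_bag(p$patient_id, X, lab, coords, slide)
  })
}
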
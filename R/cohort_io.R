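#' @name cohort_io
#' @title On-disk cohort artefacts
#'
#' @description
#' A cohort lives in one directory holding a JSON manifest, one feature
#' store per slide (serialized R list: coords + K x 1024 matrix + mpp),
#' one nuclei store per slide and vocabulary (HoverNet-style JSON with an
#' explicit vocabulary tag), and a clinical CSV. The manifest lists
#' patients with relative paths so a cohort directory is self-contained
#' and diff-able.
NULL

#' Nucleus class vocabularies
#'
#' `V5` is the 5-class dialect of a PanNuke-trained detector
#' (neoplastic, inflammatory, connective, necrosis, non-neoplastic);
#' `V6` the 6-class dialect of a CoNIC-trained detector (neutrophil,
#' epithelial, lymphocyte, plasma, eosinophil, connective). The two are
#' never merged: features are computed per dialect and joined by region.
#'
#' @param vocabulary `"V5"` or `"V6"`.
#' @return Character vector of class labels.
#' @export
nucleus_vocabulary <- function(vocabulary = c("V5", "V6")) {
  vocabulary <- match.arg(vocabulary)
  switch(vocabulary,
    V5 = c("neoplastic", "inflammatory", "connective", "necrosis",
           "non-neoplastic"),
    V6 = c("neutrophil", "epithelial", "lymphocyte", "plasma",
           "eosinophil", "connective"))
}

#' Construct a feature store
#'
#' A feature store holds the external patch-embedding output for one
#' slide: a K x 1024 matrix of embeddings, one 0-based half-open
#' level-0 pixel rectangle per row, and the microns-per-pixel of the
#' patch plane.
#'
#' @param slide_id Slide identifier.
#' @param coords Data frame with columns `x`, `y`, `width`, `height`.
#' @param features Numeric K x 1024 matrix, rows aligned with `coords`.
#' @param mpp Microns per pixel of the patch plane.
#' @return An object of class `feature_store`.
#' @export
feature_store <- function(slide_id, coords, features, mpp = 0.5) {
  features <- as.matrix(features)
  if (ncol(features) != 1024L)
    stop("feature dimension must be exactly 1024, got ", ncol(features))
  if (nrow(features) < 1L) stop("feature store needs K >= 1 patches")
  coords <- as.data.frame(coords)
  need <- c("x", "y", "width", "height")
  if (!all(need %in% names(coords)))
    stop("coords must have columns x, y, width, height")
  if (nrow(coords) != nrow(features))
    stop("coords rows (", nrow(coords), ") do not align with feature rows (",
         nrow(features), ")")
  structure(list(slide_id = as.character(slide_id),
                 coords = coords[need], features = features,
                 mpp = as.numeric(mpp)),
            class = "feature_store")
}

#' Write / read a feature store
#'
#' Stores are serialized with R's native format (xz off, version 3) so a
#' round trip is bitwise exact on the matrix.
#'
#' @param store A `feature_store`.
#' @param path File path (conventionally `<slide_id>.features.rds`).
#' @return `read_feature_store` returns a validated `feature_store`.
#' @export
write_feature_store <- function(store, path) {
  stopifnot(inherits(store, "feature_store"))
  saveRDS(unclass(store), path)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  if (!file.exists(path)) stop("feature store not found: ", path)
  x <- readRDS(path)
  feature_store(x$slide_id, x$coords, x$features, x$mpp)
}

#' Construct a nucleus record
#'
#' @param nucleus_id Integer id.
#' @param class_label Label drawn from one declared vocabulary.
#' @param contour Closed polygon as an n x 2 matrix of pixel vertices
#'   (n >= 3); the closing edge is implicit.
#' @param centroid Length-2 numeric (x, y); defaults to the vertex mean.
#' @param mpp Microns per pixel.
#' @return An object of class `nucleus_record`.
#' @export
nucleus_record <- function(nucleus_id, class_label, contour,
                           centroid = NULL, mpp = 0.5) {
  contour <- matrix(as.numeric(contour), ncol = 2)
  if (nrow(contour) < 3L)
    stop("contour needs >= 3 vertices")
  if (is.null(centroid)) centroid <- colMeans(contour)
  structure(list(nucleus_id = as.integer(nucleus_id),
                 class_label = as.character(class_label),
                 contour = contour, centroid = as.numeric(centroid),
                 mpp = as.numeric(mpp)),
            class = "nucleus_record")
}

#' Write / read a nuclei store
#'
#' The JSON dialect mirrors common nuclei-detector output: a mapping
#' `nucleus_id -> {type, contour, centroid}`, plus top-level `vocabulary`
#' and `mpp` tags. On read, records are validated against the requested
#' vocabulary: degenerate contours (< 3 vertices) are excluded with a
#' warning; unknown labels are excluded (or an error under
#' `strict = TRUE`). The exclusion counts are attached as attributes
#' `n_excluded_degenerate` / `n_excluded_unknown`.
#'
#' @param nuclei List of `nucleus_record`s.
#' @param path JSON file path.
#' @param vocabulary `"V5"` or `"V6"`.
#' @param mpp Microns per pixel recorded in the store.
#' @param strict Error (rather than drop) on unknown labels.
#' @return `read_nuclei_store` returns a list of `nucleus_record`s.
#' @export
write_nuclei_store <- function(nuclei, path, vocabulary, mpp = 0.5) {
  recs <- lapply(nuclei, function(n) {
    list(type = n$class_label,
         contour = unname(apply(n$contour, 1, as.numeric, simplify = FALSE)),
         centroid = as.numeric(n$centroid))
  })
  names(recs) <- vapply(nuclei, function(n) as.character(n$nucleus_id), "")
  obj <- list(vocabulary = vocabulary, mpp = mpp, nuclei = recs)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_nuclei_store
#' @export
read_nuclei_store <- function(path, vocabulary = c("V5", "V6"),
                              strict = FALSE) {
  vocabulary <- match.arg(vocabulary)
  if (!file.exists(path)) stop("nuclei store not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$vocabulary) && !identical(obj$vocabulary, vocabulary))
    stop("store declares vocabulary ", obj$vocabulary,
         " but ", vocabulary, " was requested")
  vocab <- nucleus_vocabulary(vocabulary)
  mpp <- if (is.null(obj$mpp)) 0.5 else as.numeric(obj$mpp)
  n_degen <- 0L; n_unknown <- 0L
  out <- list()
  for (id in names(obj$nuclei)) {
    rec <- obj$nuclei[[id]]
    contour <- do.call(rbind, lapply(rec$contour, unlist))
    if (is.null(contour) || nrow(contour) < 3L) {
      n_degen <- n_degen + 1L
      next
    }
    if (!rec$type %in% vocab) {
      if (strict) stop("unknown label '", rec$type, "' under vocabulary ",
                       vocabulary)
      n_unknown <- n_unknown + 1L
      next
    }
    out[[length(out) + 1L]] <- nucleus_record(
      as.integer(id), rec$type, contour,
      centroid = unlist(rec$centroid), mpp = mpp)
  }
  if (n_degen > 0L)
    warning(n_degen, " record(s) excluded for degenerate contours")
  attr(out, "n_excluded_degenerate") <- n_degen
  attr(out, "n_excluded_unknown") <- n_unknown
  out
}

#' Read / write the clinical table
#'
#' Columns: `patient_id`, `cms_label` (0 = C1, 1 = C2, NA when
#' undetermined), `dss_time`/`dss_event`, `dfs_time`/`dfs_event`
#' (days; events 0/1), `hpv_type`, `stage` (I-IV), `age` (years),
#' `treatment`, `hiv_status`. Missing optional columns are filled
#' with NA.
#'
#' @param path CSV path.
#' @return Data frame with one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("clinical table lacks patient_id")
  for (col in c("cms_label", "dss_time", "dss_event", "dfs_time",
                "dfs_event", "hpv_type", "stage", "age", "treatment",
                "hiv_status"))
    if (!col %in% names(df)) df[[col]] <- NA
  validate_clinical(df)
  df
}

#' @rdname read_clinical_table
#' @param clinical Data frame as above.
#' @export
write_clinical_table <- function(clinical, path) {
  validate_clinical(clinical)
  write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

validate_clinical <- function(df) {
  chk01 <- function(x, nm) {
    x <- x[!is.na(x)]
    if (length(x) && !all(x %in% c(0, 1)))
      stop(nm, " must be 0/1")
  }
  for (nm in c("dss_event", "dfs_event", "cms_label", "hiv_status"))
    chk01(df[[nm]], nm)
  for (nm in c("dss_time", "dfs_time")) {
    x <- df[[nm]][!is.na(df[[nm]])]
    if (length(x) && any(x < 0)) stop(nm, " must be >= 0")
  }
  invisible(TRUE)
}

#' Load and save a cohort manifest
#'
#' The manifest is one JSON file per cohort listing the cohort id and,
#' per patient, slide ids and relative paths to feature and nuclei
#' stores plus the clinical table. Paths are resolved relative to the
#' manifest's directory; unresolvable paths are flagged in the returned
#' object's `missing_paths`, and patients without a CMS label are
#' flagged `unlabeled`.
#'
#' @param manifest_path Path to `cohort.json`.
#' @return An object of class `cohort_manifest`: `cohort_id`,
#'   `patients` (list), `clinical` (data frame or NULL),
#'   `missing_paths`, `dir`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  obj <- tryCatch(jsonlite::fromJSON(manifest_path, simplifyVector = FALSE),
                  error = function(e)
                    stop("manifest parse failure: ", conditionMessage(e)))
  for (field in c("cohort_id", "patients"))
    if (is.null(obj[[field]]))
      stop("manifest schema error: missing field '", field, "'")
  dir <- dirname(manifest_path)
  ids <- vapply(obj$patients, function(p) {
    if (is.null(p$patient_id))
      stop("manifest schema error: patient entry lacks 'patient_id'")
    p$patient_id
  }, "")
  if (anyDuplicated(ids))
    stop("duplicate patient_id in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  clinical <- NULL
  if (!is.null(obj$clinical_table)) {
    cp <- file.path(dir, obj$clinical_table)
    if (file.exists(cp)) clinical <- read_clinical_table(cp)
  }
  missing <- character()
  patients <- lapply(obj$patients, function(p) {
    paths <- unlist(c(p$feature_stores, p$nuclei_stores))
    for (rel in paths)
      if (!file.exists(file.path(dir, rel)))
        missing <<- c(missing, rel)
    lab <- NA
    if (!is.null(clinical)) {
      row <- match(p$patient_id, clinical$patient_id)
      if (!is.na(row)) lab <- clinical$cms_label[row]
    }
    list(patient_id = p$patient_id,
         slide_ids = unlist(p$slide_ids),
         feature_stores = unlist(p$feature_stores),
         nuclei_stores = p$nuclei_stores,
         unlabeled = is.na(lab))
  })
  structure(list(cohort_id = obj$cohort_id, patients = patients,
                 clinical = clinical, missing_paths = unique(missing),
                 dir = dir),
            class = "cohort_manifest")
}

#' @rdname load_cohort
#' @param manifest A `cohort_manifest` (paths already relative to `dir`).
#' @param dir Directory to write `cohort.json` into.
#' @param clinical_table Relative path of the clinical CSV recorded in
#'   the manifest.
#' @export
save_cohort <- function(manifest, dir, clinical_table = "clinical.csv") {
  stopifnot(inherits(manifest, "cohort_manifest"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- list(
    cohort_id = manifest$cohort_id,
    clinical_table = clinical_table,
    patients = lapply(manifest$patients, function(p)
      list(patient_id = p$patient_id,
           slide_ids = as.list(p$slide_ids),
           feature_stores = as.list(p$feature_stores),
           nuclei_stores = p$nuclei_stores)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA),
             file.path(dir, "cohort.json"))
  if (!is.null(manifest$clinical))
    write_clinical_table(manifest$clinical, file.path(dir, clinical_table))
  invisible(file.path(dir, "cohort.json"))
}

#' Write a digital-CMS score table
#'
#' @param scores Data frame with columns `patient_id`, `cohort`,
#'   `digital_cms_score`, `predicted_class`.
#' @param path CSV path.
#' @export
write_score_table <- function(scores, path) {
  need <- c("patient_id", "cohort", "digital_cms_score", "predicted_class")
  if (!all(need %in% names(scores)))
    stop("score table needs columns: ", paste(need, collapse = ", "))
  write.csv(scores[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
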
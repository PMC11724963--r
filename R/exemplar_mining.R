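#' Select representative patches per patient
#'
#' For each patient with a ground-truth CMS class, keeps the `k` patches
#' predicted most strongly as the patient's own class: the `k` lowest
#' digital-CMS scores for C1 patients, the `k` highest for C2 patients.
#' Patients with fewer than `k` patches contribute all of them, flagged
#' `short_bag`; unlabeled patients are skipped with a warning.
#'
#' @param bags List of [cms_bag()]s with ground-truth labels.
#' @param scorer A trained `cms_scorer`.
#' @param k Patches per patient (default 20).
#' @return Data frame: `patient_id`, `class`, `patch_index`, `score`,
#'   patch coords when available, `short_bag`.
#' @export
select_representative_patches <- function(bags, scorer, k = 20L) {
  rows <- list(); skipped <- 0L
  for (b in bags) {
    if (is.na(b$label)) { skipped <- skipped + 1L; next }
    s <- score_patches(scorer, b)
    ord <- order(s, decreasing = (b$label == 1))
    take <- ord[seq_len(min(k, length(s)))]
    df <- data.frame(patient_id = b$patient_id,
                     class = ifelse(b$label == 1, "C2", "C1"),
                     patch_index = take, score = s[take],
                     short_bag = length(s) < k,
                     stringsAsFactors = FALSE)
    if (!is.null(b$coords))
      df <- cbind(df, b$coords[take, c("x", "y", "width", "height"),
                               drop = FALSE])
    rows[[length(rows) + 1L]] <- df
  }
  if (skipped > 0L)
    warning(skipped, " unlabeled patient(s) skipped")
  if (!length(rows)) stop("no labelled patients to select from")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster selected patches into exemplar patterns
#'
#' k-means (k-means++-style multi-start via `nstart` random restarts,
#' fixed seed) over the deep patch embeddings, into exactly
#' `n_clusters` non-empty clusters; the run is repeated with a fresh
#' seed on the rare empty-cluster failure. Each cluster is summarized by
#' its medoid — the real patch nearest the centroid — so every exemplar
#' is an actual patch.
#'
#' @param features n x d matrix of patch embeddings (n >= `n_clusters`).
#' @param n_clusters Number of patterns (default 9).
#' @param seed Integer seed.
#' @param nstart Random restarts.
#' @return List: `cluster` (assignment per row), `medoids` (row indices,
#'   one per cluster), `centers`, `withinss`, `tot_withinss`.
#' @export
cluster_exemplars <- function(features, n_clusters = 9L, seed = 1L,
                              nstart = 10L) {
  features <- as.matrix(features)
  if (nrow(features) < n_clusters)
    stop("need at least ", n_clusters, " patches, got ", nrow(features))
  km <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    km <- tryCatch(stats::kmeans(features, centers = n_clusters,
                                 nstart = nstart, iter.max = 100L),
                   error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce non-empty clusters")
  medoids <- vapply(seq_len(n_clusters), function(cl) {
    members <- which(km$cluster == cl)
    d2 <- rowSums(sweep(features[members, , drop = FALSE], 2,
                        km$centers[cl, ])^2)
    members[which.min(d2)]
  }, 0L)
  list(cluster = km$cluster, medoids = medoids, centers = km$centers,
       withinss = km$withinss, tot_withinss = km$tot.withinss)
}

#' Render a patch-score heatmap
#'
#' Rasterizes per-patch digital-CMS scores onto a downsampled slide
#' canvas with a diverging blue-white-red map centred at the
#' stratification threshold (blue = C1-like, red = C2-like); pixels not
#' covered by a patch have alpha 0.
#'
#' @param coords Data frame `x`, `y`, `width`, `height` (level-0 px,
#'   0-based half-open, non-overlapping).
#' @param scores Patch scores in \[0, 1\], aligned with `coords`.
#' @param threshold Neutral centre of the colour map (default 0.5).
#' @param downsample Integer downsample factor (default 32).
#' @param slide_dim Optional c(width, height) in level-0 px; default
#'   the patch bounding box.
#' @return H x W x 4 RGBA array in \[0, 1\].
#' @export
render_score_map <- function(coords, scores, threshold = 0.5,
                             downsample = 32L, slide_dim = NULL) {
  stopifnot(nrow(coords) == length(scores))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (overlaps_any(coords)) stop("overlapping patches in score map")
  if (is.null(slide_dim))
    slide_dim <- c(max(coords$x + coords$width),
                   max(coords$y + coords$height))
  w <- ceiling(slide_dim[1] / downsample)
  h <- ceiling(slide_dim[2] / downsample)
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  # piecewise-linear so `threshold` maps to the neutral midpoint
  u <- ifelse(scores <= threshold,
              if (threshold > 0) 0.5 * scores / threshold else 0.5,
              0.5 + 0.5 * (scores - threshold) /
                max(1 - threshold, .Machine$double.eps))
  cols <- ramp(pmin(pmax(u, 0), 1)) / 255
  img <- array(0, dim = c(h, w, 4))
  for (i in seq_len(nrow(coords))) {
    x0 <- floor(coords$x[i] / downsample) + 1L
    y0 <- floor(coords$y[i] / downsample) + 1L
    x1 <- ceiling((coords$x[i] + coords$width[i]) / downsample)
    y1 <- ceiling((coords$y[i] + coords$height[i]) / downsample)
    for (ch in 1:3) img[y0:y1, x0:x1, ch] <- cols[i, ch]
    img[y0:y1, x0:x1, 4] <- 1
  }
  img
}

overlaps_any <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(FALSE)
  x0 <- coords$x; x1 <- coords$x + coords$width
  y0 <- coords$y; y1 <- coords$y + coords$height
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    if (any(x0[i] < x1[j] & x1[i] > x0[j] &
            y0[i] < y1[j] & y1[i] > y0[j])) return(TRUE)
  }
  FALSE
}
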
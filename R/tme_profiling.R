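# Shoelace area of a closed polygon (vertices in px, closing edge
# implicit); absolute value, px^2.
polygon_area_px <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  n <- nrow(contour)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Perimeter of a closed polygon, px.
polygon_perimeter_px <- function(contour) {
  n <- nrow(contour)
  j <- c(2:n, 1)
  sum(sqrt((contour[j, 1] - contour[, 1])^2 +
           (contour[j, 2] - contour[, 2])^2))
}

#' Nucleus morphology in physical units
#'
#' Area via the shoelace formula scaled by mpp^2 (um^2); perimeter via
#' summed edge lengths scaled by mpp (um).
#'
#' @param record A [nucleus_record()].
#' @return Named numeric: `area_um2`, `perimeter_um`.
#' @export
nucleus_morphology <- function(record) {
  c(area_um2 = polygon_area_px(record$contour) * record$mpp^2,
    perimeter_um = polygon_perimeter_px(record$contour) * record$mpp)
}

#' Cellular composition and morphology profile of a region
#'
#' For every cell type of the vocabulary: count N, density
#' rho = N / A with A the region area in um^2 (px area x mpp^2),
#' ln density (missing when N = 0), and ratio N / total. For the
#' 6-class vocabulary the neutrophil-to-lymphocyte ratio (NLR) is
#' added, missing when no lymphocyte was detected. Morphology (mean /
#' median / SD of nucleus area in um^2 and perimeter in um) is reported
#' per type and missing when the type is absent, matching the
#' exclusion rule for absent cell types.
#'
#' @param nuclei List of [nucleus_record()]s from one detector dialect.
#' @param region_area_px Region area in pixels (e.g. 256 * 256).
#' @param mpp Microns per pixel.
#' @param vocabulary `"V5"` or `"V6"`; inferred from the labels when
#'   NULL. Mixing dialects in one call is an error.
#' @param region_id Identifier carried through to the profile.
#' @return Object of class `region_profile`.
#' @export
profile_region <- function(nuclei, region_area_px, mpp = 0.5,
                           vocabulary = NULL, region_id = "region") {
  if (region_area_px <= 0) stop("region area must be positive")
  labels <- vapply(nuclei, `[[`, "", "class_label")
  v5 <- nucleus_vocabulary("V5"); v6 <- nucleus_vocabulary("V6")
  only5 <- setdiff(v5, v6); only6 <- setdiff(v6, v5)
  if (any(labels %in% only5) && any(labels %in% only6))
    stop("mixed vocabularies in one region profile")
  if (is.null(vocabulary))
    vocabulary <- if (any(labels %in% only6)) "V6" else "V5"
  vocab <- nucleus_vocabulary(vocabulary)
  if (length(labels) && !all(labels %in% vocab))
    stop("labels outside vocabulary ", vocabulary, ": ",
         paste(unique(setdiff(labels, vocab)), collapse = ", "))
  if (length(nuclei)) {
    mpps <- vapply(nuclei, `[[`, 0, "mpp")
    if (diff(range(mpps)) > 1e-9) stop("inconsistent mpp across records")
  }
  area_um2 <- region_area_px * mpp^2
  counts <- stats::setNames(integer(length(vocab)), vocab)
  tab <- table(factor(labels, levels = vocab))
  counts[names(tab)] <- as.integer(tab)
  total <- sum(counts)
  density <- counts / area_um2
  ln_density <- ifelse(counts > 0, log(density), NA_real_)
  ratio <- if (total > 0) counts / total
           else stats::setNames(rep(NA_real_, length(vocab)), vocab)
  nlr <- NA_real_
  if (vocabulary == "V6" && counts["lymphocyte"] > 0)
    nlr <- counts["neutrophil"] / counts["lymphocyte"]
  morph <- do.call(rbind, lapply(vocab, function(tp) {
    idx <- which(labels == tp)
    if (!length(idx))
      return(data.frame(cell_type = tp, n = 0L, area_mean = NA_real_,
                        area_median = NA_real_, area_sd = NA_real_,
                        perim_mean = NA_real_, perim_median = NA_real_,
                        perim_sd = NA_real_))
    m <- t(vapply(nuclei[idx], nucleus_morphology, numeric(2)))
    data.frame(cell_type = tp, n = length(idx),
               area_mean = mean(m[, 1]), area_median = stats::median(m[, 1]),
               area_sd = stats::sd(m[, 1]),
               perim_mean = mean(m[, 2]),
               perim_median = stats::median(m[, 2]),
               perim_sd = stats::sd(m[, 2]))
  }))
  structure(list(region_id = region_id, vocabulary = vocabulary,
                 area_um2 = area_um2, counts = counts, total = total,
                 density = density, ln_density = ln_density,
                 ratio = ratio, nlr = unname(nlr), morphology = morph),
            class = "region_profile")
}

#' Flatten a region profile to one feature row
#'
#' Column names follow `<stat>_<cell type>` (e.g. `ln_density_lymphocyte`,
#' `ratio_neutrophil`, `area_sd_neoplastic`), plus `nlr` for the
#' 6-class dialect; used to assemble group-comparison tables.
#'
#' @param profile A [profile_region()] result.
#' @return One-row data frame.
#' @export
region_profile_row <- function(profile) {
  vocab <- names(profile$counts)
  out <- list(region_id = profile$region_id)
  safe <- function(x) gsub("-", "_", x)
  for (tp in vocab) {
    out[[paste0("count_", safe(tp))]] <- unname(profile$counts[tp])
    out[[paste0("density_", safe(tp))]] <- unname(profile$density[tp])
    out[[paste0("ln_density_", safe(tp))]] <- unname(profile$ln_density[tp])
    out[[paste0("ratio_", safe(tp))]] <- unname(profile$ratio[tp])
    mr <- profile$morphology[profile$morphology$cell_type == tp, ]
    for (st in c("area_mean", "area_median", "area_sd",
                 "perim_mean", "perim_median", "perim_sd"))
      out[[paste0(st, "_", safe(tp))]] <- mr[[st]]
  }
  if (profile$vocabulary == "V6") out$nlr <- profile$nlr
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Lymphocyte density over tumour-rich patches
#'
#' Nuclei are binned by centroid into a half-open grid of
#' `patch_um` x `patch_um` um^2 patches. A patch is tumour-rich when it
#' contains strictly more than `min_neoplastic` neoplastic nuclei
#' (5-class dialect); the lymphocyte count comes from the 6-class
#' dialect joined spatially on the same grid. The slide-level value is
#' the natural log of the pooled density (total lymphocytes in
#' qualifying patches / total qualifying area). With no qualifying
#' patch the value is missing, not zero.
#'
#' @param v5_nuclei,v6_nuclei Nucleus records from the two dialects,
#'   same pixel space.
#' @param mpp Microns per pixel.
#' @param patch_um Grid cell side in um (default 128).
#' @param min_neoplastic Strict lower bound on neoplastic count
#'   (default 50).
#' @return List: `ln_density`, `density` (um^-2), `n_patches`
#'   (qualifying), `n_lymphocytes`; densities NA when no patch
#'   qualifies, ln also NA when no lymphocyte was found.
#' @export
tumour_rich_lymphocyte_density <- function(v5_nuclei, v6_nuclei,
                                           mpp = 0.5, patch_um = 128,
                                           min_neoplastic = 50) {
  bin_of <- function(recs) {
    if (!length(recs)) return(character())
    xy <- t(vapply(recs, `[[`, numeric(2), "centroid"))
    paste(floor(xy[, 1] * mpp / patch_um),
          floor(xy[, 2] * mpp / patch_um))
  }
  lab5 <- vapply(v5_nuclei, `[[`, "", "class_label")
  neo_bins <- bin_of(v5_nuclei[lab5 == "neoplastic"])
  neo_count <- table(neo_bins)
  rich <- names(neo_count)[neo_count > min_neoplastic]
  if (!length(rich))
    return(list(ln_density = NA_real_, density = NA_real_,
                n_patches = 0L, n_lymphocytes = 0L))
  lab6 <- vapply(v6_nuclei, `[[`, "", "class_label")
  lym_bins <- bin_of(v6_nuclei[lab6 == "lymphocyte"])
  n_lym <- sum(lym_bins %in% rich)
  dens <- n_lym / (length(rich) * patch_um^2)
  list(ln_density = if (n_lym > 0) log(dens) else NA_real_,
       density = dens, n_patches = length(rich), n_lymphocytes = n_lym)
}

#' Cliff's delta
#'
#' `(#(x > y) - #(x < y)) / (n1 * n2)` over all cross-group pairs;
#' always in \[-1, 1\].
#'
#' @param x,y Numeric samples.
#' @return Scalar delta.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  d <- outer(x, y, "-")
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Compare TME features between the C1 and C2 groups
#'
#' Per feature: Welch two-tailed t-test, Mann-Whitney U (normal
#' approximation with tie correction) and Cliff's delta (C1 vs C2
#' orientation), with missing values dropped pairwise. Both raw p
#' columns are Benjamini-Hochberg adjusted across the tested features;
#' the significance flag uses the adjusted t-test p at `level`.
#' Features with fewer than two non-missing values in a group are
#' reported untestable (all statistics NA).
#'
#' @param profiles_c1,profiles_c2 Data frames of feature rows (e.g.
#'   stacked [region_profile_row()]s) for the two groups.
#' @param features Character vector of columns to test; default all
#'   shared numeric columns except `region_id`.
#' @param level BH significance level (default 0.05).
#' @return Data frame, one row per feature: group means/medians,
#'   `t_stat`, `t_p`, `mwu_u`, `mwu_p`, `cliffs_delta`, `t_p_adj`,
#'   `mwu_p_adj`, `significant`, `direction` ("C1>C2" / "C2>C1").
#' @export
compare_groups <- function(profiles_c1, profiles_c2, features = NULL,
                           level = 0.05) {
  if (is.null(features)) {
    shared <- intersect(names(profiles_c1), names(profiles_c2))
    features <- shared[vapply(profiles_c1[shared], is.numeric, TRUE) &
                       shared != "region_id"]
  }
  rows <- lapply(features, function(f) {
    x <- profiles_c1[[f]]; y <- profiles_c2[[f]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    base <- data.frame(feature = f, n_c1 = length(x), n_c2 = length(y),
                       mean_c1 = if (length(x)) mean(x) else NA_real_,
                       mean_c2 = if (length(y)) mean(y) else NA_real_,
                       median_c1 = if (length(x)) stats::median(x) else NA_real_,
                       median_c2 = if (length(y)) stats::median(y) else NA_real_,
                       stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L ||
        (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))) {
      testable <- length(x) >= 2L && length(y) >= 2L
      if (!testable)
        return(cbind(base, t_stat = NA_real_, t_p = NA_real_,
                     mwu_u = NA_real_, mwu_p = NA_real_,
                     cliffs_delta = NA_real_, testable = FALSE))
      # identical constant groups: no variation, null by symmetry
      return(cbind(base, t_stat = 0, t_p = 1, mwu_u = length(x) * length(y) / 2,
                   mwu_p = 1, cliffs_delta = 0, testable = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    cbind(base, t_stat = unname(tt$statistic), t_p = tt$p.value,
          mwu_u = unname(wt$statistic), mwu_p = wt$p.value,
          cliffs_delta = cliffs_delta(x, y), testable = TRUE)
  })
  out <- do.call(rbind, rows)
  out$t_p_adj <- NA_real_; out$mwu_p_adj <- NA_real_
  tb <- which(out$testable)
  out$t_p_adj[tb] <- stats::p.adjust(out$t_p[tb], method = "BH")
  out$mwu_p_adj[tb] <- stats::p.adjust(out$mwu_p[tb], method = "BH")
  out$significant <- !is.na(out$t_p_adj) & out$t_p_adj < level
  out$direction <- ifelse(is.na(out$mean_c1) | is.na(out$mean_c2), NA,
                          ifelse(out$mean_c1 > out$mean_c2,
                                 "C1>C2", "C2>C1"))
  rownames(out) <- NULL
  out
}

#' Spearman correlation of digital-CMS scores with a biological feature
#'
#' Rho is the Pearson correlation of average ranks; the two-sided p
#' comes from the t approximation with n - 2 degrees of freedom.
#' Incomplete pairs are dropped; a constant vector leaves rho
#' undefined (NA).
#'
#' @param scores Digital-CMS scores.
#' @param values Paired biological feature values.
#' @return List: `rho`, `p`, `n`.
#' @export
correlate_scores <- function(scores, values) {
  ok <- !(is.na(scores) | is.na(values))
  x <- scores[ok]; y <- values[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Standard H-DAB stain vectors
#'
#' Rows are unit optical-density vectors for haematoxylin, DAB and the
#' orthogonal residual (Ruifrok-Johnston convention).
#'
#' @return 3 x 3 numeric matrix, rows H / DAB / residual.
#' @export
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  dab <- c(0.269, 0.568, 0.778)
  res <- c(h[2] * dab[3] - h[3] * dab[2],
           h[3] * dab[1] - h[1] * dab[3],
           h[1] * dab[2] - h[2] * dab[1])
  m <- rbind(h = h / sqrt(sum(h^2)), dab = dab / sqrt(sum(dab^2)),
             res = res / sqrt(sum(res^2)))
  colnames(m) <- c("r", "g", "b")
  m
}

#' CD8+ area fraction from an H-DAB IHC image
#'
#' Colour deconvolution in optical-density space separates the DAB
#' channel; pixels with DAB density above `dab_threshold` are called
#' CD8-positive, and the score is the positive area divided by the
#' tissue area (tissue mask from [compute_tissue_mask()] unless
#' supplied).
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @param dab_threshold DAB optical-density threshold (default 0.15).
#' @param stains 3 x 3 stain matrix, rows = stains
#'   (default [hdab_stain_matrix()]).
#' @param tissue_mask Optional logical mask; computed when NULL.
#' @return Fraction in \[0, 1\].
#' @export
cd8_area_fraction <- function(img, dab_threshold = 0.15,
                              stains = hdab_stain_matrix(),
                              tissue_mask = NULL) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a 3-channel image")
  if (is.null(tissue_mask)) tissue_mask <- compute_tissue_mask(img)
  n_tissue <- sum(tissue_mask)
  if (n_tissue == 0) stop("empty tissue mask: CD8 fraction undefined")
  od <- -log10(pmax(img, 1 / 255))
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  conc <- odm %*% solve(stains)    # rows: per-pixel stain densities
  dab <- matrix(conc[, 2], nrow = dim(img)[1])
  sum(dab > dab_threshold & tissue_mask) / n_tissue
}
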
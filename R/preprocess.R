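#' Tile grid specification
#'
#' Non-overlapping sliding-window grid used for WSI-style tiling:
#' 256 x 256 px patches at 0.5 microns per pixel, stride equal to the
#' patch size, origin at (0, 0). Partial edge tiles are dropped so every
#' patch has exactly `patch_size^2` pixels.
#'
#' @param patch_size Patch side in pixels.
#' @param target_mpp Microns per pixel the tiles are assumed to be at.
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(patch_size = 256L, target_mpp = 0.5) {
  patch_size <- as.integer(patch_size)
  if (patch_size <= 0L) stop("patch_size must be positive")
  structure(list(patch_size = patch_size, target_mpp = target_mpp,
                 stride = patch_size, origin = c(0L, 0L)),
            class = "tile_grid")
}

#' Tissue mask by saturation-intensity thresholding
#'
#' Classifies pixels as tissue via Otsu thresholding on the HSV
#' saturation channel, after excluding near-white (background glass) and
#' near-black pixels. If the saturation channel is essentially constant
#' (uniform images), a fixed fallback of saturation > 0.15 and value in
#' (0.1, 0.98] is used instead of Otsu.
#'
#' @param img H x W x 3 array with values in \[0, 1\].
#' @return H x W logical matrix; `TRUE` marks tissue.
#' @export
compute_tissue_mask <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a 3-channel H x W x 3 image")
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  v <- mx
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  not_white <- !(v > 0.95 & s < 0.1)
  not_black <- v > 0.1
  if (diff(range(s)) < 1e-6) {
    mask <- (s > 0.15) & not_white & not_black
  } else {
    thr <- otsu_threshold(s[not_white & not_black])
    if (is.na(thr)) thr <- 0.15
    # glass background is always low-saturation; an Otsu split above
    # 0.25 reflects intra-tissue contrast (e.g. two stains), not
    # tissue-vs-background, so cap the threshold there
    thr <- min(thr, 0.25)
    mask <- (s > thr) & not_white & not_black
  }
  matrix(mask, nrow = nrow(r), ncol = ncol(r))
}

# Otsu's between-class-variance maximizer on a 256-bin histogram.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) < 1e-6) return(NA_real_)
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(sigma_b)]
}

#' Tile an image and keep high-tissue patches
#'
#' Slides the non-overlapping grid over the image and keeps a patch only
#' if its tissue-mask coverage strictly exceeds `min_tissue_fraction`
#' (a patch at exactly the threshold is dropped). Coordinates follow the
#' 0-based, half-open level-0 pixel convention, so patch area is exactly
#' `width * height`.
#'
#' @param img H x W x 3 array (values in \[0, 1\]).
#' @param mask H x W logical tissue mask aligned with `img`; computed
#'   with [compute_tissue_mask()] when `NULL`.
#' @param grid A [tile_grid()].
#' @param min_tissue_fraction Strict lower bound on tissue coverage,
#'   in (0, 1\]. Default 0.8.
#' @return List with `coords` (data frame `x`, `y`, `width`, `height`,
#'   `tissue_fraction`) and `patches` (list of patch arrays). Empty,
#'   with a warning, when the image is smaller than one patch.
#' @export
tile_and_filter <- function(img, mask = NULL, grid = tile_grid(),
                            min_tissue_fraction = 0.8) {
  if (is.null(mask)) mask <- compute_tissue_mask(img)
  if (!all(dim(mask) == dim(img)[1:2]))
    stop("mask is not aligned with the image")
  if (min_tissue_fraction <= 0 || min_tissue_fraction > 1)
    stop("min_tissue_fraction must lie in (0, 1]")
  ps <- grid$patch_size
  h <- nrow(mask); w <- ncol(mask)
  nx <- w %/% ps; ny <- h %/% ps
  if (nx < 1L || ny < 1L) {
    warning("image (", h, "x", w, ") smaller than one ", ps, "-px patch")
    return(list(coords = data.frame(x = integer(), y = integer(),
                                    width = integer(), height = integer(),
                                    tissue_fraction = numeric()),
                patches = list()))
  }
  coords <- list(); patches <- list()
  for (iy in seq_len(ny) - 1L) for (ix in seq_len(nx) - 1L) {
    rows <- (iy * ps + 1L):((iy + 1L) * ps)
    cols <- (ix * ps + 1L):((ix + 1L) * ps)
    frac <- mean(mask[rows, cols])
    if (frac > min_tissue_fraction) {
      coords[[length(coords) + 1L]] <-
        data.frame(x = ix * ps, y = iy * ps, width = ps, height = ps,
                   tissue_fraction = frac)
      patches[[length(patches) + 1L]] <- img[rows, cols, , drop = FALSE]
    }
  }
  list(coords = if (length(coords)) do.call(rbind, coords)
       else data.frame(x = integer(), y = integer(), width = integer(),
                       height = integer(), tissue_fraction = numeric()),
       patches = patches)
}
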
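test_that("densities, morphology and NLR follow their defining formulas", {
  # 100 cells in a 256 x 256 px region at 0.5 mpp: A = 16384 um^2
  set.seed(1)
  nuc <- lapply(1:100, function(i)
    square_nucleus(i, "lymphocyte", (i %% 10) * 20, (i %/% 10) * 20, 6))
  pr <- profile_region(nuc, 256 * 256, mpp = 0.5, vocabulary = "V6")
  expect_equal(pr$area_um2, 16384)
  expect_equal(unname(pr$density["lymphocyte"]), 100 / 16384)
  expect_equal(unname(pr$ln_density["lymphocyte"]), log(100 / 16384),
               tolerance = 1e-12)
  expect_equal(unname(round(pr$ln_density["lymphocyte"], 3)), -5.099)

  # one square nucleus 10 x 10 px at 0.5 mpp: 25 um^2 area, 20 um perimeter
  sq <- square_nucleus(1, "epithelial", 0, 0, 10)
  m <- nucleus_morphology(sq)
  expect_equal(unname(m["area_um2"]), 25)
  expect_equal(unname(m["perimeter_um"]), 20)

  # NLR = neutrophils / lymphocytes = 10 / 4 = 2.5
  nuc2 <- c(lapply(1:10, function(i)
    square_nucleus(i, "neutrophil", i * 12, 0, 5)),
    lapply(1:4, function(i)
      square_nucleus(10 + i, "lymphocyte", i * 12, 50, 5)))
  pr2 <- profile_region(nuc2, 256 * 256, 0.5, "V6")
  expect_equal(pr2$nlr, 2.5)
  # ratios sum to one over the vocabulary; counts conserve the total
  expect_equal(sum(pr2$ratio), 1)
  expect_equal(sum(pr2$counts), 14)
  # absent cell type: morphology missing, ln density missing
  expect_true(is.na(pr2$ln_density["plasma"]))
  expect_true(is.na(pr2$morphology$area_mean[
    pr2$morphology$cell_type == "plasma"]))
  # zero lymphocytes: NLR missing, not infinite
  pr3 <- profile_region(nuc2[1:10], 256 * 256, 0.5, "V6")
  expect_true(is.na(pr3$nlr))
  # mixed dialects rejected
  mixed <- c(nuc2[1:2], list(square_nucleus(99, "neoplastic", 0, 99, 5)))
  expect_error(profile_region(mixed, 256 * 256, 0.5), "mixed")
})

test_that("morphology scales correctly with resolution", {
  sq <- square_nucleus(1, "epithelial", 0, 0, 10, mpp = 0.5)
  sq2 <- square_nucleus(1, "epithelial", 0, 0, 10, mpp = 1.0)
  m1 <- nucleus_morphology(sq); m2 <- nucleus_morphology(sq2)
  expect_equal(unname(m2["area_um2"] / m1["area_um2"]), 4)
  expect_equal(unname(m2["perimeter_um"] / m1["perimeter_um"]), 2)
  # density in um^-2 invariant to pixel resolution for fixed content
  n <- lapply(1:10, function(i) square_nucleus(i, "lymphocyte",
                                               i * 10, 0, 4, mpp = 0.5))
  n2 <- lapply(1:10, function(i) square_nucleus(i, "lymphocyte",
                                                i * 5, 0, 2, mpp = 1.0))
  d1 <- profile_region(n, 256^2, 0.5, "V6")$density["lymphocyte"]
  d2 <- profile_region(n2, 128^2, 1.0, "V6")$density["lymphocyte"]
  expect_equal(d1, d2)
})

test_that("the tumour-rich rule is strict at more than 50 neoplastic cells", {
  mk_patch <- function(n, label, ox, mpp = 0.5) lapply(seq_len(n), function(i)
    square_nucleus(i, label,
                   ox + (i %% 16) * 15 + 1, (i %/% 16) * 15 + 1, 4, mpp))
  # one 128-um patch = 256 px at 0.5 mpp; 51 neoplastic qualifies
  v5 <- mk_patch(51, "neoplastic", 0)
  v6 <- mk_patch(30, "lymphocyte", 0)
  r <- tumour_rich_lymphocyte_density(v5, v6)
  expect_equal(r$n_patches, 1L)
  expect_equal(r$density, 30 / 16384)
  expect_equal(r$ln_density, log(30 / 16384))
  # exactly 50 is excluded
  r50 <- tumour_rich_lymphocyte_density(mk_patch(50, "neoplastic", 0), v6)
  expect_equal(r50$n_patches, 0L)
  expect_true(is.na(r50$ln_density))   # missing, not zero
  # two patches, one qualifying: lymphocytes pooled over qualifying only
  v5b <- c(mk_patch(60, "neoplastic", 0), mk_patch(10, "neoplastic", 256))
  v6b <- c(mk_patch(20, "lymphocyte", 0), mk_patch(40, "lymphocyte", 256))
  rb <- tumour_rich_lymphocyte_density(v5b, v6b)
  expect_equal(rb$n_patches, 1L)
  expect_equal(rb$n_lymphocytes, 20L)
})

test_that("group comparisons match enumeration and step-up oracles", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffs_delta(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 2), c(1, 2)), 0)
  set.seed(2)
  for (rep in 1:20) {
    x <- sample(1:8, 12, TRUE); y <- sample(1:8, 9, TRUE)
    d <- 0
    for (xi in x) for (yi in y) d <- d + sign(xi - yi)
    expect_equal(cliffs_delta(x, y), d / (12 * 9))
    expect_gte(cliffs_delta(x, y), -1); expect_lte(cliffs_delta(x, y), 1)
  }

  # BH equals the step-up oracle
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o); q <- numeric(m); prev <- 1
    for (i in seq_len(m)) {
      rank <- m - i + 1
      prev <- min(prev, p[o[i]] * m / rank)
      q[o[i]] <- prev
    }
    q
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(3)
  for (rep in 1:100) {
    p <- runif(sample(3:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }

  # identical groups: delta 0, p ~ 1; adjusted p >= raw p always
  df1 <- data.frame(f = c(1, 2, 3), g = c(5, 6, 7))
  cmp_id <- compare_groups(df1, df1)
  expect_equal(cmp_id$cliffs_delta, c(0, 0))
  expect_true(all(cmp_id$t_p > 0.9))
  set.seed(4)
  a <- data.frame(u = rnorm(15), v = rnorm(15, 1), w = rnorm(15))
  b <- data.frame(u = rnorm(15, 2), v = rnorm(15), w = rnorm(15))
  cmp <- compare_groups(a, b)
  expect_true(all(cmp$t_p_adj >= cmp$t_p - 1e-15))
  expect_true(all(cmp$t_p_adj <= 1))
  expect_equal(cmp$t_p_adj, p.adjust(cmp$t_p, "BH"))
  expect_equal(cmp$direction[cmp$feature == "u"], "C2>C1")
  # a feature entirely missing in one group is untestable, not an error
  a$z <- NA_real_; b$z <- rnorm(15)
  cmpz <- compare_groups(a, b)
  expect_false(cmpz$testable[cmpz$feature == "z"])
  expect_true(is.na(cmpz$t_p_adj[cmpz$feature == "z"]))
})

test_that("Spearman correlation equals the rank-then-Pearson oracle", {
  expect_equal(correlate_scores(1:10, (1:10)^3)$rho, 1)
  expect_equal(correlate_scores(1:10, -(1:10))$rho, -1)
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    r <- correlate_scores(x, y)
    # independent oracle: Pearson on average ranks
    rx <- rank(x); ry <- rank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(r$rho, oracle, tolerance = 1e-12)
    expect_equal(r$n, 50)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  }
  expect_true(is.na(correlate_scores(rep(1, 5), 1:5)$rho))
  expect_error(correlate_scores(1:2, 1:2), "3 complete pairs")
})

test_that("CD8 scoring recovers planted DAB fractions via deconvolution", {
  for (f in c(0, 0.3, 1)) {
    tile <- generate_ihc_tile(f, size_px = 128L)
    expect_equal(cd8_area_fraction(tile$img), tile$positive_fraction,
                 tolerance = 0.02)
  }
  # empty tissue mask is an error, not zero
  white <- flat_image(32, 32, c(1, 1, 1))
  expect_error(cd8_area_fraction(white), "empty tissue")
  # stain matrix rows are unit vectors
  m <- hdab_stain_matrix()
  expect_equal(unname(rowSums(m^2)), c(1, 1, 1), tolerance = 1e-12)
})
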
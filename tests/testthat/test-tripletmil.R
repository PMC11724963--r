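# Independent symbolic evaluation of the ranking loss, kept deliberately
# separate from the package implementation.
oracle_loss <- function(p, n1, n2, a1 = 0.5, a2 = 0.1) {
  max(a1 - (p - n1), 0) + max(a1 - (p - n2), 0) + max((n1 - n2)^2 - a2, 0)
}

test_that("triplet loss matches its worked values and the symbolic oracle", {
  expect_equal(triplet_loss(1.0, 0.0, 0.0), 0.0)
  expect_equal(triplet_loss(0.6, 0.4, 0.2), 0.4)
  expect_equal(triplet_loss(0.5, 0.5, 0.5), 1.0)
  set.seed(1)
  for (i in 1:1000) {
    x <- runif(3, -2, 2)
    expect_equal(triplet_loss(x[1], x[2], x[3]),
                 oracle_loss(x[1], x[2], x[3]), tolerance = 1e-10)
  }
  expect_error(triplet_loss(Inf, 0, 0), "finite")
  expect_error(triplet_params(alpha1 = 0), "alpha1")
  expect_error(triplet_params(alpha2 = -1), "alpha2")
})

test_that("loss is zero exactly when both margins and the intra-class bound hold", {
  a1 <- 0.5; a2 <- 0.1
  grid <- expand.grid(p = seq(0, 1, length.out = 21),
                      n1 = seq(0, 1, length.out = 21),
                      n2 = seq(0, 1, length.out = 21))
  l <- triplet_loss(grid$p, grid$n1, grid$n2)
  satisfied <- (grid$p - pmax(grid$n1, grid$n2) >= a1) &
    ((grid$n1 - grid$n2)^2 <= a2)
  expect_true(all(l >= 0))
  expect_identical(l == 0, satisfied)
  # perturbing any satisfied condition by eps makes the loss positive
  expect_gt(triplet_loss(0.5 + 0.1 - 1e-6, 0.1, 0.1), 0)
  expect_gt(triplet_loss(1, 0, sqrt(a2) + 1e-6), 0)
})

test_that("patch scoring is pointwise, symmetric at zero weights, deterministic", {
  bags <- tiny_bags(1, 1, k = 5, seed = 2)
  zero <- structure(list(mlp = list(W1 = matrix(0, 1024, 8),
                                    b1 = numeric(8),
                                    w2 = matrix(0, 8, 1), b2 = 0),
                         hidden = 8L), class = "cms_scorer")
  expect_equal(score_patches(zero, bags[[1]]), rep(0.5, 5))
  set.seed(3)
  rnd <- zero
  rnd$mlp <- digitalCMS:::mlp_init(1024, 8)
  s1 <- score_patches(rnd, bags[[1]])
  expect_identical(s1, score_patches(rnd, bags[[1]]))   # bitwise repeatable
  dup <- cms_bag("d", bags[[1]]$features[c(1, 1, 2), ])
  sd_ <- score_patches(rnd, dup)
  expect_identical(sd_[1], sd_[2])
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_error(score_patches(rnd, matrix(0, 2, 512)), "dimension")
})

test_that("average aggregation matches a brute-force sum and stays bounded", {
  expect_equal(aggregate_slide_score(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(aggregate_slide_score(rep(0.37, 9)), 0.37)
  set.seed(4)
  s <- runif(1000)
  acc <- 0; for (v in s) acc <- acc + v      # independent summation
  expect_equal(aggregate_slide_score(s), acc / 1000, tolerance = 1e-12)
  expect_true(aggregate_slide_score(s) >= min(s) &&
              aggregate_slide_score(s) <= max(s))
  expect_error(aggregate_slide_score(numeric(0)), "at least one")
})

test_that("triplet sampling respects class composition and determinism", {
  bags <- tiny_bags(2, 1, k = 4, seed = 5)     # 2 C1 + 1 C2
  set.seed(6)
  tr <- sample_triplets(bags, 10)
  expect_equal(nrow(tr), 10)
  labs <- vapply(bags, function(b) as.numeric(b$label), 0)
  expect_true(all(labs[tr[, "p"]] == 1))
  expect_true(all(labs[tr[, "n1"]] == 0 & labs[tr[, "n2"]] == 0))
  expect_true(all(tr[, "n1"] != tr[, "n2"]))
  set.seed(6)
  expect_identical(tr, sample_triplets(bags, 10))
  expect_error(sample_triplets(tiny_bags(3, 0, seed = 7), 5), "C2")
  expect_error(sample_triplets(tiny_bags(1, 3, seed = 7), 5), "C1")
})

test_that("stratified folds are within one sample of perfect stratification", {
  for (seed in 1:20) {
    set.seed(seed)
    labs <- rbinom(40 + seed, 1, 0.4)
    fold <- stratified_folds(labs, 3, seed = seed)
    expect_setequal(unique(fold), 1:3)
    for (cl in 0:1) {
      cnt <- table(factor(fold[labs == cl], levels = 1:3))
      expect_lte(max(cnt) - min(cnt), 1)
    }
  }
})

test_that("training is seed-deterministic and logs a non-increasing checkpoint", {
  spec <- synthetic_spec(n_patients_per_class = 6L,
                         patches_per_bag = c(8L, 12L), seed = 20)
  co <- generate_cohort(spec, "T")
  m1 <- train_triplet_mil(co$bags, epochs = 4, hidden = 16, seed = 21)
  m2 <- train_triplet_mil(co$bags, epochs = 4, hidden = 16, seed = 21)
  expect_identical(m1$mlp, m2$mlp)
  expect_identical(m1$training_log, m2$training_log)
  # checkpointed monitor loss no worse than the first epoch's
  expect_lte(min(m1$training_log$monitor_loss),
             m1$training_log$monitor_loss[1] + 1e-12)
  expect_error(train_triplet_mil(co$bags[1:6]), "both classes")
})

test_that("cross-cohort orchestration produces per-setting models and score tables", {
  mk <- function(id, seed) {
    spec <- synthetic_spec(n_patients_per_class = 6L,
                           patches_per_bag = c(6L, 9L),
                           effect_size = 1, seed = seed, signal_seed = 99)
    co <- generate_cohort(spec, id)
    list(cohort_id = id, bags = co$bags, clinical = co$clinical)
  }
  cohorts <- list(A = mk("A", 31), B = mk("B", 32), C = mk("C", 33))
  plan <- leave_one_out_plan(c("A", "B", "C"), seed = 5)
  res <- run_cross_cohort(cohorts, plan, epochs = 2, hidden = 8,
                          monitor_triplets = 5)
  expect_length(res, 3)
  expect_equal(sum(vapply(res, function(r) length(r$models), 0L)), 9L)
  for (r in res) {
    # one score row per held-out patient
    expect_setequal(r$test_scores$patient_id,
                    vapply(cohorts[[r$setting$test]]$bags, `[[`, "",
                           "patient_id"))
    # fold class ratios within one sample of the global ratio
    labs <- vapply(unlist(lapply(cohorts[r$setting$train], `[[`, "bags"),
                          recursive = FALSE),
                   function(b) as.numeric(b$label), 0)
    for (cl in 0:1) {
      cnt <- table(factor(r$fold[labs == cl], levels = 1:3))
      expect_lte(max(cnt) - min(cnt), 1)
    }
  }
  expect_error(run_cross_cohort(cohorts[1:2], plan), "not supplied")
})
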
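# O(n^2) pair-counting AUC with ties counted 1/2.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUC equals pair counting, handles ties, and is transform-invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  set.seed(1)
  for (rep in 1:10) {
    s <- sample(seq(0, 1, 0.1), 20, replace = TRUE)   # many ties
    l <- rbinom(20, 1, 0.5)
    if (length(unique(l)) < 2) next
    r <- roc_auc(s, l)
    expect_equal(r$auc, auc_pairs(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(exp(s), l)$auc, r$auc, tolerance = 1e-12)
    expect_equal(roc_auc(3 * s - 7, l)$auc, r$auc, tolerance = 1e-12)
    expect_true(all(r$sensitivity >= 0 & r$sensitivity <= 1))
    expect_true(all(r$specificity >= 0 & r$specificity <= 1))
  }
  set.seed(2)
  s <- rnorm(2000); l <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.03)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("Youden cutoff equals an exhaustive scan with the lowest-threshold tie rule", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))
  expect_equal(youden_cutoff(r), 0.375)      # midpoint of (0.35, 0.4], J = 1
  scan_oracle <- function(scores, labels) {
    u <- sort(unique(scores))
    cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
    j <- vapply(cand, function(t)
      mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1, 0)
    min(cand[j >= max(j) - 1e-12])
  }
  set.seed(3)
  for (rep in 1:100) {
    s <- round(runif(15), 2); l <- rbinom(15, 1, 0.5)
    if (length(unique(l)) < 2 || length(unique(s)) < 2) next
    expect_equal(youden_cutoff(roc_auc(s, l)), scan_oracle(s, l))
  }
  expect_error(youden_cutoff(roc_auc(rep(1, 4), c(0, 1, 0, 1))),
               "identical")
})

test_that("log-rank matches a hand-computed oracle and vanishes on identical groups", {
  # identical survival data in both groups: statistic 0, p = 1
  km0 <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                    rep(c("a", "b"), each = 3))
  expect_equal(km0$statistic, 0, tolerance = 1e-12)
  expect_equal(km0$p_value, 1, tolerance = 1e-12)

  # toy fully-observed data: hypergeometric expectation/variance by hand
  time <- c(1, 2, 3, 4, 5, 6); event <- rep(1, 6)
  group <- rep(c("g1", "g2"), each = 3)
  o_minus_e <- 0; v <- 0
  for (t in time) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == "g1")
    d <- sum(time == t)
    o_minus_e <- o_minus_e + sum(time == t & group == "g1") - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle_stat <- o_minus_e^2 / v
  km <- km_logrank(time, event, group)
  expect_equal(km$statistic, oracle_stat, tolerance = 1e-10)
  expect_equal(km$df, 1)

  # KM estimator properties: starts at 1 before the first event,
  # non-increasing, equals the empirical survivor function uncensored
  set.seed(4)
  tt <- rexp(40); gg <- rep("x", 40)
  km1 <- km_logrank(c(tt, rexp(40, 2)), rep(1, 80),
                    c(gg, rep("y", 40)))
  for (g in c("x", "y")) {
    cur <- km1$curves[km1$curves$group == g, ]
    expect_true(all(diff(cur$surv) <= 1e-12))
    emp <- vapply(cur$time, function(t0) mean(
      (if (g == "x") tt else c(tt, rexp(0))) > t0), 0)
  }
  cur <- km1$curves[km1$curves$group == "x", ]
  expect_equal(cur$surv, vapply(cur$time, function(t0) mean(tt > t0), 0),
               tolerance = 1e-12)
  expect_error(km_logrank(1:3, c(1, 1, 1), rep("a", 3)), "2 groups")
})

test_that("Cox fits recover null and true hazard ratios", {
  set.seed(5)
  df <- data.frame(time = rexp(60), event = 1, x = rep(0:1, 30))
  fit <- fit_coxph(df, "time", "event", "x")
  expect_lt(abs(log(fit$table$hr[1])), 0.6)   # beta ~ 0 under the null
  df0 <- df; df0$event <- 0
  expect_error(fit_coxph(df0, "time", "event", "x"), "no events")

  # parameter recovery: exponential data, true HR = 2, 20% censoring
  spec <- synthetic_spec(n_patients_per_class = 250L,
                         survival_hazard_ratio = 2,
                         censoring_rate = 0.2, seed = 6)
  co <- generate_cohort(spec, "HR", features = FALSE)
  fit2 <- fit_coxph(co$clinical, "dss_time", "dss_event", "cms_label")
  expect_gt(fit2$table$hr[1], 1.6)
  expect_lt(fit2$table$hr[1], 2.5)
  # categorical expansion against declared reference levels
  fit3 <- fit_coxph(co$clinical, "dss_time", "dss_event",
                    c("cms_label", "stage", "hpv_type"),
                    reference_levels = list(stage = "I",
                                            hpv_type = "HPV16"))
  expect_true(any(grepl("stageIV", fit3$table$term)))
  expect_false(any(grepl("stageI$", fit3$table$term)))
})

test_that("concordance matches pair enumeration and DeLong handles degeneracy", {
  # perfectly concordant with event order, no censoring
  tt <- c(5, 4, 3, 2, 1); sc <- 1:5
  r <- cindex_delong(sc, sc, time = tt, event = rep(1, 5),
                     labels = c(0, 0, 0, 1, 1))
  expect_equal(r$c_index_a, 1.0)
  expect_equal(r$delong_p, 1)              # identical classifiers
  expect_equal(r$auc_a, r$auc_b)

  # brute-force comparable-pair oracle under censoring
  set.seed(7)
  n <- 30
  time <- rexp(n); event <- rbinom(n, 1, 0.7); s <- rnorm(n)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # comparable: the smaller observed time is an event
    first <- if (time[i] < time[j]) i else j
    other <- if (first == i) j else i
    if (time[i] == time[j]) next
    if (event[first] == 0) next
    if (s[first] > s[other]) conc <- conc + 1
    else if (s[first] < s[other]) disc <- disc + 1
  }
  oracle_c <- conc / (conc + disc)
  r2 <- cindex_delong(s, rev(s), time = time, event = event)
  expect_equal(r2$c_index_a, oracle_c, tolerance = 1e-12)

  # DeLong on genuinely different classifiers returns a finite p
  set.seed(8)
  l <- rbinom(40, 1, 0.5); sa <- rnorm(40) + l; sb <- rnorm(40)
  r3 <- cindex_delong(sa, sb, labels = l)
  expect_true(r3$delong_p >= 0 && r3$delong_p <= 1)
  expect_error(cindex_delong(1:3, 1:4), "same subjects")
})

test_that("null log-rank rejects at the nominal rate", {
  set.seed(9)
  rej <- vapply(1:200, function(i) {
    t1 <- rexp(50); t2 <- rexp(50)    # hazard ratio 1, no censoring
    km <- km_logrank(c(t1, t2), rep(1, 100), rep(c("a", "b"), each = 50))
    km$p_value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
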
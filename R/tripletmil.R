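#' Triplet ranking loss margins
#'
#' `alpha1` is the inter-class margin: a C2 bag's digital-CMS score must
#' exceed each of the two C1 scores in a triplet by at least `alpha1`.
#' `alpha2` bounds the squared gap between the two C1 scores, limiting
#' intra-class variation. Defaults follow the ranking-MIL convention of
#' 0.5 and 0.1.
#'
#' @param alpha1 Inter-class margin, > 0.
#' @param alpha2 Intra-class squared-gap bound, >= 0.
#' @return An object of class `triplet_params`.
#' @export
triplet_params <- function(alpha1 = 0.5, alpha2 = 0.1) {
  if (!is.finite(alpha1) || alpha1 <= 0) stop("alpha1 must be > 0")
  if (!is.finite(alpha2) || alpha2 < 0) stop("alpha2 must be >= 0")
  structure(list(alpha1 = alpha1, alpha2 = alpha2),
            class = "triplet_params")
}

#' Triplet ranking loss
#'
#' For a C2 score `x_p` and two distinct C1 scores `x_n1`, `x_n2`:
#' \deqn{L = [\alpha_1 - (x_p - x_{n1})]_+ + [\alpha_1 - (x_p - x_{n2})]_+
#'         + [\|x_{n1} - x_{n2}\|_2^2 - \alpha_2]_+}
#' The loss is non-negative and zero exactly when both inter-class gaps
#' reach `alpha1` and the squared intra-class gap is at most `alpha2`.
#' All three arguments are vectorized.
#'
#' @param x_p,x_n1,x_n2 Finite numeric scores (C2, C1, C1).
#' @param params A [triplet_params()].
#' @return Numeric loss, same length as the inputs.
#' @export
triplet_loss <- function(x_p, x_n1, x_n2, params = triplet_params()) {
  if (!all(is.finite(c(x_p, x_n1, x_n2)))) stop("scores must be finite")
  relu <- function(z) pmax(z, 0)
  relu(params$alpha1 - (x_p - x_n1)) +
    relu(params$alpha1 - (x_p - x_n2)) +
    relu((x_n1 - x_n2)^2 - params$alpha2)
}

#' Construct a MIL bag
#'
#' One patient is one bag: the patch embeddings of all of the patient's
#' slides stacked into a K x 1024 matrix, labelled only at bag level
#' (0 = C1, 1 = C2, NA = unlabeled).
#'
#' @param patient_id Patient identifier.
#' @param features K x 1024 numeric matrix.
#' @param label 0, 1 or NA.
#' @param coords Optional data frame (`x`, `y`, `width`, `height`) per
#'   patch row.
#' @param slide_id Optional per-patch slide id (recycled if length 1).
#' @return An object of class `cms_bag`.
#' @export
cms_bag <- function(patient_id, features, label = NA, coords = NULL,
                    slide_id = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("bag needs K >= 1 patches")
  if (ncol(features) != 1024L)
    stop("bag feature dimension must be 1024, got ", ncol(features))
  if (!is.na(label) && !label %in% c(0, 1))
    stop("label must be 0 (C1), 1 (C2) or NA")
  if (!is.null(coords) && nrow(coords) != nrow(features))
    stop("coords do not align with features")
  if (!is.null(slide_id) && length(slide_id) == 1L)
    slide_id <- rep(slide_id, nrow(features))
  structure(list(patient_id = as.character(patient_id),
                 features = features, label = label,
                 coords = coords, slide_id = slide_id),
            class = "cms_bag")
}

# He-initialized 1024 -> hidden -> 1 MLP with ReLU; weights drawn from
# the current RNG stream.
mlp_init <- function(d_in = 1024L, hidden = 512L) {
  list(W1 = matrix(rnorm(d_in * hidden, sd = sqrt(2 / d_in)), d_in, hidden),
       b1 = numeric(hidden),
       w2 = matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1),
       b2 = 0)
}

# Forward pass; returns intermediates needed for backprop.
mlp_forward <- function(par, X) {
  Z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  z2 <- drop(A1 %*% par$w2) + par$b2
  s <- stats::plogis(z2)               # patch scores in [0, 1]
  list(Z1 = Z1, A1 = A1, s = s, bag = mean(s))
}

# Gradient of the bag score wrt parameters, scaled by upstream gbag.
mlp_backward <- function(par, X, fw, gbag) {
  K <- length(fw$s)
  dz2 <- gbag * fw$s * (1 - fw$s) / K
  dA1 <- dz2 %*% t(par$w2)
  dZ1 <- dA1 * (fw$Z1 > 0)
  list(W1 = crossprod(X, dZ1), b1 = colSums(dZ1),
       w2 = crossprod(fw$A1, matrix(dz2, ncol = 1)), b2 = sum(dz2))
}

#' Score the patches of a bag
#'
#' Applies the trained instance scorer to every patch embedding; scores
#' are sigmoid-transformed, so each lies in \[0, 1\] with higher values
#' more C2-like. Order is aligned with the bag's feature rows and the
#' result is deterministic given fixed parameters.
#'
#' @param scorer A `cms_scorer` from [train_triplet_mil()].
#' @param bag A [cms_bag()], or a bare K x 1024 matrix.
#' @return Numeric vector of K patch scores.
#' @export
score_patches <- function(scorer, bag) {
  X <- if (inherits(bag, "cms_bag")) bag$features else as.matrix(bag)
  if (ncol(X) != nrow(scorer$mlp$W1))
    stop("feature dimension ", ncol(X), " does not match scorer input ",
         nrow(scorer$mlp$W1))
  mlp_forward(scorer$mlp, X)$s
}

#' Aggregate patch scores into a patient-level digital-CMS score
#'
#' Average aggregation: the patient-level score is the arithmetic mean
#' of the patch scores, hence bounded by their min and max.
#'
#' @param patch_scores Numeric vector of >= 1 patch scores.
#' @return The mean score.
#' @export
aggregate_slide_score <- function(patch_scores) {
  if (length(patch_scores) < 1L) stop("need at least one patch score")
  mean(patch_scores)
}

#' Score whole bags
#'
#' @param scorer A `cms_scorer`.
#' @param bags A list of [cms_bag()]s.
#' @return Data frame: `patient_id`, `digital_cms_score`, `label`.
#' @export
score_bags <- function(scorer, bags) {
  data.frame(
    patient_id = vapply(bags, `[[`, "", "patient_id"),
    digital_cms_score = vapply(bags, function(b)
      aggregate_slide_score(score_patches(scorer, b)), 0),
    label = vapply(bags, function(b) as.numeric(b$label), 0),
    stringsAsFactors = FALSE)
}

#' Sample training triplets
#'
#' Each triplet holds one C2 bag and two distinct C1 bags, all drawn
#' uniformly with replacement across triplets.
#'
#' @param bags List of labelled [cms_bag()]s.
#' @param n_triplets Number of triplets.
#' @return Integer matrix with columns `p`, `n1`, `n2` indexing `bags`.
#' @export
sample_triplets <- function(bags, n_triplets) {
  labels <- vapply(bags, function(b) as.numeric(b$label), 0)
  i_c2 <- which(labels == 1); i_c1 <- which(labels == 0)
  if (length(i_c2) < 1L)
    stop("need at least 1 C2 bag, found ", length(i_c2))
  if (length(i_c1) < 2L)
    stop("need at least 2 C1 bags, found ", length(i_c1))
  p <- i_c2[sample.int(length(i_c2), n_triplets, replace = TRUE)]
  n1 <- integer(n_triplets); n2 <- integer(n_triplets)
  for (i in seq_len(n_triplets)) {
    pair <- i_c1[sample.int(length(i_c1), 2L, replace = FALSE)]
    n1[i] <- pair[1]; n2[i] <- pair[2]
  }
  cbind(p = p, n1 = n1, n2 = n2)
}

#' Train the triplet-ranking MIL scorer
#'
#' A 1024 -> `hidden` -> 1 ReLU MLP scores each patch; the sigmoid of
#' the output is the patch digital-CMS score and the bag score is the
#' patch-score mean. Training minimizes the summed triplet loss over
#' sampled triplets by SGD with momentum 0.9, weight decay 1e-4,
#' learning rate 3e-3 decayed by 0.1 every 10 epochs, for at most 20
#' epochs with early stopping once the monitoring loss stops improving
#' for `patience` consecutive epochs. The returned scorer carries the
#' checkpoint with the lowest monitoring loss and a per-epoch training
#' log. All randomness (init, triplet sampling) flows from `seed`.
#'
#' @param bags Labelled training bags (both classes present).
#' @param params [triplet_params()].
#' @param monitor_bags Bags of the monitoring (validation) fold; when
#'   NULL the training bags are monitored.
#' @param epochs Maximum epochs (default 20).
#' @param lr,momentum,weight_decay,lr_decay,lr_decay_every SGD schedule.
#' @param hidden Hidden width of the MLP.
#' @param patience Early-stopping patience in epochs.
#' @param triplets_per_epoch Default: four times the number of C2
#'   training bags (each C2 bag enters several ranking comparisons per
#'   epoch).
#' @param monitor_triplets Number of fixed triplets used to estimate
#'   the monitoring loss.
#' @param seed Integer seed.
#' @return An object of class `cms_scorer`: `mlp` (weights at the best
#'   checkpoint), `hidden`, `params`, `training_log` (data frame with
#'   epoch, lr, train_loss, monitor_loss, monitor_auc), `best_epoch`.
#' @export
train_triplet_mil <- function(bags, params = triplet_params(),
                              monitor_bags = NULL, epochs = 20L,
                              lr = 3e-3, momentum = 0.9,
                              weight_decay = 1e-4, lr_decay = 0.1,
                              lr_decay_every = 10L, hidden = 512L,
                              patience = 3L, triplets_per_epoch = NULL,
                              monitor_triplets = 30L, seed = 1L) {
  labels <- vapply(bags, function(b) as.numeric(b$label), 0)
  if (any(is.na(labels))) stop("all training bags must be labelled")
  if (length(unique(labels)) < 2L)
    stop("training requires bags of both classes")
  set.seed(seed)
  par <- mlp_init(ncol(bags[[1]]$features), hidden)
  vel <- lapply(par, function(x) x * 0)
  # several ranking comparisons per C2 bag per epoch: one per epoch
  # starves SGD of steps before the learning-rate decay
  if (is.null(triplets_per_epoch))
    triplets_per_epoch <- 4L * sum(labels == 1)
  mon <- if (is.null(monitor_bags)) bags else monitor_bags
  mon_lab <- vapply(mon, function(b) as.numeric(b$label), 0)
  mon_trip <- sample_triplets(mon, monitor_triplets)

  bag_scores <- function(p, set) vapply(set, function(b)
    mean(mlp_forward(p, b$features)$s), 0)
  monitor_loss <- function(p) {
    sc <- bag_scores(p, mon)
    mean(triplet_loss(sc[mon_trip[, "p"]], sc[mon_trip[, "n1"]],
                      sc[mon_trip[, "n2"]], params))
  }

  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), monitor_loss = numeric(),
                    monitor_auc = numeric())
  best <- list(loss = Inf, par = par, epoch = 0L)
  stale <- 0L
  for (epoch in seq_len(epochs)) {
    lr_e <- lr * lr_decay^((epoch - 1) %/% lr_decay_every)
    trips <- sample_triplets(bags, triplets_per_epoch)
    epoch_loss <- 0
    for (t in seq_len(nrow(trips))) {
      idx <- trips[t, ]
      fw <- lapply(idx, function(i) mlp_forward(par, bags[[i]]$features))
      x <- vapply(fw, `[[`, 0, "bag")   # p, n1, n2
      a1 <- params$alpha1; a2 <- params$alpha2
      h1 <- (a1 - (x[1] - x[2])) > 0
      h2 <- (a1 - (x[1] - x[3])) > 0
      h3 <- ((x[2] - x[3])^2 - a2) > 0
      epoch_loss <- epoch_loss + triplet_loss(x[1], x[2], x[3], params)
      gx <- c(-(h1 + h2),
              h1 + 2 * h3 * (x[2] - x[3]),
              h2 - 2 * h3 * (x[2] - x[3]))
      grad <- NULL
      for (j in 1:3) {
        if (gx[j] == 0) next
        gj <- mlp_backward(par, bags[[idx[j]]]$features, fw[[j]], gx[j])
        grad <- if (is.null(grad)) gj
                else Map(`+`, grad, gj)
      }
      if (!is.null(grad)) {
        for (nm in names(par)) {
          vel[[nm]] <- momentum * vel[[nm]] -
            lr_e * (grad[[nm]] + weight_decay * par[[nm]])
          par[[nm]] <- par[[nm]] + vel[[nm]]
        }
      }
    }
    ml <- monitor_loss(par)
    ma <- if (length(unique(mon_lab)) == 2L)
      auc_rank(bag_scores(par, mon), mon_lab) else NA_real_
    log <- rbind(log, data.frame(epoch = epoch, lr = lr_e,
                                 train_loss = epoch_loss / nrow(trips),
                                 monitor_loss = ml, monitor_auc = ma))
    if (ml < best$loss - 1e-12) {
      best <- list(loss = ml, par = par, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  structure(list(mlp = best$par, hidden = hidden, params = params,
                 training_log = log, best_epoch = best$epoch,
                 seed = seed),
            class = "cms_scorer")
}

#' @export
print.cms_scorer <- function(x, ...) {
  cat("Triplet-MIL digital-CMS scorer\n",
      " MLP: ", nrow(x$mlp$W1), " -> ", x$hidden, " -> 1 (ReLU, sigmoid)\n",
      " best epoch: ", x$best_epoch, " (monitor loss ",
      format(min(x$training_log$monitor_loss), digits = 4), ")\n", sep = "")
  invisible(x)
}

# Rank-based AUC (Mann-Whitney with average ranks == trapezoidal ROC).
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment
#'
#' Folds partition the samples; within each class, fold sizes differ by
#' at most one, so per-fold class counts are within one of perfect
#' stratification.
#'
#' @param labels 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(labels, k = 3L, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-cohort training plan
#'
#' Each setting merges the training cohorts into one discovery set for
#' stratified three-fold cross validation and holds one cohort out for
#' testing. `leave_one_out_plan` builds the standard all-rotations plan.
#'
#' @param settings List of `list(train = c(...), test = "...")`.
#' @param n_folds Folds in the discovery CV (default 3).
#' @param seed Integer seed.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(settings, n_folds = 3L, seed = 1L) {
  structure(list(settings = settings, n_folds = as.integer(n_folds),
                 stratify_on = "cms_label", seed = as.integer(seed)),
            class = "cv_plan")
}

#' @rdname cv_plan
#' @param cohort_ids Character vector of cohort ids.
#' @export
leave_one_out_plan <- function(cohort_ids, n_folds = 3L, seed = 1L) {
  settings <- lapply(cohort_ids, function(test)
    list(train = setdiff(cohort_ids, test), test = test))
  cv_plan(settings, n_folds, seed)
}

#' Run the cross-cohort experiments
#'
#' For every setting of the plan: merge the training cohorts' labelled
#' bags, split into stratified folds, train one model per fold (two
#' folds train, the left-out fold monitors early stopping and supplies
#' the validation AUC), select the best-performing model by validation
#' AUC, and score every patient of the held-out cohort with it. The
#' best model's scores on the full discovery set are also returned for
#' downstream cutoff selection.
#'
#' @param cohorts Named list; each element a list with `cohort_id` and
#'   `bags` (list of [cms_bag()]s).
#' @param plan A [cv_plan()].
#' @param ... Passed on to [train_triplet_mil()].
#' @return List (one element per setting) of: `setting`, `models`,
#'   `val_aucs`, `best_fold`, `test_scores` (score table for the
#'   held-out cohort), `discovery_scores`.
#' @export
run_cross_cohort <- function(cohorts, plan, ...) {
  missing <- setdiff(unique(unlist(lapply(plan$settings, unlist))),
                     names(cohorts))
  if (length(missing))
    stop("cohort(s) named in plan but not supplied: ",
         paste(missing, collapse = ", "))
  out <- list()
  for (si in seq_along(plan$settings)) {
    st <- plan$settings[[si]]
    train_bags <- unlist(lapply(cohorts[st$train], `[[`, "bags"),
                         recursive = FALSE)
    labelled <- !vapply(train_bags, function(b) is.na(b$label), TRUE)
    train_bags <- train_bags[labelled]
    labels <- vapply(train_bags, function(b) as.numeric(b$label), 0)
    fold <- stratified_folds(labels, plan$n_folds,
                             seed = plan$seed * 100L + si)
    models <- list(); val_aucs <- numeric(plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      m <- train_triplet_mil(train_bags[fold != f],
                             monitor_bags = train_bags[fold == f],
                             seed = plan$seed * 1000L + si * 10L + f, ...)
      models[[f]] <- m
      val_aucs[f] <- auc_rank(
        score_bags(m, train_bags[fold == f])$digital_cms_score,
        labels[fold == f])
    }
    best <- which.max(val_aucs)
    test_tab <- score_bags(models[[best]], cohorts[[st$test]]$bags)
    test_tab$cohort <- st$test
    test_tab$predicted_class <- NA  # filled once a cutoff is chosen
    disc <- score_bags(models[[best]], train_bags)
    disc$cohort <- paste(st$train, collapse = "+")
    out[[si]] <- list(setting = st, models = models, val_aucs = val_aucs,
                      best_fold = best, fold = fold,
                      test_scores = test_tab, discovery_scores = disc)
  }
  out
}
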
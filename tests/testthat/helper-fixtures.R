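# Shared fixtures, built in code and cached for the whole run.

# Small labelled bags for bookkeeping-level tests (no learning needed).
tiny_bags <- function(n_c1 = 4, n_c2 = 4, k = 6, seed = 42,
                      prefix = "P") {
  set.seed(seed)
  labs <- c(rep(0, n_c1), rep(1, n_c2))
  lapply(seq_along(labs), function(i)
    cms_bag(sprintf("%s%02d", prefix, i),
            matrix(rnorm(k * 1024), k, 1024), labs[i]))
}

# One trained model on the synthetic study conditions (effect 2, signal
# fraction 0.3, 40 bags/class), shared by the learning, localisation and
# exemplar tests; trained at most once per test run.
mil_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(seed = 11)
      co <- generate_cohort(spec, "FIX")
      labs <- vapply(co$bags, function(b) as.numeric(b$label), 0)
      fold <- stratified_folds(labs, 3, seed = 12)
      model <- train_triplet_mil(co$bags[fold != 1],
                                 monitor_bags = co$bags[fold == 1],
                                 seed = 13)
      cache <<- list(cohort = co, labels = labs, fold = fold,
                     model = model)
    }
    cache
  }
})

# Uniform-colour RGB image helper.
flat_image <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# A square nucleus of side `side` px with lower-left corner at (x0, y0).
square_nucleus <- function(id, label, x0, y0, side, mpp = 0.5) {
  nucleus_record(id, label,
                 rbind(c(x0, y0), c(x0 + side, y0),
                       c(x0 + side, y0 + side), c(x0, y0 + side)),
                 mpp = mpp)
}
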
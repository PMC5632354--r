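# Shared fixtures: small cohorts and hand-built recordings, generated in code.

tiny_config <- function(...) {
  args <- list(n_per_group = 6, nirs_channels = 3, seed = 42)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(cohort_config, args)
}

# A recording whose channels are filled from a generator function(t) so the
# signal content is known exactly.
signal_recording <- function(f, channels = 2, fs = 5,
                             schedule = make_schedule(),
                             chromophore = "OXY") {
  n <- round(schedule_duration(schedule) * fs)
  t <- (seq_len(n) - 1) / fs
  data <- matrix(rep(f(t), each = channels), channels, n, byrow = FALSE)
  nirs_recording("test", chromophore, data, fs, schedule)
}

# Independent brute-force wrapper reference: scores every subset by its own
# CV loop calling the SVM library directly, preferring (in order) higher
# accuracy, smaller subsets, lexicographically earlier index sets.
oracle_best_subset <- function(splits, p) {
  subsets <- unlist(lapply(seq_len(p), function(k) {
    m <- utils::combn(p, k)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }), recursive = FALSE)
  best <- NULL; best_score <- -Inf
  for (ss in subsets) {
    correct <- 0; total <- 0
    for (s in splits) {
      fit <- e1071::svm(s$xtr[, ss, drop = FALSE],
                        factor(s$ytr, levels = c("ADHD", "TD")),
                        kernel = "linear", cost = 1, scale = FALSE)
      pred <- as.character(predict(fit, s$xte[, ss, drop = FALSE]))
      correct <- correct + sum(pred == s$yte)
      total <- total + length(s$yte)
    }
    sc <- correct / total
    if (sc > best_score) { best <- ss; best_score <- sc }
  }
  list(best_subset = best, best_score = best_score)
}

# Random engineered inner pool for wrapper tests: n subjects, p features,
# the first feature carrying a group shift of size d.
random_inner_pool <- function(n = 18, p = 4, d = 1.5, n_subsets = 3,
                              seed = 1) {
  set.seed(seed)
  labels <- rep(c("ADHD", "TD"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[labels == "ADHD", 1] <- x[labels == "ADHD", 1] + d
  idx <- sample(n)
  subsets <- split(idx, rep_len(seq_len(n_subsets), n))
  splits <- lapply(subsets, function(te) {
    tr <- setdiff(seq_len(n), te)
    list(xtr = x[tr, , drop = FALSE], ytr = labels[tr],
         xte = x[te, , drop = FALSE], yte = labels[te])
  })
  structure(list(splits = unname(splits), p = p), class = "inner_pool")
}
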
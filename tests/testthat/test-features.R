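test_that("z-scoring matches direct mean/SD computation in both modes", {
  tab <- feature_table(cbind(a = c(1, 2, 3), b = c(4, 0, 2)),
                       c("ADHD", "TD", "ADHD"), domain = "NPS")
  z <- zscore_table(tab, "population")
  expect_equal(unname(z$x[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z$x), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z$x, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)

  # train-only statistics applied to a held-out row at the train mean -> 0
  tab2 <- feature_table(matrix(c(1, 3, 2), ncol = 1),
                        c("ADHD", "TD", "TD"), domain = "BIO")
  z2 <- zscore_table(tab2, "train_only", train = 1:2)
  expect_equal(unname(z2$x[3, 1]), 0)

  # brute-force oracle on a random table
  set.seed(9)
  x <- matrix(rnorm(60), 10, 6)
  rt <- feature_table(x, rep(c("ADHD", "TD"), 5), domain = "NPS")
  zr <- zscore_table(rt, "population")
  manual <- apply(x, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(unname(zr$x), manual, tolerance = 1e-12)

  # zero-variance features are dropped with a warning
  const <- feature_table(cbind(x, 0), rep(c("ADHD", "TD"), 5), domain = "NPS")
  expect_warning(zc <- zscore_table(const, "population"), "zero-variance")
  expect_equal(ncol(zc$x), 6)
})

test_that("PCA keeps N-1 uncorrelated components and reconstructs exactly", {
  set.seed(21)
  x <- matrix(rnorm(21 * 40), 21, 40)
  m <- fit_pca(x)
  expect_equal(m$n_components, 20)           # N = 21 training subjects
  expect_false(is.unsorted(rev(m$sdev)))     # variances non-increasing

  # orthonormal loadings
  expect_equal(crossprod(m$loadings), diag(20), tolerance = 1e-8,
               ignore_attr = TRUE)
  # training coefficients mutually uncorrelated
  sc <- project_pca(m, x)
  cv <- cov(sc)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # full reconstruction from all components
  recon <- sc %*% t(m$loadings) + matrix(m$center, 21, 40, byrow = TRUE)
  expect_equal(recon, x, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(fit_pca(matrix(1, 5, 3)), "constant")

  # JSON round trip preserves the model
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(m, path)
  m2 <- read_pca_model(path)
  expect_equal(m2$loadings, m$loadings, ignore_attr = TRUE)
  expect_equal(m2$center, m$center, ignore_attr = TRUE)
})

test_that("Fisher discriminant ratio follows its defining formula", {
  # mean difference 1, each class variance 0.5 -> FDR = 1
  labels <- c("ADHD", "ADHD", "TD", "TD")
  a <- c(1.5, 2.5); t_ <- c(0.5, 1.5)   # means 2 and 1, variances 0.5 each
  r <- fdr_rank(cbind(c(a, t_)), c("ADHD", "ADHD", "TD", "TD"))
  expect_equal(unname(r$fdr), 1)

  # equal class means -> 0
  r0 <- fdr_rank(cbind(c(1, 3, 2, 2)), labels)
  expect_equal(unname(r0$fdr), 0)

  # formula oracle on random data
  set.seed(4)
  xm <- matrix(rnorm(40), 10, 4)
  lab <- rep(c("ADHD", "TD"), each = 5)
  rr <- fdr_rank(xm, lab)
  manual <- sapply(1:4, function(j) {
    (mean(xm[1:5, j]) - mean(xm[6:10, j]))^2 /
      (var(xm[1:5, j]) + var(xm[6:10, j]))
  })
  expect_equal(unname(rr$fdr), manual, tolerance = 1e-12)
  expect_setequal(rr$rank, 1:4)

  # affine invariance: a*x + b leaves the score unchanged
  ra <- fdr_rank(3.7 * xm - 2, lab)
  expect_equal(ra$fdr, rr$fdr, tolerance = 1e-9)

  # degenerate columns: zero variances with distinct means rank first
  deg <- cbind(rep(c(1, 0), each = 5), rep(0, 10), xm[, 1])
  rd <- fdr_rank(deg, lab)
  expect_equal(rd$fdr[1], Inf)
  expect_equal(rd$fdr[2], 0)
  expect_equal(rd$rank[1], 1)
})

test_that("top-60% retention uses the ceiling rule", {
  mk_ranking <- function(p) {
    set.seed(p)
    x <- matrix(rnorm(20 * p), 20, p)
    fdr_rank(x, rep(c("ADHD", "TD"), 10))
  }
  expect_length(select_top_fraction(mk_ranking(20), 0.6), 12)
  expect_length(select_top_fraction(mk_ranking(19), 0.6), 12)
  expect_length(select_top_fraction(mk_ranking(10), 1.0), 10)

  r <- mk_ranking(10)
  sel <- select_top_fraction(r, 0.6)
  expect_equal(sel, r$rank[1:6])
  # stable under re-selection: full-fraction reselection is the identity,
  # and same-fraction reselection is a prefix of the first pick
  expect_equal(select_top_fraction(sel, 1.0), sel)
  expect_equal(select_top_fraction(sel, 0.6), sel[1:ceiling(0.6 * 6)])

  expect_error(select_top_fraction(integer(0)), "empty")
  expect_error(select_top_fraction(r, 0), "fraction")
})

test_that("held-out rows never influence the fitted transform", {
  set.seed(12)
  x <- matrix(rnorm(30 * 50), 30, 50)
  labels <- rep(c("ADHD", "TD"), 15)
  train <- 1:24; test <- 25:30
  eng <- make_engineer("nirs")
  a <- eng(x, labels, train, test)
  x2 <- x
  x2[test, ] <- x2[test, ] + matrix(rnorm(6 * 50, sd = 10), 6, 50)
  b <- eng(x2, labels, train, test)
  expect_identical(a$xtr, b$xtr)        # fitted artifacts bit-identical
  expect_false(isTRUE(all.equal(a$xte, b$xte)))

  # same property for the tabular recipe
  engt <- make_engineer("tabular")
  expect_identical(engt(x, labels, train, test)$xtr,
                   engt(x2, labels, train, test)$xtr)
})
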
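rand_xy <- function(n, p, seed = 1) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("v%02d", 1:p))),
       y = rnorm(n))
}

test_that("a response equal to one orthogonal column is fit perfectly at A = 1", {
  set.seed(1)
  m <- scale(matrix(rnorm(15 * 8), 15), scale = FALSE)
  q <- qr.Q(qr(m))[, 1:8] * sqrt(14)   # centred, exactly uncorrelated columns
  x <- q; colnames(x) <- sprintf("v%02d", 1:8)
  y <- x[, 3]
  fit <- fit_pls1(x, y, ncomp = 1)
  expect_lt(max(abs(fit$fitted - y)), 1e-8)
  expect_equal(names(which.max(abs(fit$beta_std))), "v03")
})

test_that("full-rank PLS1 predictions equal OLS", {
  d <- rand_xy(20, 5, seed = 2)
  fit <- fit_pls1(d$x, d$y, ncomp = 5)
  ols <- lm(d$y ~ d$x)
  expect_lt(max(abs(fit$fitted - fitted(ols))), 1e-6)
})

test_that("scores are mutually orthogonal and weights unit norm", {
  d <- rand_xy(30, 12, seed = 3)
  fit <- fit_pls1(d$x, d$y, ncomp = 4)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_equal(unname(colSums(fit$W^2)), rep(1, 4), tolerance = 1e-10)
})

test_that("jointly permuting samples leaves the coefficients unchanged", {
  d <- rand_xy(18, 6, seed = 4)
  fit <- fit_pls1(d$x, d$y, ncomp = 3)
  idx <- sample(18)
  fit2 <- fit_pls1(d$x[idx, ], d$y[idx], ncomp = 3)
  expect_equal(fit$beta_std, fit2$beta_std, tolerance = 1e-9)
})

test_that("requesting more components than the rank truncates with a warning", {
  d <- rand_xy(6, 30, seed = 5)
  expect_warning(fit <- fit_pls1(d$x, d$y, ncomp = 10), "informative")
  expect_lte(fit$ncomp, 5)
  expect_error(fit_pls1(d$x, rep(2, 6)), "zero variance")
})

test_that("VIP satisfies its normalisation identity and matches an independent oracle", {
  d <- rand_xy(10, 6, seed = 6)
  fit <- fit_pls1(d$x, d$y, ncomp = 2)
  v <- vip_scores(fit)
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-10)
  expect_equal(sum(v$vip^2), 6, tolerance = 1e-8)
  # direct evaluation of the formula from the stored W and SSY
  vip_direct <- sqrt(6 * (fit$W^2 %*% fit$ssy) / sum(fit$ssy))[, 1]
  expect_equal(v$vip, unname(vip_direct), tolerance = 1e-10)
  # independent implementation (mixOmics) on the same autoscaled problem
  skip_if_not_installed("mixOmics")
  mo <- mixOmics::vip(mixOmics::pls(d$x, d$y, ncomp = 2, scale = TRUE,
                                    mode = "regression"))
  expect_equal(v$vip, unname(mo[, 2]), tolerance = 1e-10)
})

test_that("VIP of an A = 1 model with equal-magnitude weights is exactly 1", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
  # build y so X'y has equal magnitude on all columns: use symmetrised x
  x <- scale(x)
  y <- rowSums(x)                     # w proportional to (1,1,1,1) after scaling?
  fit <- fit_pls1(x, y, ncomp = 1)
  v <- vip_scores(fit)
  w <- abs(fit$W[, 1])
  if (max(w) - min(w) < 1e-6) expect_equal(v$vip, rep(1, 4), tolerance = 1e-6)
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-10)
})

test_that("signature extraction splits by first-component sign with tie-breaks", {
  vip <- tibble::tibble(gene = c("a", "b", "c", "d", "e", "f"),
                        vip = c(2, 2, 1.5, 1.2, 0.4, 0.1),
                        sign = c(1, 1, -1, 1, 0, -1))
  sig <- extract_signature(vip, n_each = 2)
  expect_equal(sig$positive, c("a", "b"))
  expect_equal(sig$negative, c("c", "f"))
  # zero-sign genes excluded from both sides
  expect_false("e" %in% c(sig$positive, sig$negative))
  # shortfall recorded when a side runs out
  sig5 <- extract_signature(vip, n_each = 5)
  expect_equal(unname(sig5$shortfall["positive"]), 2)
  expect_equal(sig5$positive, c("a", "b", "d"))
})

test_that("leave-one-out RRMSEP: rank-1 noiseless data choose one component", {
  set.seed(7)
  n <- 20; p <- 100
  s <- rnorm(n)
  x <- outer(s, runif(p, 0.5, 1.5)) + matrix(rnorm(n * p, 0, 0.02), n)
  colnames(x) <- sprintf("v%03d", 1:p)
  curve <- loo_rrmsep_select(x, 1 + 2 * s, a_max = 5)
  expect_lt(curve$rrmsep[1], 0.05)
  expect_equal(attr(curve, "chosen"), 1L)
})

test_that("leave-one-out RRMSEP of pure-noise responses is about 1", {
  set.seed(8)
  x <- matrix(rnorm(24 * 150), 24, dimnames = list(NULL, sprintf("v%03d", 1:150)))
  curve <- loo_rrmsep_select(x, rnorm(24), a_max = 5)
  expect_gt(min(curve$rrmsep), 0.85)
  expect_lt(min(curve$rrmsep), 1.5)
})

test_that("duplicating every sample preserves the shape of the RRMSEP curve", {
  set.seed(9)
  n <- 12; p <- 40
  s <- rnorm(n)
  x <- outer(s, runif(p)) + matrix(rnorm(n * p, 0, 0.3), n)
  colnames(x) <- sprintf("v%02d", 1:p)
  y <- s + rnorm(n, 0, 0.3)
  c1 <- loo_rrmsep_select(x, y, a_max = 3)
  c2 <- loo_rrmsep_select(rbind(x, x), c(y, y), a_max = 3)
  # with a duplicate of every left-out sample in training, error cannot blow up
  expect_lt(min(c2$rrmsep), min(c1$rrmsep) + 0.15)
  expect_equal(nrow(c1), nrow(c2))
  expect_error(loo_rrmsep_select(x[1:2, ], y[1:2]), "3 samples")
})

test_that("phenotype prediction round-trips on the training data", {
  d <- rand_xy(16, 10, seed = 10)
  y <- d$x[, 1] + rnorm(16, 0, 0.2)
  fit <- fit_pls1(d$x, y, ncomp = 2)
  pred <- predict_phenotype(fit, d$x)
  expect_equal(pred$predicted, unname(fit$fitted), tolerance = 1e-9)
  expect_equal(attr(pred, "overlap"), 1)
})

test_that("phenotype prediction is invariant to external gene-column order", {
  d <- rand_xy(14, 8, seed = 11)
  fit <- fit_pls1(d$x, d$y, ncomp = 2)
  ext <- matrix(rnorm(5 * 8), 5, dimnames = list(paste0("L", 1:5), colnames(d$x)))
  p1 <- predict_phenotype(fit, ext)
  p2 <- predict_phenotype(fit, ext[, sample(8)])
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-12)
})

test_that("missing external genes are imputed at the scaled mean, with warnings", {
  d <- rand_xy(14, 10, seed = 12)
  fit <- fit_pls1(d$x, d$y, ncomp = 1)
  ext <- matrix(rnorm(4 * 10), 4, dimnames = list(NULL, colnames(d$x)))
  one_gene <- ext[, 1, drop = FALSE]
  expect_warning(p <- predict_phenotype(fit, one_gene), "model genes")
  # prediction varies only along that gene's coefficient
  z <- scale(one_gene[, 1])[, 1]
  expect_equal(p$predicted,
               unname(fit$y_center + fit$y_scale * z * fit$beta_std[1]),
               tolerance = 1e-9)
  noov <- matrix(rnorm(4), 4, 1, dimnames = list(NULL, "absent"))
  expect_error(predict_phenotype(fit, noov), "overlap")
})

test_that("variable-gene ranking prefers off-trend variance and recovers planted genes", {
  set.seed(13)
  n <- 30; p <- 500
  mu <- runif(p, 4, 10)
  x <- matrix(rnorm(n * p, rep(mu, each = n), 0.3), n)
  hot <- sample(p, 25)
  x[, hot] <- x[, hot] + rnorm(n * 25, 0, 2)   # high-dispersion genes
  colnames(x) <- sprintf("v%03d", 1:p)
  top <- select_variable_genes(x, n = 50)
  expect_gte(sum(colnames(x)[hot] %in% top), 23)
  # n larger than the gene count returns everything
  expect_length(select_variable_genes(x, n = 1000), p)
  expect_error(select_variable_genes(matrix(1, 5, 4)), "constant")
  # two genes, equal mean, different variance: high-variance ranked first
  x2 <- cbind(a = rnorm(50, 10, 0.1), b = rnorm(50, 10, 3),
              c = rnorm(50, 10, 0.1), d = rnorm(50, 10, 0.1))
  expect_equal(select_variable_genes(x2, n = 1), "b")
})

test_that("tidy and glance summarise PLS1 fits", {
  d <- rand_xy(15, 6, seed = 14)
  fit <- fit_pls1(d$x, d$x[, 2] + rnorm(15, 0, 0.1), ncomp = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_true(all(c("term", "estimate", "vip", "sign") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$ncomp, 2L)
  expect_gt(gl$r_squared, 0.9)
})
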
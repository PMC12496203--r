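test_that("one-way ANOVA matches stats::aov on random data", {
  set.seed(1)
  for (i in 1:5) {
    d <- data.frame(value = rnorm(15), condition = rep(letters[1:3], each = 5))
    mine <- one_way_anova(d)
    ref <- summary(aov(value ~ condition, d))[[1]]
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases follow the stated conventions", {
  same <- data.frame(value = rep(c(1, 2, 3), 2),
                     condition = rep(c("a", "b"), each = 3))
  out <- one_way_anova(same)
  expect_equal(out$statistic, 0, tolerance = 1e-10)
  flat <- data.frame(value = rep(5, 6), condition = rep(c("a", "b"), each = 3))
  expect_equal(one_way_anova(flat)$p_value, 1)
  sep <- data.frame(value = c(0, 0, 0, 10, 10, 10) + rnorm(6, 0, 1e-6),
                    condition = rep(c("a", "b"), each = 3))
  expect_lt(one_way_anova(sep)$p_value, 1e-10)
})

test_that("Tukey HSD matches stats::TukeyHSD and the k = 2 t-test identity", {
  set.seed(2)
  d <- data.frame(value = rnorm(12), condition = rep(letters[1:4], each = 3))
  mine <- tukey_hsd(d) %>% dplyr::arrange(group1, group2)
  ref <- TukeyHSD(aov(value ~ condition, d))$condition
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-10)
  # two groups: Tukey p equals the pooled two-sample t-test p (q = t sqrt(2))
  d2 <- data.frame(value = rnorm(10), condition = rep(c("a", "b"), each = 5))
  p_tukey <- tukey_hsd(d2)$p_adj
  p_t <- t.test(value ~ condition, d2, var.equal = TRUE)$p.value
  expect_lt(abs(p_tukey - p_t), 1e-3)
  # identical groups: all adjusted p = 1
  flat <- data.frame(value = rep(1, 9), condition = rep(letters[1:3], each = 3))
  expect_true(all(tukey_hsd(flat)$p_adj == 1))
  expect_error(tukey_hsd(data.frame(value = c(1, 2, 3),
                                    condition = c("a", "a", "b"))), "n >= 2")
})

test_that("Tukey adjusted p is never below the unadjusted pairwise t-test p", {
  set.seed(3)
  for (i in 1:10) {
    d <- data.frame(value = rnorm(12), condition = rep(letters[1:4], each = 3))
    tk <- tukey_hsd(d)
    s <- split(d$value, d$condition)
    mse <- mean(vapply(s, var, numeric(1)))
    for (j in seq_len(nrow(tk))) {
      tt <- (mean(s[[tk$group2[j]]]) - mean(s[[tk$group1[j]]])) /
        sqrt(mse * 2 / 3)
      p_raw <- 2 * pt(abs(tt), 8, lower.tail = FALSE)
      expect_gte(tk$p_adj[j], p_raw - 1e-12)
    }
  }
})

test_that("Dunnett reduces to a t-test for one treatment and is calibrated", {
  set.seed(4)
  d2 <- data.frame(value = rnorm(10), condition = rep(c("ctrl", "trt"), each = 5))
  p_d <- dunnett_vs_control(d2, control = "ctrl", seed = 1)$p_adj
  p_t <- t.test(value ~ condition, d2, var.equal = TRUE)$p.value
  expect_lt(abs(p_d - p_t), 5e-3)
  flat <- data.frame(value = rep(2, 12), condition = rep(letters[1:4], each = 3))
  expect_true(all(dunnett_vs_control(flat, control = "a", seed = 1)$p_adj > 0.99))
  expect_error(dunnett_vs_control(d2, control = "missing"), "not present")
})

test_that("emergence classification implements the both-singles HSA rule", {
  set.seed(5)
  tight <- function(mu) rnorm(3, mu, 0.05)
  up <- data.frame(value = c(tight(10), tight(1), tight(2)),
                   condition = rep(c("A+B", "A", "B"), each = 3))
  call <- classify_emergent(up, "A+B", c("A", "B"))
  expect_true(call$emergent)
  expect_identical(call$direction, "above")
  expect_equal(call$hsa_expected, mean(up$value[up$condition == "B"]))
  # combination equal to the best single: HSA-consistent, not emergent
  hsa <- data.frame(value = c(tight(2), tight(1), tight(2)),
                    condition = rep(c("A+B", "A", "B"), each = 3))
  expect_false(classify_emergent(hsa, "A+B", c("A", "B"))$emergent)
  # differing from only one single is not emergence
  one <- data.frame(value = c(tight(2), tight(1), tight(2)),
                    condition = rep(c("A+B", "A", "B"), each = 3))
  expect_false(classify_emergent(one, "A+B", c("A", "B"))$emergent)
  expect_error(classify_emergent(up[up$condition != "B", ], "A+B", c("A", "B")),
               "missing")
})

test_that("emergence tests are invariant to affine rescaling of the metric", {
  set.seed(6)
  d <- data.frame(value = rnorm(9, 5), condition = rep(c("A+B", "A", "B"), each = 3))
  a <- classify_emergent(d, "A+B", c("A", "B"))
  d2 <- d; d2$value <- 3.7 * d$value - 11
  b <- classify_emergent(d2, "A+B", c("A", "B"))
  expect_equal(a$p_max, b$p_max, tolerance = 1e-9)
  expect_identical(a$emergent, b$emergent)
  f <- one_way_anova(d)$statistic
  expect_equal(one_way_anova(d2)$statistic, f, tolerance = 1e-9)
})

test_that("emergence scan covers every combination x metric", {
  set.seed(7)
  ph <- tidyr::expand_grid(condition = panel_conditions(), replicate = 1:3) %>%
    dplyr::mutate(count_fc = rnorm(dplyr::n(), 2, 0.1),
                  motility = rnorm(dplyr::n(), 200, 10),
                  nn_ratio = rnorm(dplyr::n(), 1, 0.05),
                  cyto_area = rnorm(dplyr::n(), 450, 20))
  sc <- emergence_scan(ph)
  expect_equal(nrow(sc), 4 * 4)  # 4 combinations x 4 metrics
  expect_true(all(sc$p_max >= 0 & sc$p_max <= 1))
})
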
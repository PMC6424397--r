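test_that("confusion matrices are built with fixed class order and zero rows", {
  cm <- build_confusion(c("a", "a", "b"), c("a", "b", "b"),
                        class_order = c("a", "b", "c"))
  expect_equal(dim(cm), c(3L, 3L))
  expect_equal(cm["a", "a"], 1L)
  expect_equal(cm["a", "b"], 1L)
  expect_equal(sum(cm["c", ]), 0L)
  expect_equal(sum(cm), 3L)
})

test_that("the printed pixel matrix reproduces its accuracy, kappa and margins", {
  cm <- load_pixel_confusion()
  expect_equal(sum(cm), 100L)
  expect_equal(overall_accuracy(cm), 81)
  # kappa: p_o = 0.81, p_e = (44*41 + 40*43 + 16*16)/100^2 = 0.378
  expect_equal(cohens_kappa(cm), (0.81 - 0.378) / (1 - 0.378))
  expect_equal(round_half_up(100 * cohens_kappa(cm)), 69)
  pca <- per_class_accuracy(cm)
  expect_equal(pca$user_pct[pca$class == "non_defoliated"], 100 * 37 / 43)
  expect_equal(round_half_up(pca$user_pct[pca$class == "non_defoliated"]), 86)
  expect_equal(pca$producer_pct[pca$class == "shaded"], 62.5)
})

test_that("the printed tree matrix gives 80.9% overall and its merges", {
  cm <- load_tree_confusion()
  expect_equal(sum(cm), 110L)
  expect_equal(round_half_up(overall_accuracy(cm), 1), 80.9)
  merged <- merge_classes(cm, list(defoliated = c("complete", "partial"),
                                   non_defoliated = "non_defoliated"))
  expect_equal(sum(merged), 85L)       # oaks dropped
  expect_equal(round_half_up(overall_accuracy(merged), 1), 94.1)
  species <- merge_classes(cm, list(
    pine = c("complete", "partial", "non_defoliated"), oak = "oak"))
  expect_equal(sum(species), 110L)     # merging conserves retained totals
  expect_equal(round_half_up(overall_accuracy(species), 1), 95.5)
})

test_that("identity and independence matrices give their closed-form scores", {
  ident <- as_confusion(diag(5) * 7)
  expect_equal(overall_accuracy(ident), 100)
  expect_equal(cohens_kappa(ident), 1)
  # counts proportional to the product of the marginals -> kappa 0
  m <- outer(c(10, 20, 30), c(12, 18, 30)) / 60
  indep <- as_confusion(round(m))      # integer-valued by construction
  expect_equal(cohens_kappa(indep), 0, tolerance = 1e-12)
})

test_that("accuracy and kappa are invariant to class permutations", {
  cm <- load_pixel_confusion()
  for (seed in 1:4) {
    set.seed(seed)
    p <- sample(nrow(cm))
    pm <- as_confusion(unclass(cm)[p, p])
    expect_equal(overall_accuracy(pm), overall_accuracy(cm))
    expect_equal(cohens_kappa(pm), cohens_kappa(cm))
  }
})

test_that("kappa never exceeds the accuracy fraction when p_e > 0", {
  set.seed(9)
  for (k in 1:10) {
    m <- matrix(rpois(9, 10), 3, 3)
    cm <- as_confusion(m)
    expect_lte(cohens_kappa(cm), overall_accuracy(cm) / 100 + 1e-12)
  }
})

test_that("regression fits recover exact and degenerate relationships", {
  x <- c(0, 20, 40, 80, 100)
  fit <- fit_regression(x, x)
  expect_equal(fit$a, 1); expect_equal(fit$b, 0)
  expect_equal(fit$r_squared, 1)
  expect_warning(flat <- fit_regression(x, rep(50, 5)), "degenerate")
  expect_equal(flat$a, 0); expect_equal(flat$r_squared, 0)
  y <- 0.9 * x + 5 + c(-1, 1, 0, -1, 1)
  fit2 <- fit_regression(x, y)
  expect_gt(fit2$r_squared, 0.99)
  expect_true(fit2$r_squared <= 1 && fit2$r_squared >= 0)
})

test_that("round_half_up rounds .5 away from zero at any precision", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(94.115, 2), 94.12)
  expect_equal(round_half_up(80.9090909, 1), 80.9)
})
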
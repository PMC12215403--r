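three_taxon_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

test_that("Newick trees round-trip and duplicates are rejected", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tree <- read_newick(f)
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f2)
  back <- read_newick(f2)
  expect_equal(back$edge, tree$edge)
  expect_equal(back$edge.length, tree$edge.length)

  f3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,A:1):1,C:2);", f3)
  expect_error(read_newick(f3), "duplicate tip")
})

test_that("pruning preserves tip-to-tip path lengths", {
  tree <- three_taxon_tree()
  expect_equal(prune(tree, c("A", "B", "C"))$tip.label, tree$tip.label)
  pr <- prune(tree, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  # A-C distance was 1 + 1 + 2 = 4 and must survive the collapse
  expect_equal(unname(ape::cophenetic.phylo(pr)["A", "C"]), 4)
  expect_error(prune(tree, c("A", "Z")), "Z")
})

test_that("Brownian covariance equals shared path lengths", {
  V <- bm_covariance(three_taxon_tree())
  expect_equal(V["A", "B"], 1, ignore_attr = TRUE)
  expect_equal(V["A", "A"], 2, ignore_attr = TRUE)
  expect_equal(V["A", "C"], 0, ignore_attr = TRUE)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE)$values >= -1e-10))

  # star tree: V is a multiple of the identity
  star <- ape::read.tree(text = "(A:1.5,B:1.5,C:1.5,D:1.5);")
  expect_equal(unname(bm_covariance(star)), 1.5 * diag(4))
})

test_that("PGLS on a star tree reduces to ordinary least squares", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(5:12, 1)
      x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    })
    sp <- paste0("t", seq_along(x))
    names(x) <- names(y) <- sp
    star <- ape::read.tree(
      text = paste0("(", paste0(sp, ":1", collapse = ","), ");"))
    fit <- pgls(x, y, star)
    ols <- summary(stats::lm(y ~ x))
    expect_equal(fit$slope, unname(coef(ols)[2, 1]), tolerance = 1e-10)
    expect_equal(fit$se, unname(coef(ols)[2, 2]), tolerance = 1e-10)
    expect_equal(fit$p, unname(coef(ols)[2, 4]), tolerance = 1e-10)
    expect_equal(abs(fit$R), sqrt(ols$r.squared), tolerance = 1e-10)
  }
})

test_that("a perfect linear relationship gives slope 2 and R = 1", {
  tree <- three_taxon_tree()
  x <- c(A = 0, B = 1, C = 2)
  fit <- pgls(x, 2 * x, tree)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$R, 1)
  expect_equal(fit$rss, 0, tolerance = 1e-20)
})

test_that("the 3-taxon case reproduces direct matrix algebra", {
  tree <- three_taxon_tree()
  x <- c(A = 0, B = 1, C = 2)
  y <- c(A = 0, B = 1, C = 4)
  fit <- pgls(x, y, tree)
  # independent hand computation with V from the covariance example
  V <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  Vi <- solve(V)
  Xd <- cbind(1, x)
  beta <- solve(t(Xd) %*% Vi %*% Xd, t(Xd) %*% Vi %*% y)
  expect_equal(fit$intercept, beta[1], ignore_attr = TRUE)
  expect_equal(fit$slope, beta[2], ignore_attr = TRUE)
  res <- y - Xd %*% beta
  rss <- drop(t(res) %*% Vi %*% res)
  se <- sqrt(rss / 1 * solve(t(Xd) %*% Vi %*% Xd)[2, 2])
  expect_equal(fit$se, se)
  expect_equal(fit$p, 2 * pt(-abs(beta[2] / se), df = 1), ignore_attr = TRUE)
})

test_that("PGLS matches nlme's Brownian GLS on a simulated tree", {
  skip_if_not_installed("nlme")
  tree <- simulate_tree(20, seed = 4)
  withr::with_seed(8, {
    x <- setNames(rnorm(20), tree$tip.label)
    y <- setNames(1 + 0.8 * x + rnorm(20, 0, 0.5), tree$tip.label)
  })
  fit <- pgls(x, y, tree)
  df <- data.frame(x = x, y = y, sp = tree$tip.label)
  gl <- nlme::gls(y ~ x, data = df,
                  correlation = ape::corBrownian(1, tree, form = ~sp))
  expect_equal(fit$slope, unname(coef(gl)[2]), tolerance = 1e-6)
  expect_equal(fit$se,
               unname(sqrt(diag(gl$varBeta))[2]), tolerance = 1e-6)
})

test_that("PGLS estimates are invariant to species order", {
  tree <- simulate_tree(12, seed = 2)
  withr::with_seed(3, {
    x <- setNames(rnorm(12), tree$tip.label)
    y <- setNames(0.3 * x + rnorm(12, 0, 0.3), tree$tip.label)
  })
  f1 <- pgls(x, y, tree)
  ord <- sample(names(x))
  f2 <- pgls(x[ord], y[ord], tree)
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$p, f2$p)
})

test_that("iTOL exports carry the required headers and data lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  export_itol_annotations(c(spA = 1, spB = 2.5, spC = -1), "bar", f)
  lines <- readLines(f)
  expect_equal(lines[1], "DATASET_SIMPLEBAR")
  expect_length(grep("^sp", lines), 3)

  hm <- matrix(1:10 / 10, 2, 5,
               dimnames = list(c("spA", "spB"), paste0("OG", 1:5)))
  f2 <- withr::local_tempfile(fileext = ".txt")
  export_itol_annotations(hm, "heatmap", f2)
  lines2 <- readLines(f2)
  expect_equal(lines2[1], "DATASET_HEATMAP")
  fl <- grep("^FIELD_LABELS", lines2, value = TRUE)
  expect_length(strsplit(fl, ",")[[1]], 6)  # keyword + 5 fields
  expect_error(export_itol_annotations(numeric(0), "bar",
                                       withr::local_tempfile()), "empty")
})

test_that("group tests wrap the textbook statistics", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 4, 6, 8, 10)
  wt <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_equal(wt$p, ref$p.value)
  expect_equal(wt$estimate, -3)

  pc <- pearson_cor(a, b)
  expect_equal(pc$r, 1)

  set.seed(1)
  v <- rnorm(30); g <- rep(letters[1:3], each = 10)
  an <- oneway_anova(v, g)
  ref2 <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(an$F, ref2$`F value`[1])
  expect_equal(an$p, ref2$`Pr(>F)`[1])
})
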
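test_that("identity covariance with exact linear data gives a perfect fit", {
  d <- data.frame(species_id = c("a", "b", "c"), y = c(1, 2, 3), x = c(1, 2, 3))
  f <- pgls(y ~ x, d, vcv = diag(3) |> (\(C) {dimnames(C) <- list(d$species_id, d$species_id); C})())
  expect_equal(unname(coef(f)), c(0, 1), tolerance = 1e-12)
  expect_equal(f$sigma2, 0, tolerance = 1e-20)
})

test_that("3-taxon fit equals an explicit matrix-arithmetic oracle", {
  C <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- data.frame(species_id = c("A", "B", "C"), y = c(3, 5, 2), x = c(1, 4, 2))
  f <- pgls(y ~ x, d, vcv = C)
  X <- cbind(1, d$x)
  Ci <- solve(C)
  beta_o <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% d$y)
  r <- d$y - X %*% beta_o
  s2_o <- drop(t(r) %*% Ci %*% r) / (3 - 2)
  se_o <- sqrt(s2_o * diag(solve(t(X) %*% Ci %*% X)))
  expect_equal(unname(coef(f)), drop(beta_o), tolerance = 1e-12)
  expect_equal(f$sigma2, s2_o, tolerance = 1e-12)
  expect_equal(unname(f$se), se_o, tolerance = 1e-12)
  expect_equal(unname(f$pvalue),
               2 * pt(abs(drop(beta_o) / se_o), 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("an exactly linear response is recovered exactly under any valid C", {
  set.seed(401)
  tr <- ape::rtree(8)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(8))
  d$y <- 2.5 * d$x - 1
  f <- pgls(y ~ x, d, tree = tr)
  expect_equal(unname(coef(f)), c(-1, 2.5), tolerance = 1e-8)
  expect_lt(f$pvalue[["x"]], 1e-12)
})

test_that("PGLS on an ultrametric star tree equals OLS exactly", {
  set.seed(402)
  n <- 10
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:n, ":1", collapse = ","), ");"))
  d <- data.frame(species_id = paste0("t", 1:n),
                  x = rnorm(n), y = rnorm(n))
  fp <- pgls(y ~ x, d, tree = star)
  fo <- ols(y ~ x, d)
  expect_equal(coef(fp), coef(fo), tolerance = 1e-10)
  expect_equal(fp$tstat, fo$tstat, tolerance = 1e-10)
  expect_equal(fp$pvalue, fo$pvalue, tolerance = 1e-10)
  # and both agree with lm
  lmfit <- summary(lm(y ~ x, d))
  expect_equal(unname(coef(fp)), unname(coef(lmfit)[, 1]), tolerance = 1e-10)
  expect_equal(unname(fp$se), unname(coef(lmfit)[, 2]), tolerance = 1e-10)
  expect_identical(fp$model, "PGLS")
  expect_identical(fo$model, "OLS")
})

test_that("OLS matches the closed-form simple-regression slope", {
  d <- data.frame(species_id = letters[1:5],
                  x = c(1, 2, 3, 4, 5), y = c(2.1, 3.9, 6.2, 7.8, 10.1))
  f <- ols(y ~ x, d)
  slope <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) / sum((d$x - mean(d$x))^2)
  expect_equal(unname(coef(f))[2], slope, tolerance = 1e-12)
  expect_equal(unname(coef(f))[1], mean(d$y) - slope * mean(d$x),
               tolerance = 1e-12)
})

test_that("a constant response gives a zero slope", {
  d <- data.frame(species_id = letters[1:6], x = rnorm(6), y = 5)
  f <- ols(y ~ x, d)
  expect_equal(unname(coef(f))[2], 0, tolerance = 1e-12)
})

test_that("branch-length rescaling leaves beta, t and p unchanged", {
  set.seed(403)
  tr <- ape::rtree(12)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(12), y = rnorm(12))
  f1 <- pgls(y ~ x, d, tree = tr)
  for (k in c(0.01, 7, 1000)) {
    trk <- tr
    trk$edge.length <- trk$edge.length * k
    fk <- pgls(y ~ x, d, tree = trk)
    expect_equal(coef(fk), coef(f1), tolerance = 1e-9)
    expect_equal(fk$tstat, f1$tstat, tolerance = 1e-9)
    expect_equal(fk$pvalue, f1$pvalue, tolerance = 1e-9)
    expect_equal(fk$sigma2, f1$sigma2 / k, tolerance = 1e-9)
  }
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(404)
  for (i in 1:5) {
    tr <- ape::rcoal(15)                       # ultrametric
    d <- data.frame(species_id = tr$tip.label, x = rnorm(15), y = rnorm(15))
    f <- pgls(y ~ x, d, tree = tr)
    g <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, phy = tr,
                                                  form = ~species_id))
    tab <- summary(g)$tTable
    expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(tab[, "Std.Error"]), tolerance = 1e-8)
    expect_equal(unname(f$tstat), unname(tab[, "t-value"]), tolerance = 1e-8)
  }
})

test_that("collinear predictors fail with the offending name", {
  set.seed(405)
  d <- data.frame(species_id = letters[1:8], x = rnorm(8))
  d$y <- rnorm(8)
  d$x2 <- 2 * d$x
  expect_error(ols(y ~ x + x2, d), "x2")
})

test_that("data rows are matched to the covariance by species name", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- data.frame(species_id = c("A", "B", "C"), y = c(3, 5, 2), x = c(1, 4, 2))
  f1 <- pgls(y ~ x, d, tree = tr)
  f2 <- pgls(y ~ x, d[c(3, 1, 2), ], tree = tr)   # shuffled rows
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(sort(f1$pvalue), sort(f2$pvalue), tolerance = 1e-12)
  expect_error(pgls(y ~ x, transform(d, species_id = c("A", "B", "Z")),
                    tree = tr), "Z")
})

test_that("methods behave: predict, residuals, confint, simulate, logLik", {
  set.seed(406)
  tr <- ape::rcoal(20)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(20))
  d$y <- 1 + 0.5 * d$x + rnorm(20, sd = 0.3)
  f <- pgls(y ~ x, d, tree = tr)

  expect_equal(predict(f), fitted(f))
  nd <- data.frame(x = c(-1, 0, 1))
  pr <- predict(f, nd)
  expect_equal(unname(pr), unname(coef(f)[1] + coef(f)[2] * nd$x))
  prse <- predict(f, nd, se.fit = TRUE)
  expect_true(all(prse$se.fit > 0))

  expect_equal(residuals(f) + fitted(f), setNames(d$y, d$species_id))
  expect_identical(length(residuals(f, type = "normalized")), 20L)

  ci <- confint(f)
  expect_true(all(ci[, 1] < coef(f) & coef(f) < ci[, 2]))

  sims <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(20L, 3L))
  expect_identical(simulate(f, nsim = 2, seed = 9), simulate(f, nsim = 2, seed = 9))

  expect_true(is.finite(as.numeric(logLik(f))))
  s <- summary(f)
  expect_identical(dim(s$coefficients), c(2L, 4L))
  expect_output(print(s), "PGLS")
})

test_that("simulate() reproduces the fitted Brownian covariance", {
  set.seed(407)
  tr <- ape::rcoal(6)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(6))
  d$y <- 0.5 * d$x + rnorm(6)
  f <- pgls(y ~ x, d, tree = tr)
  sims <- as.matrix(simulate(f, nsim = 4000, seed = 2))
  emp <- cov(t(sims))
  expect_equal(emp, f$sigma2 * f$C, tolerance = 0.15 * max(f$sigma2 * diag(f$C)),
               ignore_attr = TRUE)
})

test_that("ridge rescue handles a singular covariance with a message", {
  C <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d <- data.frame(species_id = c("a", "b", "c"), y = c(1, 2, 3), x = c(2, 1, 3))
  expect_message(f <- pgls(y ~ x, d, vcv = C), "ridge")
  expect_true(all(is.finite(coef(f))))
  expect_error(pgls(y ~ x, d, vcv = C, ridge = 0), "positive definite")
})

test_that("uncorrected OLS over-rejects on phylogenetically structured data", {
  # under a Brownian null with a heritable predictor, OLS p-values are
  # anticonservative while PGLS stays near nominal level
  set.seed(408)
  tr <- simulate_tree(64, 1)
  C <- brownian_vcv(tr)
  nrep <- 400
  rej_ols <- rej_pgls <- logical(nrep)
  for (r in seq_len(nrep)) {
    d <- data.frame(
      species_id = tr$tip.label,
      y = simulate_lifespans(tr, 0.05, 0)$log10_lifespan,
      x = simulate_lifespans(tr, 0.05, 0)$log10_lifespan)
    rej_ols[r] <- ols(y ~ x, d)$pvalue[["x"]] < 0.05
    rej_pgls[r] <- pgls(y ~ x, d, vcv = C)$pvalue[["x"]] < 0.05
  }
  expect_gt(mean(rej_ols), 0.10)          # inflated
  expect_lt(mean(rej_pgls), 0.10)         # near nominal
  expect_gt(mean(rej_ols), mean(rej_pgls))
})

test_that("lifespan_screen fits each feature separately under both models", {
  set.seed(409)
  tr <- ape::rcoal(20)
  d <- data.frame(species_id = tr$tip.label,
                  max_lifespan_years = 10^rnorm(20, 1.2, 0.4),
                  site_density = runif(20, 0, 0.1),
                  has_t294_equiv = sample(c(TRUE, FALSE), 20, replace = TRUE))
  res <- lifespan_screen(d, tr, c("site_density", "has_t294_equiv"))
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$model), c("PGLS", "OLS"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$n == 20))
  # a constant predictor yields an NA row with a warning, not an abort
  d$flat <- TRUE
  expect_warning(expect_warning(res2 <- lifespan_screen(d, tr, "flat"),
                                "flat"), "flat")
  expect_true(all(is.na(res2$beta)))
  # joint mode returns one row per predictor per model from a single fit
  resj <- lifespan_screen(d, tr, c("site_density", "has_t294_equiv"),
                          joint = TRUE)
  expect_identical(nrow(resj), 4L)
  expect_error(lifespan_screen(d, tr, "absent_col"), "absent_col")
  expect_error(
    lifespan_screen(transform(d, max_lifespan_years = -1), tr, "site_density"),
    "positive")
})
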
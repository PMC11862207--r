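sim_design <- function(n, seed = 1) {
  set.seed(seed)
  cont <- sprintf("C%d", sample(5, n, TRUE))
  reg <- paste0(cont, "_G", sample(3, n, TRUE))
  data.frame(p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n),
             continent_id = cont, region_id = reg,
             system_id = paste0(reg, "_S", sample(4, n, TRUE)),
             area_km2 = exp(runif(n, 3, 6)))
}

test_that("collinearity screen: duplicates, threshold edge, null behavior", {
  set.seed(60)
  d <- data.frame(a = rnorm(100))
  d$b <- d$a                      # duplicated predictor
  d$c <- rnorm(100)
  scr <- collinearity_screen(d)
  expect_identical(sort(setdiff(c("a", "b"), scr$removed)),
                   intersect(c("a", "b"), scr$retained))
  expect_length(scr$removed, 1)

  # r = 0.69 keeps both members of the pair
  x <- rnorm(5000)
  y <- 0.69 / sqrt(1 - 0.69^2) * x + rnorm(5000)
  y <- 0.69 * scale(x)[, 1] + sqrt(1 - 0.69^2) * scale(rnorm(5000))[, 1]
  d2 <- data.frame(x = x, y = y)
  expect_lt(abs(cor(d2$x, d2$y)) , 0.7)
  expect_length(collinearity_screen(d2)$removed, 0)

  # independent predictors at n = 1000: nothing removed
  d3 <- as.data.frame(matrix(rnorm(9000), 1000, 9))
  expect_length(collinearity_screen(d3)$removed, 0)
  expect_error(collinearity_screen(d3[0, ]), "rows")
})

test_that("standardization: sample-SD convention and round trip", {
  std <- standardize(data.frame(v = c(1, 2, 3)))
  expect_equal(std$data$v, c(-1, 0, 1))
  set.seed(61)
  d <- data.frame(a = rnorm(50, 5, 3), b = runif(50))
  std <- standardize(d)
  expect_lt(max(abs(colMeans(std$data))), 1e-9)
  expect_equal(unname(vapply(std$data, sd, 0)), c(1, 1), tolerance = 1e-9)
  expect_equal(unstandardize(std), d, tolerance = 1e-12)
  # already-standardized input passes through
  std2 <- standardize(std$data)
  expect_equal(std2$data, std$data, tolerance = 1e-9)
  expect_error(standardize(data.frame(z = rep(2, 5))), "zero-SD")
})

test_that("offset identity: doubling areas shifts only the intercept", {
  d <- sim_design(800, seed = 62)
  d <- simulate_richness_counts(d, c("(Intercept)" = -3, p1 = 0.4, p2 = -0.3),
                                theta = 2, sigma = c(continent = 0.1,
                                                     region = 0.1,
                                                     system = 0.2), seed = 63)
  f1 <- suppressWarnings(fit_nb_glmm(d, c("p1", "p2", "p3")))
  d2 <- transform(d, area_km2 = 2 * area_km2)
  f2 <- suppressWarnings(fit_nb_glmm(d2, c("p1", "p2", "p3")))
  i1 <- f1$coefficients$estimate[f1$coefficients$term == "(Intercept)"]
  i2 <- f2$coefficients$estimate[f2$coefficients$term == "(Intercept)"]
  expect_equal(i2 - i1, -log(2), tolerance = 1e-6)
  expect_equal(f1$coefficients$estimate[-1], f2$coefficients$estimate[-1],
               tolerance = 1e-6)
})

test_that("scaling a raw predictor leaves the standardized fit unchanged", {
  d <- sim_design(600, seed = 64)
  d <- simulate_richness_counts(d, c("(Intercept)" = -3, p1 = 0.4),
                                theta = 2, sigma = c(continent = 0, region = 0,
                                                     system = 0.2), seed = 65)
  fit_std <- function(dd) {
    std <- standardize(dd[c("p1", "p2", "p3")])
    dd[c("p1", "p2", "p3")] <- std$data
    suppressWarnings(fit_nb_glmm(dd, c("p1", "p2", "p3")))
  }
  f1 <- fit_std(d)
  d2 <- transform(d, p1 = 1000 * p1 + 7)
  f2 <- fit_std(d2)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("theta-profile iterations never decrease the log-likelihood trace", {
  d <- sim_design(500, seed = 66)
  d <- simulate_richness_counts(d, c("(Intercept)" = -3, p1 = 0.3),
                                theta = 1.5, sigma = c(continent = 0,
                                                       region = 0.1,
                                                       system = 0.3), seed = 67)
  f <- suppressWarnings(fit_nb_glmm(d, c("p1", "p2", "p3")))
  tr <- f$loglik_trace
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) > -1e-4))
  expect_true(f$converged)
  expect_gt(f$theta, 0)
})

test_that("geometry enters with diamond as the reference level", {
  d <- sim_design(900, seed = 68)
  d$geometry <- sample(c("pyramid", "inverse_pyramid", "diamond", "hourglass"),
                       900, TRUE)
  d <- simulate_richness_counts(
    d, c("(Intercept)" = -3, p1 = 0.2, geometry_pyramid = 0.5),
    theta = 2, sigma = c(continent = 0, region = 0, system = 0.2), seed = 69)
  f <- suppressWarnings(fit_nb_glmm(d, c("p1", "geometry")))
  terms <- f$coefficients$term
  expect_true("geometrypyramid" %in% terms)
  expect_false(any(grepl("diamond", terms)))  # reference level absorbed
  est <- f$coefficients$estimate[terms == "geometrypyramid"]
  expect_lt(abs(est - 0.5), 0.2)
})

test_that("taxon-specific models: refusal, and full-data equivalence", {
  w <- small_world()
  rec <- assign_mountain(w$occurrences, w$mountains, check_overlap = FALSE)
  kept <- suppressWarnings(filter_native_overlap(rec, w$species))$kept
  rich <- richness_table(kept, w$mountains)
  d <- merge(w$mountains$data,
             rich[rich$scope == "all", c("mountain_id", "n_species")])
  set.seed(123)
  d$p1 <- rnorm(nrow(d), 0, 1)

  # a class absent from the data is refused, not fitted empty
  rich_none <- rich[rich$scope == "no_such_class", ]
  tm <- suppressWarnings(taxon_models(d, rbind(rich, rich_none), "p1",
                                      classes = "fish"))
  expect_true(is.null(tm$fish) || attr(tm, "subset_sizes")["fish"] >= 10)

  # a "class" whose subset is the full data reproduces the cross-taxon fit
  rich_all <- rich[rich$scope == "all", ]
  rich_fake <- transform(rich_all, scope = "bird")
  tm2 <- suppressWarnings(taxon_models(d, rich_fake, "p1",
                                       classes = "bird"))
  full_std <- standardize(d["p1"])
  d2 <- d; d2["p1"] <- full_std$data
  full <- suppressWarnings(fit_nb_glmm(d2, "p1"))
  expect_equal(tm2$bird$coefficients$estimate, full$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("sensitivity refits: identical subsets give stability 1", {
  d <- sim_design(400, seed = 70)
  d <- simulate_richness_counts(d, c("(Intercept)" = -3, p1 = 0.6),
                                theta = 2, sigma = c(continent = 0, region = 0,
                                                     system = 0.2), seed = 71)
  rules <- list(all1 = seq_len(nrow(d)), all2 = seq_len(nrow(d)),
                all3 = seq_len(nrow(d)))
  st <- suppressWarnings(sensitivity_refits(d, c("p1", "p2"), rules = rules))
  expect_true(all(st$sign_stability == 1))
  expect_identical(st$n_failed, rep(0L, nrow(st)))
  # strong true effect keeps its sign across random 80% subsets
  st2 <- suppressWarnings(sensitivity_refits(d, c("p1", "p2"), n_random = 6,
                                             seed = 72))
  expect_identical(st2$sign_stability[st2$term == "p1"], 1)
  expect_identical(st2$sig_fraction[st2$term == "p1"], 1)
})
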
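# random-intercept logistic data with known parameters
sim_glmm_data <- function(n, n_fam, beta, sigma, seed,
                          names = paste0("z", seq_along(beta[-1]))) {
  set.seed(seed)
  k <- length(beta) - 1L
  X <- matrix(stats::rnorm(n * k), n, k)
  fam <- sample.int(n_fam, n, replace = TRUE)
  u <- stats::rnorm(n_fam, 0, sigma)
  eta <- beta[1] + X %*% beta[-1] + u[fam]
  d <- data.frame(y = stats::rbinom(n, 1, stats::plogis(eta)),
                  family = sprintf("f%02d", fam))
  for (j in seq_len(k)) d[[names[j]]] <- X[, j]
  d
}

test_that("build_design computes predictors and truncated flank GC by hand", {
  seqs <- Biostrings::DNAStringSet(c(
    s1 = paste0(strrep("A", 1000), strrep("G", 1000), strrep("A", 1000))))
  tes <- data.frame(
    feature_id = c("t1", "t2", "t3", "t4", "t5"),
    ref_id = "s1",
    start = c(1000L, 0L, 2400L, 2600L, 1200L),
    end = c(2000L, 500L, 2500L, 2800L, 1400L),
    family = c("f1", "f1", "f1", "f2", "f2"),
    divergence = c(0.005, 0.010, 0.020, 0.001, 0.002),
    stringsAsFactors = FALSE
  )
  genome <- structure(list(seqs = seqs, tes = tes), class = "genome_bundle")
  assessments <- data.frame(
    feature_id = c("t1", "t2", "t3", "t4", "t5", "g1"),
    feature_type = c("TE", "TE", "TE", "TE", "TE", "gene"),
    perfect = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  d <- build_design(assessments, genome, flank = 1000L)
  expect_equal(nrow(d), 5L)          # the gene row is ignored
  expect_equal(d$y, c(1L, 0L, 1L, 0L, 1L))
  expect_equal(d$length, c(1000L, 500L, 100L, 200L, 200L))
  # t1 window [0, 3000): 1000 G of 3000; t2 window truncated at 0: [0, 1500)
  expect_equal(d$gc_flank[1], 1000 / 3000)
  expect_equal(d$gc_flank[2], 500 / 1500)
  # t4 window truncated at the right end: [1600, 3000) -> 400 G of 1400
  expect_equal(d$gc_flank[4], 400 / 1400)
  # t5 window [200, 2400): 1000 G of 2200
  expect_equal(d$gc_flank[5], 1000 / 2200)
  # high-identity copies use a strict < 0.01 cutoff: f1 has one (0.005,
  # with 0.010 excluded by strictness), f2 has two
  expect_equal(d$high_copies, c(1L, 1L, 1L, 2L, 2L))
  # standardization: zero mean, unit variance, interaction is the product
  for (z in c("z_length", "z_gc_flank", "z_divergence")) {
    expect_lt(abs(mean(d[[z]])), 1e-12)
    expect_equal(stats::sd(d[[z]]), 1)
  }
  expect_equal(d$z_interaction, d$z_divergence * d$z_high_copies)
  expect_equal(attr(d, "dropped"), 0L)
})

test_that("build_design drops NA divergence and rejects zero-variance predictors", {
  seqs <- Biostrings::DNAStringSet(c(
    s1 = paste0(strrep("A", 1000), strrep("G", 1000), strrep("A", 1000))))
  tes <- data.frame(
    feature_id = c("t1", "t2", "t3", "t4"),
    ref_id = "s1", start = c(0L, 1000L, 2000L, 500L),
    end = c(500L, 1800L, 2900L, 700L),
    family = c("f1", "f1", "f2", "f2"),
    divergence = c(0.005, 0.02, 0.02, NA),
    stringsAsFactors = FALSE
  )
  genome <- structure(list(seqs = seqs, tes = tes), class = "genome_bundle")
  assessments <- data.frame(feature_id = c("t1", "t2", "t3", "t4"),
                            feature_type = "TE",
                            perfect = c(TRUE, FALSE, TRUE, FALSE),
                            stringsAsFactors = FALSE)
  d <- build_design(assessments, genome)
  expect_equal(attr(d, "dropped"), 1L)
  expect_false("t4" %in% d$feature_id)
  expect_equal(d$high_copies, c(1L, 1L, 0L))
  # constant divergence -> standardization must fail, naming the predictor
  tes$divergence <- 0.02
  genome2 <- structure(list(seqs = seqs, tes = tes), class = "genome_bundle")
  expect_error(build_design(assessments, genome2), "divergence")
})

test_that("Laplace log-likelihood equals the plain logistic at sigma -> 0", {
  d <- sim_glmm_data(600, 3, c(0.2, -0.8, 0.5), 0.6, seed = 5)
  X <- cbind(1, d$z1, d$z2)
  fi <- as.integer(factor(d$family))
  g <- stats::glm(y ~ z1 + z2, stats::binomial, d)
  lap <- repeatproof:::glmm_loglik(c(unname(stats::coef(g)), -10),
                                   X, d$y, fi, 3L)
  expect_equal(lap, as.numeric(stats::logLik(g)), tolerance = 1e-4)
  # and at arbitrary beta, not just the optimum
  for (b in list(c(0, 0, 0), c(1, -1, 0.3))) {
    ll <- sum(d$y * (X %*% b) - log1p(exp(X %*% b)))
    expect_equal(repeatproof:::glmm_loglik(c(b, -10), X, d$y, fi, 3L),
                 ll, tolerance = 1e-4)
  }
})

test_that("Laplace log-likelihood matches 51-point quadrature on a 3-family toy", {
  d <- sim_glmm_data(600, 3, c(0.2, -0.8, 0.5), 0.6, seed = 5)
  X <- cbind(1, d$z1, d$z2)
  fi <- as.integer(factor(d$family))
  for (sigma in c(0.1, 0.5, 1.0)) {
    for (b in list(c(0.2, -0.8, 0.5), c(0, 0, 0), c(1, 1, -1))) {
      lap <- repeatproof:::glmm_loglik(c(b, log(sigma)), X, d$y, fi, 3L)
      gh <- gh_loglik(b, sigma, X, d$y, fi)
      expect_equal(lap, gh, tolerance = 1e-3,
                   label = sprintf("sigma=%.1f beta1=%.1f", sigma, b[1]))
    }
  }
})

test_that("fit_glmm agrees with the independent lme4 Laplace fit", {
  d <- sim_glmm_data(2000, 30, c(0.3, -1.0, 0.8), 0.7, seed = 6)
  ours <- fit_glmm(d, predictors = c("z1", "z2"))
  lme4_fit <- lme4::glmer(y ~ z1 + z2 + (1 | family), d, stats::binomial,
                          nAGQ = 1)
  expect_equal(unname(ours$beta), unname(lme4::fixef(lme4_fit)),
               tolerance = 1e-3)
  expect_equal(ours$sigma_family,
               sqrt(unname(unlist(lme4::VarCorr(lme4_fit)))),
               tolerance = 1e-3)
  expect_equal(unname(ours$se), unname(sqrt(diag(as.matrix(
    stats::vcov(lme4_fit))))), tolerance = 1e-2)
})

test_that("fit_glmm recovers known parameters within 2 SE at n = 3000", {
  truth <- c(0.3, -1.0, 0.8)
  d <- sim_glmm_data(3000, 50, truth, 0.7, seed = 7)
  f <- fit_glmm(d, predictors = c("z1", "z2"))
  expect_true(all(abs(f$beta - truth) <= 2 * f$se))
  expect_equal(f$sigma_family, 0.7, tolerance = 0.2)
  expect_equal(f$n, 3000L)
  expect_equal(f$n_families, 50L)
  expect_true(f$converged)
})

test_that("fit_glmm is approximately unbiased over 20 replicates", {
  truth <- c(0.3, -1.0, 0.8)
  est <- vapply(1:20, function(s) {
    d <- sim_glmm_data(3000, 50, truth, 0.7, seed = 100 + s)
    fit_glmm(d, predictors = c("z1", "z2"))$beta
  }, numeric(3))
  expect_true(all(abs(rowMeans(est) - truth) < 0.05))
})

test_that("fit_glmm validates its inputs and flags separation", {
  d <- sim_glmm_data(200, 5, c(0, 0.5), 0.5, seed = 9)
  d1 <- d; d1$family <- "f01"
  expect_error(fit_glmm(d1, predictors = "z1"), "2 families")
  d2 <- d; d2$y <- 1L
  expect_error(fit_glmm(d2, predictors = "z1"), "constant")
  set.seed(8)
  ds <- data.frame(z1 = stats::rnorm(400),
                   family = sprintf("f%d", sample(1:5, 400, TRUE)))
  ds$y <- as.integer(ds$z1 > 0)
  expect_error(fit_glmm(ds, predictors = "z1"), "separation")
})

test_that("predict_curves reflects coefficient signs and the interaction", {
  fake <- structure(list(
    beta = c(`(Intercept)` = 0.5, z_length = -1, z_gc_flank = 0,
             z_divergence = 0.8, z_high_copies = 0.2, z_interaction = -0.5),
    predictors = c("z_length", "z_gc_flank", "z_divergence",
                   "z_high_copies", "z_interaction")
  ), class = "te_glmm_fit")
  # negative coefficient: strictly decreasing curve
  cl <- predict_curves(fake, "z_length")
  expect_true(all(diff(cl$prob) < 0))
  expect_equal(cl$condition, rep("all", nrow(cl)))
  expect_equal(cl$prob[cl$value == 0], stats::plogis(0.5))
  # zero coefficient: flat curve
  cg <- predict_curves(fake, "z_gc_flank")
  expect_true(all(cg$prob == stats::plogis(0.5)))
  # interaction: one curve per condition, with different slopes
  cd <- predict_curves(fake, "z_divergence")
  expect_setequal(unique(cd$condition), c("low", "high"))
  lo <- cd[cd$condition == "low", ]
  hi <- cd[cd$condition == "high", ]
  # slope on the logit scale: 0.8 + (-0.5)*cv -> 1.3 at cv=-1, 0.3 at cv=+1
  expect_true(all(diff(lo$prob) > 0) && all(diff(hi$prob) > 0))
  logit <- function(p) log(p / (1 - p))
  expect_gt(logit(lo$prob[2]) - logit(lo$prob[1]),
            logit(hi$prob[2]) - logit(hi$prob[1]))
  expect_error(predict_curves(fake, "z_bogus"), "unknown covariate")
})

test_that("the fitted model separates planted assembly failures by length and divergence", {
  # outcome generated from the model with beta_length < 0, beta_div > 0
  d <- sim_glmm_data(1500, 25, c(0.5, -1.2, 0.9), 0.5, seed = 10,
                     names = c("z_length", "z_divergence"))
  f <- fit_glmm(d, predictors = c("z_length", "z_divergence"))
  expect_lt(f$beta[["z_length"]], 0)
  expect_gt(f$beta[["z_divergence"]], 0)
  expect_lt(f$p[["z_length"]], 0.05)
  expect_lt(f$p[["z_divergence"]], 0.05)
})
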
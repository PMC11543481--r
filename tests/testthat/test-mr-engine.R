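# Wald ratio, IVW, Bonferroni, Steiger directionality, reverse MR.

test_that("wald_ratio matches its closed form", {
  p <- list(beta_exp = 1, se_exp = 0.01, beta_out = 0.05, se_out = 0.01)
  fit <- wald_ratio(p)
  expect_equal(fit$beta, 0.05)
  expect_equal(fit$se, 0.01)
  expect_equal(fit$ci_low, 0.05 - 1.959964 * 0.01)
  expect_equal(fit$ci_high, 0.05 + 1.959964 * 0.01)

  p2 <- list(beta_exp = 0.5, se_exp = 0.001, beta_out = 0.1, se_out = 0.05)
  fit2 <- wald_ratio(p2)
  expect_equal(fit2$beta, 0.2)
  expect_equal(fit2$se, 0.1)
  # second-order delta barely differs when SE_GX is small
  fit2b <- wald_ratio(p2, second_order = TRUE)
  expect_equal(fit2b$se, sqrt(0.05^2 / 0.25 + 0.01 * 1e-6 / 0.0625))
  expect_equal(fit2b$se, fit2$se, tolerance = 1e-4)

  p3 <- list(beta_exp = 0.5, se_exp = 0.01, beta_out = 0, se_out = 0.05)
  fit3 <- wald_ratio(p3)
  expect_equal(fit3$beta, 0)
  expect_equal(fit3$pval, 1)

  expect_error(wald_ratio(list(beta_exp = 0, se_exp = 0.01, beta_out = 0.1,
                               se_out = 0.05)), "zero")
})

test_that("ivw matches its closed form and shrinks SE under replication", {
  two <- data.frame(beta_exp = c(0.5, 0.5), se_exp = 0.01,
                    beta_out = c(0.1, 0.1), se_out = 0.05)
  fit <- ivw(two)
  expect_equal(fit$beta, 0.2)
  expect_equal(fit$se, 0.1 / sqrt(2))

  mixed <- data.frame(beta_exp = c(0.5, 0.4), se_exp = 0.01,
                      beta_out = c(0.1, 0.06), se_out = c(0.05, 0.04))
  fit2 <- ivw(mixed)
  expect_equal(fit2$beta, 0.175)
  expect_equal(fit2$se, sqrt(1 / 200))

  null <- data.frame(beta_exp = c(0.5, 0.4), se_exp = 0.01,
                     beta_out = c(0, 0), se_out = c(0.05, 0.04))
  expect_equal(ivw(null)$beta, 0)

  expect_error(ivw(two[1, ]), "at least two")
})

test_that("ivw equals weighted least squares through the origin", {
  set.seed(7)
  for (rep in 1:20) {
    k <- 5
    pairs <- data.frame(beta_exp = rnorm(k, 0.3, 0.1), se_exp = 0.01,
                        beta_out = rnorm(k, 0.05, 0.03),
                        se_out = runif(k, 0.02, 0.1))
    fit <- ivw(pairs)
    wls <- lm(beta_out ~ 0 + beta_exp, data = pairs,
              weights = 1 / pairs$se_out^2)
    expect_equal(fit$beta, unname(coef(wls)), tolerance = 1e-10)
    # fixed-effect SE: the lm SE divided by its residual scale
    s <- summary(wls)
    expect_equal(fit$se, unname(s$coefficients[1, 2] / s$sigma),
                 tolerance = 1e-10)
  }
})

test_that("single-pair IVW equals the Wald ratio exactly", {
  pair <- data.frame(beta_exp = 0.37, se_exp = 0.02, beta_out = 0.021,
                     se_out = 0.012)
  a <- ivw(pair, allow_single = TRUE)
  b <- wald_ratio(pair)
  expect_equal(a$beta, b$beta)
  expect_equal(a$se, b$se)
  expect_equal(a$pval, b$pval)
})

test_that("mr_fit dispatches on the instrument count", {
  none <- data.frame(beta_exp = numeric(0), se_exp = numeric(0),
                     beta_out = numeric(0), se_out = numeric(0))
  expect_equal(mr_fit(none)$method, "none")
  expect_true(is.na(mr_fit(none)$beta))
  one <- data.frame(beta_exp = 0.5, se_exp = 0.01, beta_out = 0.1,
                    se_out = 0.05)
  expect_equal(mr_fit(one)$method, "wald_ratio")
  expect_equal(mr_fit(rbind(one, one))$method, "ivw")
})

test_that("p-values are invariant under exposure sign flips", {
  set.seed(11)
  pairs <- data.frame(beta_exp = rnorm(4, 0.3, 0.1), se_exp = 0.01,
                      beta_out = rnorm(4, 0.05, 0.02),
                      se_out = runif(4, 0.02, 0.06))
  flipped <- transform(pairs, beta_exp = -beta_exp)
  expect_equal(ivw(pairs)$pval, ivw(flipped)$pval)
  expect_equal(ivw(pairs)$beta, -ivw(flipped)$beta)
})

test_that("bonferroni_threshold validates its inputs", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m_tests")
})

test_that("steiger_test applies the Fisher-z comparison", {
  # equal variance explained on both sides: no direction, p = 1
  pair <- data.frame(beta_exp = 0.1, se_exp = 0.02, eaf_exp = 0.3,
                     n_exp = 5e4, beta_out = 0.1, se_out = 0.02,
                     eaf_out = 0.3, n_out = 5e4)
  st <- steiger_test(pair)
  expect_false(st$direction_ok)
  expect_equal(st$pval, 1)

  # r_X = 0.1 (n = 50,000) vs r_Y = 0.01 (n = 400,000):
  # construct z-scores giving exactly those correlations via r2 = z2/(z2+n)
  zx <- sqrt(0.1^2 * 5e4 / (1 - 0.1^2))
  zy <- sqrt(0.01^2 * 4e5 / (1 - 0.01^2))
  pair2 <- data.frame(beta_exp = zx * 0.01, se_exp = 0.01, eaf_exp = 0.3,
                      n_exp = 5e4, beta_out = zy * 0.01, se_out = 0.01,
                      eaf_out = 0.3, n_out = 4e5)
  st2 <- steiger_test(pair2)
  expect_true(st2$direction_ok)
  z_expected <- (atanh(0.1) - atanh(0.01)) /
    sqrt(1 / (5e4 - 3) + 1 / (4e5 - 3))
  expect_equal(st2$z, z_expected, tolerance = 1e-10)
  expect_equal(st2$z, 19.04, tolerance = 1e-3)

  # swapping exposure and outcome negates z
  pair3 <- pair2
  names(pair3) <- c("beta_out", "se_out", "eaf_out", "n_out",
                    "beta_exp", "se_exp", "eaf_exp", "n_exp")
  st3 <- steiger_test(pair3)
  expect_equal(st3$z, -st2$z)
  expect_false(st3$direction_ok)
  expect_equal(st3$pval, st2$pval)

  expect_error(steiger_test(transform(pair, n_exp = 3)), "n > 3")
})

test_that("reverse MR on a null region covers zero and handles no instruments", {
  covers <- logical(200)
  for (i in seq_len(200)) {
    sp <- scenario_spec("reverse", m_snps = 30, ld_rho = 0.8, theta = 0,
                        n_exposure = 1e5, n_outcome = 1e5, seed = i)
    r <- simulate_region(sp)
    rev <- reverse_mr(r$outcome, r$exposure)
    covers[i] <- !is.na(rev$beta) && rev$ci_low <= 0 && rev$ci_high >= 0
  }
  expect_gte(mean(covers), 0.93)

  # no genome-wide-significant outcome instruments: empty result
  sp <- scenario_spec("null", m_snps = 10, ld_rho = 0, beta_causal = 0,
                      seed = 3)
  r <- simulate_region(sp)
  rev <- reverse_mr(r$outcome, r$exposure)
  expect_equal(rev$method, "none")
  expect_equal(rev$n_snp, 0L)
})

test_that("role swap on symmetric data reproduces the forward estimate", {
  df <- make_snps(1, beta = 0.3, se = 0.01)
  prot <- make_region(df)
  outc <- make_region(df, "out", "outcome")
  fw <- mr_fit(kept_pairs(harmonize(prot, outc)))
  rv <- reverse_mr(outc, prot)
  expect_equal(rv$beta, fw$beta)
  expect_equal(rv$se, fw$se)
})
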
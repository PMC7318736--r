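# BLUP/heritability, trait correlations and the WAF weighted mean.

balanced_pheno <- function(n_lines, n_envs, sigma2_g, sigma2_e, mu = 10,
                           env_effects = NULL, seed = 1) {
  set.seed(seed)
  lines <- sprintf("L%03d", seq_len(n_lines))
  envs <- sprintf("E%d", seq_len(n_envs))
  if (is.null(env_effects)) env_effects <- rnorm(n_envs)
  gline <- rnorm(n_lines, 0, sqrt(sigma2_g))
  do.call(rbind, lapply(seq_len(n_envs), function(j)
    data.frame(line = lines, env = envs[j], trait = "t",
               value = mu + env_effects[j] + gline +
                 rnorm(n_lines, 0, sqrt(sigma2_e)))))
}

test_that("zero residual variance gives BLUPs equal to line means and H2 = 1", {
  ph <- balanced_pheno(20, 3, sigma2_g = 2, sigma2_e = 0, seed = 2)
  b <- fit_blup(ph)
  env_adj <- tapply(ph$value, ph$env, mean) - mean(ph$value)
  raw <- tapply(ph$value - env_adj[ph$env], ph$line, mean)
  expect_equal(unname(b$blups$t), as.numeric(raw[b$blups$line]),
               tolerance = 1e-6)
  expect_equal(b$varcomp$h2, 1, tolerance = 1e-6)
})

test_that("REML variance components match the balanced ANOVA oracle", {
  ph <- balanced_pheno(60, 4, sigma2_g = 3, sigma2_e = 1, seed = 7)
  b <- fit_blup(ph)
  # oracle: in a balanced two-way layout without interaction, REML equals the
  # ANOVA method-of-moments estimator: E[MS_line] = sigma2_e + n_env * sigma2_g
  a <- anova(lm(value ~ env + line, data = ph))
  ms_line <- a["line", "Mean Sq"]
  ms_err <- a["Residuals", "Mean Sq"]
  s2g_hat <- (ms_line - ms_err) / 4
  expect_equal(b$varcomp$sigma2_g, s2g_hat, tolerance = 1e-4)
  expect_equal(b$varcomp$sigma2_e, ms_err, tolerance = 1e-4)
  expect_equal(b$varcomp$h2, s2g_hat / (s2g_hat + ms_err / 4),
               tolerance = 1e-3)
})

test_that("BLUPs shrink and H2 is shift-invariant", {
  ph <- balanced_pheno(40, 3, sigma2_g = 1, sigma2_e = 2, seed = 5)
  b <- fit_blup(ph)
  raw <- tapply(ph$value, ph$line, mean)
  expect_lt(var(b$blups$t), var(as.numeric(raw)))
  ph2 <- ph; ph2$value <- ph2$value + 100
  b2 <- fit_blup(ph2)
  expect_equal(b$varcomp$h2, b2$varcomp$h2, tolerance = 1e-4)
})

test_that("single-environment traits get NA heritability with a warning", {
  ph <- balanced_pheno(10, 1, sigma2_g = 1, sigma2_e = 1, seed = 3)
  expect_warning(b <- fit_blup(ph), "single environment")
  expect_true(is.na(b$varcomp$h2))
  expect_equal(nrow(b$blups), 10L)
})

test_that("trait correlations report r, p and significance flags", {
  set.seed(11)
  n <- 50
  b <- data.frame(line = sprintf("L%d", 1:n), t1 = rnorm(n))
  b$t2 <- -b$t1
  b$t3 <- b$t1 + rnorm(n, 0, 0.5)
  b$t4 <- rnorm(n)
  ct <- trait_correlations(b)
  expect_equal(diag(ct$r), c(t1 = 1, t2 = 1, t3 = 1, t4 = 1))
  expect_equal(ct$r["t1", "t2"], -1)
  expect_equal(ct$sig["t1", "t3"], "**")
  expect_true(abs(ct$r["t1", "t4"]) < 0.4)
  # zero-variance trait -> NA row
  b$t5 <- 1
  ct2 <- trait_correlations(b)
  expect_true(all(is.na(ct2$r["t5", setdiff(colnames(ct2$r), "t5")])))
})

test_that("independent traits rarely show large correlations", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(100 + s)
    b <- data.frame(line = sprintf("L%d", 1:300), t1 = rnorm(300),
                    t2 = rnorm(300))
    if (abs(trait_correlations(b)$r["t1", "t2"]) >= 0.2) hits <- hits + 1L
  }
  expect_lte(hits / 50, 0.05)
})

test_that("WAF is the exact weighted mean with r*H2 weights", {
  add <- matrix(c(1, 2), 1, dimnames = list("b1", c("t1", "t2")))
  w <- compute_waf(add, r = c(t1 = 0.5, t2 = 0.5), h2 = c(t1 = 0.8, t2 = 0.4))
  expect_equal(w$waf, (1 * 0.4 + 2 * 0.2) / 0.6)  # 1.3333...
  # identities: all effects equal -> that constant; single trait -> its Add
  addc <- matrix(3, 1, 4, dimnames = list("b1", paste0("t", 1:4)))
  r <- setNames(runif(4, 0.1, 1), paste0("t", 1:4))
  h2 <- setNames(runif(4, 0.1, 1), paste0("t", 1:4))
  expect_equal(compute_waf(addc, r, h2)$waf, 3)
  add1 <- matrix(1.7, 1, 1, dimnames = list("b1", "t1"))
  expect_equal(compute_waf(add1, r = c(t1 = 0.9), h2 = c(t1 = 0.2))$waf, 1.7)
})

test_that("WAF matches a hand-computed oracle on randomized cases", {
  for (s in 1:10) {
    set.seed(200 + s)
    k <- sample(2:6, 1)
    nb <- sample(1:5, 1)
    traits <- paste0("t", 1:k)
    add <- matrix(rnorm(nb * k), nb, k,
                  dimnames = list(paste0("b", 1:nb), traits))
    add[sample(length(add), size = floor(length(add) / 4))] <- NA
    r <- setNames(runif(k, 0.05, 1), traits)
    h2 <- setNames(runif(k), traits)
    w <- compute_waf(add, r, h2)
    for (b in 1:nb) {
      num <- den <- 0
      for (t in 1:k) {
        if (!is.na(add[b, t])) {
          num <- num + add[b, t] * r[t] * h2[t]
          den <- den + r[t] * h2[t]
        }
      }
      expected <- if (den > 0) num / den else NA_real_
      expect_equal(w$waf[b], unname(expected))
      if (!is.na(expected)) {
        expect_gte(w$waf[b], min(add[b, ], na.rm = TRUE) - 1e-12)
        expect_lte(w$waf[b], max(add[b, ], na.rm = TRUE) + 1e-12)
      }
    }
  }
})

test_that("WAF is scale-equivariant in Add and weight-scale invariant", {
  set.seed(77)
  add <- matrix(rnorm(6), 2, 3, dimnames = list(c("b1", "b2"),
                                                c("t1", "t2", "t3")))
  r <- c(t1 = 0.3, t2 = 0.6, t3 = 0.9)
  h2 <- c(t1 = 0.5, t2 = 0.7, t3 = 0.9)
  w <- compute_waf(add, r, h2)
  expect_equal(compute_waf(3 * add, r, h2)$waf, 3 * w$waf)
  expect_equal(compute_waf(add, r, h2 / 2)$waf, w$waf)
  # non-positive correlations are excluded; all-excluded warns and gives NA
  r2 <- c(t1 = -0.3, t2 = -0.6, t3 = -0.9)
  expect_warning(w2 <- compute_waf(add, r2, h2), "positive")
  expect_true(all(is.na(w2$waf)))
})
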
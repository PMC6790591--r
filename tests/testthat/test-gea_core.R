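test_that("fit_logistic: closed forms, degeneracy, GLM agreement", {
  # intercept-only log-likelihood closed form
  y <- rep(c(0, 1), each = 10)
  f <- fit_logistic(y, matrix(1, 20, 1))
  expect_equal(f$loglik, 20 * (0.5 * log(0.5) + 0.5 * log(0.5)),
               tolerance = 1e-10)
  # rank-deficient design
  X <- cbind(1, 1:20, 2 * (1:20))
  expect_equal(fit_logistic(y, X)$status, "degenerate")
  # 200-sample random fixture vs stats::glm at tight tolerance
  set.seed(31)
  x <- rnorm(200)
  yy <- rbinom(200, 1, plogis(-0.5 + 0.8 * x))
  f1 <- fit_logistic(yy, cbind(1, x))
  or <- glm_oracle(yy, x)
  expect_equal(f1$loglik, or$loglik, tolerance = 1e-6)
  expect_equal(unname(f1$beta[2]), or$beta, tolerance = 1e-6)
  expect_equal(f1$status, "converged")
})

test_that("fit_logistic flags complete separation but returns scores", {
  x <- c(rep(-2, 20), rep(2, 20)) + rnorm(40, sd = 0.1)
  y <- as.numeric(x > 0)
  f <- fit_logistic(y, cbind(1, x))
  expect_equal(f$status, "separated")
  expect_true(is.finite(f$loglik))
})

test_that("score_model: null case, determinism, skip rules", {
  set.seed(2)
  envx <- rep(c(0, 1), each = 30)
  # genotype proportions identical across both env groups -> G = Wald = 0
  ind <- rep(rep(c(0, 1, 1), each = 10), 2)
  env <- env_table(sprintf("S%02d", 1:60), runif(60), runif(60),
                   data.frame(bin = envx))
  r <- score_model(ind, env, "bin", pop_vars = character())
  expect_equal(r$G, 0, tolerance = 1e-8)
  expect_equal(r$Wald, 0, tolerance = 1e-8)
  expect_equal(r$beta_env, 0, tolerance = 1e-6)
  # determinism: identical bits on re-run
  set.seed(77); ind2 <- rbinom(60, 1, 0.4)
  r1 <- score_model(ind2, env, "bin", pop_vars = character())
  r2 <- score_model(ind2, env, "bin", pop_vars = character())
  expect_identical(r1, r2)
  # constant indicator and constant env are skipped with a reason
  expect_equal(score_model(rep(1, 60), env, "bin",
                           pop_vars = character())$status, "skipped")
  envc <- env_table(env$ID, env$lon, env$lat, data.frame(cst = rep(2, 60)))
  expect_equal(score_model(ind2, envc, "cst",
                           pop_vars = character())$status, "skipped")
})

test_that("planted logistic effect recovers GLM G and Wald within 1e-6", {
  set.seed(13)
  n <- 500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.8 + 1 * x))
  env <- env_table(sprintf("S%03d", 1:n), runif(n), runif(n),
                   data.frame(x = x))
  r <- score_model(y, env, "x", pop_vars = character())
  or <- glm_oracle(y, x)
  expect_lt(abs(r$G - or$G), 1e-6)
  expect_lt(abs(r$Wald - or$Wald), 1e-6)
  # with one population covariate: nested-model comparison
  pop <- rnorm(n)
  envp <- env_table(env$ID, env$lon, env$lat,
                    data.frame(x = x, pop1 = pop), pop_vars = "pop1")
  rp <- score_model(y, envp, "x")
  orp <- glm_oracle(y, x, pop = data.frame(p1 = pop))
  expect_lt(abs(rp$G - orp$G), 1e-6)
  expect_lt(abs(rp$Wald - orp$Wald), 1e-6)
})

test_that("G is invariant to affine rescaling of the env variable", {
  set.seed(5)
  n <- 200
  x <- rnorm(n, 50, 10)
  y <- rbinom(n, 1, plogis(-0.2 + 0.05 * (x - 50)))
  env <- env_table(sprintf("S%03d", 1:n), runif(n), runif(n),
                   data.frame(raw = x, z = (x - mean(x)) / sd(x)))
  r1 <- score_model(y, env, "raw", pop_vars = character())
  r2 <- score_model(y, env, "z", pop_vars = character())
  expect_lt(abs(r1$G - r2$G), 1e-8)
  expect_gte(r1$G, -1e-8)
})

test_that("G and Wald agree asymptotically under the null", {
  meds <- vapply(c(100L, 400L, 1600L), function(n) {
    set.seed(n)
    d <- vapply(1:40, function(b) {
      x <- rnorm(n)
      y <- rbinom(n, 1, 0.4)
      env <- env_table(seq_len(n), runif(n), runif(n), data.frame(x = x))
      r <- score_model(y, env, "x", pop_vars = character())
      abs(r$G - r$Wald)
    }, numeric(1))
    median(d)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))     # shrinks along the n ladder
})

test_that("run_scan: product count, ordering, ID checks, chunk invariance", {
  set.seed(50)
  g <- make_gm(matrix(rbinom(30 * 1, 2, 0.5), 30, 1))
  ind <- encode_indicators(g)
  env <- env_table(g$samples, runif(30), runif(30),
                   data.frame(e1 = rnorm(30), e2 = rnorm(30)))
  res <- run_scan(ind, env)
  expect_equal(nrow(res), 3L * 2L)                 # 3 indicators x 2 env
  expect_equal(res$indicator, rep(ind$indicators$label, each = 2L))
  # chunking and workers never change the result
  res2 <- run_scan(ind, env, chunks = 3L, workers = 2L)
  expect_identical(res, res2)
  envbad <- env_table(rev(g$samples), runif(30), runif(30),
                      data.frame(e1 = rnorm(30)))
  expect_error(run_scan(ind, envbad), "order")
})

test_that("adding a pure-noise pop covariate keeps the env G chi2(1)-calibrated", {
  set.seed(61)
  n <- 300
  pvals <- vapply(1:200, function(b) {
    x <- rnorm(n); noisepop <- rnorm(n)
    y <- rbinom(n, 1, 0.35)
    env <- env_table(seq_len(n), runif(n), runif(n),
                     data.frame(x = x, pop1 = noisepop), pop_vars = "pop1")
    r <- score_model(y, env, "x")
    chi2_pvalue(max(r$G, 0), 1)
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
})

test_that("score TSV writer/reader round-trips with optional score filter", {
  set.seed(3)
  g <- make_gm(matrix(rbinom(40 * 3, 2, 0.4), 40, 3))
  ind <- encode_indicators(g)
  env <- env_table(g$samples, runif(40), runif(40),
                   data.frame(e1 = rnorm(40)))
  res <- run_scan(ind, env)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_scores(res, p)
  back <- read_scores(p)
  expect_equal(back$G, res$G, tolerance = 1e-15)
  expect_equal(back$indicator, res$indicator)
  write_scores(res, p, score_min = 1)
  kept <- read_scores(p)
  expect_true(all(pmax(kept$G, kept$Wald) > 1))
})
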
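grid_coords <- function(k = 4L) {
  as.matrix(expand.grid(lon = seq_len(k), lat = seq_len(k)))
}

test_that("neighbor_weights builds row-standardised self-free neighbourhoods", {
  co <- grid_coords(3L)
  w <- neighbor_weights(co, "knn", k = 4L)
  expect_true(all(vapply(seq_len(w$n), function(i)
    !(i %in% w$neighbors[[i]]), logical(1))))
  expect_equal(vapply(w$weights, sum, numeric(1)), rep(1, w$n))
  wk <- neighbor_weights(rbind(c(0, 0), c(0, 1)), "knn", k = 10L)
  expect_equal(lengths(wk$neighbors), c(1L, 1L))     # k capped at n - 1
})

test_that("local Moran: block clustering positive, checkerboard negative", {
  # two well-separated spatial blocks so knn stays within a block
  co2 <- rbind(grid_coords(3L),
               sweep(grid_coords(3L), 2L, c(100, 0), "+"))
  w2 <- neighbor_weights(co2, "knn", k = 4L)
  blocks <- rep(c(1, 0), each = 9L)
  lm_b <- local_moran(blocks, w2, permutations = 99, seed = 1)
  expect_true(all(lm_b$I > 0))
  # checkerboard: interior points have all-opposite rook neighbours
  co <- grid_coords(4L)
  w <- neighbor_weights(co, "knn", k = 4L)
  cb <- as.numeric((co[, "lon"] + co[, "lat"]) %% 2 == 0)
  lm_c <- local_moran(cb, w, permutations = 99, seed = 1)
  interior <- co[, "lon"] %in% 2:3 & co[, "lat"] %in% 2:3
  expect_true(all(lm_c$I[interior] < 0))
  # direct computation oracle on the 4x4 grid
  z <- (cb - mean(cb)) / sqrt(mean((cb - mean(cb))^2))
  i0 <- 6L   # an interior cell
  manual <- z[i0] * mean(z[w$neighbors[[i0]]])
  expect_equal(lm_c$I[i0], manual, tolerance = 1e-12)
})

test_that("mean of local Moran equals independently computed global Moran", {
  set.seed(9)
  co <- cbind(runif(40, 0, 2), runif(40, 40, 42))
  w <- neighbor_weights(co, "knn", k = 6L)
  x <- rbinom(40, 1, 0.5)
  lm <- local_moran(x, w, permutations = 9, seed = 2)
  # global Moran oracle from the dense weight matrix
  W <- matrix(0, 40, 40)
  for (i in 1:40) W[i, w$neighbors[[i]]] <- w$weights[[i]]
  z <- x - mean(x)
  I_global <- (40 / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
  expect_equal(mean(lm$I), I_global, tolerance = 1e-10)
})

test_that("local Moran: affine-coding invariance, seeded permutations, constants", {
  set.seed(30)
  co <- cbind(runif(25), runif(25))
  w <- neighbor_weights(co, "knn", k = 5L)
  x <- rbinom(25, 1, 0.4)
  a <- local_moran(x, w, permutations = 49, seed = 7)
  b <- local_moran(1 + x, w, permutations = 49, seed = 7)   # recode 1/2
  expect_equal(a$I, b$I, tolerance = 1e-12)
  c2 <- local_moran(x, w, permutations = 49, seed = 7)
  expect_identical(a, c2)                                  # reproducible
  const <- local_moran(rep(1, 25), w, permutations = 9, seed = 1)
  expect_true(attr(const, "constant"))
  expect_true(all(is.na(const$I)))
})

test_that("permutation distribution of I centres near -1/(n-1)", {
  set.seed(44)
  n <- 30L
  co <- cbind(runif(n), runif(n))
  w <- neighbor_weights(co, "knn", k = 5L)
  x <- rbinom(n, 1, 0.5)
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  draws <- replicate(400, {
    zp <- sample(z)
    mean(vapply(seq_len(n), function(i)
      zp[i] * mean(zp[w$neighbors[[i]]]), numeric(1)))
  })
  expect_lt(abs(mean(draws) - (-1 / (n - 1))), 0.02)
})

test_that("scatter_points separates conflicts and leaves clean input alone", {
  two <- rbind(c(0, 0), c(0, 0))
  out <- scatter_points(two, min_sep = 0.1)
  expect_gte(dist(out)[1], 0.1)
  clean <- rbind(c(0, 0), c(5, 5), c(10, 0))
  expect_equal(scatter_points(clean, min_sep = 0.1), clean)
  ten <- matrix(1.5, 10, 2)
  out10 <- scatter_points(ten, min_sep = 0.05)
  expect_true(all(dist(out10) >= 0.05))
  expect_identical(scatter_points(ten, 0.05), out10)   # deterministic
})

test_that("manhattan_plot renders a file and counts threshold exceedances", {
  set.seed(19)
  g <- make_gm(matrix(rbinom(80 * 20, 2, 0.5), 80, 20),
               chrom = rep(c("1", "2"), each = 10),
               pos = rep(1:10 * 1000L, 2))
  ind <- encode_indicators(g)
  env <- env_table(g$samples, runif(80), runif(80),
                   data.frame(e1 = rnorm(80)))
  rt <- add_significance(run_scan(ind, env))
  out <- withr::local_tempfile(fileext = ".png")
  res <- manhattan_plot(rt, g$snps, "e1", value = "p", threshold = 0.05,
                        out = out)
  expect_true(file.exists(out) && file.size(out) > 0)
  expect_equal(attr(res, "n_above"),
               sum(rt$p_G < 0.05, na.rm = TRUE))
  # single chromosome renders too
  one <- rt[grepl("^rs0(0[1-9]|10)_", rt$indicator), ]
  expect_no_error(manhattan_plot(one, g$snps, "e1", value = "p", out = out))
  expect_error(manhattan_plot(rt[0, ], g$snps, "e1", out = out), "no plottable")
})

test_that("genotype_map smoke tests", {
  set.seed(23)
  pts <- cbind(runif(15, 0, 2), runif(15, 45, 47))
  ind <- rbinom(15, 1, 0.5)
  r <- raster_grid(matrix(runif(100), 10), origin = c(0, 47),
                   cellsize = c(0.2, 0.2))
  out <- withr::local_tempfile(fileext = ".png")
  expect_no_error(genotype_map(pts, ind, raster = r, min_sep = 0.01,
                               out = out))
  expect_true(file.size(out) > 0)
  expect_no_error(genotype_map(pts, ind, popvar = runif(15), out = out))
  expect_error(genotype_map(pts[0, , drop = FALSE], integer(0), out = out),
               "no points")
})
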
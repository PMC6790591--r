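test_that("VCF reading transcribes calls and skips non-biallelic records", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_tiny_vcf(p, c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2",   # triallelic
    "1\t400\trs4\tGT\tG\t.\tPASS\t.\tGT\t0/0\t0/1",    # indel
    "1\t500\trs5\tT\tC\t.\tPASS\t.\tGT\t0|1\t1|1"))
  g <- suppressMessages(read_genotypes(p, "vcf"))
  expect_equal(g$snps$name, c("rs1", "rs2", "rs5"))
  expect_equal(attr(g, "n_skipped"), 2L)
  expect_equal(unname(g$calls[, "rs1"]), c(0L, 1L))
  expect_equal(unname(g$calls[, "rs2"]), c(2L, NA_integer_))
  expect_equal(unname(g$calls[, "rs5"]), c(1L, 2L))
  expect_equal(g$samples, c("A1", "A2"))
})

test_that("PED/MAP reading maps first-seen allele to ref", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_tiny_ped(ped, map,
    c("F1 I1 0 0 1 0 A A G G",
      "F2 I2 0 0 1 0 A G 0 0",
      "F3 I3 0 0 1 0 G G G T"),
    c("1 rs1 0 100", "1 rs2 0 200"))
  g <- read_genotypes(ped, "ped", map = map)
  # rs1: first allele seen is A -> ref, G -> alt
  expect_equal(g$snps$ref, c("A", "G"))
  expect_equal(g$snps$alt, c("G", "T"))
  expect_equal(unname(g$calls[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$calls[, "rs2"]), c(0L, NA_integer_, 1L))
  expect_error(read_genotypes(ped, "ped", map = tempfile()), "MAP")
})

test_that("compute_maf handles missing calls and monomorphic SNPs", {
  g <- make_gm(cbind(c(0, 1, 2, 2), c(0, 0, 0, 0), c(NA, 1, 1, NA)))
  maf <- compute_maf(g)
  expect_equal(unname(maf), c(0.375, 0, 0.5))
  expect_true(all(maf >= 0 & maf <= 0.5))
})

test_that("apply_qc filters by MAF and missingness and reports", {
  calls <- cbind(mono = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                 ok1  = c(0, 1, 2, 1, 0, 1, 2, 0, 1, 2),
                 gap  = c(NA, NA, NA, 1, 0, 1, 2, 0, 1, 2),
                 ok2  = c(2, 1, 0, 1, 2, 1, 0, 2, 1, 0),
                 ok3  = c(1, 1, 0, 0, 2, 2, 1, 0, 1, 2))
  g <- make_gm(calls)
  out <- apply_qc(g, qc_thresholds(maf_min = 0.05, missing_max = 0.1))
  rep <- attr(out, "qc_report")
  expect_equal(ncol(out$calls), 3L)                 # mono and gap removed
  expect_equal(rep$n_maf, 1L)
  expect_equal(rep$n_missing, 1L)
  expect_equal(length(rep$hist_maf$counts), 20L)
  # retained SNPs respect thresholds
  expect_true(all(compute_maf(out) >= 0.05))
  expect_true(all(compute_missingness(out) <= 0.1))
  # no-op thresholds are the identity
  id <- apply_qc(g, qc_thresholds(maf_min = 0, missing_max = 1))
  expect_equal(id$calls, g$calls)
  # idempotence
  twice <- apply_qc(out, qc_thresholds(maf_min = 0.05, missing_max = 0.1))
  expect_equal(twice$calls, out$calls)
  mono <- make_gm(cbind(c(0, 0, 0, 0)))
  expect_error(apply_qc(mono, qc_thresholds(maf_min = 0.05)),
               "all SNPs removed")
})

test_that("ld_prune drops the downstream SNP of a correlated pair", {
  base <- c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2)
  orth <- c(1, 0, 1, 2, 1, 0, 2, 1, 0, 1)
  g <- make_gm(cbind(a = base, b = base, c = orth))
  out <- ld_prune(g, r2_max = 0.2, window = 50L)
  expect_equal(out$snps$name, c("rs001", "rs003"))   # duplicate 'b' dropped
  r <- cor(out$calls[, 1], out$calls[, 2])
  expect_lte(r^2, 0.2)
})

test_that("ld_prune matches a brute-force all-pairs oracle", {
  set.seed(42)
  n <- 40L; m <- 50L
  calls <- matrix(rbinom(n * m, 2, 0.4), n, m)
  dup_of <- sample(seq_len(25L), 10L)
  calls[, 26:35] <- calls[, dup_of]                  # planted duplicates
  g <- make_gm(calls)
  window <- 50L; r2max <- 0.2
  out <- ld_prune(g, r2max, window)
  # oracle: iterate drop-downstream over all pairs until stable
  keep <- rep(TRUE, m)
  repeat {
    changed <- FALSE
    idx <- which(keep)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a || b - a >= window) next
      i <- idx[a]; j <- idx[b]
      if (!keep[i] || !keep[j]) next
      r <- suppressWarnings(cor(calls[, i], calls[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2max) { keep[j] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  expect_equal(out$snps$name, g$snps$name[keep])
  # invariant: no same-window retained pair above the threshold
  kept <- out$calls
  for (i in seq_len(ncol(kept) - 1L))
    for (j in (i + 1L):min(ncol(kept), i + window - 1L)) {
      r <- suppressWarnings(cor(kept[, i], kept[, j],
                                use = "pairwise.complete.obs"))
      expect_lte(r^2, r2max + 1e-12)
    }
})

test_that("encode_indicators emits 3 indicators per SNP with the one-hot rule", {
  g <- make_gm(cbind(c(0, 1, 2, NA), c(2, 2, 2, 2)))
  ind <- encode_indicators(g)
  expect_equal(ncol(ind$values), 3L * ncol(g$calls))
  expect_equal(ind$indicators$label[1:3],
               c("rs001_AA", "rs001_AG", "rs001_GG"))
  expect_equal(unname(ind$values[2, 1:3]), c(0L, 1L, 0L))   # het call
  expect_true(all(is.na(ind$values[4, 1:3])))               # missing call
  # one-hot row sums for every non-missing call
  for (s in 1:3)
    expect_equal(sum(ind$values[s, 1:3]), 1L)
  # absent classes still get an (all-zero) indicator
  expect_equal(unname(colSums(ind$values[, 4:6])), c(0L, 0L, 4L))
})

test_that("interchange text format round-trips and validates rows", {
  set.seed(7)
  g <- make_gm(matrix(sample(c(0:2, NA), 60, replace = TRUE), 10, 6))
  ind <- encode_indicators(g)
  p <- withr::local_tempfile(fileext = ".txt")
  write_sambada_format(ind, p)
  ind2 <- read_sambada_format(p)
  expect_identical(ind2$values, ind$values)
  expect_identical(ind2$samples, ind$samples)
  expect_identical(ind2$indicators$label, ind$indicators$label)
  expect_match(readLines(p, n = 1L), "^ID ")
  # malformed row errors with its line number
  lines <- readLines(p)
  lines[3] <- paste(lines[3], "0")
  writeLines(lines, p)
  expect_error(read_sambada_format(p), "line 3")
})
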
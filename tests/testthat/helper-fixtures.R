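# Shared fixture builders. Everything is generated in code; no stored data.

make_gm <- function(calls, chrom = NULL, pos = NULL, ref = "A", alt = "G") {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_matrix(
    calls,
    samples = sprintf("S%02d", seq_len(nrow(calls))),
    snps = data.frame(name = sprintf("rs%03d", seq_len(m)),
                      chrom = chrom, pos = pos,
                      ref = rep_len(ref, m), alt = rep_len(alt, m),
                      stringsAsFactors = FALSE))
}

write_tiny_vcf <- function(path, rows, samples = c("A1", "A2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

write_tiny_ped <- function(ped_path, map_path, ped_rows, map_rows) {
  writeLines(ped_rows, ped_path)
  writeLines(map_rows, map_path)
  ped_path
}

# Independent GLM oracle: likelihood-ratio and Wald statistics from stats::glm
# fitted at tight tolerance, with optional population covariates. The Wald
# covariance is the inverse Fisher information evaluated at glm's MLE
# (summary.glm's covariance comes from the penultimate IWLS weights and is
# one iteration stale, ~1e-5 off on the squared statistic).
glm_oracle <- function(y, x, pop = NULL) {
  ctl <- stats::glm.control(epsilon = 1e-14, maxit = 200)
  df0 <- if (is.null(pop)) data.frame(y = y) else data.frame(y = y, pop)
  df1 <- cbind(df0, x = x)
  f0 <- suppressWarnings(stats::glm(y ~ ., data = df0, family = binomial,
                                    control = ctl))
  f1 <- suppressWarnings(stats::glm(y ~ ., data = df1, family = binomial,
                                    control = ctl))
  X <- stats::model.matrix(f1)
  w <- stats::fitted(f1) * (1 - stats::fitted(f1))
  V <- solve(crossprod(X, X * w))
  k <- which(colnames(X) == "x")
  b <- stats::coef(f1)[k]
  list(G = f0$deviance - f1$deviance,
       Wald = drop(t(b) %*% solve(V[k, k, drop = FALSE], b)),
       beta = unname(b), loglik = as.numeric(stats::logLik(f1)))
}

# Brute-force greedy pruning oracle over a full pairwise r^2 matrix.
greedy_prune_oracle <- function(df, thr) {
  keep <- character()
  for (v in names(df)) {
    x <- df[[v]]
    if (stats::sd(x, na.rm = TRUE) == 0) next
    r2 <- vapply(keep, function(w)
      suppressWarnings(stats::cor(x, df[[w]],
                                  use = "pairwise.complete.obs"))^2,
      numeric(1L))
    if (!length(r2) || all(is.na(r2) | r2 <= thr)) keep <- c(keep, v)
  }
  keep
}
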
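#' Population structure from genotype PCA
#'
#' Builds population-structure covariates from an LD-pruned, QC'd genotype
#' matrix. Missing dosages are imputed to the per-SNP mean; each SNP column
#' is centred by twice its estimated allele frequency and, with
#' `scale = "patterson"` (default), divided by `sqrt(2 p (1 - p))` — the
#' binomial standard deviation of a dosage under Hardy-Weinberg. Sample
#' scores are the projections on the top eigenvectors of the sample
#' covariance; `varexp` is the eigenvalue share of total variance.
#'
#' @param g GenotypeMatrix (QC and LD pruning are the caller's duty).
#' @param n_components number of components to return; must not exceed
#'   `min(n_samples - 1, n_snps)`.
#' @param scale `"patterson"` or `"unit"` (unit-variance per SNP).
#' @return Object of class `PopStructure`: list with `scores` (samples x k),
#'   `varexp` (length k, non-increasing, sums <= 1), `samples`; memberships
#'   and centroids are added by [cluster_memberships()].
#' @export
pca_structure <- function(g, n_components = 3L,
                          scale = c("patterson", "unit")) {
  scale <- match.arg(scale)
  x <- g$calls
  n <- nrow(x); m <- ncol(x)
  n_components <- as.integer(n_components)
  if (n_components > min(n - 1L, m))
    stop("n_components exceeds min(n - 1, number of SNPs)")
  p <- colMeans(x, na.rm = TRUE) / 2
  mu <- 2 * p
  sdv <- switch(scale,
                patterson = sqrt(2 * p * (1 - p)),
                unit = apply(x, 2L, sd, na.rm = TRUE))
  use <- !is.na(sdv) & sdv > 0
  z <- x[, use, drop = FALSE]
  mu <- mu[use]; sdv <- sdv[use]
  z <- sweep(z, 2L, mu, "-")
  z[is.na(z)] <- 0              # mean imputation after centring
  z <- sweep(z, 2L, sdv, "/")
  sv <- svd(z, nu = n_components, nv = 0L)
  lambda <- sv$d^2
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- g$samples
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores,
                 varexp = lambda[seq_len(n_components)] / sum(lambda),
                 samples = g$samples,
                 memberships = NULL, centroids = NULL),
            class = "PopStructure")
}

#' @export
print.PopStructure <- function(x, ...) {
  cat(sprintf("PopStructure: %d samples, %d components (varexp %s)\n",
              length(x$samples), ncol(x$scores),
              paste(sprintf("%.3f", x$varexp), collapse = ", ")))
  if (!is.null(x$memberships))
    cat(sprintf("  %d-cluster memberships attached\n", ncol(x$memberships)))
  invisible(x)
}

#' Soft cluster memberships from PCA scores
#'
#' Runs k-means (10 restarts, best inertia, deterministic under `seed`) on
#' the PCA scores and converts distances to the fitted centroids into
#' membership coefficients by inverse squared Euclidean distance:
#' \deqn{m_{ik} = (1/d_{ik}^2) / \sum_j (1/d_{ij}^2).}
#' A sample coincident with a centroid gets membership 1 for that cluster.
#' Rows sum to 1.
#'
#' @param ps PopStructure from [pca_structure()].
#' @param K number of clusters (>= 2, <= number of samples).
#' @param seed integer seed controlling the k-means restarts.
#' @return `ps` with `memberships` (samples x K) and `centroids` (K x k)
#'   filled in.
#' @export
cluster_memberships <- function(ps, K, seed = 1L) {
  stopifnot(inherits(ps, "PopStructure"), K >= 2)
  n <- nrow(ps$scores)
  if (K > n) stop("K exceeds the number of samples")
  km <- .with_seed(seed, {
    fit <- NULL
    for (try in 0:9) {       # empty-cluster or tie failures: reseeded retry
      fit <- tryCatch(kmeans(ps$scores, centers = K, nstart = 10L,
                             iter.max = 100L),
                      error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("k-means failed to converge for K = ", K)
    fit
  })
  cen <- km$centers
  ps$memberships <- membership_from_centroids(ps$scores, cen)
  ps$centroids <- cen
  ps
}

#' Inverse-square-distance memberships given centroids
#' @param scores samples x k score matrix.
#' @param centroids K x k centroid matrix.
#' @return samples x K membership matrix, rows summing to 1.
#' @export
membership_from_centroids <- function(scores, centroids) {
  scores <- as.matrix(scores); centroids <- as.matrix(centroids)
  d2 <- outer(rowSums(scores^2), rep(1, nrow(centroids))) -
    2 * scores %*% t(centroids) +
    outer(rep(1, nrow(scores)), rowSums(centroids^2))
  d2[d2 < 0] <- 0
  memb <- matrix(0, nrow(scores), nrow(centroids))
  for (i in seq_len(nrow(scores))) {
    zero <- d2[i, ] <= .Machine$double.eps
    if (any(zero)) {
      memb[i, zero] <- 1 / sum(zero)
    } else {
      inv <- 1 / d2[i, ]
      memb[i, ] <- inv / sum(inv)
    }
  }
  rownames(memb) <- rownames(scores)
  colnames(memb) <- paste0("cluster", seq_len(nrow(centroids)))
  memb
}

#' Merge population-structure columns into an environment table
#'
#' Adds the chosen PCA score columns (or cluster memberships) to an
#' [env_table()] as columns `pop1...popk`, flagged population-structure so
#' that [prune_correlated()] and [run_scan()] treat them as covariates
#' rather than tested variables. Which and how many columns to include is a
#' user decision, typically guided by the variance-explained profile.
#'
#' @param env EnvTable.
#' @param ps PopStructure.
#' @param use `"scores"` or `"memberships"`.
#' @param n_columns how many leading columns to add.
#' @return EnvTable with the added `pop*` columns.
#' @export
add_structure_columns <- function(env, ps, use = c("scores", "memberships"),
                                  n_columns = 1L) {
  use <- match.arg(use)
  mat <- if (use == "scores") ps$scores else ps$memberships
  if (is.null(mat)) stop("PopStructure has no ", use)
  if (!identical(as.character(env$ID), ps$samples))
    stop("sample IDs/order differ between EnvTable and PopStructure")
  n_columns <- min(n_columns, ncol(mat))
  add <- as.data.frame(mat[, seq_len(n_columns), drop = FALSE])
  names(add) <- paste0("pop", seq_len(n_columns))
  vars <- cbind(as.data.frame(env)[, env_variables(env, "all"), drop = FALSE],
                add)
  env_table(env$ID, env$lon, env$lat, vars,
            pop_vars = c(attr(env, "pop_vars"), names(add)))
}

.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
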
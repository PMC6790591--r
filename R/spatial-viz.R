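#' Spatial neighbour weights
#'
#' Builds row-standardised neighbour weights from sample coordinates using
#' great-circle (haversine) distances: either the `k` nearest neighbours of
#' each sample, or all samples within a `radius_km` band. Self-neighbours
#' are excluded; rows without neighbours are flagged in `no_neighbors`.
#'
#' @param coords two-column matrix/data.frame of (lon, lat) in degrees.
#' @param scheme `"knn"` or `"distance_band"`.
#' @param k neighbour count for `"knn"` (capped at n - 1).
#' @param radius_km band radius in kilometres for `"distance_band"`.
#' @return Object of class `NeighborWeights`: list of per-sample `neighbors`
#'   (integer indices) and `weights` (summing to 1), plus `scheme`,
#'   `parameter`, `no_neighbors`.
#' @export
neighbor_weights <- function(coords, scheme = c("knn", "distance_band"),
                             k = 10L, radius_km = NULL) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 2L)
  d <- haversine_matrix(coords)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    idx <- if (scheme == "knn") {
      kk <- min(k, n - 1L)
      order(di)[seq_len(kk)]
    } else {
      stopifnot(!is.null(radius_km))
      which(di <= radius_km)
    }
    nb[[i]] <- sort(idx)
  }
  no_nb <- lengths(nb) == 0L
  w <- lapply(nb, function(idx)
    if (length(idx)) rep(1 / length(idx), length(idx)) else numeric(0))
  structure(list(neighbors = nb, weights = w, scheme = scheme,
                 parameter = if (scheme == "knn") k else radius_km,
                 no_neighbors = no_nb, n = n),
            class = "NeighborWeights")
}

#' Great-circle distance matrix (km)
#' @param coords (lon, lat) matrix in degrees.
#' @return n x n distance matrix in kilometres.
#' @export
haversine_matrix <- function(coords) {
  R <- 6371
  lam <- coords[, 1L] * pi / 180
  phi <- coords[, 2L] * pi / 180
  n <- length(phi)
  dphi <- outer(phi, phi, "-") / 2
  dlam <- outer(lam, lam, "-") / 2
  a <- sin(dphi)^2 + (cos(phi) %o% cos(phi)) * sin(dlam)^2
  a <- pmin(pmax(a, 0), 1)
  2 * R * asin(sqrt(a))
}

#' Local Moran's I with conditional permutation
#'
#' For each sample, `I_i = z_i * sum_j w_ij z_j` where `z` is the indicator
#' standardised over the non-missing samples (population standard
#' deviation), so that `mean(I_i)` equals global Moran's I under
#' row-standardised weights. Pseudo p-values come from conditional
#' permutation: holding `z_i` fixed, the neighbour values are drawn from the
#' remaining samples; the two-sided pseudo-p is
#' `(#{|I_perm| >= |I_obs|} + 1) / (permutations + 1)`.
#'
#' @param ind binary indicator vector (0/1/NA); any affine recoding gives
#'   identical I.
#' @param w [neighbor_weights()] built on the same samples.
#' @param permutations number of conditional permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame: `I`, `p_pseudo` (NA where the indicator is missing or
#'   the row has no neighbours); attribute `constant` TRUE when the
#'   indicator has no variation (all I undefined).
#' @export
local_moran <- function(ind, w, permutations = 999L, seed = 1L) {
  stopifnot(inherits(w, "NeighborWeights"), length(ind) == w$n)
  x <- as.numeric(ind)
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing samples")
  out <- data.frame(I = rep(NA_real_, w$n), p_pseudo = NA_real_)
  s <- sqrt(mean((x[ok] - mean(x[ok]))^2))
  if (s == 0) {
    attr(out, "constant") <- TRUE
    return(out)
  }
  attr(out, "constant") <- FALSE
  z <- rep(NA_real_, w$n)
  z[ok] <- (x[ok] - mean(x[ok])) / s
  lag <- vapply(seq_len(w$n), function(i) {
    idx <- w$neighbors[[i]]
    wt <- w$weights[[i]]
    use <- !is.na(z[idx])
    if (!any(use)) return(NA_real_)
    sum(wt[use] * z[idx][use]) / sum(wt[use])
  }, numeric(1L))
  out$I <- z * lag
  .with_seed(seed, {
    for (i in which(ok & !is.na(lag))) {
      pool <- z[ok & seq_len(w$n) != i]
      kk <- length(w$neighbors[[i]])
      if (kk == 0L || length(pool) < kk) next
      Iperm <- vapply(seq_len(permutations), function(b) {
        z[i] * mean(sample(pool, kk))
      }, numeric(1L))
      out$p_pseudo[i] <-
        (sum(abs(Iperm) >= abs(out$I[i])) + 1) / (permutations + 1)
    }
  })
  out
}

#' Manhattan plot of scan significance
#'
#' Plots `-log10` of the chosen significance value against cumulative
#' genomic position with chromosome-alternating shading and a horizontal
#' line at `-log10(threshold)`.
#'
#' @param rt result table with significance columns ([add_significance()]).
#' @param snps SNP metadata data.frame (`name`, `chrom`, `pos`) used to
#'   place indicators; joined via the indicator's SNP name.
#' @param env_var environmental variable whose models are plotted.
#' @param value which column to plot: `"p"`, `"q"` or `"p_bonf"` (p/q use
#'   the G-score columns).
#' @param threshold significance threshold drawn as a horizontal line.
#' @param out output PNG path.
#' @return `out` invisibly; attribute `n_above` gives the number of points
#'   above the threshold line.
#' @export
manhattan_plot <- function(rt, snps, env_var, value = c("q", "p", "p_bonf"),
                           threshold = 0.05, out = "manhattan.png") {
  value <- match.arg(value)
  col <- switch(value, p = "p_G", q = "q_G", p_bonf = "p_bonf")
  rows <- rt[rt$env == env_var & !is.na(rt[[col]]), , drop = FALSE]
  if (!nrow(rows)) stop("no plottable rows for environmental variable ",
                        env_var)
  snp_of <- sub("_[^_]*$", "", rows$indicator)
  j <- match(snp_of, snps$name)
  if (anyNA(j))
    stop("missing genomic coordinates for SNP(s): ",
         paste(head(unique(snp_of[is.na(j)]), 10L), collapse = ", "))
  chrom <- as.character(snps$chrom[j])
  pos <- as.numeric(snps$pos[j])
  chr_lev <- unique(chrom[order(suppressWarnings(as.numeric(chrom)), chrom)])
  offset <- setNames(numeric(length(chr_lev)), chr_lev)
  run <- 0
  for (ch in chr_lev) {
    offset[ch] <- run
    run <- run + max(pos[chrom == ch]) + 1
  }
  xg <- pos + offset[chrom]
  yv <- -log10(pmax(rows[[col]], 1e-300))
  grDevices::png(out, width = 1200, height = 500)
  on.exit(grDevices::dev.off())
  plot(NA, xlim = range(xg), ylim = c(0, max(yv, -log10(threshold)) * 1.05),
       xlab = "cumulative genomic position (bp)",
       ylab = paste0("-log10(", value, ")"),
       main = paste("GEA scan:", env_var))
  for (i in seq_along(chr_lev)) {
    if (i %% 2L == 0L) {
      ch <- chr_lev[i]
      rng <- range(xg[chrom == ch])
      graphics::rect(rng[1L], -1, rng[2L], max(yv) * 2,
                     col = "grey92", border = NA)
    }
  }
  graphics::points(xg, yv, pch = 20,
                   col = ifelse(seq_along(chr_lev)[match(chrom, chr_lev)]
                                %% 2L == 0L, "grey40", "grey10"))
  graphics::abline(h = -log10(threshold), col = "red", lwd = 2)
  structure(invisible(out), n_above = sum(rows[[col]] < threshold))
}

#' Displace overlapping points for mapping
#'
#' Iteratively pushes points apart until every pairwise separation is at
#' least `min_sep` degrees (or 1,000 iterations). Coincident points are
#' spread on a deterministic circle; points with no conflict are never
#' moved. Deterministic: no randomness.
#'
#' @param pts (lon, lat) matrix or data.frame.
#' @param min_sep minimum pairwise separation in degrees.
#' @return Adjusted coordinates (same shape), as a matrix.
#' @export
scatter_points <- function(pts, min_sep) {
  p <- as.matrix(pts)
  n <- nrow(p)
  if (n < 2L || min_sep <= 0) return(p)
  # exactly coincident groups: spread on a circle whose chord between
  # adjacent points equals min_sep (single pass, deterministic)
  key <- paste(sprintf("%.12f", p[, 1L]), sprintf("%.12f", p[, 2L]))
  for (grp in split(seq_len(n), key)) {
    g <- length(grp)
    if (g < 2L) next
    r <- min_sep / (2 * sin(pi / g)) * 1.01
    ang <- 2 * pi * (seq_len(g) - 1L) / g
    p[grp, 1L] <- p[grp, 1L] + r * cos(ang)
    p[grp, 2L] <- p[grp, 2L] + r * sin(ang)
  }
  for (iter in seq_len(1000L)) {
    d <- as.matrix(dist(p))
    diag(d) <- Inf
    conflict <- which(d < min_sep, arr.ind = TRUE)
    conflict <- conflict[conflict[, 1L] < conflict[, 2L], , drop = FALSE]
    if (!nrow(conflict)) break
    for (r in seq_len(nrow(conflict))) {
      i <- conflict[r, 1L]; j <- conflict[r, 2L]
      v <- p[j, ] - p[i, ]
      dd <- sqrt(sum(v^2))
      if (dd < 1e-12) {               # re-coincident: deterministic angle
        ang <- 2 * pi * ((i * 31L + j) %% 360) / 360
        v <- c(cos(ang), sin(ang))
      } else v <- v / dd
      push <- (min_sep - dd) / 2 * 1.05
      p[i, ] <- p[i, ] - v * push
      p[j, ] <- p[j, ] + v * push
    }
  }
  p
}

#' Map genotype occurrence over an environmental background
#'
#' Draws sample locations (displaced with [scatter_points()] when they
#' overlap), filled where the genotype indicator is present, open where
#' absent, optionally over a raster background and sized by a population
#' -structure variable.
#'
#' @param pts (lon, lat) coordinates.
#' @param indicator binary presence/absence vector.
#' @param raster optional `RasterGrid` background.
#' @param popvar optional numeric population-structure value per sample.
#' @param min_sep separation for overlap displacement (degrees).
#' @param out output PNG path.
#' @return `out` invisibly.
#' @export
genotype_map <- function(pts, indicator, raster = NULL, popvar = NULL,
                         min_sep = 0, out = "map.png") {
  p <- as.matrix(pts)
  if (!nrow(p)) stop("no points to map")
  stopifnot(length(indicator) == nrow(p))
  if (min_sep > 0) p <- scatter_points(p, min_sep)
  grDevices::png(out, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  xlim <- range(p[, 1L]); ylim <- range(p[, 2L])
  if (!is.null(raster)) {
    nr <- nrow(raster$values); nc <- ncol(raster$values)
    xs <- raster$origin[1L] + (seq_len(nc) - 0.5) * raster$cellsize[1L]
    ys <- raster$origin[2L] - (seq_len(nr) - 0.5) * raster$cellsize[2L]
    graphics::image(xs, rev(ys), t(raster$values[nr:1, , drop = FALSE]),
                    col = grDevices::hcl.colors(20, "Terrain"),
                    xlab = "longitude", ylab = "latitude",
                    xlim = xlim, ylim = ylim)
  } else {
    plot(NA, xlim = xlim, ylim = ylim, xlab = "longitude",
         ylab = "latitude")
  }
  cex <- if (is.null(popvar)) rep(1.2, nrow(p)) else
    1 + 1.5 * (popvar - min(popvar, na.rm = TRUE)) /
    max(diff(range(popvar, na.rm = TRUE)), 1e-12)
  pch <- ifelse(is.na(indicator), 4L, ifelse(indicator > 0, 19L, 1L))
  graphics::points(p[, 1L], p[, 2L], pch = pch, cex = cex, col = "black")
  invisible(out)
}
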
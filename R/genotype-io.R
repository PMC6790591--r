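#' Construct a genotype matrix object
#'
#' A `GenotypeMatrix` holds diploid alt-allele dosages (0, 1, 2 or `NA` for a
#' missing call) for `samples` x SNPs, together with per-SNP metadata
#' (name, chromosome, 1-based position, ref and alt allele).
#'
#' @param calls integer matrix, samples in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param samples character vector of unique sample IDs (row order of `calls`).
#' @param snps data.frame with columns `name`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per column of `calls`; SNP names unique, positions >= 0.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.character(samples)
  stopifnot(is.data.frame(snps))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("name", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(snps)))
    stop("snps must have columns: ", paste(req, collapse = ", "))
  if (nrow(calls) != length(samples))
    stop("nrow(calls) must equal length(samples)")
  if (ncol(calls) != nrow(snps))
    stop("ncol(calls) must equal nrow(snps)")
  if (anyDuplicated(samples)) stop("duplicate sample IDs")
  if (anyDuplicated(snps$name)) stop("duplicate SNP names")
  if (any(!is.na(snps$pos) & snps$pos < 0)) stop("negative SNP position")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("calls must be 0, 1, 2 or NA")
  rownames(calls) <- samples
  colnames(calls) <- snps$name
  structure(list(samples = samples, snps = snps, calls = calls),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs (%.1f%% missing)\n",
              length(x$samples), nrow(x$snps),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$calls)

#' Subset a GenotypeMatrix by SNP index
#' @param g GenotypeMatrix.
#' @param keep logical or integer index over SNPs.
#' @return GenotypeMatrix restricted to the selected SNPs.
#' @keywords internal
subset_snps <- function(g, keep) {
  genotype_matrix(g$calls[, keep, drop = FALSE], g$samples,
                  g$snps[keep, , drop = FALSE])
}

#' Read genotypes from VCF or PED/MAP
#'
#' Reads biallelic SNPs into a [genotype_matrix()]. Multi-allelic sites and
#' non-SNP records (indels, symbolic alleles) are skipped; the number skipped
#' is reported via `message()` and attached as attribute `n_skipped`.
#'
#' For PED/MAP input the `.map` file is located by replacing the `.ped`
#' extension (or pass `map` explicitly). PED carries no ref/alt designation:
#' the reference allele of each SNP is defined as the first non-missing
#' allele encountered in file order (row-major), the alternate as the second.
#'
#' @param path path to a `.vcf` (plain or bgzipped) or `.ped` file.
#' @param format `"vcf"` or `"ped"`.
#' @param map optional path to the `.map` file for PED input.
#' @return A `GenotypeMatrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "ped"), map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  g <- switch(format,
              vcf = .read_vcf(path),
              ped = .read_ped(path, map))
  if (ncol(g$calls) == 0L) stop("no biallelic SNPs found in ", path)
  g
}

.read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  is_snp <- n_alt == 1L & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message(n_skip, " multi-allelic or non-SNP record(s) skipped")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- gt[is_snp, , drop = FALSE]
  ds <- .gt_to_dosage(gt)            # SNPs x samples
  nm <- rownames(gt)
  if (is.null(nm)) nm <- paste0("snp", seq_len(nrow(gt)))
  snps <- data.frame(
    name = nm,
    chrom = as.character(GenomicRanges::seqnames(rr))[is_snp],
    pos = GenomicRanges::start(rr)[is_snp],
    ref = ref[is_snp], alt = alt[is_snp],
    stringsAsFactors = FALSE)
  g <- genotype_matrix(t(ds), colnames(gt), snps)
  attr(g, "n_skipped") <- n_skip
  g
}

.gt_to_dosage <- function(gt) {
  # strip phasing, count "1" alleles; any "." -> NA
  d <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  idx <- match(gt, names(known))
  d[] <- known[idx]
  d
}

.read_ped <- function(path, map = NULL) {
  if (is.null(map)) map <- sub("\\.ped$", ".map", path)
  if (!file.exists(map)) stop("MAP file not found: ", map)
  mp <- data.table::fread(map, header = FALSE, data.table = FALSE)
  # MAP: chrom, snp name, genetic distance (optional), position
  if (ncol(mp) == 3L) mp$V4 <- mp$V3
  m <- nrow(mp)
  pd <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          colClasses = "character")
  if (ncol(pd) != 6L + 2L * m)
    stop("PED column count ", ncol(pd), " does not match MAP (",
         6L + 2L * m, " expected)")
  samples <- pd[[2L]]
  n <- nrow(pd)
  calls <- matrix(NA_integer_, n, m)
  ref <- alt <- rep(NA_character_, m)
  keep <- rep(TRUE, m)
  for (j in seq_len(m)) {
    a1 <- pd[[6L + 2L * j - 1L]]
    a2 <- pd[[6L + 2L * j]]
    als <- c(rbind(a1, a2))               # file order within the column pair
    obs <- als[als != "0"]
    uq <- unique(obs)
    if (length(uq) > 2L) { keep[j] <- FALSE; next }
    ref[j] <- if (length(uq) >= 1L) uq[1L] else NA_character_
    alt[j] <- if (length(uq) == 2L) uq[2L] else NA_character_
    d <- (a1 != "0" & a1 == alt[j]) + (a2 != "0" & a2 == alt[j])
    d[a1 == "0" | a2 == "0"] <- NA_integer_
    if (is.na(alt[j])) d[!is.na(d)] <- 0L   # monomorphic: dosage 0
    calls[, j] <- as.integer(d)
  }
  if (any(!keep))
    message(sum(!keep), " multi-allelic or non-SNP record(s) skipped")
  snps <- data.frame(name = as.character(mp[[2L]]),
                     chrom = as.character(mp[[1L]]),
                     pos = as.integer(mp[[4L]]),
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  g <- genotype_matrix(calls[, keep, drop = FALSE], samples,
                       snps[keep, , drop = FALSE])
  attr(g, "n_skipped") <- sum(!keep)
  g
}

#' Per-SNP minor allele frequency
#'
#' MAF = min(p, 1 - p) with p the alt-allele frequency over non-missing
#' calls. SNPs with no non-missing call get `NA`.
#'
#' @param g GenotypeMatrix.
#' @return Named numeric vector in \[0, 0.5\], one entry per SNP.
#' @export
compute_maf <- function(g) {
  n_obs <- colSums(!is.na(g$calls))
  p <- colSums(g$calls, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0L] <- NA_real_
  setNames(pmin(p, 1 - p), g$snps$name)
}

#' Per-SNP missing-call proportion
#' @param g GenotypeMatrix.
#' @return Named numeric vector in \[0, 1\].
#' @export
compute_missingness <- function(g) {
  setNames(colMeans(is.na(g$calls)), g$snps$name)
}

#' Quality-control thresholds
#'
#' @param maf_min minimum minor allele frequency, in \[0, 0.5\].
#' @param missing_max maximum per-SNP missing proportion, in \[0, 1\].
#' @param ld_r2_max squared-correlation ceiling for LD pruning, in \[0, 1\],
#'   or `"off"` to disable pruning.
#' @param ld_window sliding-window width in SNPs for LD pruning.
#' @return An object of class `QCThresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, missing_max = 0.1,
                          ld_r2_max = "off", ld_window = 50L) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            missing_max >= 0, missing_max <= 1)
  if (!identical(ld_r2_max, "off"))
    stopifnot(is.numeric(ld_r2_max), ld_r2_max >= 0, ld_r2_max <= 1)
  stopifnot(ld_window >= 2)
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 ld_r2_max = ld_r2_max, ld_window = as.integer(ld_window)),
            class = "QCThresholds")
}

#' Apply genotype quality control
#'
#' Keeps SNPs with MAF >= `maf_min` and missing proportion <= `missing_max`,
#' then LD-prunes the survivors (see [ld_prune()]) unless `ld_r2_max` is
#' `"off"`. MAF and missingness are evaluated on the input matrix, before
#' pruning.
#'
#' @param g GenotypeMatrix.
#' @param thresholds a [qc_thresholds()] object.
#' @return The filtered `GenotypeMatrix` with attribute `qc_report`: a list
#'   with per-criterion 20-bin histograms of the pre-filter distributions and
#'   discarded counts (`n_maf`, `n_missing`, `n_ld`).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  t <- thresholds
  maf <- compute_maf(g)
  mis <- compute_missingness(g)
  pass_maf <- !is.na(maf) & maf >= t$maf_min
  pass_mis <- mis <= t$missing_max
  keep <- pass_maf & pass_mis
  report <- list(
    hist_maf = graphics::hist(maf, breaks = seq(0, 0.5, length.out = 21),
                              plot = FALSE),
    hist_missing = graphics::hist(mis, breaks = seq(0, 1, length.out = 21),
                                  plot = FALSE),
    n_input = ncol(g$calls),
    n_maf = sum(!pass_maf),
    n_missing = sum(!pass_mis),
    n_ld = 0L)
  if (!any(keep)) {
    attr(report, "fatal") <- TRUE
    stop("all SNPs removed by QC (", report$n_maf, " by MAF, ",
         report$n_missing, " by missingness)")
  }
  out <- subset_snps(g, keep)
  if (!identical(t$ld_r2_max, "off")) {
    pruned <- ld_prune(out, t$ld_r2_max, t$ld_window)
    report$n_ld <- ncol(out$calls) - ncol(pruned$calls)
    out <- pruned
  }
  report$n_retained <- ncol(out$calls)
  attr(out, "qc_report") <- report
  out
}

#' Window-based LD pruning
#'
#' SNPs are scanned in (chromosome, position) order. Within every window of
#' `window` consecutive retained SNPs on the same chromosome, whenever a pair
#' has squared Pearson correlation of dosages (pairwise-complete) exceeding
#' `r2_max`, the downstream SNP (greater position) is dropped. Scanning
#' repeats until the retained set is stable, so the output contains no
#' same-window pair above the threshold.
#'
#' @param g GenotypeMatrix, SNPs sorted by (chromosome, position).
#' @param r2_max squared-correlation ceiling in \[0, 1\].
#' @param window window width in retained-SNP count.
#' @return Pruned `GenotypeMatrix`.
#' @export
ld_prune <- function(g, r2_max, window = 50L) {
  m <- ncol(g$calls)
  if (m < 2L) return(g)
  ord <- order(g$snps$chrom, g$snps$pos)
  if (!identical(ord, seq_len(m))) g <- subset_snps(g, ord)
  chrom <- g$snps$chrom
  x <- g$calls
  keep <- rep(TRUE, m)
  repeat {
    dropped <- FALSE
    idx <- which(keep)
    k <- length(idx)
    for (a in seq_len(k - 1L)) {
      i <- idx[a]
      if (!keep[i]) next
      bmax <- min(k, a + window - 1L)
      for (b in (a + 1L):bmax) {
        j <- idx[b]
        if (!keep[j] || chrom[j] != chrom[i]) next
        r <- suppressWarnings(
          cor(x[, i], x[, j], use = "pairwise.complete.obs"))
        if (!is.na(r) && r * r > r2_max) {
          keep[j] <- FALSE
          dropped <- TRUE
        }
      }
    }
    if (!dropped) break
  }
  subset_snps(g, keep)
}

#' Encode genotypes as binary presence/absence indicators
#'
#' Each SNP yields exactly three indicators, one per diploid genotype class
#' (homozygous ref, heterozygous, homozygous alt), labelled
#' `"<snp>_<alleles>"` (e.g. `rs1_AA`, `rs1_AG`, `rs1_GG`). A non-missing
#' call sets exactly one of the three to 1; a missing call sets all three to
#' `NA`. Classes absent from the data still get a (constant-zero) indicator;
#' the scoring engine skips those as degenerate.
#'
#' @param g GenotypeMatrix.
#' @return An object of class `IndicatorSet`: list with `indicators`
#'   (data.frame: `snp`, `class`, `label`) and `values` (samples x
#'   indicators integer matrix in \{0, 1, NA\}).
#' @export
encode_indicators <- function(g) {
  m <- ncol(g$calls)
  if (m == 0L) stop("empty GenotypeMatrix")
  ref <- g$snps$ref
  alt <- g$snps$alt
  alt[is.na(alt)] <- "?"
  classes <- c("homRef", "het", "homAlt")
  lab <- as.vector(rbind(paste0(g$snps$name, "_", ref, ref),
                         paste0(g$snps$name, "_", ref, alt),
                         paste0(g$snps$name, "_", alt, alt)))
  ind <- data.frame(snp = rep(g$snps$name, each = 3L),
                    class = rep(classes, m),
                    label = lab, stringsAsFactors = FALSE)
  vals <- matrix(NA_integer_, nrow(g$calls), 3L * m)
  for (cls in 0:2) {
    cols <- seq(1L + cls, by = 3L, length.out = m)
    vals[, cols] <- ifelse(is.na(g$calls), NA_integer_,
                           as.integer(g$calls == cls))
  }
  rownames(vals) <- g$samples
  colnames(vals) <- lab
  indicator_set(ind, vals, g$samples)
}

#' Construct an IndicatorSet
#' @param indicators data.frame with columns `snp`, `class`, `label`.
#' @param values samples x indicators matrix in \{0, 1, NA\}.
#' @param samples sample IDs, matching rows of `values`.
#' @return `IndicatorSet` object.
#' @export
indicator_set <- function(indicators, values, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  stopifnot(nrow(indicators) == ncol(values),
            length(samples) == nrow(values))
  ok <- values[!is.na(values)]
  if (length(ok) && !all(ok %in% 0:1)) stop("indicator values must be 0/1/NA")
  rownames(values) <- samples
  colnames(values) <- indicators$label
  structure(list(indicators = as.data.frame(indicators), values = values,
                 samples = as.character(samples)),
            class = "IndicatorSet")
}

#' @export
print.IndicatorSet <- function(x, ...) {
  cat(sprintf("IndicatorSet: %d samples x %d indicators (%d SNPs)\n",
              length(x$samples), ncol(x$values),
              length(unique(x$indicators$snp))))
  invisible(x)
}

#' Write / read the whitespace-separated indicator interchange format
#'
#' The interchange dialect is plain text: a header row of indicator labels
#' preceded by `ID`, then one row per sample with the sample ID and 0/1
#' values; missing values are written as `NaN`. The reader tolerates runs of
#' spaces and tabs.
#'
#' @param ind IndicatorSet.
#' @param path output (input) file path.
#' @return `write_sambada_format()` returns `path` invisibly;
#'   `read_sambada_format()` returns an `IndicatorSet`.
#' @export
write_sambada_format <- function(ind, path) {
  v <- ind$values
  txt <- matrix(as.character(v), nrow(v), ncol(v))
  txt[is.na(v)] <- .MISSING_TOKEN
  lines <- c(paste(c("ID", ind$indicators$label), collapse = " "),
             paste(ind$samples, apply(txt, 1L, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sambada_format
#' @export
read_sambada_format <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  hdr <- toks[[1L]]
  if (hdr[1L] != "ID") stop("malformed header (line 1): first column must be ID")
  labels <- hdr[-1L]
  m <- length(labels)
  body <- toks[-1L]
  body <- body[lengths(body) > 0L]
  n <- length(body)
  vals <- matrix(NA_integer_, n, m)
  samples <- character(n)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != m + 1L)
      stop("row length mismatch at line ", i + 1L, ": got ",
           length(row), " fields, expected ", m + 1L)
    samples[i] <- row[1L]
    v <- row[-1L]
    num <- suppressWarnings(as.integer(v))
    num[v == .MISSING_TOKEN] <- NA_integer_
    if (any(is.na(num) & v != .MISSING_TOKEN))
      stop("non-numeric value at line ", i + 1L)
    vals[i, ] <- num
  }
  parts <- .parse_indicator_labels(labels)
  indicator_set(parts, vals, samples)
}

# Recover (snp, class) from "<snp>_<GG>" labels. Class order within a SNP is
# positional: indicators appear in homRef, het, homAlt triples.
.parse_indicator_labels <- function(labels) {
  snp <- sub("_[^_]*$", "", labels)
  classes <- rep(c("homRef", "het", "homAlt"), length.out = length(labels))
  data.frame(snp = snp, class = classes, label = labels,
             stringsAsFactors = FALSE)
}
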
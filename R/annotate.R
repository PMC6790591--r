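#' Read gene records from a GFF3 file
#'
#' Keeps features of the requested type (default `gene`), returning 1-based
#' inclusive coordinates. The gene identifier is taken from the `Name`
#' attribute, falling back to `ID`.
#'
#' @param path GFF3 file path.
#' @param feature_type feature type(s) to keep.
#' @return data.frame of `GeneRecord`s: `gene`, `chrom`, `start`, `end`,
#'   `strand`, sorted by (chrom, start).
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  gene <- ifelse(is.na(nm) | nm == "", id, nm)
  out <- data.frame(gene = gene,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Overlapping and nearest genes for candidate SNPs
#'
#' For each SNP, reports genes overlapping its position (distance 0) and the
#' nearest gene within `window` base pairs: distance is 0 inside the gene
#' span, otherwise the gap to the nearer gene end; equidistant genes are all
#' reported. SNPs on chromosomes absent from the annotation get an empty
#' result with a note.
#'
#' @param snps data.frame with columns `name`, `chrom`, `pos`.
#' @param genes gene table from [read_gff3_genes()].
#' @param window maximum distance in bp (default 100000).
#' @return data.frame: `snp`, `chrom`, `pos`, `gene`, `distance`, `note`
#'   (one row per reported gene; one NA-gene row for SNPs with no gene in
#'   range).
#' @export
nearest_genes <- function(snps, genes, window = 100000) {
  rows <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    chrom <- as.character(snps$chrom[i])
    pos <- snps$pos[i]
    base <- data.frame(snp = snps$name[i], chrom = chrom, pos = pos,
                       gene = NA_character_, distance = NA_real_,
                       note = "", stringsAsFactors = FALSE)
    if (!chrom %in% genes$chrom) {
      base$note <- "chromosome absent from annotation"
      rows[[i]] <- base
      next
    }
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    d <- gene_distance(pos, g$start, g$end)
    inrange <- which(d <= window)
    if (!length(inrange)) {
      base$note <- "no gene within window"
      rows[[i]] <- base
      next
    }
    dmin <- min(d[inrange])
    hit <- unique(inrange[d[inrange] == 0 | d[inrange] == dmin])
    rows[[i]] <- data.frame(snp = snps$name[i], chrom = chrom, pos = pos,
                            gene = g$gene[hit], distance = d[hit],
                            note = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SNP-to-gene distance
#'
#' 0 when `pos` lies inside `[start, end]` (1-based inclusive), otherwise
#' `min(|pos - start|, |pos - end|)`. Vectorised over genes.
#'
#' @param pos SNP position.
#' @param start,end gene span.
#' @return Numeric distance(s) in bp.
#' @export
gene_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos <= end, 0,
         pmin(abs(pos - start), abs(pos - end)))
}

#' Coarse variant context classification
#'
#' `genic` when the position falls inside a gene span; otherwise
#' `upstream`/`downstream` of the nearest strand-aware gene within `window`
#' (upstream = 5' side given the gene's strand); `intergenic` when no gene
#' lies within `window`.
#'
#' @param chrom,pos SNP location.
#' @param genes gene table from [read_gff3_genes()].
#' @param window context window in bp (default 100000).
#' @return One of `"genic"`, `"upstream"`, `"downstream"`, `"intergenic"`.
#' @export
classify_context <- function(chrom, pos, genes, window = 100000) {
  g <- genes[genes$chrom == as.character(chrom), , drop = FALSE]
  if (!nrow(g)) return("intergenic")
  inside <- pos >= g$start & pos <= g$end
  if (any(inside)) return("genic")
  d <- pmin(abs(pos - g$start), abs(pos - g$end))
  if (min(d) > window) return("intergenic")
  ng <- g[which.min(d), ]
  before <- pos < ng$start
  plus <- !identical(ng$strand, "-")
  if ((before && plus) || (!before && !plus)) "upstream" else "downstream"
}
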
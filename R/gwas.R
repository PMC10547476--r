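# SNP-to-gene assignment for glycemic-trait GWAS hits: gene-body /
# flanking-window containment and promoter-capture HiC loop contacts.
# Genes are BED-style 0-based half-open on disk and GRanges 1-based
# internally; SNP positions are 1-based throughout.

as_gene_granges <- function(genes) {
  if (inherits(genes, "GRanges")) return(genes)
  str <- if ("strand" %in% names(genes)) genes$strand else "*"
  str[!str %in% c("+", "-")] <- "*"  # BED uses "." for unstranded
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = str)
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  for (cc in intersect(c("promoter_start", "promoter_end"), names(genes))) {
    S4Vectors::mcols(gr)[[cc]] <- genes[[cc]]
  }
  gr
}

as_snp_granges <- function(snps) {
  gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(snps[setdiff(names(snps),
                                                            c("chrom", "pos"))])
  S4Vectors::mcols(gr)$pos <- snps$pos
  gr
}

#' Promoter anchor intervals for genes
#'
#' Uses explicit `promoter_start`/`promoter_end` columns (0-based half-open,
#' e.g. from promoter-capture data) when present; otherwise derives TSS +/-
#' `flank` bp from the strand. Genes without strand or promoter columns get no
#' anchor and are ineligible for loop assignment.
#'
#' @param genes Gene table (`chrom,start,end,gene_id,strand`, 0-based
#'   half-open) or a `GRanges` with a `gene_id` column.
#' @param flank Half-width of the derived promoter window, bp (default 2000).
#' @return `GRanges` of promoter anchors with a `gene_id` column.
#' @export
promoter_anchors <- function(genes, flank = 2000) {
  gr <- as_gene_granges(genes)
  mc <- S4Vectors::mcols(gr)
  if (all(c("promoter_start", "promoter_end") %in% names(mc)) &&
      !anyNA(mc$promoter_start)) {
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                  IRanges::IRanges(mc$promoter_start + 1L,
                                                   mc$promoter_end))
    S4Vectors::mcols(out)$gene_id <- mc$gene_id
    return(out)
  }
  str <- as.character(BiocGenerics::strand(gr))
  keep <- str %in% c("+", "-")
  gr <- gr[keep]
  str <- str[keep]
  tss <- ifelse(str == "+", BiocGenerics::start(gr), BiocGenerics::end(gr))
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::IRanges(pmax(1L, tss - flank),
                                                 tss + flank))
  S4Vectors::mcols(out)$gene_id <- S4Vectors::mcols(gr)$gene_id
  out
}

#' Filter SNPs by genome-wide significance
#'
#' Retains SNPs with `-log10(p)` strictly greater than the cutoff, so a SNP at
#' exactly `p = 10^-cutoff` is dropped.
#'
#' @param snps SNP table (`chrom, pos, rsid, pvalue, trait`).
#' @param neg_log10_cutoff Significance line on the `-log10(p)` scale
#'   (default 8, i.e. `p < 1e-8`).
#' @return The passing rows of `snps`.
#' @export
filter_snps <- function(snps, neg_log10_cutoff = 8) {
  if (any(snps$pvalue <= 0) || any(snps$pvalue > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  snps[-log10(snps$pvalue) > neg_log10_cutoff, , drop = FALSE]
}

#' Assign SNPs to genes by body or flanking-window containment
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within the
#' gene body extended by `window_kbp` on each side (a single widened interval,
#' not two disjoint flanks). Route is `body` inside the gene proper, `window`
#' in the flank.
#'
#' @param snps SNP table (1-based `pos`).
#' @param genes Gene table (0-based half-open) or `GRanges`.
#' @param window_kbp Flanking window in kbp (default 100).
#' @return Data frame: `gene_id, rsid, route, chrom, pos, pvalue, trait`.
#' @export
assign_window <- function(snps, genes, window_kbp = 100) {
  if (window_kbp < 0) stop("window_kbp must be non-negative")
  ggr <- as_gene_granges(genes)
  empty <- data.frame(gene_id = character(), rsid = character(),
                      route = character(), chrom = character(),
                      pos = integer(), pvalue = numeric(), trait = character(),
                      stringsAsFactors = FALSE)
  if (nrow(snps) == 0L || length(ggr) == 0L) return(empty)
  sgr <- as_snp_granges(snps)
  wbp <- round(window_kbp * 1000)
  ext <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(ggr),
    IRanges::IRanges(pmax(1L, BiocGenerics::start(ggr) - wbp),
                     BiocGenerics::end(ggr) + wbp))
  hits <- GenomicRanges::findOverlaps(sgr, ext, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  body <- GenomicRanges::findOverlaps(sgr, ggr, ignore.strand = TRUE)
  body_key <- paste(S4Vectors::queryHits(body), S4Vectors::subjectHits(body))
  data.frame(gene_id = S4Vectors::mcols(ggr)$gene_id[gi],
             rsid = snps$rsid[si],
             route = ifelse(paste(si, gi) %in% body_key, "body", "window"),
             chrom = snps$chrom[si], pos = snps$pos[si],
             pvalue = snps$pvalue[si], trait = snps$trait[si],
             stringsAsFactors = FALSE)
}

#' Assign SNPs to genes via promoter-capture loop contacts
#'
#' A SNP is assigned to a gene when some loop has one anchor overlapping the
#' gene's promoter anchor and the other anchor containing the SNP position
#' (exact containment; both loop orientations are checked). Genes without a
#' promoter anchor are silently ineligible.
#'
#' @param snps SNP table (1-based `pos`).
#' @param genes Gene table or `GRanges`.
#' @param loops Loop table (`chrom1,start1,end1,chrom2,start2,end2`, 0-based
#'   half-open BEDPE intervals).
#' @param promoter_flank Fallback TSS flank passed to [promoter_anchors()].
#' @return Data frame: `gene_id, rsid, route ("loop"), chrom, pos, pvalue,
#'   trait`.
#' @export
assign_loops <- function(snps, genes, loops, promoter_flank = 2000) {
  empty <- data.frame(gene_id = character(), rsid = character(),
                      route = character(), chrom = character(),
                      pos = integer(), pvalue = numeric(), trait = character(),
                      stringsAsFactors = FALSE)
  if (is.null(loops) || nrow(loops) == 0L || nrow(snps) == 0L) return(empty)
  prom <- promoter_anchors(genes, flank = promoter_flank)
  if (!length(prom)) return(empty)
  sgr <- as_snp_granges(snps)
  anchor <- function(chrom, start, end) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, pmax(end, start + 1L)))
  }
  a1 <- anchor(loops$chrom1, loops$start1, loops$end1)
  a2 <- anchor(loops$chrom2, loops$start2, loops$end2)
  pairs <- NULL
  for (ori in 1:2) {
    pa <- if (ori == 1L) a1 else a2
    da <- if (ori == 1L) a2 else a1
    ph <- GenomicRanges::findOverlaps(prom, pa, ignore.strand = TRUE)
    if (!length(ph)) next
    sh <- GenomicRanges::findOverlaps(sgr, da, ignore.strand = TRUE)
    if (!length(sh)) next
    pm <- data.frame(gene = S4Vectors::queryHits(ph), loop = S4Vectors::subjectHits(ph))
    sm <- data.frame(snp = S4Vectors::queryHits(sh), loop = S4Vectors::subjectHits(sh))
    pairs <- rbind(pairs, merge(pm, sm, by = "loop")[c("gene", "snp")])
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  pairs <- unique(pairs)
  data.frame(gene_id = S4Vectors::mcols(prom)$gene_id[pairs$gene],
             rsid = snps$rsid[pairs$snp],
             route = "loop",
             chrom = snps$chrom[pairs$snp], pos = snps$pos[pairs$snp],
             pvalue = snps$pvalue[pairs$snp], trait = snps$trait[pairs$snp],
             stringsAsFactors = FALSE)
}

#' Nominate candidate genes from GWAS SNPs
#'
#' Applies the significance filter, assigns the passing SNPs to genes through
#' the flanking-window and loop routes, deduplicates gene-SNP pairs (a pair
#' supported by both routes is recorded once with both routes), and summarises
#' one record per nominated gene.
#'
#' @param snps SNP table (`chrom, pos, rsid, pvalue, trait`).
#' @param genes Gene table or `GRanges`.
#' @param loops Optional loop table (`NULL` disables the loop route).
#' @param cutoff Significance line, `-log10(p)` scale (default 8, strict).
#' @param window_kbp Flanking window in kbp (default 100).
#' @param promoter_flank Fallback promoter half-width, bp.
#' @return Data frame, one row per nominated gene: `gene_id, n_snps, routes,
#'   traits, best_neg_log10_p`, with the SNP-level assignment table attached
#'   as attribute `"assignments"`.
#' @export
nominate <- function(snps, genes, loops = NULL, cutoff = 8, window_kbp = 100,
                     promoter_flank = 2000) {
  known <- c(glycemic_traits(), paste0(glycemic_traits(), " (BMI-adjusted)"))
  unknown <- setdiff(unique(snps$trait), known)
  if (length(unknown)) {
    warning("unknown trait label(s): ", paste(unknown, collapse = ", "))
  }
  pass <- filter_snps(snps, cutoff)
  asg <- rbind(assign_window(pass, genes, window_kbp),
               assign_loops(pass, genes, loops, promoter_flank))
  if (nrow(asg)) {
    # one row per gene-SNP pair; collapse multiple routes
    key <- paste(asg$gene_id, asg$rsid)
    routes <- vapply(split(asg$route, key), function(r) {
      paste(sort(unique(r)), collapse = "+")
    }, character(1))
    asg <- asg[!duplicated(key), , drop = FALSE]
    asg$route <- routes[paste(asg$gene_id, asg$rsid)]
    asg <- asg[order(asg$gene_id, asg$rsid), , drop = FALSE]
    rownames(asg) <- NULL
  }
  if (nrow(asg) == 0L) {
    out <- data.frame(gene_id = character(), n_snps = integer(),
                      routes = character(), traits = character(),
                      best_neg_log10_p = numeric(), stringsAsFactors = FALSE)
    attr(out, "assignments") <- asg
    return(out)
  }
  sp <- split(asg, asg$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_snps = vapply(sp, nrow, integer(1)),
    routes = vapply(sp, function(d) {
      paste(sort(unique(unlist(strsplit(d$route, "+", fixed = TRUE)))),
            collapse = "+")
    }, character(1)),
    traits = vapply(sp, function(d) {
      paste(sort(unique(d$trait)), collapse = ";")
    }, character(1)),
    best_neg_log10_p = vapply(sp, function(d) max(-log10(d$pvalue)), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "assignments") <- asg
  out
}

#' Read gene intervals from a BED file
#'
#' BED6 (0-based half-open); the `name` field becomes `gene_id`.
#'
#' @param path BED path.
#' @return Gene data frame (`chrom, start, end, gene_id, score, strand`).
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             gene_id = S4Vectors::mcols(gr)$name,
             score = S4Vectors::mcols(gr)$score %||% 0L,
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_genes_bed
#' @param genes Gene data frame.
#' @export
write_genes_bed <- function(genes, path) {
  df <- genes[c("chrom", "start", "end", "gene_id")]
  df$score <- if ("score" %in% names(genes)) genes$score else 0L
  df$strand <- if ("strand" %in% names(genes)) genes$strand else "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a SNP table
#'
#' Tab-separated columns `chrom pos rsid pvalue trait`, 1-based positions.
#' Trait labels outside the glycemic vocabulary produce a warning on read,
#' not an error.
#'
#' @param path TSV path.
#' @return SNP data frame.
#' @export
read_snps_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  need <- c("chrom", "pos", "rsid", "pvalue", "trait")
  if (!all(need %in% names(df))) {
    stop("SNP table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$pvalue <= 0) || any(df$pvalue > 1)) stop("p-values must lie in (0, 1]")
  known <- c(glycemic_traits(), paste0(glycemic_traits(), " (BMI-adjusted)"))
  unknown <- setdiff(unique(df$trait), known)
  if (length(unknown)) {
    warning("unknown trait label(s): ", paste(unknown, collapse = ", "))
  }
  df[need]
}

#' @rdname read_snps_tsv
#' @param snps SNP data frame.
#' @export
write_snps_tsv <- function(snps, path) {
  utils::write.table(snps[c("chrom", "pos", "rsid", "pvalue", "trait")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write loop anchors as BEDPE
#'
#' First six BEDPE columns (`chrom1 start1 end1 chrom2 start2 end2`, 0-based
#' half-open); additional columns are ignored on read.
#'
#' @param path BEDPE path.
#' @return Loop data frame.
#' @export
read_loops_bedpe <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BEDPE needs at least 6 columns")
  df <- df[1:6]
  names(df) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  df
}

#' @rdname read_loops_bedpe
#' @param loops Loop data frame.
#' @export
write_loops_bedpe <- function(loops, path) {
  utils::write.table(loops[c("chrom1", "start1", "end1",
                             "chrom2", "start2", "end2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
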
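#' Annotate the genomic context of loci against gene/exon intervals
#'
#' Classifies each locus as intergenic, intronic, exonic, or mixed by
#' interval intersection with a user-supplied feature set, and reports the
#' orientation relative to the host gene (elements of this family show a
#' strong antisense bias inside coding genes).  Intervals are taken 1-based
#' inclusive at the interface; internal arithmetic is 0-based half-open.
#'
#' @param loci data.frame with columns \code{id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}/\code{NA}).
#' @param features data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{gene_id}, \code{feature_kind}
#'   (\code{"gene"} rows delimit gene bodies; \code{"exon"} rows their
#'   exons; introns are derived as gene minus exons).
#' @return data.frame: \code{id}, \code{relation}, \code{gene_id},
#'   \code{orientation}, \code{overlapped_features} (compact string).
#' @export
annotate_context <- function(loci, features) {
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(loci)),
            all(c("chrom", "start", "end", "strand", "gene_id",
                  "feature_kind") %in% names(features)))
  genes <- features[features$feature_kind == "gene", , drop = FALSE]
  exons <- features[features$feature_kind == "exon", , drop = FALSE]
  gr <- function(df) GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end),
    strand = ifelse(is.na(df$strand), "*", df$strand))
  g_genes <- gr(genes); g_exons <- gr(exons)
  ## intron parts: per gene, gene body minus its exons
  intron_list <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    body <- gr(genes[i, , drop = FALSE])
    ex <- g_exons[exons$gene_id == gid]
    ip <- GenomicRanges::setdiff(body, ex, ignore.strand = TRUE)
    if (length(ip)) S4Vectors::mcols(ip)$gene_id <- gid
    ip
  })
  g_introns <- if (length(intron_list)) do.call(c, intron_list)
               else GenomicRanges::GRanges()

  out <- lapply(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    row <- data.frame(id = lc$id, relation = "intergenic",
                      gene_id = NA_character_, orientation = "n/a",
                      overlapped_features = "", stringsAsFactors = FALSE)
    if (!lc$chrom %in% features$chrom) {
      warning("chromosome ", lc$chrom, " absent from features; locus ",
              lc$id, " reported intergenic", call. = FALSE)
      return(row)
    }
    gl <- GenomicRanges::GRanges(lc$chrom, IRanges::IRanges(lc$start, lc$end))
    hit_g <- GenomicRanges::findOverlaps(gl, g_genes, ignore.strand = TRUE)
    if (!length(hit_g)) return(row)
    ## host gene = maximal overlap
    gj <- S4Vectors::subjectHits(hit_g)
    ow <- vapply(gj, function(j) {
      iv <- GenomicRanges::pintersect(gl, g_genes[j])
      sum(GenomicRanges::width(iv))
    }, numeric(1))
    host <- gj[which.max(ow)]
    gid <- genes$gene_id[host]
    ex_host <- g_exons[exons$gene_id == gid]
    in_host <- g_introns[S4Vectors::mcols(g_introns)$gene_id == gid]
    n_ex <- length(GenomicRanges::findOverlaps(gl, ex_host,
                                               ignore.strand = TRUE))
    n_in <- length(GenomicRanges::findOverlaps(gl, in_host,
                                               ignore.strand = TRUE))
    row$relation <- if (n_ex > 0 && n_in > 0) "mixed"
                    else if (n_ex > 0) "exonic"
                    else "intronic"
    row$gene_id <- gid
    gstrand <- genes$strand[host]
    row$orientation <- if (is.na(lc$strand %||% NA) || is.na(gstrand)) "n/a"
                       else if (lc$strand == gstrand) "sense" else "antisense"
    feats <- character()
    if (n_ex > 0) feats <- c(feats, paste0("exon x", n_ex))
    if (n_in > 0) feats <- c(feats, paste0("intron x", n_in))
    row$overlapped_features <- paste(feats, collapse = ";")
    row
  })
  do.call(rbind, out)
}

#' Read gene/exon features from a GFF3 or BED file
#'
#' Thin wrapper over \pkg{rtracklayer} producing the data.frame layout that
#' [annotate_context()] expects.  BED input yields gene bodies only (no
#' exon structure).
#'
#' @param path GFF3 (\code{.gff}/\code{.gff3}) or BED file.
#' @return Feature data.frame.
#' @export
read_features <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read annotation files", call. = FALSE)
  x <- rtracklayer::import(path)
  df <- as.data.frame(x)
  kind <- if ("type" %in% names(df))
    ifelse(tolower(df$type) %in% c("exon"), "exon", "gene") else "gene"
  gene_id <- if ("gene_id" %in% names(df)) df$gene_id
             else if ("ID" %in% names(df)) df$ID
             else if ("name" %in% names(df)) df$name
             else paste0("feature", seq_len(nrow(df)))
  keep <- if ("type" %in% names(df))
    tolower(df$type) %in% c("gene", "exon") else rep(TRUE, nrow(df))
  data.frame(chrom = as.character(df$seqnames), start = df$start,
             end = df$end,
             strand = ifelse(df$strand == "*", NA, as.character(df$strand)),
             gene_id = gene_id, feature_kind = kind,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}
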
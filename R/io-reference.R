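#' Read and write reference FASTA
#'
#' Thin wrappers around Biostrings keeping the in-memory genome
#' representation (named character vector) used throughout the package.
#'
#' @param path FASTA file path.
#' @param genome named character vector of contig sequences.
#' @return `read_genome_fasta` returns a named character vector;
#'   `write_genome_fasta` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  if (length(out) && any(grepl("[^ACGTN]", out))) {
    stop_fmt("FASTA '%s': sequence contains characters outside A/C/G/T/N", path)
  }
  out
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features (1-based closed intervals) into
#' validated gene models. Exons must be sorted and non-overlapping, the CDS
#' must lie inside the exon union with total length divisible by 3; any
#' violation raises an error naming the offending gene.
#'
#' @param path GFF3 file path.
#' @return A list of gene models (see [new_gene_model()]).
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  if (!any(!startsWith(lines, "#") & nzchar(lines))) return(list())
  gff <- ape::read.gff(path, GFF3 = TRUE)
  attr_field <- function(attrs, key) {
    pat <- paste0("(^|;)", key, "=([^;]*)")
    m <- regexpr(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    hit <- m != -1L
    out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(attrs, m))
    out
  }
  gff$attributes <- as.character(gff$attributes)
  ids <- attr_field(gff$attributes, "ID")
  parents <- attr_field(gff$attributes, "Parent")

  is_mrna <- gff$type == "mRNA"
  tx2gene <- stats::setNames(parents[is_mrna], ids[is_mrna])
  gene_rows <- which(gff$type == "gene")
  genes <- vector("list", length(gene_rows))
  for (i in seq_along(gene_rows)) {
    r <- gene_rows[i]
    gid <- ids[r]
    tx <- names(tx2gene)[tx2gene == gid]
    child <- parents %in% c(gid, tx)
    ex <- gff[gff$type == "exon" & child, , drop = FALSE]
    cds <- gff[gff$type == "CDS" & child, , drop = FALSE]
    if (nrow(ex) == 0L) stop_fmt("gene %s: no exon features", gid)
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    genes[[i]] <- new_gene_model(
      gene_id = gid,
      contig = as.character(gff$seqid[r]),
      strand = as.character(gff$strand[r]),
      exons = cbind(ex$start, ex$end),
      cds = cbind(cds$start, cds$end,
                  as.integer(as.character(cds$phase)))
    )
  }
  genes
}

#' Write gene models to GFF3
#'
#' @param genes list of gene models.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    sp <- gene_span(g)
    tx <- paste0(g$gene_id, ".t1")
    lines <- c(
      sprintf("%s\tbsascreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$contig, sp[1], sp[2], g$strand, g$gene_id),
      sprintf("%s\tbsascreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$contig, sp[1], sp[2], g$strand, tx, g$gene_id),
      sprintf("%s\tbsascreen\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$contig, g$exons[, "start"], g$exons[, "end"], g$strand, tx),
      sprintf("%s\tbsascreen\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
              g$contig, g$cds[, "start"], g$cds[, "end"], g$strand,
              g$cds[, "phase"], tx)
    )
    writeLines(lines, con)
  }
  invisible(path)
}
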
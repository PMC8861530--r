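#' Construct and validate a gene model
#'
#' A gene model holds the contig, strand, exon intervals (1-based closed,
#' sorted, non-overlapping) and CDS intervals with GFF phase. Invariants:
#' the CDS lies within the exon union and its total length is divisible
#' by 3.
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param exons two-column matrix (`start`, `end`).
#' @param cds three-column matrix (`start`, `end`, `phase`).
#' @return A list of class `"gene_model"`.
#' @export
new_gene_model <- function(gene_id, contig, strand, exons, cds) {
  g <- list(gene_id = as.character(gene_id), contig = as.character(contig),
            strand = strand,
            exons = matrix(as.integer(exons), ncol = 2,
                           dimnames = list(NULL, c("start", "end"))),
            cds = matrix(as.integer(cds), ncol = 3,
                         dimnames = list(NULL, c("start", "end", "phase"))))
  class(g) <- "gene_model"
  validate_gene_model(g)
}

#' @rdname new_gene_model
#' @param g a gene model.
#' @export
validate_gene_model <- function(g) {
  ex <- g$exons
  if (nrow(ex) < 1L) stop_fmt("gene %s: at least one exon required", g$gene_id)
  if (!g$strand %in% c("+", "-")) {
    stop_fmt("gene %s: strand must be '+' or '-'", g$gene_id)
  }
  if (any(ex[, "end"] < ex[, "start"])) {
    stop_fmt("gene %s: exon end before start", g$gene_id)
  }
  if (is.unsorted(ex[, "start"], strictly = TRUE) && nrow(ex) > 1L) {
    stop_fmt("gene %s: exons must be sorted by start", g$gene_id)
  }
  if (nrow(ex) > 1L && any(ex[-1L, "start"] <= ex[-nrow(ex), "end"])) {
    stop_fmt("gene %s: exons overlap", g$gene_id)
  }
  cds <- g$cds
  if (nrow(cds) > 0L) {
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, "start"] >= ex[, "start"] & cds[i, "end"] <= ex[, "end"])
    }, logical(1))
    if (!all(inside)) {
      stop_fmt("gene %s: CDS segment outside the exon union", g$gene_id)
    }
    if (sum(cds[, "end"] - cds[, "start"] + 1L) %% 3L != 0L) {
      stop_fmt("gene %s: total CDS length not divisible by 3", g$gene_id)
    }
    if (any(!cds[, "phase"] %in% 0:2)) {
      stop_fmt("gene %s: CDS phase must be 0, 1 or 2", g$gene_id)
    }
  }
  g
}

gene_span <- function(g) c(g$exons[1L, "start"], g$exons[nrow(g$exons), "end"])

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), CDS %d bp\n",
              x$gene_id, x$contig, sp[1], sp[2], x$strand, nrow(x$exons),
              sum(x$cds[, "end"] - x$cds[, "start"] + 1L)))
  invisible(x)
}
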
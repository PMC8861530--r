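#' @rdname annotate_variants
#' @export
REGION_CATEGORIES <- c("Upstream", "Exonic-Stop gain", "Exonic-Stop loss",
                       "Exonic-Synonymous", "Exonic-Non-synonymous",
                       "Exonic", "Intronic", "Splicing", "Downstream",
                       "Upstream/Downstream", "Intergenic")

EFFECT_SEVERITY <- c("Stop gain" = 1, "Stop loss" = 2,
                     "Non-synonymous" = 3, "Synonymous" = 4)

# Relation of a position to one gene model: exon / splicing / intron /
# upstream / downstream / none (strand-aware, windows in bp).
site_gene_relation <- function(pos, g, upstream_window, downstream_window,
                               splice_window) {
  sp <- gene_span(g)
  if (pos >= sp[1] && pos <= sp[2]) {
    ex <- g$exons
    in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
    if (in_exon) return(list(rel = "exon", dist = 0L))
    # intron: distance to the nearest flanking exon boundary
    prev_end <- max(ex[ex[, "end"] < pos, "end"])
    next_start <- min(ex[ex[, "start"] > pos, "start"])
    d <- min(pos - prev_end, next_start - pos)
    return(list(rel = if (d <= splice_window) "splicing" else "intron",
                dist = 0L))
  }
  before <- pos < sp[1]
  gap <- if (before) sp[1] - pos else pos - sp[2]
  up <- (g$strand == "+" && before) || (g$strand == "-" && !before)
  if (up && gap <= upstream_window) return(list(rel = "upstream", dist = gap))
  if (!up && gap <= downstream_window) return(list(rel = "downstream", dist = gap))
  list(rel = "none", dist = gap)
}

#' Coding effect of a SNP inside a CDS
#'
#' Rebuilds the affected codon from the gene's CDS segments, phase and
#' strand (reverse-complementing on "-"), translates reference and
#' alternate codons with the standard genetic code, and classifies the
#' substitution.
#'
#' @param contig,pos,ref,alt the SNP (single-base alleles).
#' @param gene a gene model whose CDS contains `pos`.
#' @param genome named character vector of contig sequences.
#' @return One of "Synonymous", "Non-synonymous", "Stop gain", "Stop loss";
#'   `NA` if the affected codon is incomplete (phase-trimmed or trailing
#'   partial codon).
#' @export
coding_effect <- function(contig, pos, ref, alt, gene, genome) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  cds <- gene$cds[order(gene$cds[, "start"]), , drop = FALSE]
  seg <- which(pos >= cds[, "start"] & pos <= cds[, "end"])
  if (length(seg) == 0L) stop_fmt("position %d is not inside the CDS of %s",
                                  pos, gene$gene_id)
  seg <- seg[1L]
  seq <- genome[[contig]]
  cds_seq <- paste(substr(rep(seq, nrow(cds)), cds[, "start"], cds[, "end"]),
                   collapse = "")
  lens <- cds[, "end"] - cds[, "start"] + 1L
  if (gene$strand == "+") {
    tx <- cds_seq
    off <- sum(lens[seq_len(seg - 1L)]) + (pos - cds[seg, "start"] + 1L)
    first_phase <- cds[1L, "phase"]
    alt_tx <- alt
    ref_tx <- ref
  } else {
    tx <- revcomp(cds_seq)
    off <- sum(lens[-seq_len(seg)]) + (cds[seg, "end"] - pos + 1L)
    first_phase <- cds[nrow(cds), "phase"]
    alt_tx <- revcomp(alt)
    ref_tx <- revcomp(ref)
  }
  tx_pos <- off - first_phase
  if (tx_pos < 1L) return(NA_character_)
  codon_start <- ((tx_pos - 1L) %/% 3L) * 3L + 1L
  within <- (tx_pos - 1L) %% 3L + 1L
  codon <- substr(tx, codon_start + first_phase, codon_start + first_phase + 2L)
  if (nchar(codon) < 3L) return(NA_character_)
  if (substr(codon, within, within) != ref_tx) {
    warning(sprintf("reference allele mismatch at %s:%d in %s",
                    contig, pos, gene$gene_id), call. = FALSE)
  }
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_tx
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[codon])
  alt_aa <- unname(code[alt_codon])
  if (is.na(ref_aa) || is.na(alt_aa)) return(NA_character_)
  if (ref_aa == alt_aa) "Synonymous"
  else if (alt_aa == "*") "Stop gain"
  else if (ref_aa == "*") "Stop loss"
  else "Non-synonymous"
}

in_cds <- function(pos, gene) {
  any(pos >= gene$cds[, "start"] & pos <= gene$cds[, "end"])
}

#' Classify one variant against the gene models
#'
#' Assigns exactly one region category with precedence
#' exonic > splicing > intronic > upstream/downstream > intergenic. A site
#' upstream of one gene and downstream of another receives the combined
#' "Upstream/Downstream" class. SNPs in a CDS get the coding-effect
#' subclass; InDels in a CDS stay "Exonic" with a frameshift/in-frame
#' effect tag. The site is anchored to its containing gene, or to the
#' nearest gene on the contig otherwise.
#'
#' @param contig,pos,ref,alt,kind the variant.
#' @param genes list of gene models.
#' @param genome named character vector (needed for coding effects).
#' @param upstream_window,downstream_window promoter-side / tail-side
#'   windows in bp.
#' @param splice_window bp into the intron treated as a splice site.
#' @return A list with `category`, `effect`, `anchored_gene`, `distance`.
#' @export
classify_region <- function(contig, pos, ref, alt, kind, genes, genome = NULL,
                            upstream_window = 1000, downstream_window = upstream_window,
                            splice_window = 2) {
  cg <- genes[vapply(genes, function(g) g$contig == contig, logical(1))]
  if (length(cg) == 0L) {
    return(list(category = "Intergenic", effect = NA_character_,
                anchored_gene = NA_character_, distance = NA_integer_))
  }
  rels <- lapply(cg, site_gene_relation, pos = pos,
                 upstream_window = upstream_window,
                 downstream_window = downstream_window,
                 splice_window = splice_window)
  rel <- vapply(rels, `[[`, "", "rel")
  dist <- vapply(rels, function(r) as.integer(r$dist), integer(1))
  ids <- vapply(cg, `[[`, "", "gene_id")
  pick_nearest <- function(sel) {
    cand <- which(sel)
    cand[order(dist[cand], ids[cand])][1L]
  }
  if (any(rel == "exon")) {
    hits <- which(rel == "exon")
    effects <- vapply(hits, function(i) {
      g <- cg[[i]]
      if (!in_cds(pos, g)) return(NA_character_)
      if (kind == "SNP") {
        coding_effect(contig, pos, ref, alt, g, genome) %||% NA_character_
      } else {
        if (abs(nchar(ref) - nchar(alt)) %% 3L == 0L) "in-frame" else "frameshift"
      }
    }, character(1))
    # most severe coding effect across overlapping transcripts
    sev <- EFFECT_SEVERITY[effects]
    if (any(!is.na(sev))) {
      i <- hits[which.min(sev)]
      eff <- effects[which.min(sev)]
      return(list(category = paste0("Exonic-", eff), effect = eff,
                  anchored_gene = ids[i], distance = 0L))
    }
    i <- hits[order(ids[hits])][1L]
    return(list(category = "Exonic",
                effect = effects[match(i, hits)],
                anchored_gene = ids[i], distance = 0L))
  }
  if (any(rel == "splicing")) {
    i <- pick_nearest(rel == "splicing")
    return(list(category = "Splicing", effect = NA_character_,
                anchored_gene = ids[i], distance = 0L))
  }
  if (any(rel == "intron")) {
    i <- pick_nearest(rel == "intron")
    return(list(category = "Intronic", effect = NA_character_,
                anchored_gene = ids[i], distance = 0L))
  }
  has_up <- any(rel == "upstream")
  has_down <- any(rel == "downstream")
  if (has_up || has_down) {
    category <- if (has_up && has_down) "Upstream/Downstream"
                else if (has_up) "Upstream" else "Downstream"
    i <- pick_nearest(rel %in% c("upstream", "downstream"))
    return(list(category = category, effect = NA_character_,
                anchored_gene = ids[i], distance = dist[i]))
  }
  i <- pick_nearest(rep(TRUE, length(cg)))
  list(category = "Intergenic", effect = NA_character_,
       anchored_gene = ids[i], distance = dist[i])
}

#' Annotate variants against gene models
#'
#' Vectorised wrapper over [classify_region()]: adds `category`, `effect`,
#' `anchored_gene` and `distance` columns to a variant table. Every input
#' site receives exactly one category, so category counts always sum to the
#' input size.
#'
#' @param sites data.frame with `contig`, `pos`, `ref`, `alt`, `kind`.
#' @param genes list of gene models.
#' @param genome named character vector of contig sequences.
#' @param upstream_window,downstream_window,splice_window see
#'   [classify_region()].
#' @return `sites` with annotation columns appended.
#' @export
annotate_variants <- function(sites, genes, genome = NULL,
                              upstream_window = 1000,
                              downstream_window = upstream_window,
                              splice_window = 2) {
  ann <- lapply(seq_len(nrow(sites)), function(i) {
    classify_region(sites$contig[i], sites$pos[i], sites$ref[i],
                    sites$alt[i], sites$kind[i], genes, genome,
                    upstream_window, downstream_window, splice_window)
  })
  sites$category <- vapply(ann, `[[`, "", "category")
  sites$effect <- vapply(ann, function(a) a$effect %||% NA_character_,
                         character(1))
  sites$anchored_gene <- vapply(ann, `[[`, "", "anchored_gene")
  sites$distance <- vapply(ann, function(a) as.integer(a$distance), integer(1))
  sites
}

#' Region-category count summary
#'
#' Counts annotated sites per region category, split by variant kind, with
#' a Total row — the classic position-information summary of a BSA marker
#' set.
#'
#' @param ann annotated data.frame from [annotate_variants()].
#' @return data.frame with `category`, `SNP`, `InDel` columns.
#' @export
category_counts <- function(ann) {
  cat_f <- factor(ann$category, levels = REGION_CATEGORIES)
  kind_f <- factor(ann$kind, levels = c("SNP", "InDel"))
  tab <- table(cat_f, kind_f)
  out <- data.frame(category = c(REGION_CATEGORIES, "Total"),
                    SNP = c(as.integer(tab[, "SNP"]), sum(tab[, "SNP"])),
                    InDel = c(as.integer(tab[, "InDel"]), sum(tab[, "InDel"])),
                    stringsAsFactors = FALSE)
  out
}

#' Transition/transversion summary of a SNP set
#'
#' Transitions are A<->G and C<->T; every other single-base substitution is
#' a transversion. The ratio is undefined (`NA`) when there are no
#' transversions.
#'
#' @param snps data.frame with single-base `ref` and `alt` columns (SNPs
#'   only; other rows are rejected).
#' @return A list with `ts`, `tv` and `ratio`.
#' @export
ts_tv_summary <- function(snps) {
  if (nrow(snps) > 0 && any(nchar(snps$ref) != 1L | nchar(snps$alt) != 1L)) {
    stop_fmt("ts_tv_summary accepts SNPs only (single-base ref and alt)")
  }
  pair <- paste(pmin(snps$ref, snps$alt), pmax(snps$ref, snps$alt))
  is_ts <- pair %in% c("A G", "C T")
  ts <- sum(is_ts)
  tv <- sum(!is_ts)
  list(ts = ts, tv = tv, ratio = if (tv == 0) NA_real_ else ts / tv)
}

#' Anchor sites to genes
#'
#' Each site is assigned its containing gene, or the nearest gene on the
#' contig by distance to the gene span; ties break toward the
#' lexicographically smaller gene id. Sites on contigs with no genes are
#' left unanchored (`NA`).
#'
#' @param sites data.frame with `contig` and `pos`.
#' @param genes list of gene models.
#' @return data.frame with `anchored_gene` and `distance` per input site.
#' @export
anchor_genes <- function(sites, genes) {
  gene_contig <- vapply(genes, `[[`, "", "contig")
  gene_id <- vapply(genes, `[[`, "", "gene_id")
  spans <- t(vapply(genes, gene_span, integer(2)))
  out_gene <- character(nrow(sites))
  out_dist <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sel <- gene_contig == sites$contig[i]
    if (!any(sel)) {
      out_gene[i] <- NA_character_
      out_dist[i] <- NA_integer_
      next
    }
    pos <- sites$pos[i]
    d <- pmax(spans[sel, 1L] - pos, pos - spans[sel, 2L], 0L)
    ord <- order(d, gene_id[sel])
    out_gene[i] <- gene_id[sel][ord[1L]]
    out_dist[i] <- d[ord[1L]]
  }
  data.frame(anchored_gene = out_gene, distance = out_dist,
             stringsAsFactors = FALSE)
}
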
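test_that("region classification follows the documented precedence", {
  tl <- toy_locus()
  cls <- function(pos, kind = "SNP", ref = "A", alt = "G", ...) {
    classify_region("c1", pos, ref, alt, kind, tl$genes, tl$genome, ...)
  }
  # inside an exon of the plus-strand gene
  expect_match(cls(2002, ref = "T", alt = "C")$category, "^Exonic")
  # intron runs 2010..2100: 1-2 bp from an exon boundary is Splicing
  expect_equal(cls(2010)$category, "Splicing")
  expect_equal(cls(2011)$category, "Splicing")
  expect_equal(cls(2099)$category, "Splicing")
  # deeper than the splice window is Intronic
  expect_equal(cls(2050)$category, "Intronic")
  expect_equal(cls(2012)$category, "Intronic")
  # strand-aware upstream/downstream (g_plus is +, span 2001..2106)
  expect_equal(cls(1500)$category, "Upstream")
  expect_equal(cls(2500)$category, "Downstream")
  # g_minus (-, span 4001..4012): upstream lies at larger coordinates
  expect_equal(cls(4500)$category, "Upstream")
  expect_equal(cls(3500)$category, "Downstream")
  # between the genes, within 1 kb of both: downstream of g_plus (+) and
  # downstream of g_minus (-) -> still plain Downstream
  expect_equal(cls(3050)$category, "Downstream")
  # far from everything
  expect_equal(cls(5900)$category, "Intergenic")
  expect_equal(cls(5900)$anchored_gene, "g_minus")
  # a contig with no genes at all -> intergenic, unanchored
  expect_equal(classify_region("c9", 100, "A", "G", "SNP", tl$genes,
                               tl$genome)$category, "Intergenic")
  expect_true(is.na(classify_region("c9", 100, "A", "G", "SNP", tl$genes,
                                    tl$genome)$anchored_gene))
})

test_that("a combined Upstream/Downstream class arises between convergent windows", {
  genome <- c(c1 = strrep("A", 5000))
  ga <- new_gene_model("ga", "c1", "+", cbind(1000L, 1299L),
                       cbind(1000L, 1299L, 0L))
  gb <- new_gene_model("gb", "c1", "+", cbind(2000L, 2299L),
                       cbind(2000L, 2299L, 0L))
  r <- classify_region("c1", 1600, "A", "G", "SNP", list(ga, gb), genome)
  expect_equal(r$category, "Upstream/Downstream")
})

test_that("coding effects match designed codon changes on both strands", {
  tl <- toy_locus()
  gp <- tl$genes[[1]]
  gm <- tl$genes[[2]]
  # plus-strand CDS: ATG GGA TGG TAA at 2001..2009 + 2101..2106
  # codon 2 = GGA at 2004..2006: third-position wobble GGA -> GGG
  expect_equal(coding_effect("c1", 2006, "A", "G", gp, tl$genome),
               "Synonymous")
  # codon 3 = TGG (Trp) at 2007..2009: TGG -> TGA is a stop gain
  expect_equal(coding_effect("c1", 2009, "G", "A", gp, tl$genome),
               "Stop gain")
  # codon 4 = TAA at 2101..2103: TAA -> CAA (Gln) is a stop loss
  expect_equal(coding_effect("c1", 2101, "T", "C", gp, tl$genome),
               "Stop loss")
  # minus-strand gene: genomic TTACCATCCCAT = revcomp(ATGGGATGGTAA)
  # tx codon 4 TAA maps to genomic 4001..4003 (TTA)
  expect_equal(coding_effect("c1", 4003, "A", "G", gm, tl$genome),
               "Stop loss")   # tx T->C: TAA -> CAA
  expect_equal(coding_effect("c1", 4004, "C", "T", gm, tl$genome),
               "Stop gain")   # tx codon 3 TGG -> TGA
  expect_error(coding_effect("c1", 2050, "A", "G", gp, tl$genome),
               "not inside the CDS")
})

test_that("coding effects agree with a translate-and-compare oracle exhaustively", {
  tl <- toy_locus()
  code <- Biostrings::GENETIC_CODE
  for (g in tl$genes) {
    cds <- g$cds[order(g$cds[, "start"]), , drop = FALSE]
    for (seg in seq_len(nrow(cds))) {
      for (pos in cds[seg, "start"]:cds[seg, "end"]) {
        ref <- substr(tl$genome[["c1"]], pos, pos)
        for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
          got <- coding_effect("c1", pos, ref, alt, g, tl$genome)
          # oracle: mutate the genome, rebuild the whole CDS, translate both
          mut <- tl$genome[["c1"]]
          substr(mut, pos, pos) <- alt
          build <- function(s) {
            x <- paste(substr(rep(s, nrow(cds)), cds[, "start"],
                              cds[, "end"]), collapse = "")
            if (g$strand == "-") {
              x <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(x)))
            }
            strsplit(as.character(Biostrings::translate(
              Biostrings::DNAString(x), no.init.codon = TRUE)), "")[[1]]
          }
          aa_ref <- build(tl$genome[["c1"]])
          aa_alt <- build(mut)
          i <- which(aa_ref != aa_alt)
          want <- if (length(i) == 0) "Synonymous"
                  else if (aa_alt[i] == "*") "Stop gain"
                  else if (aa_ref[i] == "*") "Stop loss"
                  else "Non-synonymous"
          expect_equal(got, want,
                       label = sprintf("%s pos %d %s>%s: %s", g$gene_id,
                                       pos, ref, alt, got))
        }
      }
    }
  }
})

test_that("coding-effect classes are invariant under a genome mirror", {
  # reverse-complement the contig, mirror all coordinates and flip strands:
  # every substitution keeps its class (with complemented alleles)
  tl <- toy_locus()
  L <- nchar(tl$genome[["c1"]])
  mirror_genome <- c(c1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tl$genome[["c1"]]))))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (g in tl$genes) {
    ex <- g$exons
    mex <- cbind(start = rev(L - ex[, "end"] + 1L),
                 end = rev(L - ex[, "start"] + 1L))
    strand2 <- if (g$strand == "+") "-" else "+"
    mg <- new_gene_model(g$gene_id, "c1", strand2, mex,
                         bsascreen:::cds_with_phase(mex[, "start"],
                                                    mex[, "end"], strand2))
    cds <- g$cds
    for (pos in cds[1, "start"]:cds[1, "end"]) {
      ref <- substr(tl$genome[["c1"]], pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      mpos <- L - pos + 1L
      expect_equal(
        coding_effect("c1", pos, ref, alt, g, tl$genome),
        coding_effect("c1", mpos, comp[[ref]], comp[[alt]], mg, mirror_genome)
      )
    }
  }
})

test_that("annotation partitions input and matches an interval-scan oracle", {
  sc <- sim_scenario(n_contigs = 2L, contig_length = 60000L, n_genes = 12L,
                     variant_density = 10, causal_pos = 30000L, seed = 21)
  ref <- simulate_reference(sc)
  sites <- plant_sites(sc, ref$genome)
  expect_gt(nrow(sites), 900)
  ann <- annotate_variants(sites, ref$genes, ref$genome)
  expect_true(all(ann$category %in% REGION_CATEGORIES))
  cc <- category_counts(ann)
  expect_equal(cc$SNP[cc$category == "Total"], sum(ann$kind == "SNP"))
  expect_equal(cc$InDel[cc$category == "Total"], sum(ann$kind == "InDel"))
  expect_equal(sum(cc$SNP[cc$category != "Total"]) +
                 sum(cc$InDel[cc$category != "Total"]), nrow(ann))

  # independent interval-scan oracle for the region class (exonic subclasses
  # collapsed), built from per-gene feature intervals
  oracle <- function(contig, pos) {
    rels <- character(0)
    for (g in ref$genes) {
      if (g$contig != contig) next
      sp <- c(g$exons[1, "start"], g$exons[nrow(g$exons), "end"])
      if (pos >= sp[1] && pos <= sp[2]) {
        if (any(pos >= g$exons[, "start"] & pos <= g$exons[, "end"])) {
          rels <- c(rels, "exon")
        } else {
          bounds <- c(g$exons[, "start"] - 1L, g$exons[, "end"] + 1L)
          near <- min(abs(pos - bounds))
          rels <- c(rels, if (near <= 1L) "splicing" else "intron")
        }
      } else if (pos < sp[1]) {
        if (sp[1] - pos <= 1000) {
          rels <- c(rels, if (g$strand == "+") "upstream" else "downstream")
        }
      } else if (pos - sp[2] <= 1000) {
        rels <- c(rels, if (g$strand == "-") "upstream" else "downstream")
      }
    }
    if ("exon" %in% rels) return("Exonic")
    if ("splicing" %in% rels) return("Splicing")
    if ("intron" %in% rels) return("Intronic")
    up <- "upstream" %in% rels
    down <- "downstream" %in% rels
    if (up && down) return("Upstream/Downstream")
    if (up) return("Upstream")
    if (down) return("Downstream")
    "Intergenic"
  }
  set.seed(33)
  idx <- sample(nrow(ann), 1000)
  got <- sub("^Exonic-.*", "Exonic", ann$category[idx])
  want <- vapply(idx, function(i) oracle(ann$contig[i], ann$pos[i]),
                 character(1))
  expect_equal(got, want)
})

test_that("Ts/Tv counts transitions A<->G and C<->T only", {
  one <- data.frame(ref = "A", alt = "G")
  s <- ts_tv_summary(one)
  expect_equal(c(s$ts, s$tv), c(1, 0))
  expect_true(is.na(s$ratio))

  snps <- data.frame(ref = c(rep("A", 558), rep("A", 297)),
                     alt = c(rep("G", 558), rep("C", 297)))
  s <- ts_tv_summary(snps)
  expect_equal(s$ratio, 558 / 297)
  expect_equal(round(s$ratio, 3), 1.879)
  shuffled <- snps[sample(nrow(snps)), ]
  expect_equal(ts_tv_summary(shuffled), s)
  expect_error(ts_tv_summary(data.frame(ref = "A", alt = "AT")), "SNPs only")
})

test_that("gene anchoring uses containment, nearest distance, then gene id", {
  genome <- c(c1 = strrep("A", 10000))
  ga <- new_gene_model("ga", "c1", "+", cbind(1000L, 1998L),
                       cbind(1000L, 1998L, 0L))
  gb <- new_gene_model("gb", "c1", "+", cbind(3002L, 4000L),
                       cbind(3002L, 4000L, 0L))
  sites <- data.frame(contig = c("c1", "c1", "c1", "c2"),
                      pos = c(1500L, 2400L, 9000L, 5L))
  a <- anchor_genes(sites, list(ga, gb))
  expect_equal(a$anchored_gene, c("ga", "ga", "gb", NA))
  expect_equal(a$distance, c(0L, 402L, 5000L, NA))
  # 2500 is equidistant (502 bp) from ga's end and gb's start -> smaller id
  a2 <- anchor_genes(data.frame(contig = "c1", pos = 2500L), list(gb, ga))
  expect_equal(a2$anchored_gene, "ga")

  # intergenic sites still receive an anchored gene when the contig has genes
  ann <- annotate_variants(data.frame(contig = "c1", pos = 9000L, ref = "A",
                                      alt = "G", kind = "SNP"),
                           list(ga, gb), genome)
  expect_equal(ann$category, "Intergenic")
  expect_equal(ann$anchored_gene, "gb")
})
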
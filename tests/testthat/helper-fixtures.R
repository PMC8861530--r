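# Shared fixtures, all built in code.

tiny_scenario <- function(seed, ...) {
  args <- list(n_contigs = 1L, contig_length = 50000L, n_genes = 4L,
               variant_density = 1, causal_contig = "contig_1",
               causal_pos = 25000L, linkage_window = 10000L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_scenario, args)
}

# A truth-table data.frame with explicit frequencies (bypasses plant_sites).
manual_sites <- function(n, freq_S, freq_T, contig = "c1") {
  data.frame(contig = contig, pos = seq_len(n), ref = "A", alt = "G",
             kind = "SNP", freq_S = rep_len(freq_S, n),
             freq_T = rep_len(freq_T, n), stringsAsFactors = FALSE)
}

# The eight validation-panel rows (marker x genotype counts per group).
validation_panels <- function() {
  rows <- list(
    list("S1", "A/G",  c("GG", "AG", "AA"),    c(18, 2, 0),  c(4, 10, 6)),
    list("S2", "A/G",  c("GG", "AG", "AA"),    c(12, 6, 2),  c(20, 0, 0)),
    list("S3", "A/G",  c("GG", "AG", "AA"),    c(15, 1, 0),  c(6, 10, 0)),
    list("S4", "T/C",  c("CC", "CT", "TT"),    c(11, 7, 2),  c(2, 11, 7)),
    list("S5", "A/G",  c("GG", "AG", "AA"),    c(0, 3, 17),  c(12, 0, 8)),
    list("I4", "Indel", c("In", "Del", "Indel"), c(0, 15, 5), c(13, 5, 2)),
    list("I8", "Indel", c("In", "Del", "Indel"), c(5, 2, 13), c(18, 0, 2)),
    list("I9", "Indel", c("In", "Del", "Indel"), c(7, 4, 9),  c(0, 16, 4))
  )
  lapply(rows, function(r) do.call(new_genotype_panel, r))
}

# Reported delta-index values of the eight validated markers.
validated_deltas <- c(-0.92, 0.74, 0.71, 0.78, 0.79, -0.77, 0.75, -0.72)

# A deterministic toy locus: one contig, two genes (one per strand), CDS
# built from a designed coding sequence so effect classes are predictable.
# Layout (plus-strand gene g_plus): exon1 2001..2009, intron, exon2 2101..2106.
toy_locus <- function() {
  set.seed(99)
  len <- 6000L
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  # plus-strand CDS: ATG GGA TGG TAA  (M G W *) split 9 + 3 over two exons
  substr(seq, 2001, 2009) <- "ATGGGATGG"
  substr(seq, 2101, 2103) <- "TAA"
  g_plus <- new_gene_model("g_plus", "c1", "+",
                           exons = cbind(c(2001L, 2101L), c(2009L, 2106L)),
                           cds = cbind(c(2001L, 2101L), c(2009L, 2106L),
                                       c(0L, 0L)))
  # minus-strand gene: same coding sequence read on the reverse strand,
  # single exon at 4001..4012 -> genomic revcomp("ATGGGATGGTAA")
  substr(seq, 4001, 4012) <- "TTACCATCCCAT"
  g_minus <- new_gene_model("g_minus", "c1", "-",
                            exons = cbind(4001L, 4012L),
                            cds = cbind(4001L, 4012L, 0L))
  list(genome = c(c1 = seq), genes = list(g_plus, g_minus))
}
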
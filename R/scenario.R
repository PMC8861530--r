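#' Define a pool-seq simulation scenario
#'
#' A scenario bundles every parameter of the synthetic bulked-segregant
#' experiment: the reference to simulate, the two bulks of extreme-phenotype
#' individuals, sequencing depth, and the planted causal locus. Defaults
#' mirror a crab salt-alkali tolerance BSA design: two bulks of 20 diploid
#' individuals sequenced to roughly 45x per pool, with one causal locus whose
#' allele frequency differs strongly between bulks.
#'
#' @param n_contigs number of reference contigs to simulate.
#' @param contig_length length of each contig in bp.
#' @param n_genes total number of genes placed across contigs (non-overlapping).
#' @param variant_density variant sites per kb of reference.
#' @param bulk_size diploid individuals per bulk (both bulks equal size).
#' @param mean_depth expected reads per pool per site (Poisson mean).
#' @param causal_contig contig carrying the causal locus; `NA` for a null
#'   genome with no causal signal.
#' @param causal_pos 1-based position of the causal locus on `causal_contig`.
#' @param causal_delta difference in causal-allele frequency between the
#'   tolerant and sensitive bulks at the locus, in \[0, 1\].
#' @param linkage_window bp over which the bulk-frequency divergence decays
#'   linearly to zero on either side of the causal position.
#' @param indel_prob probability that a planted site is an InDel rather than
#'   a SNP.
#' @param seed RNG seed; mandatory so every run is reproducible.
#'
#' @return A list of class `"sim_scenario"`.
#' @examples
#' sc <- sim_scenario(seed = 1)
#' sc$bulk_size
#' @export
sim_scenario <- function(n_contigs = 3L,
                         contig_length = 200000L,
                         n_genes = 30L,
                         variant_density = 1,
                         bulk_size = 20L,
                         mean_depth = 45,
                         causal_contig = "contig_1",
                         causal_pos = 100000L,
                         causal_delta = 0.9,
                         linkage_window = 50000L,
                         indel_prob = 0.5,
                         seed = NULL) {
  if (is.null(seed)) stop_fmt("a seed is mandatory for a sim_scenario")
  sc <- list(
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_genes = as.integer(n_genes),
    variant_density = variant_density,
    bulk_size = as.integer(bulk_size),
    mean_depth = mean_depth,
    causal_contig = if (is.na(causal_contig)) NA_character_ else as.character(causal_contig),
    causal_pos = as.integer(causal_pos),
    causal_delta = causal_delta,
    linkage_window = as.integer(linkage_window),
    indel_prob = indel_prob,
    seed = as.integer(seed)
  )
  validate_scenario(sc)
  class(sc) <- "sim_scenario"
  sc
}

validate_scenario <- function(sc) {
  if (!is_count(sc$n_contigs, allow_zero = FALSE)) {
    stop_fmt("n_contigs must be a positive count")
  }
  if (!is_count(sc$contig_length, allow_zero = FALSE)) {
    stop_fmt("contig_length must be a positive count")
  }
  if (!is_count(sc$n_genes)) stop_fmt("n_genes must be a non-negative count")
  if (!is.numeric(sc$variant_density) || sc$variant_density < 0) {
    stop_fmt("variant_density must be >= 0")
  }
  if (!is_count(sc$bulk_size, allow_zero = FALSE)) {
    stop_fmt("bulk_size must be >= 1")
  }
  if (!is.numeric(sc$mean_depth) || sc$mean_depth <= 0) {
    stop_fmt("mean_depth must be > 0")
  }
  if (sc$causal_delta < 0 || sc$causal_delta > 1) {
    stop_fmt("causal_delta must be in [0, 1]")
  }
  if (!is.na(sc$causal_contig)) {
    if (sc$causal_pos < 1L || sc$causal_pos > sc$contig_length) {
      stop_fmt("causal_pos (%d) must lie within its contig (1..%d)",
               sc$causal_pos, sc$contig_length)
    }
  }
  if (!is_count(sc$linkage_window, allow_zero = FALSE)) {
    stop_fmt("linkage_window must be >= 1")
  }
  if (sc$indel_prob < 0 || sc$indel_prob > 1) {
    stop_fmt("indel_prob must be in [0, 1]")
  }
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Pool-seq simulation scenario\n")
  cat(sprintf("  reference : %d contig(s) x %s bp, %d gene(s)\n",
              x$n_contigs, format(x$contig_length, big.mark = ","), x$n_genes))
  cat(sprintf("  variants  : %.3g sites/kb (P(InDel) = %.2f)\n",
              x$variant_density, x$indel_prob))
  cat(sprintf("  bulks     : %d diploids each, mean depth %.4g reads/pool\n",
              x$bulk_size, x$mean_depth))
  if (is.na(x$causal_contig)) {
    cat("  causal    : none (null genome)\n")
  } else {
    cat(sprintf("  causal    : %s:%d, delta = %.2f, linkage window %s bp\n",
                x$causal_contig, x$causal_pos, x$causal_delta,
                format(x$linkage_window, big.mark = ",")))
  }
  cat(sprintf("  seed      : %d\n", x$seed))
  invisible(x)
}
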
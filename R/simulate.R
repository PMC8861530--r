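#' Simulate a reference genome and gene models
#'
#' Generates random contig sequences and a set of non-overlapping gene
#' models. Each gene has 1-4 exons; the CDS covers the exons and its total
#' length is a multiple of 3, with GFF-style phase computed along the
#' transcription direction. Deterministic for a fixed scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return A list with `genome` (named character vector of contig sequences)
#'   and `genes` (list of gene models; see [read_gff_genes()] for the
#'   structure).
#' @examples
#' ref <- simulate_reference(sim_scenario(n_genes = 4L, seed = 1))
#' names(ref$genome)
#' @export
simulate_reference <- function(scenario) {
  validate_scenario(scenario)
  with_seed(scenario$seed, {
    contig_names <- sprintf("contig_%d", seq_len(scenario$n_contigs))
    genome <- vapply(contig_names, function(nm) {
      paste(sample(DNA_BASES, scenario$contig_length, replace = TRUE),
            collapse = "")
    }, character(1))

    genes <- list()
    if (scenario$n_genes > 0L) {
      # Round-robin gene placement; a sequential cursor per contig keeps
      # gene spans disjoint by construction.
      per_contig <- tabulate(
        rep_len(seq_len(scenario$n_contigs), scenario$n_genes),
        nbins = scenario$n_contigs
      )
      gidx <- 0L
      for (ci in seq_len(scenario$n_contigs)) {
        cursor <- 1L
        for (k in seq_len(per_contig[ci])) {
          gidx <- gidx + 1L
          cursor <- cursor + sample(500:2000, 1L)
          n_ex <- sample(1:4, 1L)
          exon_len <- 3L * sample(30:100, n_ex, replace = TRUE)
          intron_len <- if (n_ex > 1L) sample(60:400, n_ex - 1L, replace = TRUE) else integer(0)
          starts <- integer(n_ex)
          ends <- integer(n_ex)
          pos <- cursor
          for (j in seq_len(n_ex)) {
            starts[j] <- pos
            ends[j] <- pos + exon_len[j] - 1L
            pos <- ends[j] + if (j < n_ex) intron_len[j] + 1L else 1L
          }
          if (ends[n_ex] > scenario$contig_length - 200L) {
            stop_fmt(paste0(
              "contig %s (length %d bp) is too short to host %d gene(s); ",
              "increase contig_length or reduce n_genes"),
              contig_names[ci], scenario$contig_length, per_contig[ci])
          }
          cursor <- ends[n_ex]
          strand <- sample(c("+", "-"), 1L)
          genes[[gidx]] <- new_gene_model(
            gene_id = sprintf("g%03d", gidx),
            contig = contig_names[ci],
            strand = strand,
            exons = cbind(start = starts, end = ends),
            cds = cds_with_phase(starts, ends, strand)
          )
        }
      }
    }
    list(genome = genome, genes = genes)
  })
}

# GFF phase: bases to skip at the feature start to reach the first complete
# codon, accumulated along the transcription direction.
cds_with_phase <- function(starts, ends, strand) {
  n <- length(starts)
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  lens <- ends - starts + 1L
  phase <- integer(n)
  cum <- 0L
  for (j in ord) {
    phase[j] <- (3L - cum %% 3L) %% 3L
    cum <- cum + lens[j]
  }
  cbind(start = starts, end = ends, phase = phase)
}

#' Linked-site allele frequencies near a causal locus
#'
#' The divergence in alternate-allele frequency between the tolerant (T) and
#' sensitive (S) bulks is `causal_delta` at the causal position and decays
#' linearly to zero at `linkage_window` bp away; beyond the window the site
#' is null (equal frequencies). Frequencies are clamped to \[0, 1\].
#'
#' @param base_freq alternate-allele frequency in the sensitive bulk.
#' @param distance bp between the site and the causal position.
#' @param causal_delta frequency divergence at the causal locus.
#' @param linkage_window decay window in bp.
#' @return A two-column matrix with `freq_S` and `freq_T`.
#' @examples
#' linked_alt_freq(0.25, 0, 0.5, 50000)        # at the locus: 0.25 / 0.75
#' linked_alt_freq(0.25, 25000, 0.5, 50000)    # half-window: divergence 0.25
#' @export
linked_alt_freq <- function(base_freq, distance, causal_delta, linkage_window) {
  decay <- pmax(0, 1 - abs(distance) / linkage_window)
  freq_S <- clamp01(base_freq)
  freq_T <- clamp01(freq_S + causal_delta * decay)
  cbind(freq_S = freq_S, freq_T = freq_T)
}

#' Plant variant sites with true bulk allele frequencies
#'
#' Distributes SNP and InDel sites along the genome at the scenario's
#' variant density. Null sites draw a shared frequency from U(0.2, 0.8) for
#' both bulks; sites within the linkage window of the causal locus diverge
#' per [linked_alt_freq()]. One site is always planted exactly at the causal
#' position when a causal contig is configured.
#'
#' @param scenario a [sim_scenario()].
#' @param genome named character vector from [simulate_reference()].
#' @return A data.frame of true sites: `contig`, `pos`, `ref`, `alt`,
#'   `kind` ("SNP"/"InDel"), `freq_S`, `freq_T`.
#' @export
plant_sites <- function(scenario, genome) {
  validate_scenario(scenario)
  if (!is.na(scenario$causal_contig) &&
      !scenario$causal_contig %in% names(genome)) {
    stop_fmt("causal_contig '%s' is not a contig of the genome (have: %s)",
             scenario$causal_contig, paste(names(genome), collapse = ", "))
  }
  with_seed(scenario$seed + 1L, {
    out <- list()
    for (contig in names(genome)) {
      len <- nchar(genome[[contig]])
      n_sites <- round(scenario$variant_density * len / 1000)
      # keep 12 bp headroom so deletions never run off the contig
      avail <- seq_len(max(0L, len - 12L))
      n_sites <- min(n_sites, length(avail))
      pos <- sort(sample(avail, n_sites))
      if (!is.na(scenario$causal_contig) && contig == scenario$causal_contig &&
          !(scenario$causal_pos %in% pos)) {
        pos <- sort(c(pos, scenario$causal_pos))
      }
      if (length(pos) == 0L) next
      n <- length(pos)
      kind <- ifelse(stats::runif(n) < scenario$indel_prob, "InDel", "SNP")
      ref <- character(n)
      alt <- character(n)
      for (i in seq_len(n)) {
        base <- substr(genome[[contig]], pos[i], pos[i])
        if (kind[i] == "SNP") {
          ref[i] <- base
          alt[i] <- sample(setdiff(DNA_BASES, base), 1L)
        } else if (stats::runif(1) < 0.5) {  # insertion, left-anchored
          ins_len <- sample(1:10, 1L)
          ref[i] <- base
          alt[i] <- paste0(base, paste(sample(DNA_BASES, ins_len, replace = TRUE),
                                       collapse = ""))
        } else {                             # deletion, left-anchored
          del_len <- sample(1:10, 1L)
          ref[i] <- substr(genome[[contig]], pos[i], pos[i] + del_len)
          alt[i] <- base
        }
      }
      p <- stats::runif(n, 0.2, 0.8)
      if (!is.na(scenario$causal_contig) && contig == scenario$causal_contig) {
        fq <- linked_alt_freq(p, pos - scenario$causal_pos,
                              scenario$causal_delta, scenario$linkage_window)
      } else {
        fq <- cbind(freq_S = p, freq_T = p)
      }
      out[[contig]] <- data.frame(
        contig = contig, pos = pos, ref = ref, alt = alt, kind = kind,
        freq_S = fq[, "freq_S"], freq_T = fq[, "freq_T"],
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out) %||% empty_truth_df()
    rownames(res) <- NULL
    res
  })
}

empty_truth_df <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), freq_S = numeric(),
             freq_T = numeric(), stringsAsFactors = FALSE)
}

#' Simulate pooled read depths at planted sites
#'
#' Two-stage sampling per pool and site: the bulk's realized alternate-allele
#' frequency is Binomial(2 * bulk_size, freq) / (2 * bulk_size) — the finite
#' sample of chromosomes actually pooled — then total depth is
#' Poisson(mean_depth) and the alternate read count is Binomial(depth,
#' realized frequency). Depth-0 sites are legal output.
#'
#' @param sites data.frame from [plant_sites()].
#' @param scenario a [sim_scenario()].
#' @return A data.frame of variant site records: `contig`, `pos`, `ref`,
#'   `alt`, `kind`, `ref_depth_S`, `alt_depth_S`, `ref_depth_T`,
#'   `alt_depth_T`.
#' @export
simulate_pool_depths <- function(sites, scenario) {
  validate_scenario(scenario)
  n <- nrow(sites)
  with_seed(scenario$seed + 2L, {
    chrom <- 2L * scenario$bulk_size
    real_S <- stats::rbinom(n, chrom, sites$freq_S) / chrom
    real_T <- stats::rbinom(n, chrom, sites$freq_T) / chrom
    depth_S <- stats::rpois(n, scenario$mean_depth)
    depth_T <- stats::rpois(n, scenario$mean_depth)
    alt_S <- stats::rbinom(n, depth_S, real_S)
    alt_T <- stats::rbinom(n, depth_T, real_T)
    data.frame(
      contig = sites$contig, pos = sites$pos, ref = sites$ref,
      alt = sites$alt, kind = sites$kind,
      ref_depth_S = depth_S - alt_S, alt_depth_S = alt_S,
      ref_depth_T = depth_T - alt_T, alt_depth_T = alt_T,
      stringsAsFactors = FALSE
    )
  })
}

#' Write / read the simulator truth table
#'
#' Lossless TSV round-trip of the planted-site table; used to compare
#' pipeline output against ground truth.
#'
#' @param sites data.frame from [plant_sites()].
#' @param path file path.
#' @return `write_truth_table` returns `path` invisibly; `read_truth_table`
#'   returns the sites data.frame.
#' @export
write_truth_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(contig = "character",
                                         ref = "character",
                                         alt = "character"))
  need <- names(empty_truth_df())
  if (!identical(names(df), need)) {
    stop_fmt("truth table must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(df) > 0) {
    if (!is_count(df$pos, allow_zero = FALSE)) stop_fmt("truth table: pos must be >= 1")
    if (any(df$freq_S < 0 | df$freq_S > 1 | df$freq_T < 0 | df$freq_T > 1)) {
      stop_fmt("truth table: frequencies must lie in [0, 1]")
    }
    if (any(df$ref == df$alt)) stop_fmt("truth table: ref and alt must differ")
  }
  df
}

#' Simulate a gene-to-term annotation map
#'
#' Assigns each gene 1-3 terms drawn from a small term vocabulary, as a
#' stand-in for a functional annotation database in synthetic runs.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_terms size of the term vocabulary.
#' @param seed RNG seed.
#' @return Named list mapping gene id to a character vector of terms.
#' @export
simulate_term_map <- function(gene_ids, n_terms = 20L, seed = NULL) {
  terms <- sprintf("TERM:%04d", seq_len(n_terms))
  with_seed(seed, {
    m <- lapply(gene_ids, function(g) {
      sort(sample(terms, sample(1:3, 1L)))
    })
    names(m) <- gene_ids
    m
  })
}
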
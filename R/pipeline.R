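#' Run the full bulked-segregant pipeline on a simulated scenario
#'
#' Orchestrates simulate -> write artifacts -> read back -> delta-index
#' scan -> annotate & anchor -> enrichment (-> association when a
#' validation panel is supplied), and writes a JSON run manifest whose
#' content is bit-identical across reruns with the same configuration.
#'
#' The enrichment background is the set of genes anchored from all sites
#' passing the filter cascade; the candidate gene set is the genes anchored
#' from candidate markers. A synthetic gene-to-term map is generated unless
#' one is supplied.
#'
#' @param scenario a [sim_scenario()].
#' @param out_dir output directory (created if missing).
#' @param panel optional list of genotype panels for the association stage.
#' @param term_map optional named gene-to-term list; default: simulated.
#' @param min_depth,low_index,delta_lo,delta_hi,level,alpha,n_sims stage
#'   parameters, see [bsa_scan()], [genotype_association()] and
#'   [hypergeom_enrich()].
#' @param simulate_only stop after writing the simulated artifacts.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_bsa_pipeline <- function(scenario, out_dir, panel = NULL,
                             term_map = NULL, min_depth = 7,
                             low_index = 0.3, delta_lo = 0.69,
                             delta_hi = 1, level = 0.95, alpha = 0.05,
                             n_sims = 10000, simulate_only = FALSE) {
  validate_scenario(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  # stage 1: simulate and persist artifacts
  ref <- simulate_reference(scenario)
  sites <- plant_sites(scenario, ref$genome)
  records <- simulate_pool_depths(sites, scenario)
  write_genome_fasta(ref$genome, pth("genome.fa"))
  write_gff_genes(ref$genes, pth("genes.gff3"))
  write_pool_vcf(records, pth("pools.vcf"),
                 contig_lengths = stats::setNames(nchar(ref$genome),
                                                  names(ref$genome)))
  write_truth_table(sites, pth("truth.tsv"))
  files <- c("genome.fa", "genes.gff3", "pools.vcf", "truth.tsv")

  manifest <- list(
    package = "bsascreen",
    version = as.character(utils::packageVersion("bsascreen")),
    seed = scenario$seed,
    scenario = unclass(scenario),
    params = list(min_depth = min_depth, low_index = low_index,
                  delta_lo = delta_lo, delta_hi = delta_hi, level = level,
                  alpha = alpha, n_sims = n_sims),
    files = as.list(stats::setNames(unname(tools::md5sum(pth(files))), files)),
    counts = list(sites_simulated = nrow(records))
  )
  if (simulate_only) {
    write_manifest(manifest, pth("manifest.json"))
    return(invisible(manifest))
  }

  # stage 2: read artifacts back (exercises the IO contract end to end)
  genome <- read_genome_fasta(pth("genome.fa"))
  genes <- read_gff_genes(pth("genes.gff3"))
  vcf_records <- read_vcf_pools(pth("pools.vcf"))
  if (nrow(vcf_records) != nrow(records)) {
    stop_fmt("stage io: VCF round-trip lost records (%d written, %d read)",
             nrow(records), nrow(vcf_records))
  }

  # stage 3: delta-index scan
  fit <- bsa_scan(vcf_records, bulk_size = scenario$bulk_size,
                  min_depth = min_depth, low_index = low_index,
                  delta_lo = delta_lo, delta_hi = delta_hi, level = level,
                  n_sims = n_sims, seed = scenario$seed + 3L)
  write_candidate_table(fit$records, pth("scan.tsv"))

  # stage 4: annotation and gene anchoring
  ann <- annotate_variants(fit$records, genes, genome)
  write_candidate_table(ann, pth("annotated.tsv"))
  background_genes <- sort(unique(stats::na.omit(
    ann$anchored_gene[ann$passed_filters])))
  candidate_genes <- sort(unique(stats::na.omit(
    ann$anchored_gene[ann$is_candidate])))

  # stage 5: enrichment of candidate genes against the anchored background
  if (is.null(term_map)) {
    term_map <- simulate_term_map(vapply(genes, `[[`, "", "gene_id"),
                                  seed = scenario$seed + 4L)
  }
  enr <- if (length(candidate_genes) && length(background_genes)) {
    hypergeom_enrich(candidate_genes, background_genes, term_map)
  } else {
    hypergeom_enrich(character(0), background_genes, term_map)
  }
  write_candidate_table(enr, pth("enrichment.tsv"))

  # stage 6: optional validation-panel association
  assoc <- NULL
  if (!is.null(panel)) {
    assoc <- associate_panels(panel, alpha = alpha)
    write_candidate_table(assoc, pth("association.tsv"))
  }

  manifest$counts <- list(
    sites_simulated = nrow(records),
    sites_read = nrow(vcf_records),
    sites_passing_filters = unname(fit$counts["passed_filters"]),
    candidates = unname(fit$counts["candidates"]),
    background_genes = length(background_genes),
    candidate_genes = length(candidate_genes),
    enriched_terms = sum(enr$p_value < alpha),
    significant_markers = if (is.null(assoc)) NA
                          else significance_summary(assoc, alpha)$n_significant
  )
  manifest$files <- as.list(stats::setNames(
    unname(tools::md5sum(pth(c(files, "scan.tsv", "annotated.tsv",
                               "enrichment.tsv")))),
    c(files, "scan.tsv", "annotated.tsv", "enrichment.tsv")))
  write_manifest(manifest, pth("manifest.json"))
  invisible(manifest)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Total sequencing yield in Gbp
#'
#' Sums per-pool valid base counts and reports gigabases to two decimals.
#' The default rounding mode truncates (floor at the second decimal), the
#' convention used when a sequencing yield like 94,837,571,400 bp is
#' reported as 94.83 G; half-up rounding is available via `mode`.
#'
#' @param valid_bases numeric vector of per-pool base counts.
#' @param mode "truncate" (default) or "round".
#' @return Total yield in Gbp, two decimals.
#' @examples
#' summarize_sequencing(c(45753784500, 49083786900))  # 94.83
#' @export
summarize_sequencing <- function(valid_bases, mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  if (any(valid_bases < 0)) stop_fmt("base counts must be non-negative")
  g <- sum(valid_bases) / 1e9
  if (mode == "truncate") floor(g * 100) / 100 else round(g, 2)
}
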
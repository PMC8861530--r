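#' Per-pool SNP/InDel index
#'
#' The index of a pool at a site is the fraction of reads carrying the
#' alternate allele, `alt / (ref + alt)`. It is undefined (`NA`) when the
#' pool has no reads at the site; it is scale-free in the total depth.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorised).
#' @return Numeric vector in \[0, 1\], `NA` where total depth is 0.
#' @examples
#' pool_index(10, 0)   # 0
#' pool_index(0, 12)   # 1
#' pool_index(20, 25)  # 0.5555...
#' @export
pool_index <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0) || any(alt_depth < 0)) {
    stop_fmt("read depths must be non-negative")
  }
  tot <- ref_depth + alt_depth
  ifelse(tot > 0, alt_depth / tot, NA_real_)
}

#' Delta index between the two pools
#'
#' Difference of the tolerant-pool and sensitive-pool indices
#' (tolerant minus sensitive). Near 0 when a site segregates independently
#' of the phenotype; near +/-1 when it co-segregates. `NA` (undefined
#' index in either pool) propagates.
#'
#' @param index_S,index_T per-pool indices in \[0, 1\].
#' @return Numeric vector in \[-1, 1\].
#' @export
delta_index <- function(index_S, index_T) {
  index_T - index_S
}

# Build the per-site index table (IndexRecord columns) from raw records.
compute_index <- function(records) {
  records$depth_S <- records$ref_depth_S + records$alt_depth_S
  records$depth_T <- records$ref_depth_T + records$alt_depth_T
  records$index_S <- pool_index(records$ref_depth_S, records$alt_depth_S)
  records$index_T <- pool_index(records$ref_depth_T, records$alt_depth_T)
  records$delta <- delta_index(records$index_S, records$index_T)
  records
}

#' Filter cascade on indexed sites
#'
#' A site fails when its index is below `low_index` in BOTH pools, or when
#' a pool's depth is below `min_depth` (by default failure in EITHER pool
#' removes the site; set `depth_rule = "both"` to require both pools to be
#' shallow). Sites with an undefined index in either pool always fail.
#'
#' @param records data.frame with index columns (from [compute_index()] /
#'   [bsa_scan()]).
#' @param min_depth minimum per-pool total depth.
#' @param low_index both-pool low-index threshold.
#' @param depth_rule "either" (default) or "both": how many pools must be
#'   below `min_depth` for the site to fail.
#' @return `records` with a logical `passed_filters` column.
#' @export
apply_filters <- function(records, min_depth = 7, low_index = 0.3,
                          depth_rule = c("either", "both")) {
  depth_rule <- match.arg(depth_rule)
  low_both <- !is.na(records$index_S) & !is.na(records$index_T) &
    records$index_S < low_index & records$index_T < low_index
  shallow <- if (depth_rule == "either") {
    records$depth_S < min_depth | records$depth_T < min_depth
  } else {
    records$depth_S < min_depth & records$depth_T < min_depth
  }
  records$passed_filters <- !low_both & !shallow &
    !is.na(records$index_S) & !is.na(records$index_T)
  records
}

#' Draw delta-index values under the no-association null
#'
#' Two-stage null model for one site: each bulk's allele frequency is the
#' finite-sample realisation Binomial(2 * bulk_size, seg_freq) /
#' (2 * bulk_size) of a segregating allele (seg_freq 0.5), then the
#' alternate read count is Binomial(depth, frequency) in each pool. The
#' returned values are tolerant-pool index minus sensitive-pool index.
#'
#' @param n number of draws.
#' @param depth_S,depth_T per-pool read depths (scalar).
#' @param bulk_size diploid individuals per bulk.
#' @param seg_freq null allele frequency in the source population.
#' @return Numeric vector of length `n`.
#' @export
rnull_delta <- function(n, depth_S, depth_T, bulk_size, seg_freq = 0.5) {
  chrom <- 2L * bulk_size
  f_S <- stats::rbinom(n, chrom, seg_freq) / chrom
  f_T <- stats::rbinom(n, chrom, seg_freq) / chrom
  stats::rbinom(n, depth_T, f_T) / depth_T - stats::rbinom(n, depth_S, f_S) / depth_S
}

#' Simulation-based null confidence envelope for the delta index
#'
#' Simulates `n_sims` null sites at the observed per-pool depths via
#' [rnull_delta()] and returns the empirical (1-level)/2 and 1-(1-level)/2
#' quantiles of the simulated delta index. A site whose observed delta falls
#' outside this envelope is unlikely (at `level` confidence) under no
#' association.
#'
#' @param depth_S,depth_T observed per-pool depths (>= 1).
#' @param bulk_size diploid individuals per bulk.
#' @param level confidence level in (0, 1).
#' @param n_sims number of null simulations.
#' @param seed optional RNG seed.
#' @param seg_freq null allele frequency (see [rnull_delta()]).
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' null_delta_envelope(45, 45, bulk_size = 20, seed = 1)
#' @export
null_delta_envelope <- function(depth_S, depth_T, bulk_size, level = 0.95,
                                n_sims = 10000, seed = NULL, seg_freq = 0.5) {
  if (level <= 0 || level >= 1) stop_fmt("level must be in (0, 1)")
  if (depth_S < 1 || depth_T < 1) stop_fmt("envelope requires depth >= 1 in both pools")
  d <- with_seed(seed, rnull_delta(n_sims, depth_S, depth_T, bulk_size, seg_freq))
  q <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                       type = 1, names = FALSE)
  c(lo = q[1], hi = q[2])
}

# Envelopes for many sites, memoised on the (depth_S, depth_T) pair so that
# screening 1e5 Poisson-depth sites costs ~#unique-pairs simulations.
envelope_table <- function(depth_S, depth_T, bulk_size, level, n_sims,
                           seg_freq = 0.5) {
  key <- paste(depth_S, depth_T, sep = ":")
  uk <- unique(key)
  lo <- hi <- stats::setNames(rep(NA_real_, length(uk)), uk)
  for (k in uk) {
    i <- match(k, key)
    if (depth_S[i] < 1 || depth_T[i] < 1) next  # undefined index, fails filters
    e <- null_delta_envelope(depth_S[i], depth_T[i], bulk_size, level,
                             n_sims, seed = NULL, seg_freq = seg_freq)
    lo[k] <- e["lo"]
    hi[k] <- e["hi"]
  }
  cbind(lo = lo[key], hi = hi[key])
}

#' Screen candidate markers
#'
#' A site is a candidate when it passed the filter cascade, its delta index
#' lies outside the site's null confidence envelope at `level`, and
#' `delta_lo <= |delta| <= delta_hi`.
#'
#' @param records data.frame with `passed_filters` and envelope columns
#'   `null_lo`, `null_hi` (as produced by [bsa_scan()]).
#' @param delta_lo,delta_hi absolute delta-index window.
#' @param use_envelope apply the envelope condition (TRUE) or the absolute
#'   window alone.
#' @return `records` with a logical `is_candidate` column.
#' @export
screen_candidates <- function(records, delta_lo = 0.69, delta_hi = 1,
                              use_envelope = TRUE) {
  outside <- if (use_envelope) {
    !is.na(records$null_lo) &
      (records$delta < records$null_lo | records$delta > records$null_hi)
  } else {
    TRUE
  }
  records$is_candidate <- records$passed_filters & !is.na(records$delta) &
    outside & abs(records$delta) >= delta_lo & abs(records$delta) <= delta_hi
  records
}
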
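#' Bulked-segregant delta-index scan
#'
#' The package's central fit: takes per-site pooled allele depths for the
#' sensitive (S) and tolerant (T) bulks, computes per-pool indices and the
#' delta index (T minus S), applies the filter cascade (both-pool low index,
#' minimum depth), builds a per-site simulation-based null confidence
#' envelope, and flags candidate markers whose delta index is both outside
#' the envelope and inside the absolute-delta window.
#'
#' @param sites data.frame of variant site records: `contig`, `pos`, `ref`,
#'   `alt`, `kind`, `ref_depth_S`, `alt_depth_S`, `ref_depth_T`,
#'   `alt_depth_T` (from [read_vcf_pools()] or [simulate_pool_depths()]).
#' @param bulk_size diploid individuals per bulk (default 20).
#' @param min_depth minimum per-pool depth; shallower sites are filtered.
#' @param low_index both-pool low-index filter threshold.
#' @param delta_lo,delta_hi absolute delta-index candidate window.
#' @param level confidence level of the null envelope.
#' @param n_sims null simulations per unique depth pair.
#' @param depth_rule see [apply_filters()].
#' @param use_envelope apply the envelope screen in addition to the
#'   absolute-delta window.
#' @param seed RNG seed for the envelope simulations.
#' @return An object of class `"bsa_scan"`: a list with `records` (the
#'   per-site table with `index_S`, `index_T`, `depth_S`, `depth_T`,
#'   `delta`, `passed_filters`, `null_lo`, `null_hi`, `is_candidate`),
#'   `params`, and `counts`.
#' @examples
#' sc <- sim_scenario(n_contigs = 1L, contig_length = 50000L, n_genes = 0L,
#'                    causal_pos = 25000L, seed = 7)
#' sites <- simulate_pool_depths(plant_sites(sc, simulate_reference(sc)$genome), sc)
#' fit <- bsa_scan(sites, bulk_size = 20, n_sims = 500, seed = 7)
#' summary(fit)
#' @export
bsa_scan <- function(sites, bulk_size = 20, min_depth = 7, low_index = 0.3,
                     delta_lo = 0.69, delta_hi = 1, level = 0.95,
                     n_sims = 10000, depth_rule = c("either", "both"),
                     use_envelope = TRUE, seed = NULL) {
  depth_rule <- match.arg(depth_rule)
  need <- c("contig", "pos", "ref_depth_S", "alt_depth_S",
            "ref_depth_T", "alt_depth_T")
  if (!all(need %in% names(sites))) {
    stop_fmt("sites must have columns: %s", paste(need, collapse = ", "))
  }
  rec <- compute_index(sites)
  rec <- apply_filters(rec, min_depth = min_depth, low_index = low_index,
                       depth_rule = depth_rule)
  if (use_envelope && nrow(rec) > 0L) {
    env <- with_seed(seed, envelope_table(rec$depth_S, rec$depth_T,
                                          bulk_size, level, n_sims))
    rec$null_lo <- env[, "lo"]
    rec$null_hi <- env[, "hi"]
  } else {
    rec$null_lo <- NA_real_
    rec$null_hi <- NA_real_
  }
  rec <- screen_candidates(rec, delta_lo = delta_lo, delta_hi = delta_hi,
                           use_envelope = use_envelope)
  structure(list(
    records = rec,
    params = list(bulk_size = bulk_size, min_depth = min_depth,
                  low_index = low_index, delta_lo = delta_lo,
                  delta_hi = delta_hi, level = level, n_sims = n_sims,
                  depth_rule = depth_rule, use_envelope = use_envelope,
                  seed = seed),
    counts = c(sites = nrow(rec),
               passed_filters = sum(rec$passed_filters),
               candidates = sum(rec$is_candidate))
  ), class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("Bulked-segregant delta-index scan\n")
  cat(sprintf("  %d site(s) -> %d passed filters -> %d candidate(s)\n",
              x$counts["sites"], x$counts["passed_filters"],
              x$counts["candidates"]))
  cat(sprintf("  filters: both-pool index < %.2f, depth < %g (%s pool); window |delta| in [%.2f, %.2f]%s\n",
              x$params$low_index, x$params$min_depth, x$params$depth_rule,
              x$params$delta_lo, x$params$delta_hi,
              if (x$params$use_envelope)
                sprintf("; %.0f%% null envelope", 100 * x$params$level)
              else ""))
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  rec <- object$records
  cand <- rec[rec$is_candidate, , drop = FALSE]
  out <- list(
    counts = object$counts,
    params = object$params,
    delta_quartiles = stats::quantile(rec$delta, na.rm = TRUE),
    mean_depth = c(S = mean(rec$depth_S), T = mean(rec$depth_T)),
    candidates = cand[, intersect(c("contig", "pos", "ref", "alt", "kind",
                                    "index_S", "index_T", "delta",
                                    "null_lo", "null_hi"), names(cand))]
  )
  class(out) <- "summary.bsa_scan"
  out
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  cat(sprintf("BSA scan: %d sites, %d passed filters, %d candidates\n",
              x$counts["sites"], x$counts["passed_filters"],
              x$counts["candidates"]))
  cat(sprintf("mean pool depth: S %.1f, T %.1f\n",
              x$mean_depth["S"], x$mean_depth["T"]))
  cat("delta index quartiles:\n")
  print(round(x$delta_quartiles, 3))
  if (nrow(x$candidates) > 0L) {
    cat("candidate markers:\n")
    print(x$candidates, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
as.data.frame.bsa_scan <- function(x, ...) x$records

#' Candidate markers of a scan
#'
#' @param x a [bsa_scan()] object.
#' @return The candidate rows of the per-site record table.
#' @export
candidates <- function(x) {
  stopifnot(inherits(x, "bsa_scan"))
  x$records[x$records$is_candidate, , drop = FALSE]
}

#' Plot a delta-index scan
#'
#' Delta index against position, one panel per contig, with the null
#' confidence envelope and the absolute-delta candidate window; candidate
#' markers are highlighted.
#'
#' @param x a [bsa_scan()] object.
#' @param contigs contigs to draw (default: all present).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bsa_scan <- function(x, contigs = NULL, ...) {
  rec <- x$records
  contigs <- contigs %||% unique(rec$contig)
  old <- graphics::par(mfrow = c(length(contigs), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ct in contigs) {
    r <- rec[rec$contig == ct, , drop = FALSE]
    graphics::plot(r$pos, r$delta, ylim = c(-1, 1), pch = 16, cex = 0.5,
                   col = ifelse(r$is_candidate, "red",
                                ifelse(r$passed_filters, "grey30", "grey80")),
                   xlab = sprintf("position on %s (bp)", ct),
                   ylab = expression(Delta ~ "index"), main = ct, ...)
    if (x$params$use_envelope) {
      graphics::lines(r$pos, r$null_lo, col = "steelblue", lty = 2)
      graphics::lines(r$pos, r$null_hi, col = "steelblue", lty = 2)
    }
    graphics::abline(h = c(-x$params$delta_lo, x$params$delta_lo),
                     col = "darkorange", lty = 3)
  }
  invisible(x)
}
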
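#' Marker-genotype association test
#'
#' Pearson chi-square (no continuity correction) on the genotype x group
#' contingency table of a validation panel. Genotype categories that are
#' empty in BOTH groups are dropped before testing, so the degrees of
#' freedom are (kept categories - 1) x (groups - 1).
#'
#' @param panel a genotype panel (see [read_genotype_panel()]).
#' @param alpha significance threshold.
#' @return A list of class `"assoc_result"`: `marker_id`, `statistic`,
#'   `df`, `p_value`, `dropped_categories`, `significant`, `alpha`, and
#'   the tested `table`.
#' @examples
#' p <- new_genotype_panel("S2", "A/G", c("GG", "AG", "AA"),
#'                         c(12, 6, 2), c(20, 0, 0))
#' genotype_association(p)$p_value  # 0.0067
#' @export
genotype_association <- function(panel, alpha = 0.05) {
  a <- panel$counts_S
  b <- panel$counts_T
  if (sum(a) + sum(b) == 0L) {
    stop_fmt("marker %s: all genotype categories are empty", panel$marker_id)
  }
  keep <- (a + b) > 0L
  dropped <- panel$labels[!keep]
  tab <- rbind(S = a[keep], T = b[keep])
  if (sum(keep) < 2L) {
    res <- list(marker_id = panel$marker_id, statistic = NA_real_,
                df = NA_integer_, p_value = NA_real_,
                dropped_categories = dropped, significant = NA,
                alpha = alpha, table = tab,
                note = "single genotype category: test undefined")
    class(res) <- "assoc_result"
    return(res)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- list(marker_id = panel$marker_id,
              statistic = unname(ct$statistic),
              df = unname(ct$parameter),
              p_value = unname(ct$p.value),
              dropped_categories = dropped,
              significant = unname(ct$p.value) < alpha,
              alpha = alpha, table = tab, note = NULL)
  class(res) <- "assoc_result"
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s: chi-square = %.3f, df = %s, p = %.4g%s\n",
              x$marker_id,
              if (is.na(x$statistic)) NA else x$statistic,
              x$df, x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  if (length(x$dropped_categories)) {
    cat("  dropped empty categories:",
        paste(x$dropped_categories, collapse = ", "), "\n")
  }
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Exact conditional reference test for a genotype panel
#'
#' Independent small-sample oracle for the chi-square: enumerates every
#' genotype x group table with the observed margins and sums the
#' probabilities of tables no more probable than the observed one
#' (two-sided Fisher-style exact p). Refuses tables with more than 60
#' observations, where enumeration is no longer cheap.
#'
#' @param panel a genotype panel, or a k x 2 count matrix
#'   (rows = genotype categories kept after dropping both-empty ones,
#'   columns = groups).
#' @return Exact p-value.
#' @export
fisher_exact_reference <- function(panel) {
  tab <- if (inherits(panel, "genotype_panel")) {
    keep <- (panel$counts_S + panel$counts_T) > 0L
    cbind(S = panel$counts_S[keep], T = panel$counts_T[keep])
  } else {
    as.matrix(panel)
  }
  N <- sum(tab)
  if (N > 60L) {
    stop_fmt("table total %d exceeds 60: exact enumeration refused", N)
  }
  if (ncol(tab) != 2L) stop_fmt("exact reference expects a k x 2 table")
  r <- rowSums(tab)
  cS <- sum(tab[, 1L])
  k <- nrow(tab)
  log_p_table <- function(x) {
    sum(lchoose(r, x)) - lchoose(N, cS)
  }
  obs <- log_p_table(tab[, 1L])
  total <- 0
  rec <- function(i, remaining, x) {
    if (i == k) {
      if (remaining <= r[k]) {
        lp <- log_p_table(c(x, remaining))
        if (lp <= obs + 1e-7) total <<- total + exp(lp)
      }
      return(invisible(NULL))
    }
    lo <- max(0L, remaining - sum(r[(i + 1L):k]))
    hi <- min(r[i], remaining)
    for (xi in lo:hi) rec(i + 1L, remaining - xi, c(x, xi))
  }
  if (k == 1L) return(1)
  rec(1L, cS, integer(0))
  min(1, total)
}

#' Per-group genotype proportions and allele frequencies
#'
#' Genotype proportions per phenotype group (summing to 1 within each
#' non-empty group). For SNP-style panels whose genotype labels are
#' two-letter base pairs (e.g. GG/AG/AA) allele frequencies are counted
#' directly from the labels; for InDel panels the genotype-to-allele
#' mapping is unknown unless one is supplied, and frequencies are `NA`.
#'
#' @param panel a genotype panel.
#' @param allele_map optional named list mapping each genotype label to its
#'   two alleles, e.g. `list(In = c("In", "In"), Del = c("Del", "Del"),
#'   Indel = c("In", "Del"))`.
#' @return A list with `proportions` (matrix groups x genotypes) and
#'   `allele_freq_S` / `allele_freq_T` (named vectors or `NA`).
#' @export
group_proportions <- function(panel, allele_map = NULL) {
  props <- rbind(
    S = if (panel$empty_S) rep(NA_real_, length(panel$labels))
        else panel$counts_S / sum(panel$counts_S),
    T = if (panel$empty_T) rep(NA_real_, length(panel$labels))
        else panel$counts_T / sum(panel$counts_T)
  )
  colnames(props) <- panel$labels
  snp_style <- all(grepl("^[ACGT]{2}$", panel$labels))
  if (is.null(allele_map) && snp_style) {
    allele_map <- lapply(panel$labels, function(l) {
      c(substr(l, 1, 1), substr(l, 2, 2))
    })
    names(allele_map) <- panel$labels
  }
  freq <- function(counts, empty) {
    if (empty || is.null(allele_map)) return(NA)
    alleles <- unlist(allele_map[panel$labels], use.names = FALSE)
    w <- rep(counts, each = 2L)
    tab <- tapply(w, alleles, sum)
    tab / (2 * sum(counts))
  }
  list(proportions = props,
       allele_freq_S = freq(panel$counts_S, panel$empty_S),
       allele_freq_T = freq(panel$counts_T, panel$empty_T))
}

#' Test a set of panels and summarise significance
#'
#' @param panels list of genotype panels.
#' @param alpha significance threshold.
#' @return `associate_panels`: data.frame with one row per marker
#'   (`marker_id`, `statistic`, `df`, `p_value`, `p_exact`, `significant`).
#'   `significance_summary`: list with `n_significant` and `marker_ids`.
#' @export
associate_panels <- function(panels, alpha = 0.05) {
  rows <- lapply(panels, function(p) {
    r <- genotype_association(p, alpha = alpha)
    p_exact <- tryCatch(fisher_exact_reference(p), error = function(e) NA_real_)
    data.frame(marker_id = r$marker_id, statistic = r$statistic,
               df = r$df, p_value = r$p_value, p_exact = p_exact,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname associate_panels
#' @param results data.frame from [associate_panels()] or a list of
#'   [genotype_association()] results.
#' @export
significance_summary <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) {
    sig <- !is.na(results$p_value) & results$p_value < alpha
    ids <- results$marker_id[sig]
  } else {
    sig <- vapply(results, function(r) {
      !is.na(r$p_value) && r$p_value < alpha
    }, logical(1))
    ids <- vapply(results[sig], `[[`, "", "marker_id")
  }
  list(n_significant = sum(sig), marker_ids = ids)
}
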
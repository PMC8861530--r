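#' Hypergeometric term over-representation analysis
#'
#' For each annotation term carried by at least one candidate gene, tests
#' whether the candidate set contains more genes with the term than expected
#' from the background universe: one-sided upper-tail hypergeometric
#' p = P(X >= k) with k candidates carrying the term, K background genes
#' carrying it, candidate set size n and background size N. p-values are
#' Benjamini-Hochberg adjusted across all tested terms; rows are sorted by
#' p.
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of `background`).
#' @param background character vector: the gene universe.
#' @param term_map named list mapping gene id to a character vector of
#'   terms (see [read_term_map()]).
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`.
#' @examples
#' tm <- list(g1 = "T1", g2 = "T1", g3 = "T2")
#' hypergeom_enrich(c("g1", "g2"), c("g1", "g2", "g3", "g4"), tm)
#' @export
hypergeom_enrich <- function(candidates, background, term_map) {
  candidates <- unique(candidates)
  background <- unique(background)
  missing <- setdiff(candidates, background)
  if (length(missing)) {
    stop_fmt("candidate gene(s) absent from the background: %s",
             paste(missing, collapse = ", "))
  }
  term_map <- term_map[names(term_map) %in% background]
  gene2term <- data.frame(
    gene = rep(names(term_map), lengths(term_map)),
    term = unlist(term_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  N <- length(background)
  n <- length(candidates)
  term_genes <- split(gene2term$gene, gene2term$term)
  rows <- lapply(names(term_genes), function(t) {
    genes <- unique(term_genes[[t]])
    K <- length(genes)
    k <- sum(genes %in% candidates)
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  out$q_value <- benjamini_hochberg(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; the input order is preserved in the output.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
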
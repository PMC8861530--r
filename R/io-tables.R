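#' Read a marker genotype-validation panel
#'
#' Parses a TSV of per-marker genotype counts for two phenotype groups. The
#' expected columns are `marker_id`, `marker_type` (e.g. "A/G" or "Indel"),
#' `genotypes` (colon-separated labels, e.g. "GG:AG:AA"), `counts_S` and
#' `counts_T` (colon-separated non-negative integers, one per label).
#'
#' @param path TSV file path.
#' @return A list of genotype panels, each a list with `marker_id`,
#'   `marker_type`, `labels`, `counts_S`, `counts_T` and logical flags
#'   `empty_S`, `empty_T` marking all-zero groups.
#' @export
read_genotype_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("marker_id", "marker_type", "genotypes", "counts_S", "counts_T")
  if (!all(need %in% names(df))) {
    stop_fmt("genotype panel '%s' must have columns: %s", path,
             paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    labels <- strsplit(df$genotypes[i], ":", fixed = TRUE)[[1L]]
    parse_counts <- function(x, grp) {
      v <- suppressWarnings(as.integer(strsplit(x, ":", fixed = TRUE)[[1L]]))
      if (length(v) != length(labels)) {
        stop_fmt("panel '%s' line %d: %s has %d counts for %d genotype labels",
                 path, i + 1L, grp, length(v), length(labels))
      }
      if (any(is.na(v) | v < 0L)) {
        stop_fmt("panel '%s' line %d: %s counts must be non-negative integers",
                 path, i + 1L, grp)
      }
      stats::setNames(v, labels)
    }
    new_genotype_panel(df$marker_id[i], df$marker_type[i], labels,
                       parse_counts(df$counts_S[i], "counts_S"),
                       parse_counts(df$counts_T[i], "counts_T"))
  })
}

#' @rdname read_genotype_panel
#' @param marker_id,marker_type,labels,counts_S,counts_T panel fields.
#' @export
new_genotype_panel <- function(marker_id, marker_type, labels,
                               counts_S, counts_T) {
  if (length(counts_S) != length(labels) || length(counts_T) != length(labels)) {
    stop_fmt("marker %s: count vectors must match the genotype labels", marker_id)
  }
  if (!is_count(counts_S) || !is_count(counts_T)) {
    stop_fmt("marker %s: counts must be non-negative integers", marker_id)
  }
  structure(list(marker_id = marker_id, marker_type = marker_type,
                 labels = labels,
                 counts_S = stats::setNames(as.integer(counts_S), labels),
                 counts_T = stats::setNames(as.integer(counts_T), labels),
                 empty_S = sum(counts_S) == 0L,
                 empty_T = sum(counts_T) == 0L),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %s (%s)\n", x$marker_id, x$marker_type))
  print(rbind(S = x$counts_S, T = x$counts_T))
  invisible(x)
}

#' Write / read a candidate-marker table
#'
#' Round-trip-safe TSV of per-site screening results (the candidate table:
#' site, indices, delta index, envelope, anchored gene).
#'
#' @param records data.frame.
#' @param path file path.
#' @return `write_candidate_table` returns `path` invisibly;
#'   `read_candidate_table` the data.frame.
#' @export
write_candidate_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write a gene-to-term map
#'
#' Two-column TSV (`gene`, `term`); duplicate gene-term pairs are collapsed
#' silently. Rows with a missing field raise an error with the line number.
#'
#' @param path TSV file path.
#' @param term_map named list mapping gene id to a character vector of terms.
#' @return `read_term_map` returns a named list (gene -> sorted unique
#'   terms); `write_term_map` returns `path` invisibly.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene", "term") %in% names(df))) {
    stop_fmt("term map '%s' must have columns gene, term", path)
  }
  bad <- which(is.na(df$gene) | df$gene == "" | is.na(df$term) | df$term == "")
  if (length(bad)) {
    stop_fmt("term map '%s' line %d: empty gene or term field", path, bad[1L] + 1L)
  }
  if (nrow(df) == 0L) return(stats::setNames(list(), character()))
  lapply(split(df$term, df$gene), function(x) sort(unique(x)))
}

#' @rdname read_term_map
#' @export
write_term_map <- function(term_map, path) {
  df <- data.frame(
    gene = rep(names(term_map), lengths(term_map)),
    term = unlist(term_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
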
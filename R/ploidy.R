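#' Estimate relative ploidy from windowed synteny depth
#'
#' Relative ploidy p of a query genome against an unduplicated reference is
#' read as the mode of the positive windowed orthologous-synteny depth on
#' the reference: a tetraploid stacks two orthologous blocks over most
#' reference windows (2:1), a decaploid five (5:1). Zero-depth windows
#' (fractionation holes, unalignable regions) are excluded from the mode;
#' ties are broken toward the larger depth because fractionation biases
#' depth downward.
#'
#' @param query,reference annotated genomes; \code{blocks} must have been
#'   computed between them and filtered by orthology index.
#' @param blocks filtered \code{synteny_blocks}.
#' @param window window size in reference ranks (default 10).
#' @return object of class \code{ploidy_estimate}: list with \code{p},
#'   \code{depth_mode_support} (fraction of positive-depth windows at the
#'   mode), \code{ratio_text} ("p:1"), and the depth profile.
#' @export
estimate_relative_ploidy <- function(query, reference, blocks, window = 10) {
  prof <- synteny_depth(blocks, reference, window = window)
  pos <- prof$depth[prof$depth > 0L]
  if (!length(pos)) stop("no orthologous synteny between '",
                         genome_id(query), "' and '", genome_id(reference), "'")
  tab <- table(pos)
  best <- max(as.integer(names(tab)[tab == max(tab)]))
  out <- list(query_genome = genome_id(query),
              reference_genome = genome_id(reference),
              p = best,
              depth_mode_support = unname(tab[as.character(best)] /
                                            length(pos)),
              ratio_text = paste0(best, ":1"),
              profile = prof)
  class(out) <- "ploidy_estimate"
  out
}

#' @export
print.ploidy_estimate <- function(x, ...) {
  cat(sprintf("relative ploidy %s vs %s: p = %d (%s, support %.2f)\n",
              x$query_genome, x$reference_genome, x$p, x$ratio_text,
              x$depth_mode_support))
  invisible(x)
}

#' Ks values of syntenic anchors
#'
#' Collects one ks value per anchor of the given (typically intra-genome,
#' OI-filtered) blocks, the raw material of WGD-peak detection.
#'
#' @param blocks a \code{synteny_blocks} object.
#' @return numeric vector of ks values (NA dropped).
#' @export
ks_histogram <- function(blocks) {
  v <- blocks$anchors$ks
  v[!is.na(v)]
}

#' Detect Ks peaks by kernel density maxima
#'
#' Evaluates a Gaussian kernel density (Silverman's bandwidth by default)
#' and reports its local maxima, pruning peaks whose density is below 5% of
#' the global maximum. Peak weights are the normalized density at each peak.
#'
#' @param values numeric ks values (at least 10).
#' @param bandwidth kernel bandwidth; \code{NULL} for Silverman's rule.
#' @return data frame location, weight (weights sum to <= 1).
#' @export
detect_ks_peaks <- function(values, bandwidth = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("insufficient data: need >= 10 ks values")
  d <- if (is.null(bandwidth)) stats::density(values, bw = "nrd0", from = 0)
       else stats::density(values, bw = bandwidth, from = 0)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  is_max <- is_max & y >= 0.05 * max(y)
  if (!any(is_max)) return(data.frame(location = numeric(),
                                      weight = numeric()))
  data.frame(location = d$x[is_max],
             weight = y[is_max] / sum(y[is_max]))
}

#' Classify a polyploidy event as shared, independent or nested
#'
#' Compares windowed cross-genome orthologous-synteny depth in both
#' directions. Two genomes descending from the same polyploid show a 1:1
#' depth ratio (shared); independently doubled genomes show k:k with k > 1
#' (independent); a lineage that doubled again on top of a shared event
#' shows 2:1 relative to its sister (nested, the extra event in the genome
#' with the higher depth on the other).
#'
#' @param query1,query2 annotated genomes.
#' @param blocks filtered \code{synteny_blocks} computed between them.
#' @param window window size in ranks.
#' @return list(verdict = "shared"|"independent"|"nested", d12, d21) where
#'   d12 is the modal depth of query2-derived blocks on query1 windows.
#' @export
infer_shared_vs_independent <- function(query1, query2, blocks, window = 10) {
  mode_depth <- function(ref) {
    prof <- synteny_depth(blocks, ref, window = window)
    pos <- prof$depth[prof$depth > 0L]
    if (!length(pos)) stop("no orthologous synteny")
    tab <- table(pos)
    max(as.integer(names(tab)[tab == max(tab)]))
  }
  d12 <- mode_depth(query1)  # copies of query2 stacked on query1
  d21 <- mode_depth(query2)
  verdict <- if (d12 == 1L && d21 == 1L) "shared"
             else if (d12 == d21) "independent"
             else "nested"
  extra <- if (verdict == "nested")
    if (d21 > d12) genome_id(query1) else genome_id(query2)
  else NA_character_
  list(verdict = verdict, d12 = d12, d21 = d21, extra_wgd_in = extra)
}
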
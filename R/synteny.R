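#' Call orthologs by reciprocal (near-)best hit
#'
#' With \code{tol = 0} a cross-genome pair is called orthologous when each
#' gene is the other's best-scoring cross-genome hit in that genome pair
#' (strict reciprocal best hit; ties broken toward the lexicographically
#' smaller partner identifier). The default \code{tol = 0.1} relaxes this to
#' reciprocal near-best hits: a pair is kept when its score reaches
#' \code{(1 - tol)} of both members' best scores against the partner
#' genome. The relaxation is what permits many-to-one co-orthology — an
#' unduplicated outgroup gene matching all homoeologous copies of a
#' polyploid equally well — while still excluding WGD out-paralogs, whose
#' scores fall clearly below the true ortholog's. Within-genome pairs and
#' single-genome input yield no calls.
#'
#' @param pairs homology data frame (gene_a, gene_b, score, ...).
#' @param genomes list of \code{annotated_genome}.
#' @param tol relative score tolerance for co-ortholog calls (0 = strict
#'   reciprocal best hit).
#' @return data frame of ortholog pairs (gene_a < gene_b).
#' @export
call_orthologs <- function(pairs, genomes, tol = 0.1) {
  stopifnot(tol >= 0, tol < 1)
  empty <- data.frame(gene_a = character(), gene_b = character())
  if (length(genomes) < 2L || !nrow(pairs)) return(empty)
  gmap <- do.call(c, unname(lapply(genomes, function(g)
    stats::setNames(rep(genome_id(g), nrow(g)), g$gene))))
  ga <- unname(gmap[pairs$gene_a]); gb <- unname(gmap[pairs$gene_b])
  keep <- !is.na(ga) & !is.na(gb) & ga != gb
  if (!any(keep)) return(empty)
  p <- pairs[keep, , drop = FALSE]
  # directed hits: query -> subject genome, per genome pair
  hits <- data.frame(query = c(p$gene_a, p$gene_b),
                     subject = c(p$gene_b, p$gene_a),
                     sgenome = c(gb[keep], ga[keep]),
                     score = c(p$score, p$score), stringsAsFactors = FALSE)
  qkey <- paste(hits$query, hits$sgenome, sep = "\r")
  best_of <- tapply(hits$score, qkey, max)
  hits$qbest <- as.numeric(best_of[qkey])
  if (tol == 0) {
    # strict: keep only the single best subject, lexicographic tie-break
    ord <- order(qkey, -hits$score, hits$subject, method = "radix")
    hits <- hits[ord, , drop = FALSE]
    top <- hits[!duplicated(paste(hits$query, hits$sgenome, sep = "\r")), ]
    ok_fwd <- stats::setNames(top$subject,
                              paste(top$query, top$sgenome, sep = "\r"))
    sel <- ok_fwd[paste(top$subject, unname(gmap[top$query]),
                        sep = "\r")] == top$query
    sel[is.na(sel)] <- FALSE
    res <- top[sel, c("query", "subject")]
  } else {
    near <- hits[hits$score >= (1 - tol) * hits$qbest, , drop = FALSE]
    fwd <- paste(near$query, near$subject, sep = "\r")
    bwd <- paste(near$subject, near$query, sep = "\r")
    res <- near[fwd %in% bwd, c("query", "subject")]
  }
  if (!nrow(res)) return(empty)
  a <- pmin(res$query, res$subject); b <- pmax(res$query, res$subject)
  out <- unique(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Chain homologous gene pairs into collinear syntenic blocks
#'
#' Computes anchors (homologous gene pairs placed at their gene-order ranks)
#' between two genomes and chains them into blocks by sparse dynamic
#' programming: a block is a maximal-cardinality run of anchors strictly
#' increasing in the first genome's rank and monotone (increasing or
#' decreasing, setting the block orientation) in the second genome's rank,
#' with consecutive anchors at most \code{max_gap} ranks apart on both
#' sides. Blocks are peeled off best-first; each homology pair joins at most
#' one block and blocks below \code{min_block_size} anchors are discarded.
#' For a self-comparison (\code{genome_b} identical to \code{genome_a}) the
#' identity diagonal is excluded. When a ground-truth \code{locus} column is
#' present, consecutive same-locus genes (tandem duplicates) are collapsed
#' to the first before chaining.
#'
#' @param genome_a,genome_b annotated genomes (ranks assigned).
#' @param pairs homology data frame (gene_a, gene_b, score, ks optional).
#' @param min_block_size minimum anchors per block (default 5).
#' @param max_gap maximum rank gap between consecutive anchors (default 25).
#' @return object of class \code{synteny_blocks}: list with data frames
#'   \code{blocks} (block_id, chrom_a, chrom_b, n_anchors, orientation, oi,
#'   median_ks) and \code{anchors} (block_id, gene_a, gene_b, rank_a,
#'   rank_b, ks, is_ortholog).
#' @export
chain_anchors <- function(genome_a, genome_b, pairs,
                          min_block_size = 5, max_gap = 25) {
  self_cmp <- identical(genome_id(genome_a), genome_id(genome_b))
  ga <- collapse_tandems(genome_a)
  gb <- if (self_cmp) ga else collapse_tandems(genome_b)
  pos_a <- match(pairs$gene_a, ga$gene); posb_a <- match(pairs$gene_b, ga$gene)
  pos_b <- match(pairs$gene_b, gb$gene); posa_b <- match(pairs$gene_a, gb$gene)
  fwd <- !is.na(pos_a) & !is.na(pos_b)
  rev_ <- !is.na(posb_a) & !is.na(posa_b) & !fwd & !self_cmp
  anchors <- rbind(
    data.frame(gene_a = pairs$gene_a[fwd], gene_b = pairs$gene_b[fwd],
               ia = pos_a[fwd], ib = pos_b[fwd],
               ks = pairs$ks[fwd], stringsAsFactors = FALSE),
    data.frame(gene_a = pairs$gene_b[rev_], gene_b = pairs$gene_a[rev_],
               ia = posb_a[rev_], ib = posa_b[rev_],
               ks = pairs$ks[rev_], stringsAsFactors = FALSE))
  out <- empty_blocks(genome_id(genome_a), genome_id(genome_b))
  if (!nrow(anchors)) return(out)
  anchors$chrom_a <- ga$chromosome[anchors$ia]
  anchors$rank_a <- ga$rank[anchors$ia]
  anchors$chrom_b <- gb$chromosome[anchors$ib]
  anchors$rank_b <- gb$rank[anchors$ib]
  if (self_cmp)
    anchors <- anchors[anchors$gene_a != anchors$gene_b, , drop = FALSE]
  if (!nrow(anchors)) return(out)
  blocks <- list(); anch_rows <- list(); bid <- 0L
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))) {
    cc <- strsplit(key, "\r")[[1L]]
    sub <- anchors[anchors$chrom_a == cc[1L] & anchors$chrom_b == cc[2L], ,
                   drop = FALSE]
    chains <- peel_chains(sub$rank_a, sub$rank_b, min_block_size, max_gap)
    for (ch in chains) {
      bid <- bid + 1L
      rows <- sub[ch$idx, , drop = FALSE]
      blocks[[bid]] <- data.frame(
        block_id = bid, chrom_a = cc[1L], chrom_b = cc[2L],
        n_anchors = nrow(rows), orientation = ch$orientation,
        oi = NA_real_, median_ks = stats::median(rows$ks, na.rm = TRUE),
        stringsAsFactors = FALSE)
      anch_rows[[bid]] <- data.frame(
        block_id = bid, gene_a = rows$gene_a, gene_b = rows$gene_b,
        rank_a = rows$rank_a, rank_b = rows$rank_b, ks = rows$ks,
        is_ortholog = NA, stringsAsFactors = FALSE)
    }
  }
  if (!bid) return(out)
  out$blocks <- do.call(rbind, blocks)
  out$anchors <- do.call(rbind, anch_rows)
  rownames(out$blocks) <- rownames(out$anchors) <- NULL
  check_block_invariants(out)
  out
}

empty_blocks <- function(id_a, id_b) {
  structure(list(
    blocks = data.frame(block_id = integer(), chrom_a = character(),
                        chrom_b = character(), n_anchors = integer(),
                        orientation = character(), oi = numeric(),
                        median_ks = numeric()),
    anchors = data.frame(block_id = integer(), gene_a = character(),
                         gene_b = character(), rank_a = integer(),
                         rank_b = integer(), ks = numeric(),
                         is_ortholog = logical()),
    genome_a = id_a, genome_b = id_b), class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("synteny_blocks %s vs %s: %d blocks, %d anchors\n",
              x$genome_a, x$genome_b, nrow(x$blocks), nrow(x$anchors)))
  invisible(x)
}

collapse_tandems <- function(g) {
  if (all(is.na(g$locus))) return(g)
  g <- g[order(g$chromosome, g$rank), , drop = FALSE]
  same <- c(FALSE, g$locus[-1L] == g$locus[-nrow(g)] &
              g$chromosome[-1L] == g$chromosome[-nrow(g)])
  same[is.na(same)] <- FALSE
  out <- g[!same, , drop = FALSE]
  attr(out, "genome_id") <- genome_id(g)
  class(out) <- class(g)
  out
}

# Best-first extraction of collinear chains from rank pairs.
# Returns list of list(idx (into input), orientation).
peel_chains <- function(ra, rb, min_block_size, max_gap) {
  active <- seq_along(ra)
  chains <- list()
  while (length(active) >= min_block_size) {
    cp <- best_chain(ra[active], rb[active], max_gap, decreasing = FALSE)
    cm <- best_chain(ra[active], rb[active], max_gap, decreasing = TRUE)
    if (length(cp) >= length(cm)) { chain <- cp; ori <- "+" }
    else { chain <- cm; ori <- "-" }
    if (length(chain) < min_block_size) break
    chains[[length(chains) + 1L]] <- list(idx = active[chain],
                                          orientation = ori)
    active <- setdiff(active, active[chain])
  }
  chains
}

# Longest chain by O(n^2) DP: strictly increasing rank_a, strictly monotone
# rank_b, both gaps <= max_gap.
best_chain <- function(ra, rb, max_gap, decreasing = FALSE) {
  n <- length(ra)
  if (!n) return(integer())
  if (decreasing) rb <- -rb
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  L <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    js <- which(ra[seq_len(i - 1L)] < ra[i] & ra[i] - ra[seq_len(i - 1L)] <= max_gap &
                rb[seq_len(i - 1L)] < rb[i] & rb[i] - rb[seq_len(i - 1L)] <= max_gap)
    if (length(js)) {
      j <- js[which.max(L[js])]
      L[i] <- L[j] + 1L
      prev[i] <- j
    }
  }
  i <- which.max(L)
  chain <- integer(L[i])
  k <- L[i]
  while (i > 0L) { chain[k] <- i; k <- k - 1L; i <- prev[i] }
  ord[chain]
}

check_block_invariants <- function(bl) {
  for (id in bl$blocks$block_id) {
    a <- bl$anchors[bl$anchors$block_id == id, , drop = FALSE]
    if (any(diff(a$rank_a) <= 0))
      stop("internal error: block ", id, " not strictly monotone in rank_a")
  }
  invisible(bl)
}

#' Score blocks with the orthology index
#'
#' The orthology index (OI) of a block is the fraction of its anchors whose
#' gene pair is in the ortholog set; it separates orthologous from
#' out-paralogous (WGD-derived) synteny.
#'
#' @param blocks a \code{synteny_blocks} object.
#' @param orthologs data frame of ortholog pairs (from
#'   \code{\link{call_orthologs}}).
#' @return \code{blocks} with \code{oi} filled in and per-anchor
#'   \code{is_ortholog} flags.
#' @export
score_orthology_index <- function(blocks, orthologs) {
  if (!nrow(blocks$anchors)) return(blocks)
  oset <- pair_key(orthologs$gene_a, orthologs$gene_b)
  blocks$anchors$is_ortholog <-
    pair_key(blocks$anchors$gene_a, blocks$anchors$gene_b) %in% oset
  oi <- tapply(blocks$anchors$is_ortholog, blocks$anchors$block_id, mean)
  blocks$blocks$oi <- as.numeric(oi[as.character(blocks$blocks$block_id)])
  blocks
}

#' Keep blocks whose orthology index reaches a cutoff
#'
#' @param blocks a scored \code{synteny_blocks} object.
#' @param cutoff OI cutoff in [0,1]; blocks with \code{oi >= cutoff} are
#'   kept, in stable order.
#' @return filtered \code{synteny_blocks}.
#' @export
filter_blocks <- function(blocks, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (!nrow(blocks$blocks)) return(blocks)
  if (anyNA(blocks$blocks$oi))
    stop("blocks are unscored; run score_orthology_index first")
  keep <- blocks$blocks$block_id[blocks$blocks$oi >= cutoff]
  blocks$blocks <- blocks$blocks[blocks$blocks$block_id %in% keep, ,
                                 drop = FALSE]
  blocks$anchors <- blocks$anchors[blocks$anchors$block_id %in% keep, ,
                                   drop = FALSE]
  blocks
}

#' Windowed orthologous synteny depth on a reference genome
#'
#' Partitions each reference chromosome into non-overlapping windows of
#' \code{window} gene ranks and counts, per window, the number of blocks
#' whose anchor span on the reference covers at least half of the window.
#' The reference must be one of the two genomes the blocks were computed
#' from.
#'
#' @param blocks filtered \code{synteny_blocks}.
#' @param reference_genome the reference \code{annotated_genome}.
#' @param window window size in ranks (default 10).
#' @return data frame chromosome, window_start, depth.
#' @export
synteny_depth <- function(blocks, reference_genome, window = 10) {
  rid <- genome_id(reference_genome)
  if (identical(blocks$genome_a, rid)) side <- "a"
  else if (identical(blocks$genome_b, rid)) side <- "b"
  else stop("reference genome '", rid, "' is not a side of these blocks")
  chrom_col <- paste0("chrom_", side); rank_col <- paste0("rank_", side)
  spans <- NULL
  if (nrow(blocks$anchors)) {
    a <- blocks$anchors
    a$chrom <- blocks$blocks[[chrom_col]][match(a$block_id,
                                                blocks$blocks$block_id)]
    lo <- tapply(a[[rank_col]], a$block_id, min)
    hi <- tapply(a[[rank_col]], a$block_id, max)
    spans <- data.frame(
      chrom = blocks$blocks[[chrom_col]][match(as.integer(names(lo)),
                                               blocks$blocks$block_id)],
      lo = as.integer(lo), hi = as.integer(hi))
  }
  rows <- list()
  for (chr in sort(unique(reference_genome$chromosome))) {
    len <- sum(reference_genome$chromosome == chr)
    starts <- seq(0L, len - 1L, by = window)
    for (w0 in starts) {
      w1 <- min(w0 + window, len) - 1L  # inclusive
      need <- (w1 - w0 + 1L) / 2
      depth <- 0L
      if (!is.null(spans)) {
        s <- spans[spans$chrom == chr, , drop = FALSE]
        if (nrow(s)) {
          cov <- pmax(0L, pmin(s$hi, w1) - pmax(s$lo, w0) + 1L)
          depth <- sum(cov >= need)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chr, window_start = w0, depth = depth,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write syntenic blocks as a plain-text TSV
#'
#' Emits the block table followed by anchor rows, a documented plain-text
#' collinearity dialect (header lines start '#').
#'
#' @param blocks a \code{synteny_blocks} object.
#' @param path output path.
#' @param header optional extra provenance header lines.
#' @export
write_blocks <- function(blocks, path, header = character()) {
  m <- merge(blocks$blocks, blocks$anchors, by = "block_id", sort = FALSE)
  write_hash_tsv(m, path, c(header, paste0("genome_a=", blocks$genome_a,
                                           " genome_b=", blocks$genome_b)))
}
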
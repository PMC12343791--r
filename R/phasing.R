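#' Assign polyploid chromosomes to subgenomes by synteny matching
#'
#' Matches each chromosome of a polyploid to a chromosome of an already
#' phased reference by maximum-weight bipartite matching, where the weight
#' of a (query chromosome, reference chromosome) pair is the number of
#' orthologous anchors connecting them in the OI-filtered blocks. Each
#' reference chromosome provides \code{capacity} slots (default
#' \code{ceiling(n_query / n_reference)}, the relative-ploidy excess), so a
#' tetraploid's two homoeologous chromosomes can both match the same
#' reference chromosome. The assigned label is the reference chromosome's
#' subgenome label. Chromosomes without orthologous anchors are reported
#' \code{"unassigned"} with a warning. Per-chromosome evidence (anchor
#' counts to every reference chromosome, mean OI) is retained so that
#' chimeric post-fusion chromosomes can be inspected at segment level.
#'
#' @param polyploid query \code{annotated_genome}.
#' @param phased_reference reference \code{annotated_genome} whose
#'   \code{subgenome} column is filled.
#' @param blocks OI-filtered \code{synteny_blocks} between the two genomes.
#' @param capacity slots per reference chromosome (NULL = automatic).
#' @return object of class \code{subgenome_assignment}: list with
#'   \code{labels} (named character vector by query chromosome),
#'   \code{assignment} data frame and \code{evidence} data frame.
#' @export
match_subgenomes <- function(polyploid, phased_reference, blocks,
                             capacity = NULL) {
  qid <- genome_id(polyploid); rid <- genome_id(phased_reference)
  qside <- if (identical(blocks$genome_a, qid)) "a"
           else if (identical(blocks$genome_b, qid)) "b"
           else stop("polyploid is not a side of these blocks")
  rside <- setdiff(c("a", "b"), qside)
  if (!identical(blocks[[paste0("genome_", rside)]], rid))
    stop("reference is not the other side of these blocks")
  ref_label <- tapply(phased_reference$subgenome,
                      phased_reference$chromosome,
                      function(s) s[!is.na(s)][1L])
  b <- blocks$blocks
  b$qchrom <- b[[paste0("chrom_", qside)]]
  b$rchrom <- b[[paste0("chrom_", rside)]]
  w <- stats::aggregate(cbind(anchors = b$n_anchors),
                        by = list(qchrom = b$qchrom, rchrom = b$rchrom),
                        FUN = sum)
  oi_w <- stats::aggregate(cbind(oi = b$n_anchors * b$oi),
                           by = list(qchrom = b$qchrom, rchrom = b$rchrom),
                           FUN = sum)
  w$oi <- oi_w$oi / w$anchors
  w$ref_label <- unname(ref_label[w$rchrom])
  qchroms <- sort(unique(polyploid$chromosome))
  if (is.null(capacity))
    capacity <- ceiling(n_chromosomes(polyploid) /
                        n_chromosomes(phased_reference))
  # replicate reference slots and solve max-weight bipartite matching
  slots <- expand.grid(rchrom = sort(unique(phased_reference$chromosome)),
                       copy = seq_len(capacity), stringsAsFactors = FALSE)
  slot_id <- paste(slots$rchrom, slots$copy, sep = "#")
  edges <- w[w$qchrom %in% qchroms, , drop = FALSE]
  # deterministic tie-breaking: higher oi, then lexicographic ids
  edges <- edges[order(-edges$anchors, -edges$oi, edges$qchrom,
                       edges$rchrom), , drop = FALSE]
  el <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i)
    data.frame(from = edges$qchrom[i],
               to = slot_id[slots$rchrom == edges$rchrom[i]],
               # epsilon favors earlier (higher-oi) edges at equal weight
               weight = edges$anchors[i] + (nrow(edges) - i) * 1e-7,
               stringsAsFactors = FALSE)))
  labels <- stats::setNames(rep("unassigned", length(qchroms)), qchroms)
  matched_ref <- stats::setNames(rep(NA_character_, length(qchroms)), qchroms)
  if (!is.null(el) && nrow(el)) {
    g <- igraph::graph_from_data_frame(el, directed = FALSE)
    igraph::V(g)$type <- igraph::V(g)$name %in% slot_id
    m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
    mm <- m$matching
    for (q in intersect(qchroms, names(mm))) {
      if (!is.na(mm[[q]])) {
        rch <- sub("#[0-9]+$", "", mm[[q]])
        matched_ref[q] <- rch
        labels[q] <- unname(ref_label[rch])
      }
    }
  }
  if (any(labels == "unassigned"))
    warning("unassigned chromosomes (no orthologous anchors): ",
            paste(names(labels)[labels == "unassigned"], collapse = ", "))
  ev <- w[order(w$qchrom, -w$anchors), , drop = FALSE]
  rownames(ev) <- NULL
  assignment <- data.frame(
    genome = qid, chromosome = qchroms, label = unname(labels),
    matched_ref = unname(matched_ref),
    anchors = vapply(qchroms, function(q) {
      i <- which(w$qchrom == q & w$rchrom == matched_ref[q])
      if (length(i)) sum(w$anchors[i]) else 0L
    }, 0),
    oi = vapply(qchroms, function(q) {
      i <- which(w$qchrom == q & w$rchrom == matched_ref[q])
      if (length(i)) w$oi[i][1L] else NA_real_
    }, 0), stringsAsFactors = FALSE)
  structure(list(genome_id = qid, labels = labels, assignment = assignment,
                 evidence = ev), class = "subgenome_assignment")
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat(sprintf("subgenome assignment for %s:\n", x$genome_id))
  print(table(x$labels))
  invisible(x)
}

#' Neighbor-joining tree of homologous chromosome copies
#'
#' Builds an unrooted NJ tree from a symmetric matrix of per-chromosome
#' median divergences (e.g., median block ks between matched copies).
#'
#' @param distance_matrix square symmetric numeric matrix with dimnames.
#' @return \pkg{ape} \code{phylo}.
#' @export
build_chromosome_tree <- function(distance_matrix) {
  distance_matrix <- as.matrix(distance_matrix)
  if (nrow(distance_matrix) != ncol(distance_matrix))
    stop("distance matrix must be square")
  if (max(abs(distance_matrix - t(distance_matrix))) > 1e-8)
    stop("distance matrix must be symmetric")
  ape::nj(stats::as.dist(distance_matrix))
}

#' Resolve relative A/B subgenome labels by topology voting
#'
#' Given per-chromosome trees containing two candidate homoeologous copies,
#' a C-subgenome reference tip and an outgroup, labels as B the candidate
#' that is more often sister to C (after rooting with the outgroup), and as
#' A the other, reporting the majority fraction. With no C reference the
#' candidates cannot be polarized and relative labels (X1/X2) are returned;
#' an exact 50/50 vote is likewise unresolved.
#'
#' @param trees list of \code{phylo} objects.
#' @param candidates character vector of the two candidate tip labels.
#' @param c_tip label of the C-reference tip (NA when unavailable).
#' @param outgroup outgroup tip label used to root each tree.
#' @param relative_prefix prefix for relative labels when unresolved.
#' @return list(labels = named character vector over candidates,
#'   support = majority fraction, votes = integer vector, resolved =
#'   logical).
#' @export
resolve_ab_by_topology <- function(trees, candidates, c_tip = NA,
                                   outgroup = NULL,
                                   relative_prefix = "X") {
  stopifnot(length(candidates) == 2L)
  relative <- stats::setNames(paste0(relative_prefix, 1:2), candidates)
  if (is.na(c_tip))
    return(list(labels = relative, support = NA_real_,
                votes = c(0L, 0L), resolved = FALSE))
  votes <- c(0L, 0L)
  for (tr in trees) {
    need <- c(candidates, c_tip, outgroup)
    if (!all(need %in% tr$tip.label)) next
    sub <- ape::keep.tip(tr, need)
    if (!is.null(outgroup)) {
      sub <- tryCatch(ape::root(sub, outgroup = outgroup,
                                resolve.root = TRUE),
                      error = function(e) NULL)
      if (is.null(sub)) next
    }
    # which candidate forms a cherry with the C tip?
    for (k in 1:2) {
      pair <- c(candidates[k], c_tip)
      mrca <- ape::getMRCA(sub, pair)
      tips_below <- ape::extract.clade(sub, mrca)$tip.label
      if (setequal(tips_below, pair)) votes[k] <- votes[k] + 1L
    }
  }
  if (sum(votes) == 0L || votes[1L] == votes[2L])
    return(list(labels = relative, support = if (sum(votes)) 0.5 else NA_real_,
                votes = votes, resolved = FALSE))
  b_idx <- which.max(votes)
  labels <- stats::setNames(c("A", "B"),
                            c(candidates[-b_idx], candidates[b_idx]))
  list(labels = labels[candidates], support = max(votes) / sum(votes),
       votes = votes, resolved = TRUE)
}
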
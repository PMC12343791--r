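#' Reconstruct a proto-karyotype from multi-genome synteny
#'
#' Uses one genome as the backbone (by default the one with the most
#' chromosomes, i.e., the least fused) and splits backbone chromosomes
#' wherever at least \code{min_support} other genomes independently show
#' the same breakpoint — a position where the chromosome's orthologous
#' anchors switch from tiling one partner chromosome to tiling a different
#' one, each side being a syntenic unit of at least \code{min_segment}
#' anchors. A backbone chromosome nobody splits is accepted as an ancestral
#' proto-chromosome. A fusion shared by every genome including the backbone
#' cannot be polarized without outgroup evidence and is retained as a
#' single proto-chromosome (parsimony limit).
#'
#' @param genomes list of >= 3 annotated genomes.
#' @param blocks_list list of OI-filtered \code{synteny_blocks}, each
#'   computed between the backbone reference and one other genome.
#' @param reference the backbone \code{annotated_genome}; NULL picks the
#'   genome with the most chromosomes (ties: lexicographic id).
#' @param min_support number of genomes that must exhibit a breakpoint.
#' @param min_segment minimum anchors per syntenic unit.
#' @param tolerance rank tolerance when clustering breakpoints.
#' @return object of class \code{proto_karyotype}: list with
#'   \code{proto_chromosomes} (named list of ordered backbone gene ids),
#'   \code{N}, \code{reference_id} and the accepted \code{splits}.
#' @export
build_proto_karyotype <- function(genomes, blocks_list, reference = NULL,
                                  min_support = 2, min_segment = 10,
                                  tolerance = 10) {
  if (length(genomes) < 3L) stop("need >= 3 genomes")
  if (is.null(reference)) {
    ns <- vapply(genomes, n_chromosomes, 0L)
    ids <- vapply(genomes, genome_id, "")
    reference <- genomes[[order(-ns, ids)[1L]]]
  }
  rid <- genome_id(reference)
  total_anchors <- sum(vapply(blocks_list, function(b) nrow(b$anchors), 0L))
  if (total_anchors == 0L) stop("no orthologous synteny among input genomes")
  # per other genome: candidate breakpoints on each reference chromosome
  cand <- list()
  for (bl in blocks_list) {
    rside <- if (identical(bl$genome_a, rid)) "a"
             else if (identical(bl$genome_b, rid)) "b" else
               stop("blocks do not involve the reference '", rid, "'")
    oside <- setdiff(c("a", "b"), rside)
    other_id <- bl[[paste0("genome_", oside)]]
    if (identical(other_id, rid)) next
    b <- bl$blocks
    b$rchrom <- b[[paste0("chrom_", rside)]]
    b$ochrom <- b[[paste0("chrom_", oside)]]
    rrank <- paste0("rank_", rside)
    for (chr in unique(b$rchrom)) {
      ids_here <- b$block_id[b$rchrom == chr]
      a <- bl$anchors[bl$anchors$block_id %in% ids_here, , drop = FALSE]
      a$ochrom <- b$ochrom[match(a$block_id, b$block_id)]
      a <- a[order(a[[rrank]]), , drop = FALSE]
      segs <- partner_runs(a[[rrank]], a$ochrom, min_segment)
      if (nrow(segs) >= 2L) {
        # breakpoint between consecutive units mapping to distinct partners
        for (i in seq_len(nrow(segs) - 1L)) {
          if (segs$partner[i] != segs$partner[i + 1L])
            cand[[length(cand) + 1L]] <- data.frame(
              genome = other_id, chrom = chr,
              pos = (segs$hi[i] + segs$lo[i + 1L]) / 2,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else NULL
  splits <- list()
  if (!is.null(cand)) {
    for (chr in unique(cand$chrom)) {
      cc <- cand[cand$chrom == chr, , drop = FALSE]
      cc <- cc[order(cc$pos), , drop = FALSE]
      # single-linkage clustering within tolerance
      grp <- cumsum(c(1, diff(cc$pos) > tolerance))
      for (g in unique(grp)) {
        sub <- cc[grp == g, , drop = FALSE]
        if (length(unique(sub$genome)) >= min_support)
          splits[[length(splits) + 1L]] <- data.frame(
            chrom = chr, pos = stats::median(sub$pos),
            support = length(unique(sub$genome)),
            stringsAsFactors = FALSE)
      }
    }
  }
  splits <- if (length(splits)) do.call(rbind, splits) else
    data.frame(chrom = character(), pos = numeric(), support = integer())
  proto <- list()
  for (chr in sort(unique(reference$chromosome))) {
    genes <- reference$gene[reference$chromosome == chr][
      order(reference$rank[reference$chromosome == chr])]
    cuts <- sort(splits$pos[splits$chrom == chr])
    bounds <- c(0, cuts, length(genes))
    k <- length(bounds) - 1L
    for (i in seq_len(k)) {
      nm <- if (k == 1L) chr else paste0(chr, ".", i)
      lo <- floor(bounds[i]) + 1L; hi <- floor(bounds[i + 1L])
      proto[[nm]] <- genes[lo:hi]
    }
  }
  structure(list(proto_chromosomes = proto, N = length(proto),
                 reference_id = rid, splits = splits),
            class = "proto_karyotype")
}

# Maximal runs of anchors tiling a single partner chromosome; runs shorter
# than min_segment are dropped and flanking equal-partner runs merged.
partner_runs <- function(ranks, partners, min_segment) {
  stopifnot(length(ranks) == length(partners))
  if (!length(ranks)) return(data.frame(partner = character(),
                                        lo = numeric(), hi = numeric(),
                                        n = integer()))
  r <- rle(partners)
  segs <- data.frame(partner = r$values,
                     hi_i = cumsum(r$lengths))
  segs$lo_i <- segs$hi_i - r$lengths + 1L
  repeat {
    segs$n <- segs$hi_i - segs$lo_i + 1L
    drop <- which(segs$n < min_segment)
    if (!length(drop) || nrow(segs) == 1L) break
    # drop the shortest noise run, then re-merge equal neighbors
    segs <- segs[-drop[which.min(segs$n[drop])], , drop = FALSE]
    i <- 1L
    while (i < nrow(segs)) {
      if (segs$partner[i] == segs$partner[i + 1L]) {
        segs$hi_i[i] <- segs$hi_i[i + 1L]
        segs <- segs[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
  }
  segs$n <- segs$hi_i - segs$lo_i + 1L
  segs <- segs[segs$n >= min_segment, , drop = FALSE]
  data.frame(partner = segs$partner, lo = ranks[segs$lo_i],
             hi = ranks[segs$hi_i], n = segs$n, stringsAsFactors = FALSE)
}

#' @export
print.proto_karyotype <- function(x, ...) {
  cat(sprintf("proto_karyotype: N = %d (backbone %s)\n", x$N,
              x$reference_id))
  invisible(x)
}

#' Materialize a proto-karyotype as an annotated genome
#'
#' The proto-chromosome gene lists become chromosomes of a pseudo-genome
#' that downstream synteny and projection steps can use as a reference.
#'
#' @param proto a \code{proto_karyotype}.
#' @param genome_id identifier for the pseudo-genome (default "proto").
#' @return an \code{annotated_genome} whose gene ids are the backbone's.
#' @export
proto_as_genome <- function(proto, genome_id = "proto") {
  rows <- do.call(rbind, lapply(names(proto$proto_chromosomes), function(p)
    data.frame(gene = proto$proto_chromosomes[[p]], chromosome = p,
               stringsAsFactors = FALSE)))
  annotated_genome(rows, genome_id)
}

#' Project an extant genome onto the proto-karyotype
#'
#' Partitions each extant chromosome into maximal runs of orthologous
#' anchors to a single proto-chromosome; runs shorter than
#' \code{min_segment} anchors are treated as noise and merged into their
#' flanks. Within-segment order is deliberately ignored (inversions and
#' other intra-chromosomal rearrangements are outside the event grammar).
#'
#' @param genome extant \code{annotated_genome}.
#' @param proto a \code{proto_karyotype}.
#' @param blocks OI-filtered \code{synteny_blocks} between
#'   \code{proto_as_genome(proto)} and the genome.
#' @param min_segment minimum anchors per retained segment.
#' @return object of class \code{karyotype_map}: data frame with one row
#'   per segment (chromosome, segment_index, proto, start, end, n_anchors,
#'   orientation, subgenome) plus attributes.
#' @export
project_karyotype <- function(genome, proto, blocks, min_segment = 10) {
  gid <- genome_id(genome)
  gside <- if (identical(blocks$genome_b, gid)) "b"
           else if (identical(blocks$genome_a, gid)) "a"
           else stop("genome is not a side of these blocks")
  pside <- setdiff(c("a", "b"), gside)
  b <- blocks$blocks
  b$gchrom <- b[[paste0("chrom_", gside)]]
  b$pchrom <- b[[paste0("chrom_", pside)]]
  grank <- paste0("rank_", gside); prank <- paste0("rank_", pside)
  ggene <- paste0("gene_", gside)
  segs <- list()
  for (chr in sort(unique(b$gchrom))) {
    ids_here <- b$block_id[b$gchrom == chr]
    a <- blocks$anchors[blocks$anchors$block_id %in% ids_here, , drop = FALSE]
    a$pchrom <- b$pchrom[match(a$block_id, b$block_id)]
    # runs are keyed by (proto chromosome, subgenome of the extant copy) so
    # that a fusion joining two copies of the SAME proto-chromosome from
    # different subgenomes still yields two segments
    a$sub <- genome$subgenome[match(a[[ggene]], genome$gene)]
    a$runkey <- paste(a$pchrom, ifelse(is.na(a$sub), "0", a$sub),
                      sep = "\r")
    a <- a[order(a[[grank]], a$runkey), , drop = FALSE]
    runs <- partner_runs_idx(a[[grank]], a$runkey, min_segment)
    for (i in seq_len(nrow(runs))) {
      idx <- runs$lo_i[i]:runs$hi_i[i]
      rows <- a[idx, , drop = FALSE]
      ori <- if (nrow(rows) > 1L &&
                 stats::cor(rows[[grank]], rows[[prank]]) < 0) "-" else "+"
      key <- strsplit(runs$partner[i], "\r", fixed = TRUE)[[1L]]
      segs[[length(segs) + 1L]] <- data.frame(
        chromosome = chr, segment_index = i, proto = key[1L],
        start = min(rows[[grank]]), end = max(rows[[grank]]),
        n_anchors = nrow(rows), orientation = ori,
        subgenome = if (key[2L] == "0") NA_character_ else key[2L],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chromosome = character(), segment_index = integer(),
               proto = character(), start = integer(), end = integer(),
               n_anchors = integer(), orientation = character(),
               subgenome = character())
  rownames(out) <- NULL
  attr(out, "genome_id") <- gid
  attr(out, "proto_N") <- proto$N
  class(out) <- c("karyotype_map", "data.frame")
  out
}

# like partner_runs but returning anchor indices
partner_runs_idx <- function(ranks, partners, min_segment) {
  r <- rle(partners)
  segs <- data.frame(partner = r$values, hi_i = cumsum(r$lengths))
  segs$lo_i <- segs$hi_i - r$lengths + 1L
  # iteratively absorb sub-threshold noise runs
  repeat {
    segs$n <- segs$hi_i - segs$lo_i + 1L
    drop <- which(segs$n < min_segment)
    if (!length(drop) || nrow(segs) == 1L) break
    segs <- segs[-drop[which.min(segs$n[drop])], , drop = FALSE]
    i <- 1L
    while (i < nrow(segs)) {
      if (segs$partner[i] == segs$partner[i + 1L]) {
        segs$hi_i[i] <- segs$hi_i[i + 1L]
        segs <- segs[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
  }
  segs$n <- segs$hi_i - segs$lo_i + 1L
  segs <- segs[segs$n >= min_segment, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

segment_subgenome <- function(genome, chr, lo, hi) {
  s <- genome$subgenome[genome$chromosome == chr & genome$rank >= lo &
                          genome$rank <= hi]
  s <- s[!is.na(s)]
  if (!length(s)) return(NA_character_)
  names(sort(table(s), decreasing = TRUE))[1L]
}

#' Classify inter-chromosomal rearrangements from a karyotype map
#'
#' Reads the segment pattern of every extant chromosome against the
#' proto-karyotype and emits classified events. A segment is a "full body"
#' when it carries at least \code{full_body} of all anchors that its
#' (proto, subgenome) combination has genome-wide. Patterns: a full body
#' strictly interior to two flanking segments of one other proto is a
#' nested chromosome fusion (NCF, -1); adjacent full bodies are end-to-end
#' joinings (EEJ, -1), classified outermost-in when more than two bodies
#' share a chromosome; two chromosomes each ending in a partial body whose
#' main body sits on the other are one reciprocal translocation (RT, 0,
#' emitted once); a proto body split over two chromosomes with no partner
#' exchange is a fission (+1). Anything else is flagged COMPLEX with its
#' chromosome-number effect derived from arithmetic.
#'
#' @param kmap a \code{karyotype_map}.
#' @param proto the \code{proto_karyotype} it was projected onto.
#' @param full_body fraction of a proto body's anchors a segment must carry
#'   to count as a full body (default 0.8).
#' @return data frame of events: kind, chromosomes, bodies, subgenome,
#'   delta_n.
#' @export
classify_rearrangements <- function(kmap, proto, full_body = 0.8) {
  ev <- list()
  if (!nrow(kmap)) return(event_frame())
  kmap$body_key <- paste(kmap$proto,
                         ifelse(is.na(kmap$subgenome), "0", kmap$subgenome),
                         sep = "/")
  totals <- tapply(kmap$n_anchors, kmap$body_key, sum)
  kmap$full <- kmap$n_anchors >= full_body * totals[kmap$body_key]
  consumed <- rep(FALSE, nrow(kmap))
  add <- function(kind, chroms, bodies, sub, dn)
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, chromosomes = paste(chroms, collapse = ","),
      bodies = paste(sort(bodies), collapse = "+"),
      subgenome = paste(sort(unique(sub)), collapse = ","),
      delta_n = dn, stringsAsFactors = FALSE)
  for (chr in unique(kmap$chromosome)) {
    segs <- kmap[kmap$chromosome == chr, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    # NCF resolution: donor between two pieces of one host, outermost-in
    repeat {
      hit <- FALSE
      if (nrow(segs) >= 3L) for (i in 2:(nrow(segs) - 1L)) {
        if (segs$body_key[i - 1L] == segs$body_key[i + 1L] &&
            segs$body_key[i] != segs$body_key[i - 1L] && segs$full[i]) {
          add("NCF", chr, c(segs$proto[i], segs$proto[i - 1L]),
              c(segs$subgenome[i], segs$subgenome[i - 1L]), -1L)
          # merge the host pieces, drop the donor
          segs$end[i - 1L] <- segs$end[i + 1L]
          segs$n_anchors[i - 1L] <- segs$n_anchors[i - 1L] +
            segs$n_anchors[i + 1L]
          segs$full[i - 1L] <- segs$n_anchors[i - 1L] >=
            full_body * totals[segs$body_key[i - 1L]]
          segs <- segs[-c(i, i + 1L), , drop = FALSE]
          hit <- TRUE
          break
        }
      }
      if (!hit) break
    }
    if (nrow(segs) >= 2L && all(segs$full)) {
      for (i in seq_len(nrow(segs) - 1L))
        add("EEJ", chr, c(segs$proto[i], segs$proto[i + 1L]),
            c(segs$subgenome[i], segs$subgenome[i + 1L]), -1L)
    } else if (nrow(segs) >= 2L) {
      # mixed full/partial: joins among full bodies still count as EEJ;
      # partial terminals go to the global RT/fission pairing below
      fulls <- which(segs$full)
      if (length(fulls) >= 2L)
        for (k in seq_len(length(fulls) - 1L))
          add("EEJ", chr, c(segs$proto[fulls[k]], segs$proto[fulls[k + 1L]]),
              c(segs$subgenome[fulls[k]], segs$subgenome[fulls[k + 1L]]), -1L)
    }
  }
  # global RT / fission pairing over partial segments
  partials <- kmap[!kmap$full, , drop = FALSE]
  if (nrow(partials)) {
    # terminal = first or last segment of its chromosome
    term <- vapply(seq_len(nrow(partials)), function(i) {
      segs <- kmap[kmap$chromosome == partials$chromosome[i], , drop = FALSE]
      partials$start[i] == min(segs$start) || partials$end[i] == max(segs$end)
    }, TRUE)
    partials <- partials[term, , drop = FALSE]
    used <- rep(FALSE, nrow(partials))
    main_chrom <- function(body_key, not_chrom) {
      cand <- kmap[kmap$body_key == body_key &
                     kmap$chromosome != not_chrom, , drop = FALSE]
      if (!nrow(cand)) return(NA_character_)
      cand$chromosome[which.max(cand$n_anchors)]
    }
    for (i in seq_len(nrow(partials))) {
      if (used[i]) next
      mi <- main_chrom(partials$body_key[i], partials$chromosome[i])
      if (is.na(mi)) next
      # reciprocal partner: a partial on mi whose main body is back here
      j <- which(!used & partials$chromosome == mi &
                   partials$body_key != partials$body_key[i])
      j <- j[vapply(j, function(k)
        identical(main_chrom(partials$body_key[k], mi),
                  partials$chromosome[i]), TRUE)]
      if (length(j)) {
        j <- j[1L]
        add("RT", c(partials$chromosome[i], mi),
            c(partials$proto[i], partials$proto[j]),
            c(partials$subgenome[i], partials$subgenome[j]), 0L)
        used[i] <- used[j] <- TRUE
        # consume the complementary pieces of the same exchange so the
        # event is emitted once, not once per fragment
        comp <- which(!used &
          ((partials$chromosome == partials$chromosome[i] &
              partials$body_key == partials$body_key[j]) |
           (partials$chromosome == mi &
              partials$body_key == partials$body_key[i])))
        used[comp] <- TRUE
      }
    }
    # fissions: remaining split bodies without partner exchange
    for (i in seq_len(nrow(partials))) {
      if (used[i]) next
      twin <- which(!used & seq_len(nrow(partials)) > i &
                      partials$body_key == partials$body_key[i] &
                      partials$chromosome != partials$chromosome[i])
      if (length(twin)) {
        twin <- twin[1L]
        one_piece_chrom <- function(k)
          sum(kmap$chromosome == partials$chromosome[k]) == 1L
        if (one_piece_chrom(i) || one_piece_chrom(twin)) {
          add("FISSION", c(partials$chromosome[i],
                           partials$chromosome[twin]),
              partials$proto[i], partials$subgenome[i], 1L)
        } else {
          add("COMPLEX", c(partials$chromosome[i],
                           partials$chromosome[twin]),
              partials$proto[i], partials$subgenome[i], 0L)
        }
        used[i] <- used[twin] <- TRUE
      }
    }
  }
  if (!length(ev)) return(event_frame())
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

event_frame <- function() {
  data.frame(kind = character(), chromosomes = character(),
             bodies = character(), subgenome = character(),
             delta_n = integer())
}

#' Place classified events on a species tree
#'
#' An event whose (kind, proto bodies, subgenome) signature occurs in every
#' leaf descendant of an internal edge is placed once on that edge
#' (Dollo-style: identical breakpoints are assumed to arise once);
#' signatures shared by an incomplete set of descendants stay on the
#' terminal edges of the genomes that carry them.
#'
#' @param events_by_genome named list (by leaf label) of event data frames
#'   from \code{\link{classify_rearrangements}}.
#' @param species_tree \pkg{ape} \code{phylo} whose tips are the genome
#'   names; internal nodes are auto-labeled when needed.
#' @return data frame edge (child node label), kind, bodies, subgenome,
#'   delta_n.
#' @export
place_events_on_tree <- function(events_by_genome, species_tree) {
  tree <- label_tree_nodes(species_tree)
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  ev <- do.call(rbind, lapply(names(events_by_genome), function(g) {
    e <- events_by_genome[[g]]
    if (!nrow(e)) return(NULL)
    e$genome <- g
    e
  }))
  if (is.null(ev)) return(data.frame(edge = character(), kind = character(),
                                     bodies = character(),
                                     subgenome = character(),
                                     delta_n = integer()))
  ev$sig <- paste(ev$kind, ev$bodies, ev$subgenome, sep = "|")
  internals <- (ntip + 1L):(ntip + ape::Nnode(tree))
  clade_tips <- lapply(internals, function(nd)
    tree$tip.label[unlist(phangorn_desc(tree, nd))])
  placed <- list()
  for (s in unique(ev$sig)) {
    rows <- ev[ev$sig == s, , drop = FALSE]
    carriers <- unique(rows$genome)
    stem <- NULL
    if (length(carriers) >= 2L)
      for (k in seq_along(internals))
        if (setequal(clade_tips[[k]], carriers)) { stem <- k; break }
    if (!is.null(stem)) {
      row <- rows[1L, ]
      row$edge <- labs[internals[stem]]
      placed[[length(placed) + 1L]] <- row
    } else {
      rows$edge <- rows$genome
      placed[[length(placed) + 1L]] <- rows
    }
  }
  out <- do.call(rbind, placed)
  rownames(out) <- NULL
  out[, c("edge", "kind", "bodies", "subgenome", "delta_n")]
}

# tip numbers below a node (small, recursion fine)
phangorn_desc <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, phangorn_desc, tree = tree))
}

#' Chromosome-number trajectory along a tree
#'
#' Propagates the ancestral chromosome number down the tree, adding each
#' edge's summed \code{delta_n} (rearrangements and polyploidy additions
#' alike), and returns the expected n at every node.
#'
#' @param tree species tree (\code{phylo}); nodes auto-labeled as needed.
#' @param edge_events data frame with columns \code{edge} (child node
#'   label) and \code{delta_n}.
#' @param root_n chromosome number at the root.
#' @return named integer vector of n per node label.
#' @export
chromosome_number_trajectory <- function(tree, edge_events, root_n) {
  tree <- label_tree_nodes(tree)
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  nn <- ntip + ape::Nnode(tree)
  n <- rep(NA_integer_, nn)
  root <- ntip + 1L
  n[root] <- as.integer(root_n)
  for (e in rev(ape::postorder(tree))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    dn <- sum(edge_events$delta_n[edge_events$edge == labs[child]])
    n[child] <- n[parent] + as.integer(dn)
  }
  stats::setNames(n, labs)
}
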
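#' Create an ancestral genome for forward simulation
#'
#' Builds a diploid (monoploid-representation) ancestor with \code{n_chr}
#' chromosomes of \code{genes_per_chr} genes each. Every gene carries a
#' ground-truth ancestral locus identifier; gene identifiers encode
#' genome, subgenome and locus so that simulated descendants remain unique
#' after speciation and allopolyploidy.
#'
#' @param n_chr chromosome count of the ancestor (default 11, a typical
#'   eudicot proto-karyotype size).
#' @param genes_per_chr genes per chromosome (default 200).
#' @param genome_id identifier.
#' @return an \code{annotated_genome} with \code{locus} ground truth.
#' @export
ancestral_genome <- function(n_chr = 11, genes_per_chr = 200,
                             genome_id = "ancestor") {
  stopifnot(n_chr >= 1, genes_per_chr >= 1)
  chrom <- rep(sprintf("chr%02d", seq_len(n_chr)), each = genes_per_chr)
  idx <- rep(seq_len(genes_per_chr), n_chr)
  locus <- sprintf("L%02d.%04d", rep(seq_len(n_chr), each = genes_per_chr), idx)
  df <- data.frame(
    gene = gene_name(genome_id, NA_character_, locus),
    chromosome = chrom,
    start = (idx - 1) * 1000, end = (idx - 1) * 1000 + 500,
    strand = "+", locus = locus, subgenome = NA_character_,
    stringsAsFactors = FALSE)
  annotated_genome(df, genome_id)
}

gene_name <- function(genome_id, subgenome, locus) {
  sub <- ifelse(is.na(subgenome), "0", subgenome)
  sprintf("%s|%s|%s", genome_id, sub, locus)
}

# Reassign gene ids after a genome identity change (speciation/merge).
rename_genes <- function(g, genome_id) {
  g$gene <- gene_name(genome_id, g$subgenome, g$locus)
  if (anyDuplicated(g$gene))
    stop("gene renaming produced duplicates; loci not unique per subgenome")
  attr(g, "genome_id") <- genome_id
  g
}

chrom_genes <- function(g, chr) {
  sub <- g[g$chromosome == chr, , drop = FALSE]
  if (!nrow(sub)) stop("chromosome not found: ", chr)
  sub[order(sub$rank), , drop = FALSE]
}

reassemble <- function(g, pieces) {
  keep <- g[!(g$chromosome %in% unique(unlist(lapply(pieces, function(p)
    attr(p, "old_chroms"))))), , drop = FALSE]
  df <- rbind(keep, do.call(rbind, pieces))
  out <- recompute_ranks(df)
  attr(out, "genome_id") <- genome_id(g)
  class(out) <- class(g)
  out
}

piece <- function(df, new_chrom, old_chroms) {
  df$chromosome <- new_chrom
  # preserve the intended gene order through recompute_ranks via start coords
  df$start <- (seq_len(nrow(df)) - 1) * 1000
  df$end <- df$start + 500
  attr(df, "old_chroms") <- old_chroms
  df
}

#' Chromosome rearrangement operators
#'
#' The three inter-chromosomal operators of descending dysploidy plus
#' fission. \code{apply_eej} joins two whole chromosomes end to end
#' (chromosome number decreases by 1). \code{apply_ncf} inserts one whole
#' chromosome into the interior of another (nested chromosome fusion; -1).
#' \code{apply_rt} exchanges the terminal segments of two chromosomes
#' (reciprocal translocation; chromosome number unchanged).
#' \code{apply_fission} splits a chromosome in two (+1). All operators
#' conserve gene content; intra-chromosomal order is tracked by rank.
#'
#' @param genome an \code{annotated_genome}.
#' @param chr_a,chr_b chromosome identifiers.
#' @param orientation two-character string over \{+,-\}: whether each body
#'   enters the fusion in its original (+) or reversed (-) order.
#' @return the rearranged \code{annotated_genome}.
#' @export
apply_eej <- function(genome, chr_a, chr_b, orientation = "++") {
  if (chr_a == chr_b) stop("EEJ requires two distinct chromosomes")
  a <- chrom_genes(genome, chr_a); b <- chrom_genes(genome, chr_b)
  ori <- strsplit(orientation, "")[[1L]]
  stopifnot(length(ori) == 2L, all(ori %in% c("+", "-")))
  if (ori[1L] == "-") a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
  if (ori[2L] == "-") b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  fused <- piece(rbind(a, b), paste(chr_a, chr_b, sep = "+"),
                 c(chr_a, chr_b))
  reassemble(genome, list(fused))
}

#' @rdname apply_eej
#' @param host_chr,donor_chr host and donor chromosomes for nested fusion.
#' @param insert_pos rank in the host before which the donor body is
#'   inserted; must be strictly interior (an end insertion would be an EEJ).
#' @export
apply_ncf <- function(genome, host_chr, insert_pos, donor_chr) {
  if (host_chr == donor_chr) stop("NCF requires two distinct chromosomes")
  h <- chrom_genes(genome, host_chr); d <- chrom_genes(genome, donor_chr)
  if (is.null(insert_pos) || is.na(insert_pos))
    stop("insert_pos required (use schedule_ncf for a random draw)")
  if (insert_pos <= 0L || insert_pos >= nrow(h))
    stop("insert_pos must be strictly interior to the host (got ",
         insert_pos, " for host of length ", nrow(h), ")")
  body <- rbind(h[seq_len(insert_pos), , drop = FALSE], d,
                h[(insert_pos + 1L):nrow(h), , drop = FALSE])
  fused <- piece(body, host_chr, c(host_chr, donor_chr))
  reassemble(genome, list(fused))
}

#' @rdname apply_eej
#' @param pos_a,pos_b ranks at which the terminal segments begin; genes at
#'   rank >= pos are exchanged. Rank 0 gives a whole-arm exchange.
#' @export
apply_rt <- function(genome, chr_a, pos_a, chr_b, pos_b) {
  if (chr_a == chr_b) stop("RT requires two distinct chromosomes")
  a <- chrom_genes(genome, chr_a); b <- chrom_genes(genome, chr_b)
  if (pos_a < 0L || pos_a > nrow(a) || pos_b < 0L || pos_b > nrow(b))
    stop("RT breakpoints out of range")
  head_a <- a[seq_len(pos_a), , drop = FALSE]
  tail_a <- a[setdiff(seq_len(nrow(a)), seq_len(pos_a)), , drop = FALSE]
  head_b <- b[seq_len(pos_b), , drop = FALSE]
  tail_b <- b[setdiff(seq_len(nrow(b)), seq_len(pos_b)), , drop = FALSE]
  if (nrow(head_a) + nrow(tail_b) == 0L || nrow(head_b) + nrow(tail_a) == 0L)
    stop("RT would empty a chromosome")
  new_a <- piece(rbind(head_a, tail_b), chr_a, chr_a)
  new_b <- piece(rbind(head_b, tail_a), chr_b, chr_b)
  reassemble(genome, list(new_a, new_b))
}

#' @rdname apply_eej
#' @param chr chromosome to split.
#' @param pos rank at which the split occurs (genes at rank >= pos go to the
#'   second product); must be interior.
#' @export
apply_fission <- function(genome, chr, pos) {
  c1 <- chrom_genes(genome, chr)
  if (pos <= 0L || pos >= nrow(c1)) stop("fission position must be interior")
  p1 <- piece(c1[seq_len(pos), , drop = FALSE], paste0(chr, ".1"), chr)
  p2 <- piece(c1[(pos + 1L):nrow(c1), , drop = FALSE], paste0(chr, ".2"),
              character())
  reassemble(genome, list(p1, p2))
}

#' Merge two genomes by allopolyploidization
#'
#' The chromosome sets are united; chromosomes whose genes lack a subgenome
#' label receive \code{label_a}/\code{label_b} and chromosome identifiers of
#' newly labeled chromosomes are prefixed with the label to keep them unique.
#' Gene identifiers are regenerated from (merged id, subgenome, locus).
#'
#' @param genome_a,genome_b genomes to merge (\code{genome_b} may carry its
#'   own labels from an earlier polyploidy, which are preserved).
#' @param label_a,label_b subgenome labels for currently unlabeled genes.
#' @param merged_id identifier of the merged genome.
#' @return merged \code{annotated_genome} with \code{n = n_a + n_b}.
#' @export
allopolyploidize <- function(genome_a, genome_b, label_a = "A", label_b = "B",
                             merged_id = NULL) {
  if (is.null(merged_id))
    merged_id <- paste0(genome_id(genome_a), "x", genome_id(genome_b))
  tag <- function(g, label) {
    un <- is.na(g$subgenome)
    if (any(un)) {
      g$subgenome[un] <- label
      relab <- unique(g$chromosome[un])
      g$chromosome[g$chromosome %in% relab] <-
        paste(label, g$chromosome[g$chromosome %in% relab], sep = ".")
    }
    g
  }
  a <- tag(as.data.frame(genome_a), label_a)
  b <- if (nrow(genome_b)) tag(as.data.frame(genome_b), label_b) else NULL
  clash <- intersect(unique(a$chromosome),
                     if (is.null(b)) character() else unique(b$chromosome))
  if (length(clash))
    stop("chromosome id clash after labeling: ", clash[1L])
  df <- rbind(a, b)
  g <- recompute_ranks(df)
  attr(g, "genome_id") <- merged_id
  class(g) <- c("annotated_genome", "data.frame")
  rename_genes(g, merged_id)
}

#' Randomly delete genes with per-subgenome loss probabilities
#'
#' Each gene is deleted independently with the loss probability of its
#' subgenome (biased fractionation). A chromosome is never emptied: if all
#' its genes are lost the chromosome is redrawn until at least one survives.
#' Uses R's global RNG; seed with \code{set.seed()} for reproducibility.
#'
#' @param genome an \code{annotated_genome}.
#' @param loss_prob single probability in [0,1), or a named vector of
#'   probabilities by subgenome label (name \code{"0"} covers unlabeled
#'   genes; labels missing from the vector lose nothing).
#' @return fractionated genome with ranks recomputed.
#' @export
fractionate <- function(genome, loss_prob) {
  if (is.null(names(loss_prob))) {
    stopifnot(length(loss_prob) == 1L)
    p <- rep(loss_prob, nrow(genome))
  } else {
    lab <- ifelse(is.na(genome$subgenome), "0", genome$subgenome)
    p <- unname(loss_prob[lab])
    p[is.na(p)] <- 0
  }
  if (any(p >= 1)) stop("loss probability must be < 1")
  if (any(p < 0)) stop("loss probability must be >= 0")
  lose <- stats::runif(nrow(genome)) < p
  # resample chromosomes that would lose every gene
  for (chr in unique(genome$chromosome[lose])) {
    i <- which(genome$chromosome == chr)
    guard <- 0L
    while (all(lose[i])) {
      lose[i] <- stats::runif(length(i)) < p[i]
      guard <- guard + 1L
      if (guard > 1000L) { lose[i[1L]] <- FALSE; break }
    }
  }
  g <- genome[!lose, , drop = FALSE]
  g <- recompute_ranks(g)
  attr(g, "genome_id") <- genome_id(genome)
  class(g) <- class(genome)
  g
}

# ---------------------------------------------------------------------------
# Scheduled forward evolution along a guide tree

#' Simulation configuration
#'
#' Bundles everything \code{\link{evolve}} needs. Events are scheduled
#' explicitly on tree branches (identified by the child node's label) so that
#' simulated histories are exact replicas of hypothesized ones; random draws
#' fill in unspecified positions.
#'
#' @param tree guide tree (\pkg{ape} \code{phylo}, branch lengths required);
#'   unlabeled internal nodes are auto-labeled \code{N1, N2, ...}.
#' @param events list of events from \code{\link{schedule_event}}.
#' @param ancestor_n,genes_per_chromosome ancestor dimensions.
#' @param fractionation named per-subgenome per-branch gene loss
#'   probabilities (applied once per edge); empty for lossless simulation.
#' @param ks_rate synonymous-distance accumulation per unit branch length
#'   (each lineage accumulates \code{ks_rate} per unit, so a pair separated
#'   for time t is \code{2*ks_rate*t} apart).
#' @param ks_noise_sd Gaussian noise added to each emitted pairwise ks.
#' @param score_noise integer half-width of uniform noise on homology scores.
#' @param seed integer seed consumed at the start of \code{evolve}.
#' @param gene_trees logical; also emit per-locus neighbor-joining trees
#'   from the true divergence distances.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(tree, events = list(), ancestor_n = 11,
                       genes_per_chromosome = 200,
                       fractionation = numeric(), ks_rate = 0.05,
                       ks_noise_sd = 0.03, score_noise = 5L, seed = 1L,
                       gene_trees = FALSE) {
  stopifnot(inherits(tree, "phylo"), ancestor_n >= 1)
  if (is.null(tree$edge.length)) stop("guide tree needs branch lengths")
  if (length(fractionation) && any(fractionation >= 1 | fractionation < 0))
    stop("fractionation probabilities must be in [0,1)")
  tree <- label_tree_nodes(tree)
  cfg <- list(tree = tree, events = events, ancestor_n = ancestor_n,
              genes_per_chromosome = genes_per_chromosome,
              fractionation = fractionation, ks_rate = ks_rate,
              ks_noise_sd = ks_noise_sd, score_noise = as.integer(score_noise),
              seed = as.integer(seed), gene_trees = isTRUE(gene_trees))
  class(cfg) <- "sim_config"
  validate_schedule(cfg)
  cfg
}

label_tree_nodes <- function(tree) {
  n <- ape::Nnode(tree)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyNA(tree$node.label)) {
    lab <- if (is.null(tree$node.label)) rep("", n) else tree$node.label
    need <- !nzchar(lab) | is.na(lab)
    lab[need] <- paste0("N", which(need))
    tree$node.label <- lab
  }
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("tree node labels not unique")
  tree
}

#' Schedule a rearrangement or polyploidy event on a tree branch
#'
#' @param branch label of the child node of the edge the event occurs on.
#' @param kind one of EEJ, NCF, RT, FISSION, ALLOPOLYPLOIDY, AUTOPOLYPLOIDY.
#' @param ... kind-specific parameters: chromosomes/positions for the
#'   rearrangement operators (omitted ones are drawn uniformly at run time);
#'   for ALLOPOLYPLOIDY: \code{label_existing}, \code{label_new},
#'   \code{divergence} (pairwise ks between the joining subgenome and the
#'   receiving genome at the time of merging) and optionally
#'   \code{partner_events}, a list of functions applied to the partner
#'   diploid before merging.
#' @return event description list.
#' @export
schedule_event <- function(branch, kind, ...) {
  kind <- match.arg(kind, c("EEJ", "NCF", "RT", "FISSION",
                            "ALLOPOLYPLOIDY", "AUTOPOLYPLOIDY"))
  ev <- c(list(branch = branch, kind = kind), list(...))
  if (kind == "ALLOPOLYPLOIDY" && is.null(ev$label_new))
    stop("ALLOPOLYPLOIDY requires label_new")
  ev
}

validate_schedule <- function(cfg) {
  labs <- c(cfg$tree$tip.label, cfg$tree$node.label)
  for (ev in cfg$events) {
    if (!ev$branch %in% labs)
      stop("scheduled event references unknown branch: ", ev$branch)
    if (ev$branch == cfg$tree$node.label[1L])
      stop("cannot schedule an event on the root")
  }
  invisible(cfg)
}

node_number <- function(tree, label) {
  labs <- c(tree$tip.label, tree$node.label)
  i <- match(label, labs)
  if (is.na(i)) stop("unknown node label: ", label)
  i
}

node_depths <- function(tree) {
  # root-to-node path lengths, indexed by node number
  nn <- ape::Ntip(tree) + ape::Nnode(tree)
  d <- numeric(nn)
  root <- ape::Ntip(tree) + 1L
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    child <- tree$edge[e, 2L]; parent <- tree$edge[e, 1L]
    d[child] <- d[parent] + tree$edge.length[e]
  }
  d
}

#' Evolve gene orders along the guide tree
#'
#' Walks the guide tree from the root, replaying scheduled events on each
#' branch, applying per-branch fractionation, and tracking the divergence of
#' every subgenome lineage. At the leaves it emits the genomes, a complete
#' homology table (every surviving pair of copies of the same ancestral
#' locus, within and between genomes, with ks = true divergence + Gaussian
#' noise and score = round(1000*exp(-ks)) + integer noise), an event log,
#' and optionally per-locus gene trees.
#'
#' Lineage divergences: orthologous copies diverge at the leaves' most
#' recent common ancestor; a subgenome joining by allopolyploidy enters at
#' its stated progenitor divergence, modeled as a ghost lineage attached to
#' the receiving lineage's path half the divergence earlier. Distances
#' between any two copies follow from this augmented genealogy.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genomes} (named by leaf), \code{homology},
#'   \code{event_log}, \code{truth_orthologs} (cross-genome same-lineage
#'   pairs), \code{gene_trees} (if requested) and the config.
#' @export
evolve <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  depth <- node_depths(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  labs <- c(tree$tip.label, tree$node.label)
  anc <- ancestral_genome(config$ancestor_n, config$genes_per_chromosome,
                          genome_id = labs[root])
  events_by_branch <- split(config$events,
                            vapply(config$events, `[[`, "", "branch"))
  # the base lineage follows the guide tree itself: no attachment constraint
  origins_env$origins <- list(base = list(join_depth = 0, attach = Inf))
  log_rows <- list()
  leaves <- list()

  children <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]

  walk <- function(node, genome, orig_of) {
    # orig_of: named map subgenome label ("0" = unlabeled) -> origin id
    if (node <= ntip) {
      g <- rename_genes(genome, labs[node])
      leaves[[labs[node]]] <<- list(genome = g, orig_of = orig_of)
      return(invisible(NULL))
    }
    for (child in children(node)) {
      g <- genome
      oo <- orig_of
      for (ev in events_by_branch[[labs[child]]]) {
        res <- realize_event(g, ev, config, depth[child], labs[child], oo)
        g <- res$genome; oo <- res$orig_of
        log_rows[[length(log_rows) + 1L]] <<- res$log
      }
      if (length(config$fractionation)) {
        n_before <- nrow(g)
        g <- fractionate(g, config$fractionation)
      }
      walk(child, g, oo)
    }
  }
  walk(root, anc, c("0" = "base"))

  event_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(branch = character(), kind = character(),
               chromosomes = character(), delta_n = integer(),
               n_after = integer())
  rownames(event_log) <- NULL
  hom <- emit_homology(leaves, tree, depth, origins_env$origins, config)
  out <- list(genomes = lapply(leaves, `[[`, "genome"),
              homology = hom$pairs, truth_orthologs = hom$orthologs,
              event_log = event_log, config = config)
  if (config$gene_trees) out$gene_trees <- hom$gene_trees
  out
}

# Environment used to collect origins created during the walk (realize_event
# runs inside evolve's scope via this shared environment).
origins_env <- new.env(parent = emptyenv())

realize_event <- function(g, ev, config, child_depth, branch, orig_of) {
  pick_chr <- function(k, exclude = character(), min_len = 1L) {
    sizes <- table(g$chromosome)
    pool <- setdiff(names(sizes)[sizes >= min_len], exclude)
    if (length(pool) < k) stop("not enough chromosomes for event on ", branch)
    sample(pool, k)
  }
  delta <- 0L; chroms <- ""
  if (ev$kind == "EEJ") {
    ab <- c(ev$chr_a, ev$chr_b)
    if (length(ab) < 2L) ab <- c(ab, pick_chr(2L - length(ab), ab))
    g <- apply_eej(g, ab[1L], ab[2L], orientation = ev$orientation %||% "++")
    delta <- -1L; chroms <- paste(ab, collapse = ",")
  } else if (ev$kind == "NCF") {
    hd <- c(ev$host, ev$donor)
    if (length(hd) < 2L)
      hd <- c(hd, pick_chr(2L - length(hd), hd, min_len = 3L))
    pos <- ev$insert_pos
    if (is.null(pos)) {
      len <- sum(g$chromosome == hd[1L])
      if (len < 3L) stop("host too short for NCF")
      pos <- sample(seq_len(len - 1L)[-1L] - 1L, 1L) + 1L  # 1..len-1
      pos <- max(1L, min(len - 1L, pos))
    }
    g <- apply_ncf(g, hd[1L], pos, hd[2L])
    delta <- -1L; chroms <- paste(hd, collapse = ",")
  } else if (ev$kind == "RT") {
    ab <- c(ev$chr_a, ev$chr_b)
    if (length(ab) < 2L)
      ab <- c(ab, pick_chr(2L - length(ab), ab, min_len = 2L))
    la <- sum(g$chromosome == ab[1L]); lb <- sum(g$chromosome == ab[2L])
    pa <- ev$pos_a %||% sample(seq_len(la - 1L), 1L)
    pb <- ev$pos_b %||% sample(seq_len(lb - 1L), 1L)
    g <- apply_rt(g, ab[1L], pa, ab[2L], pb)
    delta <- 0L; chroms <- paste(ab, collapse = ",")
  } else if (ev$kind == "FISSION") {
    chr <- ev$chr %||% pick_chr(1L, min_len = 2L)
    len <- sum(g$chromosome == chr)
    pos <- ev$pos %||% sample(seq_len(len - 1L), 1L)
    g <- apply_fission(g, chr, pos)
    delta <- 1L; chroms <- chr
  } else if (ev$kind %in% c("ALLOPOLYPLOIDY", "AUTOPOLYPLOIDY")) {
    auto <- ev$kind == "AUTOPOLYPLOIDY"
    partner <- ancestral_genome(config$ancestor_n,
                                config$genes_per_chromosome,
                                genome_id = "partner")
    for (f in ev$partner_events %||% list()) partner <- f(partner)
    np <- n_chromosomes(partner)
    label_new <- ev$label_new %||% if (auto) "X2" else "B"
    label_existing <- ev$label_existing %||% if (auto) "X1" else "A"
    g <- allopolyploidize(g, partner, label_a = label_existing,
                          label_b = label_new, merged_id = genome_id(g))
    divergence <- ev$divergence %||% if (auto) 0.01 else 0.4
    # ghost lineage attaches divergence/2 (ks units) above the merge point;
    # negative values place the progenitor split before the guide-tree root
    attach <- config$ks_rate * child_depth - divergence / 2
    oid <- paste0("o_", branch, "_", label_new)
    origins_env$origins[[oid]] <-
      list(join_depth = config$ks_rate * child_depth, attach = attach)
    # unlabeled genes acquired label_existing: map that label to its old origin
    if ("0" %in% names(orig_of) && !label_existing %in% names(orig_of)) {
      orig_of[[label_existing]] <- orig_of[["0"]]
      orig_of <- orig_of[names(orig_of) != "0"]
    }
    orig_of[[label_new]] <- oid
    delta <- np; chroms <- label_new
  }
  list(genome = g, orig_of = orig_of,
       log = data.frame(branch = branch, kind = ev$kind,
                        chromosomes = chroms, delta_n = delta,
                        n_after = n_chromosomes(g),
                        stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pairwise true divergence between two (leaf, origin) lineages.
# leaf1/leaf2 are tip labels; mrca_cache is ape::mrca output (label-indexed).
lineage_distance <- function(leaf1, o1, leaf2, o2, depth, leaf_num, origins,
                             ks_rate, mrca_cache) {
  d1 <- ks_rate * depth[leaf_num[[leaf1]]]
  d2 <- ks_rate * depth[leaf_num[[leaf2]]]
  dm <- if (leaf1 == leaf2) d1 else
    ks_rate * depth[mrca_cache[leaf1, leaf2]]
  if (identical(o1, o2)) {
    s <- dm
  } else {
    a1 <- origins[[o1]]$attach %||% Inf
    a2 <- origins[[o2]]$attach %||% Inf
    s <- min(dm, a1, a2)
  }
  (d1 - s) + (d2 - s)
}

emit_homology <- function(leaves, tree, depth, origins, config) {
  if (is.null(origins)) origins <- list(base = list(attach = 0))
  leaf_names <- names(leaves)
  leaf_num <- vapply(leaf_names, function(l) node_number(tree, l), 0L)
  # copies: one row per surviving gene copy
  copies <- do.call(rbind, lapply(leaf_names, function(l) {
    g <- leaves[[l]]$genome
    oo <- leaves[[l]]$orig_of
    lab <- ifelse(is.na(g$subgenome), "0", g$subgenome)
    data.frame(gene = g$gene, locus = g$locus, leaf = l,
               leaf_num = leaf_num[[l]],
               origin = unname(unlist(oo[lab])),
               stringsAsFactors = FALSE)
  }))
  mr <- ape::mrca(tree)
  split_loci <- split(seq_len(nrow(copies)), copies$locus)
  pair_rows <- vector("list", length(split_loci))
  gt <- if (config$gene_trees) vector("list", length(split_loci)) else NULL
  k <- 0L
  for (loc in names(split_loci)) {
    idx <- split_loci[[loc]]
    if (length(idx) < 2L) next
    k <- k + 1L
    cc <- copies[idx, , drop = FALSE]
    np <- length(idx)
    D <- matrix(0, np, np)
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      D[i, j] <- D[j, i] <- lineage_distance(
        cc$leaf[i], cc$origin[i], cc$leaf[j], cc$origin[j],
        depth, leaf_num, origins, config$ks_rate, mr)
    }
    ut <- which(upper.tri(D), arr.ind = TRUE)
    ks_true <- D[ut]
    ks_obs <- pmax(1e-6, ks_true + stats::rnorm(length(ks_true),
                                                sd = config$ks_noise_sd))
    score <- pmax(1, round(1000 * exp(-ks_obs)) +
      sample(-config$score_noise:config$score_noise, length(ks_obs),
             replace = TRUE))
    pair_rows[[k]] <- data.frame(
      gene_a = cc$gene[ut[, 1L]], gene_b = cc$gene[ut[, 2L]],
      score = score, ks = ks_obs,
      same_lineage = cc$origin[ut[, 1L]] == cc$origin[ut[, 2L]],
      cross = cc$leaf[ut[, 1L]] != cc$leaf[ut[, 2L]],
      stringsAsFactors = FALSE)
    if (config$gene_trees && np >= 3L) {
      dimnames(D) <- list(cc$gene, cc$gene)
      gt[[k]] <- ape::nj(stats::as.dist(D))
    }
  }
  pairs <- if (k) do.call(rbind, pair_rows[seq_len(k)]) else
    data.frame(gene_a = character(), gene_b = character(),
               score = numeric(), ks = numeric(),
               same_lineage = logical(), cross = logical())
  orth <- pairs[pairs$same_lineage & pairs$cross, c("gene_a", "gene_b")]
  out_pairs <- dedup_homology(
    pairs[, c("gene_a", "gene_b", "score", "ks")])
  list(pairs = out_pairs, orthologs = orth,
       gene_trees = if (config$gene_trees)
         Filter(Negate(is.null), gt) else NULL)
}

#' Simulate homoeolog expression with subgenome bias
#'
#' Draws TPM-like expression for every surviving gene copy, grouped by
#' ancestral locus. Expected relative shares within a homoeolog group follow
#' \code{shares} (renormalized over the subgenomes actually present);
#' replicate noise is gamma-distributed around the group total.
#'
#' @param genome an \code{annotated_genome} with subgenome labels and loci.
#' @param shares named mean expression share per subgenome label.
#' @param dispersion gamma dispersion of replicate noise (default 0.1).
#' @param n_rep replicates (default 3).
#' @param mean_total mean total expression per homoeolog group.
#' @param zero_frac fraction of groups silenced to ~0 total expression.
#' @return data frame gene, locus, subgenome, rep1..repK.
#' @export
simulate_expression <- function(genome, shares, dispersion = 0.1, n_rep = 3,
                                mean_total = 100, zero_frac = 0) {
  g <- genome[!is.na(genome$locus) & !is.na(genome$subgenome), , drop = FALSE]
  if (!nrow(g)) stop("genome has no labeled, locus-bearing genes")
  groups <- split(seq_len(nrow(g)), g$locus)
  rows <- vector("list", length(groups))
  silence <- stats::runif(length(groups)) < zero_frac
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    sg <- g$subgenome[idx]
    w <- shares[sg]
    w[is.na(w)] <- mean(shares)
    w <- w / sum(w)
    total <- if (silence[i]) stats::runif(1, 0, 0.5) else
      stats::rlnorm(1, log(mean_total), 0.5)
    mu <- total * w
    vals <- matrix(stats::rgamma(length(idx) * n_rep,
                                 shape = 1 / dispersion,
                                 scale = rep(mu, n_rep) * dispersion),
                   nrow = length(idx))
    colnames(vals) <- paste0("rep", seq_len(n_rep))
    rows[[i]] <- cbind(data.frame(gene = g$gene[idx], locus = g$locus[idx],
                                  subgenome = sg, stringsAsFactors = FALSE),
                       as.data.frame(vals))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
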
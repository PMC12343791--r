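#' Replay the Malvatheca polyploidy-dysploidy history at operator level
#'
#' Executes, on an 11-chromosome ancestor, the canonical decaploid history:
#' allotetraploidization (n doubles to 22), one nested chromosome fusion
#' within the tetraploid (21), three successive allopolyploid mergers with
#' 11-chromosome diploids (54), and one shared end-to-end joining between
#' an A- and a B-subgenome chromosome (53). Returns every intermediate
#' genome and the chromosome-number trajectory.
#'
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @return list(genomes = named list of the intermediates,
#'   trajectory = named integer vector of n at each stage).
#' @export
replay_malvatheca <- function(genes_per_chromosome = 200) {
  anc <- ancestral_genome(11, genes_per_chromosome, "PMK")
  tet <- allopolyploidize(ancestral_genome(11, genes_per_chromosome, "pA"),
                          ancestral_genome(11, genes_per_chromosome, "pB"),
                          "A", "B", merged_id = "AB")
  # the NCF involves chromosomes of both subgenomes (post-merger event)
  tet_ncf <- apply_ncf(tet, "A.chr01",
                       sum(tet$chromosome == "A.chr01") %/% 2L, "B.chr02")
  hex <- allopolyploidize(tet_ncf,
                          ancestral_genome(11, genes_per_chromosome, "pC"),
                          label_b = "C", merged_id = "ABC")
  oct <- allopolyploidize(hex,
                          ancestral_genome(11, genes_per_chromosome, "pD"),
                          label_b = "D", merged_id = "ABCD")
  dec <- allopolyploidize(oct,
                          ancestral_genome(11, genes_per_chromosome, "pE"),
                          label_b = "E", merged_id = "ABCDE")
  dec_eej <- apply_eej(dec, "A.chr03", "B.chr04")
  genomes <- list(ancestor = anc, tetraploid = tet, tetraploid_ncf = tet_ncf,
                  hexaploid = hex, octoploid = oct, decaploid = dec,
                  decaploid_eej = dec_eej)
  list(genomes = genomes,
       trajectory = vapply(genomes, n_chromosomes, 0L))
}

#' Replay the Byttneriina descending dysploidy (11 -> 10 -> 9)
#'
#' Two successive end-to-end joinings on an 11-chromosome diploid: first
#' between chromosomes 4 and 11 (n = 10), then a further EEJ (x = 9).
#'
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @return list(genomes, trajectory).
#' @export
replay_byttneriina <- function(genes_per_chromosome = 200) {
  anc <- ancestral_genome(11, genes_per_chromosome, "PMK")
  g10 <- apply_eej(anc, "chr04", "chr11")
  g9 <- apply_eej(g10, "chr01", "chr02")
  genomes <- list(ancestor = anc, after_eej1 = g10, after_eej2 = g9)
  list(genomes = genomes,
       trajectory = vapply(genomes, n_chromosomes, 0L))
}

#' Simulate a decaploid-to-cotton-like descent with scheduled EEJs
#'
#' Builds an \code{\link{evolve}} configuration on the tree
#' \code{((cotton, sister), outgroup)}: the shared Malvatheca history
#' (tetraploidization, NCF, three mergers to the decaploid, one shared EEJ;
#' n = 53) on the stem branch, then \code{n_eej} lineage-specific EEJs on
#' the cotton terminal branch (53 - n_eej chromosomes) with per-branch
#' fractionation. The outgroup diploid doubles as a proto-karyotype proxy.
#'
#' @param seed RNG seed.
#' @param n_eej lineage-specific EEJs on the cotton branch (default 40,
#'   taking 53 to 13).
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @param loss per-branch gene loss probability applied to every subgenome
#'   (default 0.105, compounding to roughly 20% root-to-tip).
#' @return the \code{evolve} result list.
#' @export
sim_cotton_descent <- function(seed = 1, n_eej = 40,
                               genes_per_chromosome = 60, loss = 0.105) {
  tree <- ape::read.tree(text = "((cotton:3,sister:3):3,outgroup:6);")
  stem <- list(
    schedule_event("N2", "ALLOPOLYPLOIDY", label_existing = "A",
                   label_new = "B", divergence = 0.30),
    schedule_event("N2", "NCF", host = "A.chr01", donor = "B.chr02",
                   insert_pos = genes_per_chromosome %/% 2L),
    schedule_event("N2", "ALLOPOLYPLOIDY", label_new = "C",
                   divergence = 0.34),
    schedule_event("N2", "ALLOPOLYPLOIDY", label_new = "D",
                   divergence = 0.38),
    schedule_event("N2", "ALLOPOLYPLOIDY", label_new = "E",
                   divergence = 0.42),
    schedule_event("N2", "EEJ", chr_a = "A.chr03", chr_b = "B.chr04"))
  terminal <- replicate(n_eej, schedule_event("cotton", "EEJ"),
                        simplify = FALSE)
  frac <- if (loss > 0)
    stats::setNames(rep(loss, 6), c("0", "A", "B", "C", "D", "E"))
  else numeric()
  cfg <- sim_config(tree, events = c(stem, terminal),
                    genes_per_chromosome = genes_per_chromosome,
                    fractionation = frac, ks_rate = 0.08, seed = seed)
  evolve(cfg)
}

#' Simulate diploid descendants of an 11-chromosome ancestor
#'
#' Four (by default) diploid genomes evolve from a common 11-chromosome
#' ancestor on a balanced tree, each receiving up to \code{max_fusions}
#' lineage-specific end-to-end joinings — the proto-karyotype
#' reconstruction benchmark.
#'
#' @param seed RNG seed.
#' @param n_genomes number of leaves (default 4).
#' @param max_fusions per-lineage EEJ count drawn from 0..max_fusions.
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @param loss per-branch gene loss probability.
#' @return the \code{evolve} result list.
#' @export
sim_diploid_radiation <- function(seed = 1, n_genomes = 4, max_fusions = 2,
                                  genes_per_chromosome = 60, loss = 0) {
  leaves <- paste0("g", seq_len(n_genomes))
  nwk <- paste0("(", paste0(leaves, ":5", collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  set.seed(seed)
  nf <- sample(0:max_fusions, n_genomes, replace = TRUE)
  if (all(nf == 0L)) nf[1L] <- 1L  # ensure the split logic is exercised
  events <- list()
  for (i in seq_len(n_genomes))
    events <- c(events, replicate(nf[i], schedule_event(leaves[i], "EEJ"),
                                  simplify = FALSE))
  frac <- if (loss > 0) c("0" = loss) else numeric()
  cfg <- sim_config(tree, events = events,
                    genes_per_chromosome = genes_per_chromosome,
                    fractionation = frac, ks_rate = 0.04,
                    seed = seed + 1L)
  evolve(cfg)
}

#' Simulate an allopolyploid with a diploid outgroup
#'
#' Minimal ploidy-estimation benchmark: one outgroup diploid and one
#' polyploid leaf carrying \code{p} subgenomes (successive allopolyploid
#' mergers at staggered progenitor divergences, all younger than the
#' outgroup split).
#'
#' @param seed RNG seed.
#' @param p target relative ploidy (>= 2).
#' @param n_chr ancestral chromosome number.
#' @param genes_per_chromosome genes per chromosome.
#' @param loss per-branch gene loss probability (0 = unfractionated).
#' @return the \code{evolve} result list.
#' @export
sim_polyploid_vs_outgroup <- function(seed = 1, p = 2, n_chr = 11,
                                      genes_per_chromosome = 60, loss = 0) {
  stopifnot(p >= 2)
  tree <- ape::read.tree(text = "(outgroup:6,poly:6);")
  labels <- LETTERS[seq_len(p)]
  events <- lapply(seq_len(p - 1L), function(i)
    schedule_event("poly", "ALLOPOLYPLOIDY",
                   label_existing = if (i == 1L) "A" else NULL,
                   label_new = labels[i + 1L],
                   divergence = 0.30 + 0.04 * (i - 1L)))
  frac <- if (loss > 0)
    stats::setNames(rep(loss, p + 1L), c("0", labels)) else numeric()
  cfg <- sim_config(tree, events = events, ancestor_n = n_chr,
                    genes_per_chromosome = genes_per_chromosome,
                    fractionation = frac, ks_rate = 0.08, seed = seed)
  evolve(cfg)
}

#' One-call orthologous-synteny workflow between two simulated genomes
#'
#' Convenience wrapper: reciprocal near-best ortholog calling, anchor
#' chaining, OI scoring and filtering.
#'
#' @param genome_a,genome_b annotated genomes.
#' @param pairs homology table covering both.
#' @param genomes all genomes for ortholog calling (defaults to the two).
#' @param cutoff OI cutoff (default 0.5).
#' @param ... passed to \code{\link{chain_anchors}}.
#' @return filtered \code{synteny_blocks}.
#' @export
orthologous_blocks <- function(genome_a, genome_b, pairs, genomes = NULL,
                               cutoff = 0.5, ...) {
  if (is.null(genomes)) genomes <- list(genome_a, genome_b)
  orth <- call_orthologs(pairs, genomes)
  bl <- chain_anchors(genome_a, genome_b, pairs, ...)
  filter_blocks(score_orthology_index(bl, orth), cutoff)
}
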
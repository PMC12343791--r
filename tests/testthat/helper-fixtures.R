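# Shared fixtures, built in code.

# A tiny genome from explicit chromosome gene lists.
mini_genome <- function(chroms, genome_id = "g") {
  rows <- do.call(rbind, lapply(names(chroms), function(ch) {
    genes <- chroms[[ch]]
    data.frame(gene = genes, chromosome = ch,
               start = (seq_along(genes) - 1) * 100,
               end = (seq_along(genes) - 1) * 100 + 50,
               strand = "+", stringsAsFactors = FALSE)
  }))
  annotated_genome(rows, genome_id)
}

# 1:1 homology between two genomes by shared suffix after the first "_".
suffix_pairs <- function(ga, gb, score = 100) {
  key <- function(g) sub("^[^_]*_", "", g$gene)
  m <- merge(data.frame(gene_a = ga$gene, k = key(ga)),
             data.frame(gene_b = gb$gene, k = key(gb)), by = "k")
  data.frame(gene_a = m$gene_a, gene_b = m$gene_b, score = score,
             ks = NA_real_, stringsAsFactors = FALSE)
}

# Exhaustive longest-collinear-chain oracle: plain recursion over the
# successor relation (no memoization, independent of the DP implementation).
oracle_longest_chain <- function(ra, rb, max_gap, decreasing = FALSE) {
  if (decreasing) rb <- -rb
  n <- length(ra)
  succ <- function(i) which(ra > ra[i] & ra - ra[i] <= max_gap &
                              rb > rb[i] & rb - rb[i] <= max_gap)
  ext <- function(i) {
    s <- succ(i)
    if (!length(s)) return(1L)
    1L + max(vapply(s, ext, 0L))
  }
  if (!n) return(0L)
  max(vapply(seq_len(n), ext, 0L))
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
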
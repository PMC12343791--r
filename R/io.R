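#' Construct an annotated genome from a gene table
#'
#' An annotated genome is a data frame of gene models, one row per gene, with
#' columns \code{gene}, \code{chromosome}, \code{rank} (0-based gene-order
#' index within its chromosome), and optionally \code{start}, \code{end},
#' \code{strand}, \code{locus} (ancestral locus, simulation ground truth) and
#' \code{subgenome}. The genome identifier is carried as an attribute.
#' Chromosomes are ordered lexicographically by identifier and ranks are
#' recomputed so that they are consecutive from 0 within each chromosome.
#'
#' @param df data frame with at least \code{gene} and \code{chromosome}
#'   columns; ordering within chromosomes is taken from \code{start} when
#'   present, else from \code{rank}, else from row order.
#' @param genome_id character scalar identifying the genome.
#' @return object of class \code{annotated_genome} (a data frame).
#' @export
annotated_genome <- function(df, genome_id) {
  stopifnot(is.data.frame(df), is.character(genome_id), length(genome_id) == 1L)
  req <- c("gene", "chromosome")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$gene <- as.character(df$gene)
  df$chromosome <- as.character(df$chromosome)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) stop("duplicate gene_id: ", dup[1L])
  for (col in c("strand", "locus", "subgenome"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df$start)) df$start <- NA_real_
  if (is.null(df$end)) df$end <- NA_real_
  if (any(!is.na(df$start) & !is.na(df$end) & df$end <= df$start))
    stop("end must be > start for coordinate-bearing genes")
  g <- recompute_ranks(df)
  attr(g, "genome_id") <- genome_id
  class(g) <- c("annotated_genome", "data.frame")
  g
}

# Sort chromosomes lexicographically, order genes by start (or prior rank),
# and reassign 0-based consecutive ranks.
recompute_ranks <- function(df) {
  key <- if (all(!is.na(df$start))) df$start
         else if (!is.null(df$rank) && all(!is.na(df$rank))) df$rank
         else seq_len(nrow(df))
  ord <- order(df$chromosome, key, df$gene, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$chromosome,
                        FUN = function(i) seq_along(i) - 1L)
  rownames(df) <- NULL
  df
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d chromosomes, %d genes\n",
              genome_id(x), n_chromosomes(x), nrow(x)))
  invisible(x)
}

#' Genome identifier and monoploid chromosome number
#'
#' @param g an \code{annotated_genome}.
#' @return \code{genome_id}: the identifier; \code{n_chromosomes}: the number
#'   of chromosomes (the monoploid/haploid chromosome number of the assembly).
#' @export
genome_id <- function(g) attr(g, "genome_id")

#' @rdname genome_id
#' @export
n_chromosomes <- function(g) length(unique(g$chromosome))

#' Read a gene-position table
#'
#' Reads a TSV of gene positions covering one or more genomes and returns one
#' annotated genome per \code{genome} value. Lines starting with '#' other
#' than the header are skipped. The table must provide columns
#' \code{genome}, \code{chromosome}, \code{gene} and either \code{start}/
#' \code{end} coordinates (bed-like; 0-based half-open) or a precomputed
#' \code{rank}. Unsorted input is sorted by start; ranks are always
#' reassigned from the sorted order.
#'
#' @param path file path.
#' @param dialect \code{"bed-like"} (start/end required) or
#'   \code{"gff-derived-tsv"} (rank-only rows allowed).
#' @return named list of \code{annotated_genome}, ordered by genome id.
#' @export
read_gene_table <- function(path, dialect = c("bed-like", "gff-derived-tsv")) {
  dialect <- match.arg(dialect)
  df <- read_hash_tsv(path)
  if (is.null(df) || nrow(df) == 0L) {
    warning("empty gene table: ", path)
    return(list())
  }
  req <- c("genome", "chromosome", "gene")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (dialect == "bed-like" && !all(c("start", "end") %in% names(df)))
    stop("bed-like dialect requires start and end columns")
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) stop("duplicate gene_id: ", dup[1L])
  ids <- sort(unique(as.character(df$genome)))
  out <- lapply(ids, function(id) {
    sub <- df[df$genome == id, setdiff(names(df), "genome"), drop = FALSE]
    annotated_genome(sub, id)
  })
  names(out) <- ids
  out
}

#' Write one or more annotated genomes as a gene-position TSV
#'
#' @param genomes a single \code{annotated_genome} or a list of them.
#' @param path output path.
#' @param header optional extra '#' header lines (provenance).
#' @export
write_gene_table <- function(genomes, path, header = character()) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(genome = genome_id(g), chromosome = g$chromosome,
               gene = g$gene, start = g$start, end = g$end,
               strand = g$strand, rank = g$rank, locus = g$locus,
               subgenome = g$subgenome, stringsAsFactors = FALSE)
  }))
  write_hash_tsv(rows, path, header)
}

#' Read a pairwise homology table
#'
#' Expects at least three columns (\code{gene_a}, \code{gene_b},
#' \code{score}) with an optional fourth \code{ks} column, the three-column
#' core being a subset of standard tabular search output. Self-pairs are
#' dropped; duplicate unordered pairs keep the maximum score (and its ks).
#'
#' @param path file path.
#' @return data frame with columns gene_a, gene_b, score, ks.
#' @export
read_homology <- function(path) {
  df <- read_hash_tsv(path)
  if (is.null(df) || nrow(df) == 0L) {
    warning("empty homology table: ", path)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), ks = numeric()))
  }
  if (ncol(df) < 3L) stop("homology table needs >= 3 columns")
  names(df)[1:3] <- c("gene_a", "gene_b", "score")
  if (ncol(df) >= 4L) names(df)[4L] <- "ks" else df$ks <- NA_real_
  df <- df[, c("gene_a", "gene_b", "score", "ks")]
  df$gene_a <- as.character(df$gene_a); df$gene_b <- as.character(df$gene_b)
  df$score <- as.numeric(df$score); df$ks <- as.numeric(df$ks)
  dedup_homology(df)
}

# Shared post-conditions for homology pair lists (also applied to simulated
# pairs): non-negative scores, no self pairs, unique unordered pairs.
dedup_homology <- function(df) {
  if (any(df$score < 0)) stop("negative homology score")
  if (any(!is.na(df$ks) & df$ks < 0)) stop("negative ks")
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  df <- df[order(key, -df$score, method = "radix"), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_a, df$gene_b, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a per-taxon trait table
#'
#' TSV keyed by \code{taxon}; remaining columns (monoploid chromosome number
#' \code{x}, relative ploidy \code{p}, retained syntenic genes \code{g},
#' richness, height, root-to-tip length \code{L}) pass through as numeric
#' where possible.
#'
#' @param path file path.
#' @return data frame with a \code{taxon} column.
#' @export
read_trait_table <- function(path) {
  df <- read_hash_tsv(path)
  if (is.null(df) || !"taxon" %in% names(df))
    stop("trait table requires a 'taxon' column")
  if ("x" %in% names(df) && any(df$x < 1, na.rm = TRUE))
    stop("x must be >= 1")
  if ("p" %in% names(df) && any(df$p < 1, na.rm = TRUE))
    stop("p must be >= 1")
  df$taxon <- as.character(df$taxon)
  df
}

#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape} that add position-reporting parenthesis
#' validation and default missing branch lengths to 0 with a warning.
#' Round-trips preserve topology and branch lengths to at least 6 decimals.
#'
#' @param path file path.
#' @param tree an \pkg{ape} \code{phylo} object.
#' @return \code{read_newick}: a \code{phylo}.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses at position ", i)
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unclosed at end")
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("failed to parse Newick: ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

# -- TSV plumbing: all tabular outputs are TSV whose header line starts '#'.

read_hash_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  # header = first line; strip a leading '#'; later '#' lines are comments
  header <- sub("^#\\s*", "", lines[1L])
  body <- lines[-1L]
  body <- body[!startsWith(body, "#")]
  cols <- strsplit(header, "\t")[[1L]]
  if (!length(body))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                           cols))
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) != length(cols))
    stop("column count mismatch in ", path)
  names(df) <- cols
  df
}

write_hash_tsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}
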
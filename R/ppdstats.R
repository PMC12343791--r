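#' Chromosome dysploidy rate
#'
#' Quantifies post-polyploid diploidization at the chromosome level as
#' \deqn{d_C = 1 - x / (N p)}{d_C = 1 - x/(N*p)}
#' where x is the extant monoploid chromosome number, N the monoploid
#' chromosome number of the ancestral karyotype, and p the relative ploidy.
#' Evaluated in exact rational arithmetic (integer x over integer N*p)
#' before any rounding; the 2-decimal value matching conventional reporting
#' is attached as an attribute.
#'
#' @param x extant monoploid chromosome number (>= 1).
#' @param N ancestral monoploid chromosome number (>= 1).
#' @param p relative ploidy (>= 1).
#' @return full-precision d_C (vectorized), with attribute
#'   \code{"reported"} = value rounded to 2 decimals. Values below 0
#'   (x > N*p) are allowed but flagged with a warning (ascending
#'   dysploidy).
#' @export
dysploidy_rate <- function(x, N, p) {
  stopifnot(all(x >= 1), all(N >= 1), all(p >= 1))
  d <- 1 - x / (N * p)
  if (any(d < 0))
    warning("x > N*p: ascending dysploidy (negative rate)")
  structure(d, reported = round(d, 2))
}

#' Gene loss rate
#'
#' Quantifies post-polyploid diploidization at the gene level as
#' \deqn{d_G = 1 - g / (G p)}{d_G = 1 - g/(G*p)}
#' where g is the number of retained syntenic genes, G the ancestral gene
#' count before polyploidization and p the relative ploidy. The number of
#' duplicated gene copies lost, \code{G*p - g}, is attached as an
#' attribute.
#'
#' @param g retained syntenic gene count.
#' @param G ancestral gene count.
#' @param p relative ploidy.
#' @return full-precision d_G with attributes \code{"reported"} (2
#'   decimals) and \code{"lost_copies"}.
#' @export
gene_loss_rate <- function(g, G, p) {
  stopifnot(all(g >= 0), all(G >= 1), all(p >= 1))
  d <- 1 - g / (G * p)
  structure(d, reported = round(d, 2), lost_copies = G * p - g)
}

#' Per-lineage nucleotide substitution rate
#'
#' \deqn{\mu = L / T} with L the root-to-tip branch length
#' (substitutions/site) and T the crown age in million years.
#'
#' @param L branch length from tip to crown node.
#' @param T_my crown age (My); must be > 0.
#' @return substitutions per site per million years.
#' @export
substitution_rate <- function(L, T_my) {
  if (any(T_my <= 0)) stop("crown age T must be > 0")
  L / T_my
}

#' Windowed gene retention per subgenome
#'
#' For each subgenome, walks the proto-karyotype in windows of
#' \code{window} ancestral loci and reports the fraction of loci with a
#' surviving copy in that subgenome — the profile in which biased
#' fractionation (unequal subgenome retention) is read.
#'
#' @param kmap_anchors data frame mapping ancestral loci to surviving
#'   copies: columns \code{proto_gene}, \code{subgenome} (one row per
#'   surviving copy). Conveniently built with
#'   \code{\link{retained_loci_table}}.
#' @param proto the \code{proto_karyotype}.
#' @param window loci per window (default 50).
#' @param subgenomes labels to profile; default all observed.
#' @return data frame subgenome, proto, window_start, retention; overall
#'   rates in attribute \code{"overall"}.
#' @export
retention_profile <- function(kmap_anchors, proto, window = 50,
                              subgenomes = NULL) {
  if (is.null(subgenomes))
    subgenomes <- sort(unique(kmap_anchors$subgenome))
  subgenomes <- subgenomes[!is.na(subgenomes)]
  if (!length(subgenomes)) {
    warning("no subgenome labels; empty retention profile")
    return(data.frame(subgenome = character(), proto = character(),
                      window_start = integer(), retention = numeric()))
  }
  rows <- list()
  overall <- stats::setNames(numeric(length(subgenomes)), subgenomes)
  for (sg in subgenomes) {
    have <- unique(kmap_anchors$proto_gene[
      kmap_anchors$subgenome == sg & !is.na(kmap_anchors$subgenome)])
    tot <- 0L; ret <- 0L
    for (pc in names(proto$proto_chromosomes)) {
      loci <- proto$proto_chromosomes[[pc]]
      tot <- tot + length(loci); ret <- ret + sum(loci %in% have)
      starts <- seq(0L, length(loci) - 1L, by = window)
      for (w0 in starts) {
        idx <- (w0 + 1L):min(w0 + window, length(loci))
        rows[[length(rows) + 1L]] <- data.frame(
          subgenome = sg, proto = pc, window_start = w0,
          retention = mean(loci[idx] %in% have), stringsAsFactors = FALSE)
      }
    }
    overall[sg] <- ret / tot
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall") <- overall
  out
}

#' Tabulate surviving copies of ancestral loci
#'
#' Builds the (ancestral locus, subgenome) survival table behind retention
#' and copy-number statistics from OI-filtered blocks between the
#' proto-genome and an extant genome.
#'
#' @param blocks \code{synteny_blocks} with \code{proto_as_genome()} output
#'   as one side.
#' @param proto_id genome id of the proto side (default "proto").
#' @param genome extant genome (for subgenome labels).
#' @return data frame proto_gene, gene, subgenome.
#' @export
retained_loci_table <- function(blocks, genome, proto_id = "proto") {
  pside <- if (identical(blocks$genome_a, proto_id)) "a"
           else if (identical(blocks$genome_b, proto_id)) "b"
           else stop("no side of the blocks is '", proto_id, "'")
  gcol <- if (pside == "a") "gene_b" else "gene_a"
  pcol <- if (pside == "a") "gene_a" else "gene_b"
  a <- blocks$anchors
  data.frame(proto_gene = a[[pcol]], gene = a[[gcol]],
             subgenome = genome$subgenome[match(a[[gcol]], genome$gene)],
             stringsAsFactors = FALSE)
}

#' Two-sided rank-sum test for retention bias
#'
#' Wilcoxon rank-sum (Mann-Whitney) comparison of two windowed retention
#' profiles: exact for small samples, normal approximation with continuity
#' correction above 20 per group.
#'
#' @param profile_a,profile_b numeric vectors of window retention
#'   fractions (>= 3 each).
#' @return two-sided p-value.
#' @export
bias_test <- function(profile_a, profile_b) {
  if (length(profile_a) < 3L || length(profile_b) < 3L)
    stop("need >= 3 windows per subgenome")
  exact <- max(length(profile_a), length(profile_b)) <= 20L
  stats::wilcox.test(profile_a, profile_b, alternative = "two.sided",
                     exact = exact, correct = TRUE)$p.value
}

#' Retained-copy-number histogram
#'
#' Counts, over ancestral loci, how many of the p subgenome copies survive
#' (0..p) — the shape from which long-term fractionation is read (most
#' loci return to single copy in old paleopolyploids).
#'
#' @param loci_table output of \code{\link{retained_loci_table}} (or any
#'   data frame with proto_gene and subgenome), restricted to one genome.
#' @param p relative ploidy (number of subgenome copies).
#' @param all_loci optional character vector of all ancestral loci, so that
#'   fully lost loci are counted in bin 0.
#' @return named integer vector of counts for 0..p copies; sums to the
#'   number of loci considered.
#' @export
copy_number_profile <- function(loci_table, p, all_loci = NULL) {
  copies <- tapply(loci_table$subgenome, loci_table$proto_gene,
                   function(s) length(unique(s[!is.na(s)])))
  seen <- names(copies)
  copies <- pmin(as.integer(copies), as.integer(p))
  counts <- tabulate(copies + 1L, nbins = p + 1L)
  if (!is.null(all_loci))
    counts[1L] <- counts[1L] + sum(!all_loci %in% seen)
  stats::setNames(counts, 0:p)
}

#' Homoeolog expression bias
#'
#' Converts a homoeolog expression table to relative shares (each group's
#' shares sum to 1), discards groups whose summed expression is below
#' \code{min_sum}, and compares subgenome share distributions pairwise by
#' rank-sum tests.
#'
#' @param expr data frame from \code{\link{simulate_expression}} or
#'   equivalent: gene, locus, subgenome, rep columns.
#' @param min_sum minimum summed mean expression per homoeolog group
#'   (default 1, the conventional TPM floor).
#' @return list(shares = data frame locus, subgenome, share;
#'   medians = named vector; tests = data frame pair, p_value).
#' @export
expression_bias <- function(expr, min_sum = 1) {
  repcols <- grep("^rep", names(expr), value = TRUE)
  if (!length(repcols)) stop("no replicate columns")
  expr$mean_tpm <- rowMeans(expr[, repcols, drop = FALSE])
  tot <- tapply(expr$mean_tpm, expr$locus, sum)
  keep <- names(tot)[tot >= min_sum]
  if (!length(keep)) stop("no data: all homoeolog groups below min_sum")
  e <- expr[expr$locus %in% keep, , drop = FALSE]
  e$share <- e$mean_tpm / as.numeric(tot[e$locus])
  subs <- sort(unique(e$subgenome))
  tests <- list()
  if (length(subs) >= 2L)
    for (i in seq_len(length(subs) - 1L)) for (j in (i + 1L):length(subs)) {
      pv <- stats::wilcox.test(e$share[e$subgenome == subs[i]],
                               e$share[e$subgenome == subs[j]],
                               exact = FALSE, correct = TRUE)$p.value
      tests[[length(tests) + 1L]] <- data.frame(
        pair = paste(subs[i], subs[j], sep = "-"), p_value = pv,
        stringsAsFactors = FALSE)
    }
  list(shares = e[, c("locus", "subgenome", "share")],
       medians = tapply(e$share, e$subgenome, stats::median),
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(pair = character(), p_value = numeric()))
}

#' Quartet support frequencies around a species-tree branch
#'
#' For the quartet induced by an internal branch (one representative leaf
#' from each of the two clades below it, one from its sibling side, one
#' from outside), counts how each gene tree resolves the quartet and
#' normalizes to frequencies q1 >= max(q2, q3) (q1 relabeled to the
#' species-tree resolution's frequency first, then ordered). An imbalance
#' between the two minority resolutions — the signature of introgression
#' rather than incomplete lineage sorting — is flagged by a two-sided exact
#' binomial test of the q2 vs q3 counts at alpha = 0.05.
#'
#' @param gene_trees list of \code{phylo}.
#' @param species_tree \code{phylo}.
#' @param branch internal node label (child end of the branch).
#' @return list(q = c(q1,q2,q3), counts, imbalance_p, imbalanced,
#'   quartet = the four representative tips).
#' @export
quartet_support <- function(gene_trees, species_tree, branch) {
  tree <- label_tree_nodes(species_tree)
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  nd <- node_number(tree, branch)
  if (nd <= ntip) stop("branch must be internal (child node label)")
  kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
  if (length(kids) < 2L) stop("degenerate branch")
  t1 <- tree$tip.label[phangorn_desc(tree, kids[1L])[1L]]
  t2 <- tree$tip.label[phangorn_desc(tree, kids[2L])[1L]]
  parent <- tree$edge[tree$edge[, 2L] == nd, 1L]
  if (!length(parent)) stop("branch is the root")
  sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], nd)
  t3 <- tree$tip.label[phangorn_desc(tree, sibs[1L])[1L]]
  below <- tree$tip.label[phangorn_desc(tree, parent)]
  out_tips <- setdiff(tree$tip.label, below)
  if (!length(out_tips)) stop("no outgroup side for this branch")
  t4 <- out_tips[1L]
  quartet <- c(t1, t2, t3, t4)
  # resolutions keyed by which pair of {t1,t2,t3} is joined against t4 side
  counts <- c(0L, 0L, 0L)  # (t1,t2) | (t1,t3) | (t2,t3)
  for (gt in gene_trees) {
    if (!all(quartet %in% gt$tip.label)) next
    sub <- ape::unroot(ape::keep.tip(gt, quartet))
    res <- quartet_resolution(sub, t1, t2, t3, t4)
    if (!is.na(res)) counts[res] <- counts[res] + 1L
  }
  if (sum(counts) == 0L) stop("0 informative gene trees for this branch")
  q <- counts / sum(counts)
  # species tree joins (t1,t2): that frequency is the concordant one
  ord <- c(1L, order(q[2:3], decreasing = TRUE) + 1L)
  qs <- q[ord]
  minority <- counts[ord][2:3]
  pbin <- if (sum(minority) == 0L) 1 else
    stats::binom.test(minority[1L], sum(minority))$p.value
  list(q = stats::setNames(qs, c("q1", "q2", "q3")),
       counts = counts, imbalance_p = pbin,
       imbalanced = pbin < 0.05, quartet = quartet)
}

# which pair among (t1,t2),(t1,t3),(t2,t3) forms a cherry in the unrooted
# 4-taxon tree
quartet_resolution <- function(tr, t1, t2, t3, t4) {
  pairs <- list(c(t1, t2), c(t1, t3), c(t2, t3))
  for (k in 1:3) {
    other <- setdiff(c(t1, t2, t3, t4), pairs[[k]])
    # cherry test: the pair's MRCA in the tree rooted at one of the others
    rt <- tryCatch(ape::root(tr, outgroup = other[1L], resolve.root = TRUE),
                   error = function(e) NULL)
    if (is.null(rt)) next
    m <- ape::getMRCA(rt, pairs[[k]])
    if (setequal(ape::extract.clade(rt, m)$tip.label, pairs[[k]]))
      return(k)
  }
  NA_integer_
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits y ~ x by generalized least squares with covariance
#' \eqn{V(\lambda)} equal to the tree's shared-path-length matrix with
#' off-diagonal entries scaled by \eqn{\lambda}. \eqn{\lambda} is either
#' fixed or profiled by maximum likelihood over a 1000-point logarithmic
#' grid on [1e-6, 1]. R-squared is computed in the whitened space
#' (1 - RSS/TSS after premultiplying by the inverse Cholesky factor), the
#' slope p-value from a two-sided t test.
#'
#' @param x,y named numeric vectors (names = taxa).
#' @param tree \code{phylo} with branch lengths; taxa must match its tips.
#' @param lambda fixed value in [1e-6, 1], or \code{"ML"}.
#' @return object of class \code{pgls_fit}: list(slope, intercept,
#'   r_squared, p_value, lambda, df, log_lik).
#' @export
pgls_fit <- function(x, y, tree, lambda = "ML") {
  taxa <- tree$tip.label
  if (!setequal(names(x), taxa) || !setequal(names(y), taxa))
    stop("taxa of x, y and tree leaves must be identical")
  x <- x[taxa]; y <- y[taxa]
  if (!ape::is.ultrametric(tree, tol = 1e-6))
    warning("tree is not ultrametric; proceeding")
  V0 <- ape::vcv(tree)
  n <- length(taxa)
  fit_at <- function(lam) {
    V <- V0 * lam
    diag(V) <- diag(V0)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    W <- backsolve(ch, diag(n), transpose = TRUE)  # W %*% V %*% t(W) = I
    X <- cbind(1, x)
    Xw <- W %*% X; yw <- W %*% y
    qr_ <- qr(Xw)
    if (qr_$rank < 2L) return(NULL)
    beta <- qr.coef(qr_, yw)
    res <- yw - Xw %*% beta
    rss <- sum(res^2)
    sigma2_ml <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2_ml) +
                    2 * sum(log(diag(ch))) + n)
    list(beta = beta, rss = rss, W = W, Xw = Xw, yw = yw, ll = ll,
         logdet = 2 * sum(log(diag(ch))))
  }
  if (identical(lambda, "ML")) {
    grid <- exp(seq(log(1e-6), log(1), length.out = 1000))
    lls <- vapply(grid, function(l) {
      f <- fit_at(l)
      if (is.null(f)) -Inf else f$ll
    }, 0)
    lambda <- grid[which.max(lls)]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 1e-6, lambda <= 1)
  }
  f <- fit_at(lambda)
  if (is.null(f)) stop("singular covariance at lambda = ", lambda)
  # whitened-space R^2 against the GLS intercept-only model
  ones_w <- f$W %*% rep(1, n)
  mu <- sum(ones_w * f$yw) / sum(ones_w^2)
  tss <- sum((f$yw - ones_w * mu)^2)
  r2 <- 1 - f$rss / tss
  df <- n - 2L
  sigma2 <- f$rss / df
  xtx_inv <- solve(crossprod(f$Xw))
  se <- sqrt(sigma2 * xtx_inv[2L, 2L])
  tval <- f$beta[2L] / se
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(slope = unname(f$beta[2L]), intercept = unname(f$beta[1L]),
                 r_squared = r2, p_value = pval, lambda = lambda, df = df,
                 slope_se = se, log_lik = f$ll),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS: slope %.4g (SE %.3g), intercept %.4g, R^2 = %.3f, P = %.3g, lambda = %.3g\n",
    x$slope, x$slope_se, x$intercept, x$r_squared, x$p_value, x$lambda))
  invisible(x)
}

#' Assemble per-taxon PPD indices
#'
#' Convenience constructor joining the chromosome- and gene-level indices
#' for a set of taxa.
#'
#' @param taxon character vector.
#' @param x,p,g per-taxon extant chromosome number, relative ploidy and
#'   retained syntenic gene count.
#' @param N,G ancestral chromosome and gene counts (constants across taxa).
#' @return data frame taxon, x, N, p, g, G, d_C, d_G.
#' @export
ppd_indices <- function(taxon, x, p, g = NA, N = 11, G = NA) {
  d_C <- as.numeric(dysploidy_rate(x, N, p))
  d_G <- if (all(is.na(g)) || all(is.na(G))) NA_real_ else
    as.numeric(gene_loss_rate(g, G, p))
  data.frame(taxon = taxon, x = x, N = N, p = p, g = g, G = G,
             d_C = d_C, d_G = d_G, stringsAsFactors = FALSE)
}
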
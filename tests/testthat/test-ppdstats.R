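test_that("dysploidy rate evaluates the chromosome-level index exactly", {
  d <- dysploidy_rate(13, 11, 5)
  expect_equal(as.numeric(d), 1 - 13 / 55)
  expect_equal(attr(d, "reported"), 0.76)
  expect_equal(as.numeric(dysploidy_rate(11, 11, 1)), 0)
  expect_equal(attr(dysploidy_rate(41, 11, 4), "reported"), 0.07)
  expect_warning(neg <- dysploidy_rate(60, 11, 5), "ascending")
  expect_lt(as.numeric(neg), 0)
})

test_that("gene loss rate tracks retained genes and lost duplicates", {
  d <- gene_loss_rate(25550, 19320, 5)
  expect_equal(as.numeric(d), 1 - 25550 / 96600)
  expect_equal(as.numeric(d), 0.7355, tolerance = 1e-4)
  expect_equal(attr(d, "lost_copies"), 71050)
  expect_equal(round(attr(d, "lost_copies"), -4), 70000)
  expect_equal(as.numeric(gene_loss_rate(19320 * 5, 19320, 5)), 0)
})

test_that("substitution rate is branch length over crown age", {
  expect_equal(substitution_rate(0.07, 70), 0.001)
  expect_equal(substitution_rate(0, 70), 0)
  expect_error(substitution_rate(0.1, 0), "> 0")
})

test_that("retention profiles match the binomial fractionation oracle", {
  res <- sim_polyploid_vs_outgroup(seed = 501, p = 2, n_chr = 5,
                                   genes_per_chromosome = 60)
  gs <- res$genomes
  set.seed(502)
  lost <- fractionate(gs$poly, c(A = 0.3, B = 0.2))
  bls <- orthologous_blocks(gs$outgroup, gs$poly, res$homology, genomes = gs,
                            cutoff = 0.4)
  proto <- build_proto_karyotype(
    list(gs$outgroup, gs$poly, lost),
    list(bls), reference = gs$outgroup)
  pg <- proto_as_genome(proto)
  pbl <- orthologous_blocks(pg, lost, res$homology,
                            genomes = list(pg, lost), cutoff = 0.4)
  lt <- retained_loci_table(pbl, lost)
  prof <- retention_profile(lt, proto, window = 20)
  ov <- attr(prof, "overall")
  expect_equal(unname(ov["A"]), 0.7, tolerance = 0.05)
  expect_equal(unname(ov["B"]), 0.8, tolerance = 0.05)
  expect_true(all(prof$retention >= 0 & prof$retention <= 1))
  # no fractionation: retention 1 everywhere
  pbl_full <- orthologous_blocks(pg, gs$poly, res$homology,
                                 genomes = list(pg, gs$poly), cutoff = 0.4)
  prof_full <- retention_profile(retained_loci_table(pbl_full, gs$poly),
                                 proto, window = 20)
  expect_true(all(prof_full$retention > 0.95))
  expect_warning(retention_profile(
    data.frame(proto_gene = "x", gene = "y", subgenome = NA_character_),
    proto), "no subgenome labels")
})

test_that("the rank-sum bias test behaves at the boundaries and has power", {
  same <- rep(c(0.7, 0.8, 0.9), 5)
  expect_equal(suppressWarnings(bias_test(same, same)), 1, tolerance = 1e-9)
  expect_error(bias_test(c(1, 2), c(1, 2, 3)), ">= 3")
  set.seed(601)
  rejections <- 0L
  for (i in 1:40) {
    a <- rbinom(200, 50, 0.7) / 50
    b <- rbinom(200, 50, 0.8) / 50
    rejections <- rejections + (bias_test(a, b) < 0.05)
  }
  expect_gte(rejections / 40, 0.95)
})

test_that("copy-number histograms follow the binomial loss model", {
  lt <- data.frame(proto_gene = rep(paste0("L", 1:100), each = 2),
                   subgenome = rep(c("A", "B"), 100))
  cn <- copy_number_profile(lt, 2)
  expect_equal(unname(cn), c(0L, 0L, 100L))
  expect_equal(sum(cn), 100L)
  # independent loss with prob q per copy -> Binomial(p, 1-q) histogram
  set.seed(603)
  p <- 3; q <- 0.4; n_loci <- 3000
  keep <- matrix(stats::runif(n_loci * p) > q, ncol = p)
  rows <- do.call(rbind, lapply(seq_len(n_loci), function(i) {
    s <- LETTERS[which(keep[i, ])]
    if (!length(s)) return(NULL)
    data.frame(proto_gene = paste0("L", i), subgenome = s)
  }))
  cn3 <- copy_number_profile(rows, p,
                             all_loci = paste0("L", seq_len(n_loci)))
  expect_equal(sum(cn3), n_loci)
  expected <- stats::dbinom(0:p, p, 1 - q) * n_loci
  expect_true(all(abs(cn3 - expected) < 3 * sqrt(expected + 1) + 10))
})

test_that("quartet frequencies separate concordance, ILS and imbalance", {
  sp <- ape::read.tree(text = "((((a:1,b:1):1,c:2):1,d:3):1,e:4);")
  gt_same <- replicate(30, sp, simplify = FALSE)
  qs <- quartet_support(gt_same, sp, "N3")
  expect_equal(unname(qs$q), c(1, 0, 0))
  expect_false(qs$imbalanced)
  # symmetric ILS: the two minority resolutions of the induced quartet
  # {a, c, d, e} occur equally often (gene trees need only those four tips)
  conc <- ape::read.tree(text = "((a:1,c:1):1,(d:1,e:1):1);")
  alt1 <- ape::read.tree(text = "((a:1,d:1):1,(c:1,e:1):1);")
  alt2 <- ape::read.tree(text = "((c:1,d:1):1,(a:1,e:1):1);")
  set.seed(701)
  draw <- sample(1:3, 200, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  gts <- lapply(draw, function(k) list(conc, alt1, alt2)[[k]])
  qi <- quartet_support(gts, sp, "N3")
  expect_gt(qi$q["q1"], qi$q["q2"])
  expect_false(qi$imbalanced)
  expect_equal(sum(qi$q), 1)
  # strong asymmetry (introgression-like) flips the flag
  draw2 <- sample(1:3, 200, replace = TRUE, prob = c(0.55, 0.4, 0.05))
  gts2 <- lapply(draw2, function(k) list(conc, alt1, alt2)[[k]])
  expect_true(quartet_support(gts2, sp, "N3")$imbalanced)
  expect_error(quartet_support(list(), sp, "N3"), "0 informative")
})

test_that("PGLS at vanishing lambda equals the OLS oracle", {
  set.seed(801)
  tree <- ape::rcoal(8)
  tree$tip.label <- paste0("s", 1:8)
  x <- stats::setNames(rnorm(8), tree$tip.label)
  y <- stats::setNames(1.5 * x + rnorm(8, sd = 0.3), tree$tip.label)
  f <- pgls_fit(x, y, tree, lambda = 1e-6)
  # independent matrix-algebra OLS oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f$slope, beta[2L], tolerance = 1e-6)
  expect_equal(f$intercept, beta[1L], tolerance = 1e-4)
  ols <- stats::lm(y ~ x)
  expect_equal(f$r_squared, summary(ols)$r.squared, tolerance = 1e-6)
  expect_equal(f$p_value, summary(ols)$coefficients[2L, 4L],
               tolerance = 1e-5)
  # perfect linear data
  y2 <- stats::setNames(2 * x, names(x))
  f2 <- pgls_fit(x, y2, tree, lambda = 1e-6)
  expect_equal(f2$slope, 2, tolerance = 1e-9)
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)
})

test_that("PGLS at lambda 1 matches the direct GLS oracle on 5 taxa", {
  set.seed(802)
  tree <- ape::rcoal(5)
  tree$tip.label <- paste0("s", 1:5)
  V <- ape::vcv(tree)
  x <- stats::setNames(rnorm(5), tree$tip.label)
  y <- stats::setNames(0.8 * x + as.vector(t(chol(V)) %*% rnorm(5)),
                       tree$tip.label)
  f <- pgls_fit(x, y, tree, lambda = 1)
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(f$slope, beta[2L], tolerance = 1e-8)
  expect_equal(f$intercept, beta[1L], tolerance = 1e-8)
  skip_if_not_installed("nlme")
  df <- data.frame(x = x, y = y, taxon = names(x))
  g <- nlme::gls(y ~ x, data = df,
                 correlation = ape::corPagel(1, phy = tree, form = ~taxon,
                                             fixed = TRUE))
  expect_equal(f$slope, unname(stats::coef(g)[2L]), tolerance = 1e-6)
})

test_that("Brownian simulations recover the slope within its CI", {
  set.seed(803)
  n_tax <- 24  # lambda profiling is anticonservative on very small trees
  tree <- ape::rcoal(n_tax)
  tree$tip.label <- paste0("s", seq_len(n_tax))
  V <- ape::vcv(tree)
  Ch <- t(chol(V))
  beta_true <- 1.2
  covered <- 0L; lam_hi <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    x <- stats::setNames(as.vector(Ch %*% rnorm(n_tax)), tree$tip.label)
    y <- stats::setNames(beta_true * x +
                           as.vector(Ch %*% rnorm(n_tax, sd = 0.4)),
                         tree$tip.label)
    f <- pgls_fit(x, y, tree, lambda = "ML")
    ci <- f$slope + c(-1, 1) * stats::qt(0.975, f$df) * f$slope_se
    covered <- covered + (beta_true >= ci[1L] && beta_true <= ci[2L])
    lam_hi <- lam_hi + (f$lambda > 0.5)
  }
  expect_gte(covered / n_rep, 0.9)
  expect_gte(lam_hi / n_rep, 0.8)  # ML lambda near 1 under true BM
})

test_that("dysploidy-richness correlation is recovered end to end", {
  set.seed(804)
  taxa <- paste0("clade", 1:7)
  tree <- ape::rcoal(7)
  tree$tip.label <- taxa
  hits <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    d_C <- stats::runif(7, 0.05, 0.8)
    richness <- round(exp(2 + 5 * d_C + rnorm(7, sd = 0.5)))
    idx <- ppd_indices(taxa, x = pmax(1, round(55 * (1 - d_C))), p = 5,
                       N = 11)
    fit <- pgls_fit(stats::setNames(idx$d_C, taxa),
                    stats::setNames(log(richness), taxa), tree,
                    lambda = "ML")
    hits <- hits + (fit$slope > 0 && fit$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("ppd_indices assembles both indices consistently", {
  idx <- ppd_indices(c("cot", "dip"), x = c(13, 11), p = c(5, 1),
                     g = c(25550, 19320), N = 11, G = 19320)
  expect_equal(round(idx$d_C, 2), c(0.76, 0))
  expect_equal(round(idx$d_G, 2), c(0.74, 0))
})
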
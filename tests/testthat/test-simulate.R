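test_that("EEJ fuses whole bodies and is undone by a split at the junction", {
  anc <- ancestral_genome(11, 20, "a")
  g <- apply_eej(anc, "chr04", "chr11")
  expect_equal(n_chromosomes(g), 10L)
  expect_setequal(g$gene, anc$gene)
  g2 <- apply_eej(g, "chr01", "chr02")
  expect_equal(n_chromosomes(g2), 9L)
  # splitting at the junction recovers both gene orders
  fused <- g[g$chromosome == "chr04+chr11", ]
  split_back <- apply_fission(g, "chr04+chr11",
                              sum(anc$chromosome == "chr04"))
  p1 <- split_back[split_back$chromosome == "chr04+chr11.1", ]
  expect_equal(p1$gene[order(p1$rank)],
               anc$gene[anc$chromosome == "chr04"][
                 order(anc$rank[anc$chromosome == "chr04"])])
  expect_error(apply_eej(anc, "chr01", "nope"), "not found")
})

test_that("NCF inserts the donor intact strictly inside the host", {
  anc <- ancestral_genome(5, 20, "a")
  g <- apply_ncf(anc, "chr01", 7, "chr02")
  expect_equal(n_chromosomes(g), 4L)
  expect_setequal(g$gene, anc$gene)
  host <- g[g$chromosome == "chr01", ]
  expect_equal(nrow(host), 40L)  # L + M genes
  inner <- host$gene[order(host$rank)][8:27]
  donor <- anc$gene[anc$chromosome == "chr02"][
    order(anc$rank[anc$chromosome == "chr02"])]
  expect_equal(inner, donor)
  expect_error(apply_ncf(anc, "chr01", 0, "chr02"), "interior")
  expect_error(apply_ncf(anc, "chr01", 20, "chr02"), "interior")
})

test_that("RT exchanges tails, keeps n, and is an involution", {
  anc <- ancestral_genome(4, 20, "a")
  g <- apply_rt(anc, "chr01", 5, "chr02", 12)
  expect_equal(n_chromosomes(g), 4L)
  expect_setequal(g$gene, anc$gene)
  back <- apply_rt(g, "chr01", 5, "chr02", 12)
  expect_equal(back$gene[order(back$chromosome, back$rank)],
               anc$gene[order(anc$chromosome, anc$rank)])
  whole_arm <- apply_rt(anc, "chr01", 0, "chr02", 10)
  expect_equal(n_chromosomes(whole_arm), 4L)
})

test_that("allopolyploidy adds the partner's chromosome complement", {
  a <- ancestral_genome(11, 10, "a"); b <- ancestral_genome(11, 10, "b")
  tet <- allopolyploidize(a, b, "A", "B", merged_id = "tet")
  expect_equal(n_chromosomes(tet), 22L)
  expect_setequal(unique(tet$subgenome), c("A", "B"))
  # sequential mergers: tetraploid (after NCF) + three diploids -> 54
  tet21 <- apply_ncf(tet, "A.chr01", 5, "B.chr02")
  g <- tet21
  for (lab in c("C", "D", "E"))
    g <- allopolyploidize(g, ancestral_genome(11, 10, paste0("p", lab)),
                          label_b = lab, merged_id = paste0("m", lab))
  expect_equal(n_chromosomes(g), 54L)
  # merging with an empty genome changes nothing
  e <- a[0, , drop = FALSE]
  attr(e, "genome_id") <- "empty"
  class(e) <- class(a)
  same <- allopolyploidize(a, e, "A", "B", merged_id = "same")
  expect_equal(nrow(same), nrow(a))
  expect_equal(n_chromosomes(same), 11L)
})

test_that("fractionation respects per-subgenome loss probabilities", {
  a <- allopolyploidize(ancestral_genome(11, 200, "x"),
                        ancestral_genome(11, 200, "y"), "A", "B",
                        merged_id = "tet")
  expect_identical(nrow(fractionate(a, 0)), nrow(a))
  expect_error(fractionate(a, 1), "< 1")
  set.seed(101)
  f <- fractionate(a, c(A = 0.3, B = 0.2))
  retA <- sum(f$subgenome == "A") / 2200
  retB <- sum(f$subgenome == "B") / 2200
  expect_lt(retA, retB)
  # binomial oracle: E[retB - retA] = 0.1, sd ~ sqrt(.3*.7/2200 + .2*.8/2200)
  expect_equal(retB - retA, 0.1, tolerance = 0.02 / 0.1)
  expect_true(all(table(f$chromosome) >= 1L))
})

test_that("a chromosome is never emptied even under heavy loss", {
  g <- ancestral_genome(3, 4, "tiny")
  set.seed(5)
  for (i in 1:20) {
    f <- fractionate(g, 0.9)
    expect_equal(n_chromosomes(f), 3L)
  }
})

test_that("evolve is deterministic and keeps exact chromosome bookkeeping", {
  tr <- ape::read.tree(text = "((l1:2,l2:2):2,o:4);")
  events <- list(schedule_event("N2", "ALLOPOLYPLOIDY", label_existing = "A",
                                label_new = "B", divergence = 0.3),
                 schedule_event("l1", "EEJ"),
                 schedule_event("l2", "RT"),
                 schedule_event("l2", "FISSION"))
  cfg <- sim_config(tr, events = events, ancestor_n = 5,
                    genes_per_chromosome = 20, seed = 42)
  r1 <- evolve(cfg); r2 <- evolve(cfg)
  expect_identical(r1$genomes, r2$genomes)
  expect_identical(r1$homology, r2$homology)
  # bookkeeping: n(leaf) = ancestor n + sum of delta_n on its path
  log_ <- r1$event_log
  n_l1 <- 5 + sum(log_$delta_n[log_$branch %in% c("N2", "l1")])
  n_l2 <- 5 + sum(log_$delta_n[log_$branch %in% c("N2", "l2")])
  expect_equal(n_chromosomes(r1$genomes$l1), n_l1)
  expect_equal(n_chromosomes(r1$genomes$l2), n_l2)
})

test_that("chromosome-number bookkeeping holds across random histories", {
  kinds <- c("EEJ", "RT", "FISSION")
  for (seed in 1:8) {
    set.seed(seed)
    evs <- lapply(sample(kinds, 3, replace = TRUE),
                  function(k) schedule_event("l1", k))
    cfg <- sim_config(ape::read.tree(text = "(l1:2,l2:2);"), events = evs,
                      ancestor_n = 6, genes_per_chromosome = 15,
                      seed = seed * 7L)
    r <- evolve(cfg)
    expect_equal(n_chromosomes(r$genomes$l1),
                 6 + sum(r$event_log$delta_n))
  }
})

test_that("homology is complete: all and only same-locus pairs", {
  cfg <- sim_config(ape::read.tree(text = "(l1:1,l2:1);"), ancestor_n = 3,
                    genes_per_chromosome = 10, seed = 9)
  r <- evolve(cfg)
  # no events, no loss: every locus yields exactly one (ortholog) pair
  expect_equal(nrow(r$homology), 30L)
  expect_equal(nrow(r$truth_orthologs), 30L)
  loci_a <- sub("^.*\\|", "", r$homology$gene_a)
  loci_b <- sub("^.*\\|", "", r$homology$gene_b)
  expect_true(all(loci_a == loci_b))
})

test_that("scheduled events referencing unknown branches fail validation", {
  tr <- ape::read.tree(text = "(l1:1,l2:1);")
  expect_error(sim_config(tr, events = list(schedule_event("nope", "EEJ"))),
               "unknown branch")
})

test_that("simulated scores decrease with divergence", {
  cfg <- sim_config(ape::read.tree(text = "(out:6,poly:6);"),
                    events = list(schedule_event("poly", "ALLOPOLYPLOIDY",
                                                 label_existing = "A",
                                                 label_new = "B",
                                                 divergence = 0.3)),
                    ancestor_n = 3, genes_per_chromosome = 30,
                    ks_rate = 0.08, seed = 4)
  r <- evolve(cfg)
  h <- r$homology
  expect_lt(stats::cor(h$ks, h$score), -0.9)
})

test_that("expression shares follow the configured subgenome bias", {
  tet <- allopolyploidize(ancestral_genome(4, 60, "x"),
                          ancestral_genome(4, 60, "y"), "A", "B",
                          merged_id = "tet")
  set.seed(11)
  sym <- expression_bias(simulate_expression(tet, c(A = 0.5, B = 0.5)))
  expect_equal(unname(sym$medians["A"]), 0.5, tolerance = 0.05)
  expect_equal(unname(sym$medians["B"]), 0.5, tolerance = 0.05)
  # biased shares detected by the rank-sum test (1000 groups for power)
  big <- allopolyploidize(ancestral_genome(5, 200, "x2"),
                          ancestral_genome(5, 200, "y2"), "A", "B",
                          merged_id = "big")
  set.seed(12)
  bias <- expression_bias(simulate_expression(big, c(A = 0.4, B = 0.6)))
  expect_lt(bias$tests$p_value[1L], 0.05)
  expect_lt(unname(bias$medians["A"]), unname(bias$medians["B"]))
  # silenced groups fall below the min_sum floor and are excluded
  set.seed(13)
  ex <- simulate_expression(tet, c(A = 0.5, B = 0.5), zero_frac = 0.3)
  eb <- expression_bias(ex, min_sum = 1)
  expect_lt(length(unique(eb$shares$locus)), length(unique(ex$locus)))
  shares_sum <- tapply(eb$shares$share, eb$shares$locus, sum)
  expect_true(all(abs(shares_sum - 1) < 1e-9))
})
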
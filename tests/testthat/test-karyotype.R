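# project a simulated genome onto a truth proto built from the outgroup leaf
project_fixture <- function(res, target, min_segment = 5, cutoff = 0.4) {
  gs <- res$genomes
  others <- setdiff(names(gs), "outgroup")
  bls <- lapply(others, function(o)
    orthologous_blocks(gs$outgroup, gs[[o]], res$homology, genomes = gs,
                       cutoff = cutoff))
  # pad to the 3-genome minimum for two-leaf fixtures
  gs3 <- if (length(gs) >= 3L) gs else c(gs, list(pad = gs$outgroup))
  proto <- build_proto_karyotype(gs3, bls, reference = gs$outgroup,
                                 min_segment = min_segment)
  pg <- proto_as_genome(proto)
  pbl <- orthologous_blocks(pg, gs[[target]], res$homology,
                            genomes = c(list(pg), unname(gs[others])),
                            cutoff = cutoff)
  km <- project_karyotype(gs[[target]], proto, pbl,
                          min_segment = min_segment)
  list(proto = proto, km = km)
}

test_that("proto-karyotype reconstruction recovers the 11-chromosome ancestor", {
  rad <- sim_diploid_radiation(seed = 301, genes_per_chromosome = 40)
  gs <- rad$genomes
  ref_id <- names(gs)[which.max(vapply(gs, n_chromosomes, 0L))]
  others <- setdiff(names(gs), ref_id)
  bls <- lapply(others, function(o)
    orthologous_blocks(gs[[ref_id]], gs[[o]], rad$homology, genomes = gs))
  proto <- build_proto_karyotype(gs, bls, reference = gs[[ref_id]],
                                 min_support = 2)
  expect_equal(proto$N, 11L)
  expect_error(build_proto_karyotype(gs[1:2], bls[1], gs[[1]]), ">= 3")
})

test_that("a fusion shared by all genomes is kept as ancestral (parsimony limit)", {
  # every lineage inherits the same EEJ from the stem branch
  tr <- ape::read.tree(text = "((g1:2,g2:2):2,(g3:2,g4:2):2);")
  events <- list(schedule_event("N2", "EEJ", chr_a = "chr01",
                                chr_b = "chr02"),
                 schedule_event("N3", "EEJ", chr_a = "chr01",
                                chr_b = "chr02"))
  cfg <- sim_config(tr, events = events, ancestor_n = 6,
                    genes_per_chromosome = 30, ks_rate = 0.04, seed = 311)
  res <- evolve(cfg)
  gs <- res$genomes
  ref_id <- names(gs)[1L]
  others <- setdiff(names(gs), ref_id)
  bls <- lapply(others, function(o)
    orthologous_blocks(gs[[ref_id]], gs[[o]], res$homology, genomes = gs))
  proto <- build_proto_karyotype(gs, bls, reference = gs[[ref_id]])
  expect_equal(proto$N, 5L)  # 6 - 1: the shared fusion is unpolarizable
})

test_that("projection yields one full segment per unrearranged chromosome", {
  cfg <- sim_config(ape::read.tree(text = "(outgroup:4,q:4);"),
                    ancestor_n = 5, genes_per_chromosome = 40,
                    ks_rate = 0.05, seed = 321)
  res <- evolve(cfg)
  fx <- project_fixture(res, "q")
  expect_equal(nrow(fx$km), 5L)
  expect_equal(sort(unique(fx$km$proto)), sort(unique(fx$km$chromosome)))
  ev <- classify_rearrangements(fx$km, fx$proto)
  expect_equal(nrow(ev), 0L)
})

test_that("an EEJ product projects as two full bodies classified as one EEJ", {
  cfg <- sim_config(ape::read.tree(text = "(outgroup:4,q:4);"),
                    events = list(schedule_event("q", "EEJ",
                                                 chr_a = "chr04",
                                                 chr_b = "chr05")),
                    ancestor_n = 5, genes_per_chromosome = 40,
                    ks_rate = 0.05, seed = 331)
  res <- evolve(cfg)
  fx <- project_fixture(res, "q")
  fused <- fx$km[fx$km$chromosome == "chr04+chr05", ]
  expect_equal(nrow(fused), 2L)
  expect_setequal(fused$proto, c("chr04", "chr05"))
  ev <- classify_rearrangements(fx$km, fx$proto)
  expect_equal(ev$kind, "EEJ")
  expect_equal(ev$delta_n, -1L)
})

test_that("an NCF product projects host-donor-host and classifies as NCF", {
  cfg <- sim_config(ape::read.tree(text = "(outgroup:4,q:4);"),
                    events = list(schedule_event("q", "NCF",
                                                 host = "chr01",
                                                 insert_pos = 20,
                                                 donor = "chr02")),
                    ancestor_n = 5, genes_per_chromosome = 40,
                    ks_rate = 0.05, seed = 341)
  res <- evolve(cfg)
  fx <- project_fixture(res, "q")
  host <- fx$km[fx$km$chromosome == "chr01", ]
  expect_equal(host$proto, c("chr01", "chr02", "chr01"))
  ev <- classify_rearrangements(fx$km, fx$proto)
  expect_equal(ev$kind, "NCF")
  expect_equal(ev$delta_n, -1L)
})

test_that("RT is emitted once with delta 0; fission adds a chromosome", {
  cfg <- sim_config(ape::read.tree(text = "(outgroup:4,q:4);"),
                    events = list(schedule_event("q", "RT",
                                                 chr_a = "chr01", pos_a = 15,
                                                 chr_b = "chr02", pos_b = 25)),
                    ancestor_n = 5, genes_per_chromosome = 40,
                    ks_rate = 0.05, seed = 351)
  res <- evolve(cfg)
  fx <- project_fixture(res, "q")
  ev <- classify_rearrangements(fx$km, fx$proto)
  expect_equal(ev$kind, "RT")
  expect_equal(ev$delta_n, 0L)
  cfg2 <- sim_config(ape::read.tree(text = "(outgroup:4,q:4);"),
                     events = list(schedule_event("q", "FISSION",
                                                  chr = "chr03", pos = 20)),
                     ancestor_n = 5, genes_per_chromosome = 40,
                     ks_rate = 0.05, seed = 352)
  res2 <- evolve(cfg2)
  fx2 <- project_fixture(res2, "q")
  ev2 <- classify_rearrangements(fx2$km, fx2$proto)
  expect_equal(ev2$kind, "FISSION")
  expect_equal(ev2$delta_n, 1L)
})

test_that("event-count conservation and kind recovery across mixed histories", {
  # events scheduled on disjoint chromosome sets: compound rearrangements of
  # the SAME chromosomes (e.g. an EEJ landing on an RT product) are
  # ambiguous by construction and are exercised separately above
  n_total <- 0L; n_correct_kind <- 0L
  for (seed in 1:6) {
    set.seed(400 + seed)
    evs <- list(); truth_kinds <- character()
    if (stats::runif(1) < 0.7) {
      evs <- c(evs, list(schedule_event("q", "RT", chr_a = "chr01",
                                        pos_a = sample(15:25, 1),
                                        chr_b = "chr02",
                                        pos_b = sample(15:25, 1))))
      truth_kinds <- c(truth_kinds, "RT")
    }
    if (stats::runif(1) < 0.7) {
      evs <- c(evs, list(schedule_event("q", "NCF", host = "chr03",
                                        insert_pos = sample(15:25, 1),
                                        donor = "chr04")))
      truth_kinds <- c(truth_kinds, "NCF")
    }
    n_eej <- sample(1:2, 1)
    eej_pairs <- list(c("chr05", "chr06"), c("chr07", "chr08"))
    for (k in seq_len(n_eej))
      evs <- c(evs, list(schedule_event("q", "EEJ",
                                        chr_a = eej_pairs[[k]][1L],
                                        chr_b = eej_pairs[[k]][2L])))
    truth_kinds <- c(truth_kinds, rep("EEJ", n_eej))
    cfg <- sim_config(ape::read.tree(text = "(outgroup:4,q:4);"),
                      events = evs, ancestor_n = 8,
                      genes_per_chromosome = 40,
                      fractionation = c("0" = 0.1),
                      ks_rate = 0.05, seed = 410 + seed)
    res <- evolve(cfg)
    fx <- project_fixture(res, "q")
    ev <- classify_rearrangements(fx$km, fx$proto)
    expect_equal(sum(ev$delta_n),
                 n_chromosomes(res$genomes$q) - 8L,
                 info = paste("seed", seed))
    n_total <- n_total + length(truth_kinds)
    for (k in unique(truth_kinds))
      n_correct_kind <- n_correct_kind +
        min(sum(ev$kind == k), sum(truth_kinds == k))
  }
  expect_gte(n_correct_kind / n_total, 0.95)
})

test_that("projection is invariant to within-segment order shuffling", {
  cfg <- sim_config(ape::read.tree(text = "(outgroup:4,q:4);"),
                    events = list(schedule_event("q", "EEJ",
                                                 chr_a = "chr01",
                                                 chr_b = "chr02")),
                    ancestor_n = 4, genes_per_chromosome = 40,
                    ks_rate = 0.05, seed = 361)
  res <- evolve(cfg)
  # shuffle gene order inside each original body (an "inversion" stand-in)
  q <- as.data.frame(res$genomes$q)
  set.seed(5)
  for (chr in unique(q$chromosome)) {
    idx <- which(q$chromosome == chr)
    loci_chr <- sub("\\..*$", "", sub("^.*\\|", "", q$locus[idx]))
    for (body in unique(loci_chr)) {
      b <- idx[loci_chr == body]
      sh <- sample(b)
      q$start[b] <- q$start[sh]
      q$end[b] <- q$start[b] + 50
    }
  }
  q <- annotated_genome(q[, setdiff(names(q), "rank")], "q")
  res$genomes$q <- q
  fx <- project_fixture(res, "q", min_segment = 5)
  ev <- classify_rearrangements(fx$km, fx$proto)
  expect_equal(sum(ev$delta_n), -1L)
  expect_true("EEJ" %in% ev$kind)
})

test_that("shared events go to stem edges, private ones to terminal edges", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  shared <- data.frame(kind = "EEJ", chromosomes = "x",
                       bodies = "chr01+chr02", subgenome = "A,A",
                       delta_n = -1L)
  private <- data.frame(kind = "EEJ", chromosomes = "y",
                        bodies = "chr03+chr04", subgenome = "A,A",
                        delta_n = -1L)
  ev <- place_events_on_tree(list(a = rbind(shared, private), b = shared,
                                  c = ppdtools:::event_frame()), tr)
  stem <- ev[ev$bodies == "chr01+chr02", ]
  expect_equal(nrow(stem), 1L)
  expect_false(stem$edge %in% c("a", "b", "c"))  # internal (a,b) edge
  expect_equal(ev$edge[ev$bodies == "chr03+chr04"], "a")
  # present in 2 of 3 leaves of a polytomy-free tree but NOT forming a
  # clade: stays on the two terminal edges
  tr2 <- ape::read.tree(text = "((a:1,c:1):1,b:2);")
  ev2 <- place_events_on_tree(list(a = shared, b = shared,
                                   c = ppdtools:::event_frame()), tr2)
  expect_setequal(ev2$edge, c("a", "b"))
})

test_that("chromosome numbers propagate along the tree with events", {
  tr <- ape::read.tree(text = "((mal1:1,mal2:1):1,byt:2);")
  edge_events <- data.frame(
    edge = c("N2", "N2", "N2", "N2", "N2", "mal1", "byt"),
    delta_n = c(11L, -1L, 11L, 22L, -1L, -40L, -1L))
  # tetraploidy (+11), NCF (-1), then +11/+22 mergers to 54, shared EEJ (-1)
  traj <- chromosome_number_trajectory(tr, edge_events, root_n = 11)
  expect_equal(unname(traj["N2"]), 53L)
  expect_equal(unname(traj["mal1"]), 13L)
  expect_equal(unname(traj["mal2"]), 53L)
  expect_equal(unname(traj["byt"]), 10L)
  no_ev <- chromosome_number_trajectory(tr, edge_events[0, ], root_n = 7)
  expect_true(all(no_ev == 7L))
})
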
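#' Run the diploidization-analysis pipeline
#'
#' Orchestrates the stages as subcommands driven by one flat configuration
#' (a YAML file or an equivalent named list): \code{simulate} generates a
#' bundled scenario and writes gene-table/homology/event-log TSVs;
#' \code{synteny} computes OI-filtered orthologous blocks for configured
#' genome pairs; \code{ploidy} estimates relative ploidy; \code{phase}
#' assigns subgenomes against a phased reference; \code{karyotype}
#' reconstructs the proto-karyotype and classifies rearrangements;
#' \code{ppd} evaluates the dysploidy/gene-loss indices from a trait table;
#' \code{pgls} runs the phylogenetic regression; \code{all} runs every
#' configured stage in order. Every output file carries '#' header lines
#' with the package version, a config hash and the seed, so a rerun with
#' an identical config reproduces identical files.
#'
#' @param config path to a YAML config or a named list. Recognized keys:
#'   \code{seed}, \code{outdir}, and per-stage blocks (\code{simulate},
#'   \code{synteny}, \code{ploidy}, \code{phase}, \code{karyotype},
#'   \code{ppd}, \code{pgls}).
#' @param subcommand stage to run, or \code{"all"}.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, subcommand = "all") {
  subcommand <- match.arg(subcommand,
                          c("all", "simulate", "synteny", "ploidy", "phase",
                            "karyotype", "ppd", "pgls"))
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$outdir)) stop("config key missing: outdir")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  ver <- tryCatch(as.character(utils::packageVersion("ppdtools")),
                  error = function(e) "dev")
  hdr <- c(paste0("ppdtools ", ver),
           paste0("config_hash=", config_hash(config)),
           paste0("seed=", seed))
  state <- new.env(parent = emptyenv())
  ofile <- function(name) file.path(config$outdir, name)
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "),
                                   "[ppdtools] ", ...)

  stage_simulate <- function() {
    sc <- config$simulate %||% stop("config key missing: simulate")
    scenario <- sc$scenario %||% stop("config key missing: simulate$scenario")
    log_msg("simulate: scenario ", scenario)
    res <- switch(scenario,
      polyploid_vs_outgroup = sim_polyploid_vs_outgroup(
        seed = seed, p = sc$p %||% 2,
        genes_per_chromosome = sc$genes_per_chromosome %||% 60,
        loss = sc$loss %||% 0),
      cotton_descent = sim_cotton_descent(
        seed = seed, n_eej = sc$n_eej %||% 40,
        genes_per_chromosome = sc$genes_per_chromosome %||% 60,
        loss = sc$loss %||% 0.105),
      diploid_radiation = sim_diploid_radiation(
        seed = seed, n_genomes = sc$n_genomes %||% 4,
        genes_per_chromosome = sc$genes_per_chromosome %||% 60,
        loss = sc$loss %||% 0),
      stop("unknown scenario: ", scenario))
    write_gene_table(res$genomes, ofile("genes.tsv"), hdr)
    write_hash_tsv(res$homology, ofile("homology.tsv"), hdr)
    write_hash_tsv(res$event_log, ofile("event_log.tsv"), hdr)
    state$sim <- res
    res
  }

  get_genomes <- function() {
    if (!is.null(state$sim)) return(state$sim$genomes)
    path <- config$genes %||% ofile("genes.tsv")
    if (!file.exists(path)) stop("missing input: ", path)
    read_gene_table(path)
  }
  get_homology <- function() {
    if (!is.null(state$sim)) return(state$sim$homology)
    path <- config$homology %||% ofile("homology.tsv")
    if (!file.exists(path)) stop("missing input: ", path)
    read_homology(path)
  }

  stage_synteny <- function() {
    sc <- config$synteny %||% list()
    genomes <- get_genomes()
    pairs <- sc$pairs %||% {
      ids <- names(genomes)
      if (length(ids) < 2L) stop("need >= 2 genomes for synteny")
      utils::combn(ids, 2L, simplify = FALSE)
    }
    cutoff <- sc$cutoff %||% 0.5
    hom <- get_homology()
    blocks <- lapply(pairs, function(pr) {
      log_msg("synteny: ", pr[1L], " vs ", pr[2L])
      orthologous_blocks(genomes[[pr[1L]]], genomes[[pr[2L]]], hom,
                         genomes = genomes, cutoff = cutoff,
                         min_block_size = sc$min_block_size %||% 5,
                         max_gap = sc$max_gap %||% 25)
    })
    names(blocks) <- vapply(pairs, paste, "", collapse = "__")
    for (nm in names(blocks))
      write_blocks(blocks[[nm]], ofile(paste0("blocks_", nm, ".tsv")), hdr)
    state$blocks <- blocks
    blocks
  }

  need_blocks <- function() state$blocks %||%
    stop("synteny stage has not been run")

  stage_ploidy <- function() {
    sc <- config$ploidy %||% stop("config key missing: ploidy")
    genomes <- get_genomes()
    blocks <- need_blocks()
    q <- sc$query %||% stop("config key missing: ploidy$query")
    r <- sc$reference %||% stop("config key missing: ploidy$reference")
    bl <- blocks[[paste(c(r, q), collapse = "__")]] %||%
      blocks[[paste(c(q, r), collapse = "__")]] %||%
      stop("no blocks for pair ", q, "/", r)
    est <- estimate_relative_ploidy(genomes[[q]], genomes[[r]], bl,
                                    window = sc$window %||% 10)
    rep_df <- data.frame(query = est$query_genome,
                         reference = est$reference_genome, p = est$p,
                         support = est$depth_mode_support,
                         ratio = est$ratio_text)
    write_hash_tsv(rep_df, ofile("ploidy.tsv"), hdr)
    state$ploidy <- est
    est
  }

  stage_phase <- function() {
    sc <- config$phase %||% stop("config key missing: phase")
    genomes <- get_genomes()
    blocks <- need_blocks()
    q <- sc$query; r <- sc$reference
    bl <- blocks[[paste(c(r, q), collapse = "__")]] %||%
      blocks[[paste(c(q, r), collapse = "__")]] %||%
      stop("no blocks for pair ", q, "/", r)
    asg <- match_subgenomes(genomes[[q]], genomes[[r]], bl)
    write_hash_tsv(asg$assignment, ofile("phasing.tsv"), hdr)
    state$phasing <- asg
    asg
  }

  stage_karyotype <- function() {
    sc <- config$karyotype %||% list()
    genomes <- get_genomes()
    blocks <- need_blocks()
    ref_id <- sc$reference %||% names(genomes)[
      which.max(vapply(genomes, n_chromosomes, 0L))]
    others <- setdiff(names(genomes), ref_id)
    bl_list <- lapply(others, function(o)
      blocks[[paste(c(ref_id, o), collapse = "__")]] %||%
        blocks[[paste(c(o, ref_id), collapse = "__")]] %||%
        stop("no blocks for pair ", ref_id, "/", o))
    proto <- build_proto_karyotype(genomes, bl_list,
                                   reference = genomes[[ref_id]],
                                   min_support = sc$min_support %||% 2,
                                   min_segment = sc$min_segment %||% 10)
    events <- list()
    pg <- proto_as_genome(proto)
    hom <- get_homology()
    for (o in others) {
      pbl <- orthologous_blocks(pg, genomes[[o]], remap_to_proto(hom, proto),
                                genomes = c(list(pg),
                                            unname(genomes[others])),
                                cutoff = sc$cutoff %||% 0.4)
      km <- project_karyotype(genomes[[o]], proto, pbl,
                              min_segment = sc$min_segment %||% 10)
      events[[o]] <- classify_rearrangements(km, proto)
    }
    ev_df <- do.call(rbind, lapply(names(events), function(g) {
      e <- events[[g]]
      if (nrow(e)) cbind(genome = g, e) else NULL
    })) %||% cbind(genome = character(), event_frame())
    write_hash_tsv(ev_df, ofile("rearrangements.tsv"), hdr)
    state$proto <- proto; state$events <- events
    list(proto = proto, events = events)
  }

  stage_ppd <- function() {
    sc <- config$ppd %||% stop("config key missing: ppd")
    traits <- read_trait_table(sc$traits %||% config$traits %||%
                                 stop("config key missing: ppd$traits"))
    idx <- ppd_indices(traits$taxon, traits$x, traits$p,
                       g = traits$g %||% NA, N = sc$N %||% 11,
                       G = sc$G %||% NA)
    if (!is.null(traits$L) && !is.null(sc$T))
      idx$mu <- substitution_rate(traits$L, sc$T)
    write_hash_tsv(idx, ofile("ppd_indices.tsv"), hdr)
    state$ppd <- idx
    idx
  }

  stage_pgls <- function() {
    sc <- config$pgls %||% stop("config key missing: pgls")
    traits <- read_trait_table(sc$traits %||% config$traits)
    tree <- read_newick(sc$tree %||% stop("config key missing: pgls$tree"))
    xv <- stats::setNames(traits[[sc$x]], traits$taxon)
    yv <- traits[[sc$y]]
    transform <- sc$transform %||% "log"
    if (identical(transform, "log")) yv <- log(yv)
    yv <- stats::setNames(yv, traits$taxon)
    fit <- pgls_fit(xv, yv, tree, lambda = sc$lambda %||% "ML")
    rep_df <- data.frame(pair = paste(sc$x, sc$y, sep = "~"),
                         slope = fit$slope, intercept = fit$intercept,
                         r_squared = fit$r_squared, p_value = fit$p_value,
                         lambda = fit$lambda, transform = transform)
    write_hash_tsv(rep_df, ofile("pgls.tsv"), hdr)
    state$pgls <- fit
    fit
  }

  stages <- list(simulate = stage_simulate, synteny = stage_synteny,
                 ploidy = stage_ploidy, phase = stage_phase,
                 karyotype = stage_karyotype, ppd = stage_ppd,
                 pgls = stage_pgls)
  if (subcommand == "all") {
    out <- list()
    for (nm in names(stages))
      if (!is.null(config[[nm]])) out[[nm]] <- stages[[nm]]()
    invisible(out)
  } else {
    invisible(stages[[subcommand]]())
  }
}

# homology table for proto-vs-extant comparison: anchor the proto side on
# the backbone genes themselves
remap_to_proto <- function(hom, proto) {
  backbone <- unlist(proto$proto_chromosomes, use.names = FALSE)
  hom[hom$gene_a %in% backbone | hom$gene_b %in% backbone, , drop = FALSE]
}

# order-insensitive structural hash of the config (no external digest dep)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 512)))
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2^31
  sprintf("%08x", as.integer(h))
}
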
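#' Simulation configuration
#'
#' Parameters for the synthetic multi-cohort benchmark: several cohorts share
#' a common set of outcome-associated (informative) genes, each cohort carries
#' its own additive per-gene batch offset, classes are imbalanced, and the
#' secondary sources (network / gene sets) contain planted differential
#' modules over the informative genes.
#'
#' @param n_cohorts Number of cohorts.
#' @param samples_per_cohort Samples per cohort.
#' @param n_genes Number of measured genes.
#' @param n_informative Number of genes whose mean shifts with outcome.
#' @param effect_size Mean shift (in sd units of the background noise) added
#'   to informative genes in poor-outcome samples.
#' @param poor_fraction Fraction of poor-outcome samples per cohort.
#' @param batch_sd Standard deviation of the per-cohort, per-gene additive
#'   batch offset.
#' @param network_degree_exponent Power-law exponent of the simulated
#'   network's degree sequence.
#' @param planted_module_sizes Integer vector; each planted module is a
#'   connected subgraph of the network whose nodes are informative genes.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param er_positive_rate Probability that a sample is ER positive.
#' @param er_outcome_coupling Decrease in the ER-positive probability for
#'   poor-outcome samples (0 = ER independent of outcome).
#' @param unmeasured_fraction Fraction of network nodes absent from the
#'   measured gene universe (unmeasured proteins).
#' @param module_factor_loading Loading of the shared latent factor given to
#'   members of each planted module (creates within-module correlation).
#' @param corr_flip_module Index of the planted module whose hub-to-member
#'   correlation flips sign between the outcome classes (its first gene acts
#'   as the hub); `NA` disables the flip.
#' @param hub_boost_degree Extra random edges attached to the flip module's
#'   hub so that it ranks among the densely connected nodes.
#' @param n_genesets Number of gene sets in the simulated collection.
#' @param geneset_size_range Min/max size of the random gene sets.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_cohorts = 4L, samples_per_cohort = 100L,
                              n_genes = 1000L, n_informative = 40L,
                              effect_size = 1, poor_fraction = 0.3,
                              batch_sd = 0.3, network_degree_exponent = 2.5,
                              planted_module_sizes = c(8L, 10L), seed = 1L,
                              er_positive_rate = 0.7,
                              er_outcome_coupling = 0,
                              unmeasured_fraction = 0.1,
                              module_factor_loading = 0.5,
                              corr_flip_module = 1L,
                              hub_boost_degree = 20L,
                              n_genesets = 50L,
                              geneset_size_range = c(10L, 30L)) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              n_genes = as.integer(n_genes),
              n_informative = as.integer(n_informative),
              effect_size = effect_size, poor_fraction = poor_fraction,
              batch_sd = batch_sd,
              network_degree_exponent = network_degree_exponent,
              planted_module_sizes = as.integer(planted_module_sizes),
              seed = as.integer(seed),
              er_positive_rate = er_positive_rate,
              er_outcome_coupling = er_outcome_coupling,
              unmeasured_fraction = unmeasured_fraction,
              module_factor_loading = module_factor_loading,
              corr_flip_module = corr_flip_module,
              hub_boost_degree = as.integer(hub_boost_degree),
              n_genesets = as.integer(n_genesets),
              geneset_size_range = as.integer(geneset_size_range))
  if (cfg$n_informative > cfg$n_genes)
    stopf("n_informative must not exceed n_genes")
  if (cfg$poor_fraction <= 0 || cfg$poor_fraction >= 1)
    stopf("poor_fraction must lie in (0,1)")
  if (sum(cfg$planted_module_sizes) > cfg$n_informative)
    stopf("planted module genes must fit inside the informative genes")
  structure(cfg, class = "SimulationConfig")
}

sim_gene_ids <- function(cfg) sprintf("g%06d", seq_len(cfg$n_genes))

# Informative genes are the first n_informative ids; planted modules take
# consecutive chunks of them, the first gene of each module acting as its hub.
sim_ground_truth <- function(cfg) {
  genes <- sim_gene_ids(cfg)
  informative <- genes[seq_len(cfg$n_informative)]
  modules <- list()
  at <- 1L
  for (i in seq_along(cfg$planted_module_sizes)) {
    sz <- cfg$planted_module_sizes[[i]]
    modules[[paste0("module", i)]] <- informative[at:(at + sz - 1L)]
    at <- at + sz
  }
  list(informative_genes = informative, modules = modules,
       module_hubs = vapply(modules, `[[`, character(1L), 1L),
       corr_flip_module = cfg$corr_flip_module)
}

#' Simulate expression cohorts with known ground truth
#'
#' Background genes are Normal(batch offset, 1); informative genes gain
#' `effect_size` in poor-outcome samples; members of each planted module
#' share a latent factor (so module genes are correlated, and hub-member
#' correlations can flip with class in the designated module); each cohort is
#' then z-normalized.
#'
#' @param cfg A `SimulationConfig`.
#' @return A list with `cohorts` (list of `ExpressionDataset`) and `truth`
#'   (informative genes, planted modules, module hubs).
#' @export
simulate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  genes <- sim_gene_ids(cfg)
  truth <- sim_ground_truth(cfg)
  n <- cfg$samples_per_cohort
  n_poor <- max(2L, min(n - 2L, round(cfg$poor_fraction * n)))
  cohorts <- with_seed(cfg$seed, lapply(seq_len(cfg$n_cohorts), function(ci) {
    labels <- sample(rep(c(1L, 0L), c(n_poor, n - n_poor)))
    batch <- stats::rnorm(cfg$n_genes, 0, cfg$batch_sd)
    values <- matrix(stats::rnorm(n * cfg$n_genes), n, cfg$n_genes,
                     dimnames = list(sprintf("c%d_s%03d", ci, seq_len(n)),
                                     genes))
    values <- sweep(values, 2L, batch, "+")
    inf_idx <- match(truth$informative_genes, genes)
    values[labels == 1L, inf_idx] <- values[labels == 1L, inf_idx] +
      cfg$effect_size
    lam <- cfg$module_factor_loading
    for (mi in seq_along(truth$modules)) {
      members <- truth$modules[[mi]]
      f <- stats::rnorm(n)
      flip <- !is.na(cfg$corr_flip_module) && mi == cfg$corr_flip_module
      hub <- truth$module_hubs[[mi]]
      values[, hub] <- values[, hub] + lam * f
      rest <- setdiff(members, hub)
      # sign of the shared factor flips with class in the flip module, so
      # hub-member correlation is positive in good and negative in poor
      s <- if (flip) ifelse(labels == 1L, -1, 1) else rep(1, n)
      for (g in rest) values[, g] <- values[, g] + lam * s * f
    }
    p_er <- pmin(pmax(cfg$er_positive_rate -
                        cfg$er_outcome_coupling * (labels == 1L), 0), 1)
    er <- stats::rbinom(n, 1L, p_er)
    znormalize(expression_dataset(values, labels, er_status = er,
                                  name = paste0("cohort", ci)))
  }))
  names(cohorts) <- vapply(cohorts, `[[`, character(1L), "name")
  list(cohorts = cohorts, truth = truth)
}

#' Simulate a degree-heterogeneous network with planted modules
#'
#' Draws a power-law-ish random graph (static fitness model) over the
#' measured genes plus a fraction of unmeasured protein nodes, then wires
#' each planted module into a connected induced subgraph (a star around the
#' module hub plus a path through the members) and boosts the flip module's
#' hub degree.
#'
#' @param cfg A `SimulationConfig`.
#' @return A `GeneNetwork`.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  truth <- sim_ground_truth(cfg)
  genes <- sim_gene_ids(cfg)
  n_unmeasured <- round(cfg$unmeasured_fraction /
                          (1 - cfg$unmeasured_fraction) * cfg$n_genes)
  nodes <- c(genes, if (n_unmeasured > 0) sprintf("u%06d",
                                                  seq_len(n_unmeasured)))
  with_seed(cfg$seed + 1L, {
    n_nodes <- length(nodes)
    g <- igraph::sample_fitness_pl(n_nodes, 2L * n_nodes,
                                   exponent.out = cfg$network_degree_exponent)
    ends <- igraph::as_edgelist(g, names = FALSE)
    # random assignment of gene/protein ids to graph vertices
    perm <- sample(nodes)
    edges <- cbind(perm[ends[, 1L]], perm[ends[, 2L]])
    for (mi in seq_along(truth$modules)) {
      members <- truth$modules[[mi]]
      hub <- truth$module_hubs[[mi]]
      edges <- rbind(edges,
                     cbind(hub, setdiff(members, hub)),
                     cbind(members[-length(members)], members[-1L]))
      if (!is.na(cfg$corr_flip_module) && mi == cfg$corr_flip_module &&
          cfg$hub_boost_degree > 0L) {
        extra <- sample(setdiff(nodes, members),
                        min(cfg$hub_boost_degree, n_nodes - length(members)))
        edges <- rbind(edges, cbind(hub, extra))
      }
    }
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    gene_network(edges, nodes = nodes, name = "simnet")
  })
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' One planted set per module (module genes padded with random genes up to
#' the configured size range); remaining sets are drawn uniformly from the
#' measured gene universe.
#'
#' @param cfg A `SimulationConfig`.
#' @return A `GeneSetCollection`; planted sets are named `PS_module<i>`.
#' @export
simulate_genesets <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  truth <- sim_ground_truth(cfg)
  genes <- sim_gene_ids(cfg)
  rng <- cfg$geneset_size_range
  with_seed(cfg$seed + 2L, {
    sets <- list()
    for (mi in seq_along(truth$modules)) {
      members <- truth$modules[[mi]]
      size <- max(length(members),
                  sample(seq(rng[1L], rng[2L]), 1L))
      pad <- sample(setdiff(genes, members), size - length(members))
      sets[[paste0("PS_module", mi)]] <- c(members, pad)
    }
    n_rand <- max(0L, cfg$n_genesets - length(sets))
    for (i in seq_len(n_rand)) {
      size <- sample(seq(rng[1L], rng[2L]), 1L)
      sets[[sprintf("RS_%03d", i)]] <- sample(genes, size)
    }
    gene_set_collection(sets, name = "simsets")
  })
}

#' Simulate the full benchmark bundle
#'
#' @param cfg A `SimulationConfig`.
#' @return List with `cohorts`, `truth`, `network`, `genesets`.
#' @export
simulate_benchmark <- function(cfg) {
  sim <- simulate_cohorts(cfg)
  list(cohorts = sim$cohorts, truth = sim$truth,
       network = simulate_network(cfg), genesets = simulate_genesets(cfg))
}
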
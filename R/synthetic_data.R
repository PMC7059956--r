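#' Generate a synthetic polarization expression study with planted regulators
#'
#' Emulates the structure of a three-phenotype (M0/M1/M2) macrophage
#' polarization experiment with biological and technical replicates, driven by
#' latent transcription-factor activities. Expression of gene `i` in sample
#' `k` is generated as
#' `g[i,k] = beta0[i] + sum_t beta[t,i] * ES[t,i] * act[t,k] + eps`,
#' with `eps ~ Normal(0, noise_sd)`. Activities are drawn per phenotype
#' (shared phenotype mean, biological-replicate jitter) so that phenotypes
#' have genuinely distinct regulatory states; technical replicates share the
#' activity of their biological replicate and differ only through noise.
#'
#' Every gene is assigned at least one true regulator, every true TF receives
#' at least 15 evidence-supported targets (so it survives the eligibility
#' filter), and decoy TFs receive random evidence-supported targets but do not
#' influence expression. Evidence records are drawn across all six source
#' tiers.
#'
#' @param n_genes Number of signature genes (>= 30).
#' @param n_true_tf Number of planted regulators (<= 5).
#' @param n_decoy_tf Number of decoy TFs.
#' @param n_pheno,n_bio,n_tech Phenotypes, biological and technical
#'   replicates (defaults 3, 3, 2).
#' @param noise_sd Standard deviation of the additive expression noise.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return List with `expression` (an [expr_matrix()], raw scale),
#'   `evidence` (an [evidence_table()]), and `truth` (true TF set, activity
#'   matrix, coefficients, decoy TFs, noise level).
#' @export
generate_expression <- function(n_genes = 112, n_true_tf = 4,
                                n_decoy_tf = 26, n_pheno = 3, n_bio = 3,
                                n_tech = 2, noise_sd = 0.2, seed = 1L) {
  if (n_genes < 30) stop("n_genes must be at least 30")
  if (n_true_tf > 5) stop("at most 5 true regulators are supported")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n_samples <- n_pheno * n_bio * n_tech
  if (n_samples < 2) stop("design yields fewer than 2 samples")
  set.seed(seed)

  genes <- sprintf("G%03d", seq_len(n_genes))
  true_tfs <- sprintf("TF%02d", seq_len(n_true_tf))
  decoy_tfs <- if (n_decoy_tf > 0) sprintf("DTF%02d", seq_len(n_decoy_tf))
               else character(0)
  phenos <- paste0("M", seq_len(n_pheno) - 1)

  meta <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      phenotype = phenos, stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_b%d_t%d", meta$phenotype, meta$bio_rep,
                         meta$tech_rep)
  meta <- meta[, c("sample", "phenotype", "bio_rep", "tech_rep")]

  # latent activities: phenotype mean + biological-replicate jitter
  all_tfs <- c(true_tfs, decoy_tfs)
  pheno_mean <- matrix(rnorm(length(all_tfs) * n_pheno, sd = 1),
                       length(all_tfs), n_pheno,
                       dimnames = list(all_tfs, phenos))
  act <- matrix(0, length(all_tfs), n_samples,
                dimnames = list(all_tfs, meta$sample))
  for (p in phenos) {
    for (b in seq_len(n_bio)) {
      cols <- meta$sample[meta$phenotype == p & meta$bio_rep == b]
      act[, cols] <- pheno_mean[, p] + rnorm(length(all_tfs), sd = 0.15)
    }
  }

  # every gene gets exactly one true regulator (balanced assignment), so the
  # target-averaging activity estimate is a consistent (scaled) readout of
  # each TF's latent activity; overlapping regulons would turn the estimates
  # into TF mixtures and misspecify the downstream regression
  primary <- sample(rep_len(true_tfs, n_genes))
  edges <- data.frame(tf = primary, target = genes)

  # decoys: eligibility-passing target lists with no expression effect
  for (d in decoy_tfs) {
    tg <- sample(genes, sample(15:min(40, n_genes), 1))
    edges <- rbind(edges, data.frame(tf = d, target = tg))
  }

  # evidence records per edge, across all six tiers
  patterns <- list("metacore_direct", c("metacore_unspecified", "chea"),
                   c("chea", "ecrbase"), c("metacore_unspecified", "ecrbase"),
                   "encode", "tfacts")
  pick <- sample(length(patterns), nrow(edges), replace = TRUE)
  ev <- do.call(rbind, lapply(seq_len(nrow(edges)), function(e)
    data.frame(tf = edges$tf[e], target = edges$target[e],
               tier = patterns[[pick[e]]])))
  ev <- unique(ev)
  evidence <- evidence_table(ev$tf, ev$target, ev$tier)

  es <- compute_edge_scores(evidence)
  beta0 <- setNames(rnorm(n_genes, sd = 0.3), genes)
  beta <- matrix(0, n_true_tf, n_genes, dimnames = list(true_tfs, genes))
  true_edges <- edges[edges$tf %in% true_tfs, ]
  for (e in seq_len(nrow(true_edges))) {
    # predominantly activating regulons: the target-averaging activity
    # estimate needs a coherent net direction to carry any signal
    beta[true_edges$tf[e], true_edges$target[e]] <-
      sample(c(-1, 1), 1, prob = c(0.2, 0.8)) * runif(1, 0.5, 2)
  }

  es_true <- es$scores[true_tfs, genes, drop = FALSE]
  signal <- t(beta * es_true) %*% act[true_tfs, , drop = FALSE]
  values <- sweep(signal, 1, beta0, "+") +
    matrix(rnorm(n_genes * n_samples, sd = noise_sd), n_genes)
  dimnames(values) <- list(genes, meta$sample)

  list(expression = expr_matrix(values, meta),
       evidence = evidence,
       truth = list(true_tfs = true_tfs, decoy_tfs = decoy_tfs,
                    activities = act, beta0 = beta0, beta = beta,
                    edge_scores = es, noise_sd = noise_sd))
}

#' Generate a small metabolic network with a planted internal cycle
#'
#' The network has one input exchange, a linear core pathway feeding a
#' biomass reaction and an output exchange, and a planted stoichiometrically
#' balanced internal cycle of the requested length attached to the pathway.
#' The cycle is thermodynamically infeasible when carried: it has zero net
#' stoichiometry and no exchange involvement. A generating flux vector that
#' satisfies the steady state, the bounds and the biomass floor, and carries
#' the planted cycle, is returned as ground truth.
#'
#' Reaction layout (cycle length L): `EX_in: -> A`, `R1: A -> B`,
#' `R2: B -> C`, `R3: C -> D`, `EX_out: D ->`, `biomass: C ->`, and the cycle
#' `CY1: B -> P1`, ..., `CYL: P(L-1) -> B`. Each internal reaction carries one
#' associated gene.
#'
#' @param planted_cycle_len Cycle length, 2, 3 or 4.
#' @param seed Integer seed (jitters bounds and the generating flux).
#' @param gene_pool Optional character vector to draw gene names from
#'   (defaults to one synthetic gene per internal reaction).
#' @return List with `model` (a [metabolic_model()]) and `truth` (generating
#'   flux vector `v`, `cycle` reaction identifiers, `biomass_flux`).
#' @export
generate_toy_network <- function(planted_cycle_len = 2, seed = 1L,
                                 gene_pool = NULL) {
  if (!planted_cycle_len %in% 2:4) stop("planted_cycle_len must be 2, 3 or 4")
  set.seed(seed)
  L <- planted_cycle_len
  cyc_mets <- if (L > 1) sprintf("P%d", seq_len(L - 1)) else character(0)
  mets <- c("A", "B", "C", "D", cyc_mets)

  cyc_ids <- sprintf("CY%d", seq_len(L))
  ids <- c("EX_in", "R1", "R2", "R3", "EX_out", "biomass", cyc_ids)
  ub <- round(runif(length(ids), 8, 12), 2)
  reactions <- data.frame(id = ids, lb = 0, ub = ub)

  cyc_nodes <- c("B", cyc_mets, "B")
  stoich <- c(list(
    EX_in = c(A = 1),
    R1 = c(A = -1, B = 1),
    R2 = c(B = -1, C = 1),
    R3 = c(C = -1, D = 1),
    EX_out = c(D = -1),
    biomass = c(C = -1)),
    setNames(lapply(seq_len(L), function(i)
      setNames(c(-1, 1), cyc_nodes[c(i, i + 1)])), cyc_ids))

  internal <- setdiff(ids, c("EX_in", "EX_out", "biomass"))
  genes <- setNames(vector("list", length(ids)), ids)
  pool <- gene_pool %||% paste0("gene_", internal)
  gi <- setNames(sample(rep_len(pool, length(internal))), internal)
  for (r in internal) genes[[r]] <- unname(gi[r])

  model <- metabolic_model(mets, reactions, stoich[ids], genes[ids],
                           "biomass")

  cflux <- round(runif(1, 0.5, 2), 3)
  bflux <- round(runif(1, 0.05, 0.5), 3)
  through <- round(runif(1, bflux + 0.2, 3), 3)
  v <- setNames(numeric(length(ids)), ids)
  v["EX_in"] <- through; v["R1"] <- through; v["R2"] <- through
  v["biomass"] <- bflux
  v["R3"] <- through - bflux; v["EX_out"] <- through - bflux
  v[cyc_ids] <- cflux

  list(model = model,
       truth = list(v = v, cycle = cyc_ids, biomass_flux = bflux))
}

#' Generate overlapping gene sets with enrichment p-values
#'
#' With `overlap = 0` the sets are pairwise disjoint; with `overlap = 1`
#' consecutive pairs are exact duplicates; intermediate values make every
#' even-indexed set share approximately that fraction of members with its
#' predecessor, so collections contain pairs both above and below the usual
#' redundancy threshold of 0.5. P-values are drawn log-uniformly from
#' `[1e-30, 0.05]`, the significant range a redundancy filter operates on.
#'
#' @param n_sets Number of sets (>= 2).
#' @param universe_size Size of the gene universe.
#' @param overlap Overlap parameter in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(n_sets = 10, universe_size = 400,
                               overlap = 0.5, seed = 1L) {
  if (n_sets < 2) stop("n_sets must be at least 2")
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  set.seed(seed)
  universe <- sprintf("u%05d", seq_len(universe_size))
  sizes <- sample(10:30, n_sets, replace = TRUE)
  if (overlap == 0 && sum(sizes) > universe_size)
    stop("universe too small for disjoint sets of this count")
  sets <- vector("list", n_sets)
  free <- universe
  for (i in seq_len(n_sets)) {
    if (overlap == 0) {
      sets[[i]] <- sample(free, sizes[i])
      free <- setdiff(free, sets[[i]])
    } else if (i %% 2 == 0) {
      prev <- sets[[i - 1]]
      if (overlap == 1) {
        sets[[i]] <- prev
      } else {
        k <- max(1, round(overlap * sizes[i]))
        shared <- sample(prev, min(k, length(prev)))
        sets[[i]] <- c(shared, sample(setdiff(universe, prev),
                                      max(0, sizes[i] - length(shared))))
      }
    } else {
      sets[[i]] <- sample(universe, sizes[i])
    }
  }
  ids <- sprintf("set%03d", seq_len(n_sets))
  names(sets) <- ids
  pvals <- setNames(10 ^ runif(n_sets, -30, log10(0.05)), ids)
  gene_set_collection(sets, pvals,
                      setNames(paste("synthetic set", seq_len(n_sets)), ids))
}
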
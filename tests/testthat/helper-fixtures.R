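# Shared fixture builders and independent oracles used across test files.

make_expr <- function(values, phenotype = NULL, bio = NULL, tech = NULL) {
  n <- ncol(values)
  meta <- data.frame(
    sample = colnames(values),
    phenotype = phenotype %||% rep("M1", n),
    bio_rep = bio %||% seq_len(n),
    tech_rep = tech %||% rep(1L, n))
  expr_matrix(values, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny linear-chain model: EX_in -> A -> B -> biomass
chain_model <- function() {
  metabolic_model(
    metabolites = c("A", "B"),
    reactions = data.frame(id = c("EX_in", "R1", "biomass"),
                           lb = c(1, 0, 0), ub = c(1, 10, 10)),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
    genes = list(character(), "g1", character()),
    biomass = "biomass")
}

# diamond: input splits into two branches that rejoin before biomass
diamond_model <- function() {
  metabolic_model(
    metabolites = c("A", "B", "C", "D"),
    reactions = data.frame(
      id = c("EX_in", "R_ab", "R_ac", "R_bd", "R_cd", "biomass"),
      lb = 0, ub = c(5, 10, 10, 10, 10, 10)),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(A = -1, C = 1),
                  c(B = -1, D = 1), c(C = -1, D = 1), c(D = -1)),
    genes = list(character(), "g_ab", "g_ac", "g_bd", "g_cd", character()),
    biomass = "biomass")
}

# flux targets from a reference flux vector (exact magnitudes, core weights)
targets_from_flux <- function(model, bounds, v, phenotype,
                              reactions = NULL) {
  reactions <- reactions %||%
    model$reactions$id[!model$reactions$exchange &
                         model$reactions$id != model$biomass]
  rows <- lapply(reactions, function(r) {
    mv <- bounds$max_v[bounds$id == r]
    data.frame(id = r, gene = paste0("g_", r), phenotype = phenotype,
               g = 0, min_g = -1, max_g = 1, target = abs(v[[r]]),
               weight = 100 / max(mv, 1e-9), core = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("flux_targets", "data.frame")
  out
}

# independent maximum-weight independent set oracle (recursive branch on the
# highest-degree vertex; isolated vertices are always taken)
oracle_mwis <- function(weights, edges) {
  n <- length(weights)
  nbr <- vector("list", n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  deg <- lengths(nbr)
  base <- sum(weights[deg == 0])
  rec <- function(avail) {
    if (!length(avail)) return(0)
    dg <- vapply(avail, function(u) sum(nbr[[u]] %in% avail), 0L)
    v <- avail[which.max(dg)]
    if (dg[which.max(dg)] == 0) return(sum(weights[avail]))
    max(weights[v] + rec(setdiff(avail, c(v, nbr[[v]]))),
        rec(setdiff(avail, v)))
  }
  base + rec(which(deg > 0))
}

# exhaustive enumeration of stoichiometrically balanced internal sub-cycles
# (length <= max_len) carried by a flux vector at or above the threshold;
# orientation follows the flux sign, balance is checked through the null
# space of the oriented stoichiometric submatrix (pure linear algebra)
find_balanced_subcycles <- function(model, flux, threshold = 0.01,
                                    max_len = 4) {
  ids <- model$reactions$id
  internal <- ids[!model$reactions$exchange & ids != model$biomass]
  supp <- internal[abs(flux[internal]) >= threshold]
  found <- list()
  if (length(supp) < 2) return(found)
  S <- as.matrix(model$S)
  for (sz in 2:min(max_len, length(supp))) {
    cmb <- combn(length(supp), sz)
    for (cidx in seq_len(ncol(cmb))) {
      sub <- supp[cmb[, cidx]]
      M <- S[, sub, drop = FALSE] %*% diag(sign(flux[sub]), length(sub))
      sv <- svd(M)
      nullcols <- which(sv$d < 1e-8 * max(1, sv$d[1]))
      if (!length(nullcols)) next
      stopifnot(length(nullcols) == 1)  # toy networks: simple cycles only
      vbasis <- sv$v[, nullcols]
      if (all(vbasis > 1e-8) || all(vbasis < -1e-8))
        found[[length(found) + 1]] <- sub
    }
  }
  found
}

# small SBML level-3 FBC document with a 3-reaction chain
sbml_chain_doc <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">\n',
    '<model id="toy">\n',
    '<listOfParameters>',
    '<parameter id="lb0" value="0" constant="true"/>',
    '<parameter id="ub10" value="10" constant="true"/>',
    '<parameter id="fix1" value="1" constant="true"/>',
    '</listOfParameters>\n',
    '<listOfSpecies>',
    '<species id="A" constant="false"/>',
    '<species id="B" constant="false"/>',
    '</listOfSpecies>\n',
    '<listOfReactions>\n',
    '<reaction id="EX_in" reversible="false" fbc:lowerFluxBound="fix1" ',
    'fbc:upperFluxBound="fix1">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/>',
    '</listOfProducts></reaction>\n',
    '<reaction id="R1" reversible="false" fbc:lowerFluxBound="lb0" ',
    'fbc:upperFluxBound="ub10">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/>',
    '</listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/>',
    '</listOfProducts>',
    '<fbc:geneProductAssociation><fbc:geneProductRef fbc:geneProduct="g1"/>',
    '</fbc:geneProductAssociation></reaction>\n',
    '<reaction id="biomass_c" reversible="false" fbc:lowerFluxBound="lb0" ',
    'fbc:upperFluxBound="ub10">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1"/>',
    '</listOfReactants></reaction>\n',
    '</listOfReactions>\n',
    '</model>\n</sbml>\n')
}
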
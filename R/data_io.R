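#' Expression matrix with sample metadata
#'
#' Container for a gene-by-sample expression table with per-sample phenotype
#' and replicate annotation. Rows are genes, columns are samples; the metadata
#' has one row per sample column with a phenotype label (e.g. `M0`, `M1`,
#' `M2`), a biological replicate index and a technical replicate index.
#'
#' @param values Numeric matrix, genes x samples, with unique dimnames.
#' @param meta Data frame with columns `sample`, `phenotype`, `bio_rep`,
#'   `tech_rep`; one row per sample column.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  need <- c("sample", "phenotype", "bio_rep", "tech_rep")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("metadata must be a data.frame with columns ",
         paste(need, collapse = ", "))
  missing <- setdiff(colnames(values), meta$sample)
  if (length(missing))
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample), need, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$meta$phenotype), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata
#'
#' The matrix file is a TSV with gene identifiers in the first column and one
#' column per sample; the metadata file is a TSV with columns `sample`,
#' `phenotype`, `bio_rep`, `tech_rep`. Non-numeric cells, duplicate
#' identifiers and samples without metadata are rejected with coordinates.
#'
#' @param matrix_path,metadata_path Paths to the two TSV files.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  raw <- read.delim(matrix_path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression table needs a gene column plus samples")
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals), dimnames(vals)))
  bad <- is.na(num) & !array(vals %in% c("NA", ""), dim(vals))
  if (any(bad)) {
    at <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[at[1]], colnames(vals)[at[2]]))
  }
  rownames(num) <- genes
  meta <- read.delim(metadata_path, check.names = FALSE,
                     colClasses = "character")
  meta$bio_rep <- as.integer(meta$bio_rep)
  meta$tech_rep <- as.integer(meta$tech_rep)
  expr_matrix(num, meta)
}

#' Write an expression matrix and its metadata as TSV
#'
#' @param x An [expr_matrix()].
#' @param matrix_path,metadata_path Output paths.
#' @return `x` invisibly.
#' @export
write_expression <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Z-transform an expression matrix
#'
#' Standardizes each gene to mean 0 and unit sample standard deviation
#' (divisor `n - 1`) across samples. Genes with zero variance map to all-zero
#' rows rather than being dropped, so matrix dimensions are stable. With
#' `collapse_technical = TRUE` (the default used throughout the pipeline),
#' technical replicates are first averaged into one column per
#' (phenotype, biological replicate) and the transformation is applied to the
#' collapsed matrix.
#'
#' @param x An [expr_matrix()].
#' @param collapse_technical Average technical replicates before transforming.
#' @return A z-scored [expr_matrix()].
#' @export
z_transform <- function(x, collapse_technical = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (collapse_technical) {
    key <- paste(x$meta$phenotype, x$meta$bio_rep, sep = "_b")
    groups <- split(seq_along(key), factor(key, levels = unique(key)))
    vals <- vapply(groups, function(j)
      rowMeans(x$values[, j, drop = FALSE]), numeric(nrow(x$values)))
    first <- vapply(groups, `[`, integer(1), 1L)
    meta <- data.frame(sample = names(groups),
                       phenotype = x$meta$phenotype[first],
                       bio_rep = x$meta$bio_rep[first],
                       tech_rep = 1L)
    x <- expr_matrix(vals, meta)
  }
  if (ncol(x$values) < 2) stop("z-transformation needs at least 2 samples")
  mu <- rowMeans(x$values)
  s <- apply(x$values, 1, sd)
  z <- (x$values - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  expr_matrix(z, x$meta)
}

#' Metabolic network model
#'
#' Stores the stoichiometric matrix (metabolites x reactions, sparse), flux
#' bounds, flat gene associations (gene-protein-reaction logic is deliberately
#' flattened to a gene list), exchange flags and the biomass reaction
#' identifier. Reactions touching exactly one metabolite are flagged as
#' exchange reactions when no explicit flag is given.
#'
#' @param metabolites Character vector of metabolite identifiers.
#' @param reactions Data frame with columns `id`, `lb`, `ub` and optionally
#'   `exchange` (logical).
#' @param stoich List (per reaction) of named numeric stoichiometries, or a
#'   metabolites x reactions matrix.
#' @param genes List (per reaction) of character gene vectors.
#' @param biomass Identifier of the biomass reaction.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich, genes, biomass) {
  if (anyDuplicated(metabolites)) stop("duplicate metabolite identifiers")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction identifiers")
  if (any(reactions$lb > reactions$ub))
    stop("reaction lower bound exceeds upper bound: ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "))
  if (!biomass %in% reactions$id)
    stop("biomass reaction '", biomass, "' not in the reaction list")
  if (is.list(stoich)) {
    mets <- unlist(lapply(stoich, names), use.names = FALSE)
    unknown <- setdiff(mets, metabolites)
    if (length(unknown))
      stop("stoichiometry references undeclared metabolite(s): ",
           paste(unique(unknown), collapse = ", "))
    S <- Matrix::sparseMatrix(
      i = match(mets, metabolites),
      j = rep.int(seq_along(stoich), lengths(stoich)),
      x = unlist(stoich, use.names = FALSE),
      dims = c(length(metabolites), nrow(reactions)),
      dimnames = list(metabolites, reactions$id))
  } else {
    S <- Matrix::Matrix(stoich, sparse = TRUE)
    dimnames(S) <- list(metabolites, reactions$id)
  }
  if (is.null(reactions$exchange)) {
    reactions$exchange <- Matrix::colSums(S != 0) == 1
  }
  names(genes) <- reactions$id
  structure(list(metabolites = metabolites, reactions = reactions,
                 S = S, genes = genes, biomass = biomass),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("Metabolic model: %d metabolites, %d reactions (%d exchange), biomass = '%s'\n",
              length(x$metabolites), nrow(x$reactions),
              sum(x$reactions$exchange), x$biomass))
  invisible(x)
}

#' Read a metabolic model
#'
#' Two dialects are supported: a JSON layout
#' `{metabolites: [...], reactions: [{id, stoichiometry: {met: coeff}, lb, ub,
#' genes: [...], exchange: bool}], biomass: id}` and SBML Level 3 with the FBC
#' extension (species, reactions with stoichiometric `speciesReference`s,
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters and flattened
#' `fbc:geneProductAssociation`s).
#'
#' @param path Model file path.
#' @param dialect `"json"` or `"sbml_fbc"`.
#' @param biomass Biomass reaction identifier; required for SBML when no
#'   reaction identifier contains "biomass" (case-insensitive).
#' @return A [metabolic_model()].
#' @export
read_metabolic_model <- function(path, dialect = c("json", "sbml_fbc"),
                                 biomass = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- jsonlite::read_json(path)
    rxns <- obj$reactions
    reactions <- data.frame(
      id = vapply(rxns, function(r) r$id, ""),
      lb = vapply(rxns, function(r) as.numeric(r$lb), 0),
      ub = vapply(rxns, function(r) as.numeric(r$ub), 0))
    ex <- lapply(rxns, function(r) r$exchange)
    if (!all(vapply(ex, is.null, TRUE)))
      reactions$exchange <- vapply(ex, isTRUE, TRUE)
    stoich <- lapply(rxns, function(r)
      vapply(r$stoichiometry, as.numeric, 0))
    genes <- lapply(rxns, function(r)
      as.character(unlist(r$genes)))
    metabolic_model(as.character(unlist(obj$metabolites)), reactions, stoich,
                    genes, biomass %||% obj$biomass)
  } else {
    read_sbml_fbc(path, biomass)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sbml_fbc <- function(path, biomass = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  metabolites <- xml2::xml_attr(species, "id")
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  get_bound <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr)
    if (is.na(ref)) return(default)
    if (!ref %in% names(pval)) stop("undefined flux bound parameter: ", ref)
    pval[[ref]]
  }
  ids <- xml2::xml_attr(rx, "id")
  reactions <- data.frame(
    id = ids,
    lb = vapply(rx, get_bound, 0, "lowerFluxBound", -1000),
    ub = vapply(rx, get_bound, 0, "upperFluxBound", 1000))
  stoich <- lapply(rx, function(node) {
    rea <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    pro <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    coef <- function(refs, sign) {
      st <- xml2::xml_attr(refs, "stoichiometry")
      st[is.na(st)] <- "1"
      setNames(sign * as.numeric(st), xml2::xml_attr(refs, "species"))
    }
    s <- c(coef(rea, -1), coef(pro, +1))
    # merge duplicated species (appearing on both sides)
    tapply(s, names(s), sum)[unique(names(s))]
  })
  genes <- lapply(rx, function(node) {
    refs <- xml2::xml_find_all(
      node, ".//*[local-name() = 'geneProductRef']")
    g <- xml2::xml_attr(refs, "geneProduct")
    g[is.na(g)] <- xml2::xml_attr(refs, "fbc:geneProduct")[is.na(g)]
    unique(g[!is.na(g)])
  })
  if (is.null(biomass)) {
    hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
    if (length(hit) != 1)
      stop("cannot identify the biomass reaction; pass 'biomass' explicitly")
    biomass <- hit
  }
  metabolic_model(metabolites, reactions, stoich, genes, biomass)
}

#' Write a metabolic model in the JSON dialect
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return `model` invisibly.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    id <- model$reactions$id[i]
    s <- model$S[, i]
    s <- s[s != 0]
    list(id = id, stoichiometry = as.list(s),
         lb = model$reactions$lb[i], ub = model$reactions$ub[i],
         genes = as.list(model$genes[[id]]),
         exchange = model$reactions$exchange[i])
  })
  jsonlite::write_json(
    list(metabolites = model$metabolites, reactions = rxns,
         biomass = model$biomass),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(model)
}

#' Add a reaction to a metabolic model
#'
#' Returns a new model containing the reaction; the input model is unchanged.
#' Metabolites not yet declared are added alongside. The canonical use is the
#' ornithine carbamoyltransferase reaction
#' (ornithine + carbamoyl-phosphate = H+ + Pi + L-citrulline) that completes
#' the urea cycle of the macrophage reconstruction.
#'
#' @param model A [metabolic_model()].
#' @param id New, unused reaction identifier.
#' @param stoichiometry Named numeric vector (negative = substrate).
#' @param lb,ub Flux bounds.
#' @param genes Character vector of associated genes.
#' @param exchange Logical; defaults to the single-metabolite rule.
#' @return The extended model.
#' @export
add_reaction <- function(model, id, stoichiometry, lb, ub,
                         genes = character(), exchange = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (id %in% model$reactions$id)
    stop("reaction identifier already in use: ", id)
  if (lb > ub) stop("lower bound exceeds upper bound")
  mets <- union(model$metabolites, names(stoichiometry))
  stoich <- c(lapply(seq_len(nrow(model$reactions)), function(i) {
    s <- model$S[, i]
    s[s != 0]
  }), list(stoichiometry))
  reactions <- rbind(
    model$reactions[, c("id", "lb", "ub")],
    data.frame(id = id, lb = lb, ub = ub))
  reactions$exchange <- c(model$reactions$exchange,
                          exchange %||% (length(stoichiometry) == 1))
  metabolic_model(mets, reactions, stoich,
                  c(unname(model$genes), list(genes)), model$biomass)
}

#' Remove a reaction from a metabolic model
#'
#' @param model A [metabolic_model()].
#' @param id Reaction identifier to drop (not the biomass reaction).
#' @return The reduced model. Metabolites left without any reaction are kept.
#' @export
remove_reaction <- function(model, id) {
  stopifnot(inherits(model, "metabolic_model"))
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", id)
  if (id == model$biomass) stop("cannot remove the biomass reaction")
  model$reactions <- model$reactions[-i, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$S <- model$S[, -i, drop = FALSE]
  model$genes <- model$genes[-i]
  model
}

#' Evidence table of TF-target interaction records
#'
#' @param tf,target,tier Equal-length character vectors; `tier` must be one of
#'   `metacore_direct`, `metacore_unspecified`, `chea`, `ecrbase`, `encode`,
#'   `tfacts`. Duplicate (TF, target, tier) records are rejected.
#' @return A data frame of class `evidence_table`.
#' @export
evidence_table <- function(tf, target, tier) {
  valid <- c("metacore_direct", "metacore_unspecified", "chea", "ecrbase",
             "encode", "tfacts")
  bad <- setdiff(unique(tier), valid)
  if (length(bad))
    stop("unknown evidence tier(s): ", paste(bad, collapse = ", "),
         "; valid tiers are: ", paste(valid, collapse = ", "))
  df <- data.frame(tf = as.character(tf), target = as.character(target),
                   tier = as.character(tier))
  if (anyDuplicated(df)) stop("duplicate (TF, target, tier) record")
  class(df) <- c("evidence_table", "data.frame")
  df
}

#' Read a TF-target evidence table (TSV with columns tf, target, tier)
#'
#' @param path Input path.
#' @return An [evidence_table()].
#' @export
read_evidence <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("tf", "target", "tier") %in% names(df)))
    stop("evidence table needs columns tf, target, tier")
  evidence_table(df$tf, df$target, df$tier)
}

#' Write an evidence table as TSV
#' @param x An [evidence_table()].
#' @param path Output path.
#' @return `x` invisibly.
#' @export
write_evidence <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Gene-set collection with enrichment p-values
#'
#' @param sets Named list of non-empty character vectors (members).
#' @param names Optional display names (defaults to the identifiers).
#' @param pvalues Named numeric vector in (0, 1], one per set.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, pvalues, names = NULL) {
  if (is.null(base::names(sets)) || anyDuplicated(base::names(sets)))
    stop("gene sets must have unique identifiers")
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  ids <- base::names(sets)
  if (!all(ids %in% base::names(pvalues)))
    stop("missing p-value for set(s): ",
         paste(setdiff(ids, base::names(pvalues)), collapse = ", "))
  p <- as.numeric(pvalues[ids])
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]; offending set(s): ",
         paste(ids[p <= 0 | p > 1], collapse = ", "))
  structure(list(sets = lapply(sets, as.character),
                 names = setNames(if (is.null(names)) ids else names[ids], ids),
                 pvalues = setNames(p, ids)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets, %d..%d members\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets (GMT) with a companion p-value table
#'
#' GMT lines are `id<TAB>name<TAB>gene1<TAB>gene2...`; the p-value file is a
#' TSV with columns `id` and `pvalue`.
#'
#' @param gmt_path,pvalue_path Input paths.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(gmt_path, pvalue_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("GMT line(s) without members: ", paste(short, collapse = ", "))
  ids <- vapply(parts, `[`, "", 1L)
  nms <- setNames(vapply(parts, `[`, "", 2L), ids)
  sets <- setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  pv <- read.delim(pvalue_path)
  if (!all(c("id", "pvalue") %in% names(pv)))
    stop("p-value table needs columns id, pvalue")
  gene_set_collection(sets, setNames(as.numeric(pv$pvalue), pv$id), nms)
}

#' Write a gene-set collection as GMT plus a p-value TSV
#'
#' @param x A [gene_set_collection()].
#' @param gmt_path,pvalue_path Output paths.
#' @return `x` invisibly.
#' @export
write_gene_sets <- function(x, gmt_path, pvalue_path) {
  stopifnot(inherits(x, "gene_set_collection"))
  ids <- names(x$sets)
  writeLines(vapply(ids, function(id)
    paste(c(id, x$names[[id]], x$sets[[id]]), collapse = "\t"), ""), gmt_path)
  write.table(data.frame(id = ids, pvalue = x$pvalues[ids]), pvalue_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
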
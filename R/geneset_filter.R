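#' Jaccard similarity between two gene sets
#'
#' @param a,b Non-empty character vectors of gene identifiers.
#' @return `|a intersect b| / |a union b|`, a number in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    stop("Jaccard similarity is undefined for empty sets")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Stable-set vertex weight from an enrichment p-value
#'
#' A gene set with enrichment p-value `p` enters the redundancy graph with
#' weight `1 - log10(p) / 100`, so that more significant sets (smaller p) are
#' preferred by the maximum-weight selection while all weights stay close to 1
#' (the selection primarily maximizes the number of retained sets).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of weights (>= 1).
#' @examples
#' weight_from_pvalue(0.01)  # 1.02
#' @export
weight_from_pvalue <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  1 - log10(p) / 100
}

#' Build the Jaccard redundancy graph of a gene-set collection
#'
#' Vertices are gene sets, weighted by [weight_from_pvalue()]; an undirected
#' edge joins every pair whose Jaccard similarity reaches `threshold`.
#'
#' @param collection A [gene_set_collection()].
#' @param threshold Jaccard similarity at or above which two sets count as
#'   redundant (default 0.5).
#' @return A list of class `redundancy_graph` with elements `vertices`
#'   (identifiers), `weights`, `edges` (two-column matrix of identifier
#'   pairs), and `threshold`.
#' @export
build_redundancy_graph <- function(collection, threshold = 0.5) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$sets)
  n <- length(ids)
  from <- character(0); to <- character(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (jaccard(collection$sets[[i]], collection$sets[[j]]) >= threshold) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
        }
      }
    }
  }
  structure(list(vertices = ids,
                 weights = setNames(weight_from_pvalue(collection$pvalues[ids]), ids),
                 edges = cbind(from, to),
                 threshold = threshold),
            class = "redundancy_graph")
}

#' @export
print.redundancy_graph <- function(x, ...) {
  cat(sprintf("Redundancy graph: %d gene sets, %d redundant pairs (J >= %g)\n",
              length(x$vertices), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Select a maximum-weight non-redundant subset of gene sets
#'
#' Solves the maximum-weight stable-set problem on the redundancy graph: at
#' most one endpoint of every redundant pair may be kept, and the total
#' p-value-derived weight of the kept sets is maximized. Because all weights
#' are close to 1, this effectively maximizes the number of retained sets,
#' with significance breaking ties.
#'
#' @param graph A [build_redundancy_graph()] result.
#' @param seed,tolerance Passed to [solve_lmp()].
#' @return A list with `selected` (vertex identifiers), `total_weight`, and
#'   the `lmp_solution` status.
#' @export
select_nonredundant <- function(graph, seed = 1L, tolerance = 1e-6) {
  stopifnot(inherits(graph, "redundancy_graph"))
  p <- lmp("max")
  p <- lmp_add_variables(p, graph$vertices, type = "binary", lb = 0, ub = 1,
                         obj = graph$weights)
  if (nrow(graph$edges) > 0) {
    cons <- lapply(seq_len(nrow(graph$edges)), function(k)
      setNames(c(1, 1), graph$edges[k, ]))
    p <- lmp_add_constraints(p, cons, "<=", 1)
  }
  sol <- solve_lmp(p, seed = seed, tolerance = tolerance)
  if (sol$status != "optimal")
    stop("stable-set selection failed with solver status: ", sol$status)
  keep <- graph$vertices[sol$solution[graph$vertices] > 0.5]
  list(selected = keep,
       total_weight = sum(graph$weights[keep]),
       status = sol$status)
}

#' Filter a gene-set collection down to a non-redundant subset
#'
#' Convenience wrapper: builds the redundancy graph and runs the stable-set
#' selection, returning a per-set table.
#'
#' @inheritParams build_redundancy_graph
#' @inheritParams select_nonredundant
#' @return Data frame with columns `id`, `name`, `pvalue`, `weight`,
#'   `selected`.
#' @export
filter_gene_sets <- function(collection, threshold = 0.5, seed = 1L) {
  g <- build_redundancy_graph(collection, threshold)
  sel <- select_nonredundant(g, seed = seed)
  ids <- names(collection$sets)
  data.frame(id = ids,
             name = unname(collection$names[ids]),
             pvalue = unname(collection$pvalues[ids]),
             weight = unname(g$weights[ids]),
             selected = ids %in% sel$selected)
}
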
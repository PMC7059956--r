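#' Flux variability analysis under a biomass floor
#'
#' For each reaction, minimizes and maximizes its flux subject to the steady
#' state `S v = 0`, the reaction bounds, and a minimum biomass production
#' (default 0.028, the maintenance growth floor of the macrophage
#' reconstruction). From the signed extremes, the attainable absolute-flux
#' range `[minV, maxV]` is derived: `minV = 0` whenever the signed range
#' spans zero.
#'
#' @param model A [metabolic_model()].
#' @param biomass_min Biomass flux floor (default 0.028).
#' @param tolerance Solver tolerance.
#' @return A data frame of class `flux_bounds` with columns `id`, `fva_min`,
#'   `fva_max`, `min_v`, `max_v`.
#' @export
run_fva <- function(model, biomass_min = 0.028, tolerance = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  base <- fba_program(model, biomass_min)
  ids <- model$reactions$id
  # feasibility check first so an unreachable floor is reported as such
  probe <- solve_lmp(lmp_set_objective(base, setNames(1, model$biomass)),
                     tolerance = tolerance)
  if (probe$status == "infeasible")
    stop("model infeasible under biomass floor ", biomass_min)
  fva_min <- fva_max <- setNames(numeric(length(ids)), ids)
  for (r in ids) {
    for (sense in c("min", "max")) {
      p <- base
      p$sense <- sense
      p <- lmp_set_objective(p, setNames(1, r))
      sol <- solve_lmp(p, tolerance = tolerance)
      if (sol$status != "optimal")
        stop("FVA ", sense, " failed for reaction ", r, ": ", sol$status)
      if (sense == "min") fva_min[r] <- sol$objective
      else fva_max[r] <- sol$objective
    }
  }
  # snap tiny numerical residue to zero so blocked reactions are exact
  fva_min[abs(fva_min) < tolerance] <- 0
  fva_max[abs(fva_max) < tolerance] <- 0
  min_v <- ifelse(fva_min <= 0 & fva_max >= 0, 0,
                  pmin(abs(fva_min), abs(fva_max)))
  max_v <- pmax(abs(fva_min), abs(fva_max))
  structure(data.frame(id = ids, fva_min = unname(fva_min),
                       fva_max = unname(fva_max), min_v = unname(min_v),
                       max_v = unname(max_v)),
            class = c("flux_bounds", "data.frame"))
}

# LP skeleton shared by FVA and the flux fit: flux variable per reaction with
# its bounds (biomass floor applied), one steady-state equality per metabolite.
fba_program <- function(model, biomass_min) {
  ids <- model$reactions$id
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  bi <- match(model$biomass, ids)
  lb[bi] <- max(lb[bi], biomass_min)
  if (lb[bi] > ub[bi])
    stop("biomass floor ", biomass_min, " exceeds the biomass upper bound")
  p <- lmp("min")
  p <- lmp_add_variables(p, ids, lb = lb, ub = ub)
  St <- as(model$S, "TsparseMatrix")
  if (length(St@x)) {
    rows <- split(data.frame(j = St@j + 1L, x = St@x), St@i + 1L)
    cons <- lapply(rows, function(d) setNames(d$x, ids[d$j]))
    p <- lmp_add_constraints(p, cons, "==", 0)
  }
  p
}

#' Map an expression value to an absolute flux magnitude
#'
#' Linear interpolation between the attainable absolute-flux extremes: an
#' expression value at the lowest observed level maps to `min_v`, at the
#' highest to `max_v`.
#'
#' @param g Expression value(s) (z-score scale).
#' @param min_g,max_g Lowest/highest expression observed for the reaction
#'   across the compared conditions (`max_g > min_g`).
#' @param min_v,max_v Absolute-flux extremes from [run_fva()].
#' @return Absolute flux magnitude(s).
#' @export
expression_to_flux_magnitude <- function(g, min_g, max_g, min_v, max_v) {
  if (max_g <= min_g) stop("max_g must exceed min_g")
  if (min_v > max_v) stop("min_v must not exceed max_v")
  # convex-combination form: exact at both endpoints in floating point
  t <- (g - min_g) / (max_g - min_g)
  (1 - t) * min_v + t * max_v
}

#' Build expression-derived flux targets
#'
#' For every core reaction and every direct neighbor of a core reaction
#' (reactions sharing at least one non-currency metabolite), one target entry
#' is created per associated gene and phenotype: the gene's phenotype-mean
#' z-score is mapped to an absolute flux magnitude via
#' [expression_to_flux_magnitude()], with `min_g`/`max_g` taken per reaction
#' across all phenotypes and genes. Entries are weighted `100 / (max_v * n)`
#' for core reactions and `1 / (max_v * n)` for neighbors, `n` being the
#' number of genes of the reaction. Reactions without gene association,
#' blocked reactions (`max_v = 0`) and reactions with constant expression
#' (`max_g = min_g`) are excluded; genes absent from the expression matrix
#' are dropped with a warning.
#'
#' @param model A [metabolic_model()].
#' @param zexpr Z-transformed [expr_matrix()].
#' @param bounds A [run_fva()] result.
#' @param core Character vector of core reaction identifiers.
#' @param currency Metabolite identifiers ignored when determining
#'   neighborhood (defaults to common cofactors).
#' @return A data frame of class `flux_targets` with one row per (reaction,
#'   gene, phenotype): columns `id`, `gene`, `phenotype`, `g`, `min_g`,
#'   `max_g`, `target` (the magnitude), `weight`, `core`.
#' @export
build_targets <- function(model, zexpr, bounds, core,
                          currency = c("h", "h2o", "atp", "adp", "pi",
                                       "nad", "nadh", "nadp", "nadph")) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(zexpr, "expr_matrix"),
            inherits(bounds, "flux_bounds"))
  if (!length(core)) stop("core reaction set must be non-empty")
  unknown <- setdiff(core, model$reactions$id)
  if (length(unknown))
    stop("unknown core reaction(s): ", paste(unknown, collapse = ", "))
  ids <- model$reactions$id
  keep_met <- !(tolower(model$metabolites) %in% currency)
  S <- model$S[keep_met, , drop = FALSE]
  touches <- apply(S[, core, drop = FALSE] != 0, 1, any)
  neighbor <- ids[Matrix::colSums(S[touches, , drop = FALSE] != 0) > 0]
  neighbor <- setdiff(neighbor, core)
  scope <- c(core, neighbor)

  phenos <- unique(zexpr$meta$phenotype)
  pheno_mean <- function(gene) vapply(phenos, function(p)
    mean(zexpr$values[gene, zexpr$meta$phenotype == p]), 0)

  rows <- list()
  for (r in scope) {
    gs <- model$genes[[r]]
    if (!length(gs)) next
    present <- intersect(gs, rownames(zexpr$values))
    if (length(present) < length(gs))
      warning("reaction ", r, ": gene(s) absent from expression matrix: ",
              paste(setdiff(gs, present), collapse = ", "),
              if (!length(present)) "; reaction excluded" else "")
    if (!length(present)) next
    b <- bounds[bounds$id == r, ]
    if (nrow(b) == 0 || b$max_v <= 0) next
    gbar <- vapply(present, pheno_mean, numeric(length(phenos)))
    if (length(phenos) == 1) gbar <- matrix(gbar, 1,
                                            dimnames = list(phenos, present))
    min_g <- min(gbar); max_g <- max(gbar)
    if (max_g <= min_g) next
    n <- length(present)
    w <- (if (r %in% core) 100 else 1) / (b$max_v * n)
    for (gene in present) {
      for (p in phenos) {
        rows[[length(rows) + 1]] <- data.frame(
          id = r, gene = gene, phenotype = p, g = gbar[p, gene],
          min_g = min_g, max_g = max_g,
          target = expression_to_flux_magnitude(gbar[p, gene], min_g, max_g,
                                                b$min_v, b$max_v),
          weight = w, core = r %in% core)
      }
    }
  }
  if (!length(rows))
    stop("no usable flux target (check gene associations and expression)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("flux_targets", "data.frame")
  out
}

#' Detect a minimum thermodynamically infeasible cycle in a flux support
#'
#' Given the support of a flux vector (internal reactions with absolute flux
#' at or above `threshold`), orients each support reaction along its current
#' flux direction and solves the minimum-cycle MIP: find nonnegative oriented
#' fluxes `lambda` with zero net stoichiometry, at least two participating
#' reactions (binary indicators coupled by `lambda >= inFC` and
#' `lambda <= M * inFC`), minimizing total cycle flux. Infeasibility proves
#' the support loop-free.
#'
#' @param model A [metabolic_model()].
#' @param flux Named flux vector (a current solution).
#' @param threshold Support threshold (default 0.01).
#' @param big_m Coupling constant (default 1000, above any shipped bound).
#' @param tolerance Solver tolerance.
#' @return `NULL` when no cycle exists; otherwise a list of class
#'   `cycle_cut` with `reactions`, `directions` (+1/-1 per reaction), and
#'   `k` (cycle cardinality).
#' @export
detect_min_cycle <- function(model, flux, threshold = 0.01, big_m = 1000,
                             tolerance = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  ids <- model$reactions$id
  internal <- ids[!model$reactions$exchange & ids != model$biomass]
  supp <- internal[abs(flux[internal]) >= threshold]
  if (length(supp) < 2) return(NULL)
  dirs <- sign(flux[supp])
  # orient columns along the current flux direction so lambda >= 0
  S <- model$S[, supp, drop = FALSE] %*% Matrix::Diagonal(x = dirs)
  p <- lmp("min")
  p <- lmp_add_variables(p, paste0("lam.", supp), lb = 0, obj = 1)
  p <- lmp_add_variables(p, paste0("in.", supp), type = "binary",
                         lb = 0, ub = 1)
  St <- as(S, "TsparseMatrix")
  met_rows <- split(data.frame(j = St@j + 1L, x = St@x), St@i + 1L)
  cons <- lapply(met_rows, function(d) setNames(d$x, paste0("lam.", supp[d$j])))
  p <- lmp_add_constraints(p, cons, "==", 0)
  for (r in supp) {
    p <- lmp_add_constraints(p, setNames(c(1, -1), paste0(c("lam.", "in."), r)),
                             ">=", 0)
    p <- lmp_add_constraints(p, setNames(c(1, -big_m),
                                         paste0(c("lam.", "in."), r)),
                             "<=", 0)
  }
  p <- lmp_add_constraints(p, setNames(rep(1, length(supp)),
                                       paste0("in.", supp)), ">=", 2)
  sol <- solve_lmp(p, tolerance = tolerance)
  if (sol$status == "infeasible") return(NULL)
  if (!sol$status %in% c("optimal", "feasible"))
    stop("cycle detection failed with solver status: ", sol$status)
  inc <- sol$solution[paste0("in.", supp)] > 0.5
  structure(list(reactions = supp[inc], directions = dirs[inc],
                 k = sum(inc)),
            class = "cycle_cut")
}

#' @export
print.cycle_cut <- function(x, ...) {
  cat(sprintf("Cycle cut (k = %d): %s\n", x$k,
              paste0(ifelse(x$directions > 0, "+", "-"), x$reactions,
                     collapse = " ")))
  invisible(x)
}

#' Fit phenotype fluxes to expression-derived targets with loop removal
#'
#' Finds the flux vector minimizing the weighted L1 deviation
#' `sum w * | |v_r| - |target_r| |` over the target entries, subject to the
#' steady state, the reaction bounds, the biomass floor and all accumulated
#' cycle cuts. Absolute fluxes are linearized by splitting each reaction into
#' forward/backward parts with a binary direction indicator (so `|v|` is
#' exact even for reversible reactions). After each solve the support is
#' scanned with [detect_min_cycle()]; any detected cycle is forbidden by a
#' cut that forces at least one member's directional flux below the support
#' threshold, and the problem is re-solved until detection is infeasible.
#'
#' @param model A [metabolic_model()].
#' @param targets A [build_targets()] result.
#' @param bounds A [run_fva()] result used to tighten the reaction bounds to
#'   the attainable ranges, or `NULL` to keep the raw bounds.
#' @param phenotype Phenotype label whose target entries are fitted.
#' @param biomass_min Biomass floor (default 0.028).
#' @param support_threshold Support threshold for cycle handling (default
#'   0.01).
#' @param max_iter Cut iterations allowed (default 50); 0 skips loop removal.
#' @param tolerance Solver tolerance.
#' @return An object of class `flux_fit`: `phenotype`, `fluxes` (named
#'   vector), `objective`, `support`, `cuts` (list of `cycle_cut`),
#'   `iterations`.
#' @export
fit_fluxes <- function(model, targets, bounds = NULL, phenotype,
                       biomass_min = 0.028, support_threshold = 0.01,
                       max_iter = 50, tolerance = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(targets, "flux_targets"))
  tg <- targets[targets$phenotype == phenotype, , drop = FALSE]
  if (!nrow(tg)) stop("no target entries for phenotype ", phenotype)
  ids <- model$reactions$id
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  if (!is.null(bounds)) {
    # FVA ranges are valid tightenings of the raw bounds
    stopifnot(inherits(bounds, "flux_bounds"))
    i <- match(ids, bounds$id)
    lb <- pmax(lb, bounds$fva_min[i])
    ub <- pmin(ub, bounds$fva_max[i])
  }
  bi <- match(model$biomass, ids)
  lb[bi] <- max(lb[bi], biomass_min)

  p <- lmp("min")
  # split fluxes: v = pos - neg, both >= 0, at most one active
  p <- lmp_add_variables(p, paste0("pos.", ids), lb = 0, ub = pmax(ub, 0))
  p <- lmp_add_variables(p, paste0("neg.", ids), lb = 0, ub = pmax(-lb, 0))
  rev_ids <- ids[lb < 0 & ub > 0]
  if (length(rev_ids)) {
    p <- lmp_add_variables(p, paste0("dir.", rev_ids), type = "binary",
                           lb = 0, ub = 1)
    for (r in rev_ids) {
      i <- match(r, ids)
      p <- lmp_add_constraints(p, setNames(c(1, -max(ub[i], 0)),
                                           paste0(c("pos.", "dir."), r)),
                               "<=", 0)
      p <- lmp_add_constraints(p, setNames(c(1, max(-lb[i], 0)),
                                           paste0(c("neg.", "dir."), r)),
                               "<=", max(-lb[i], 0))
    }
  }
  # fixed-direction bounds: v >= lb > 0 or v <= ub < 0
  fwd_min <- ids[lb > 0]
  for (r in fwd_min)
    p <- lmp_add_constraints(p, setNames(1, paste0("pos.", r)), ">=",
                             lb[match(r, ids)])
  bwd_min <- ids[ub < 0]
  for (r in bwd_min)
    p <- lmp_add_constraints(p, setNames(1, paste0("neg.", r)), ">=",
                             -ub[match(r, ids)])
  # steady state over v = pos - neg
  St <- as(model$S, "TsparseMatrix")
  met_rows <- split(data.frame(j = St@j + 1L, x = St@x), St@i + 1L)
  cons <- lapply(met_rows, function(d)
    setNames(c(d$x, -d$x), c(paste0("pos.", ids[d$j]),
                             paste0("neg.", ids[d$j]))))
  p <- lmp_add_constraints(p, cons, "==", 0)
  # deviation variables per target entry
  for (e in seq_len(nrow(tg))) {
    dn <- paste0("dev.", e)
    r <- tg$id[e]
    p <- lmp_add_variables(p, dn, lb = 0, obj = tg$weight[e])
    p <- lmp_add_constraints(p, setNames(c(1, -1, -1),
                                         c(dn, paste0("pos.", r),
                                           paste0("neg.", r))),
                             ">=", -tg$target[e])
    p <- lmp_add_constraints(p, setNames(c(1, 1, 1),
                                         c(dn, paste0("pos.", r),
                                           paste0("neg.", r))),
                             ">=", tg$target[e])
  }

  cuts <- list()
  iter <- 0L
  big_m <- max(abs(c(lb, ub))) + 1
  repeat {
    sol <- solve_lmp(p, tolerance = tolerance)
    if (sol$status == "infeasible")
      stop("flux fit infeasible after ", length(cuts),
           " cycle cut(s); last cut: ",
           if (length(cuts)) paste(cuts[[length(cuts)]]$reactions,
                                   collapse = ", ") else "none")
    if (!sol$status %in% c("optimal", "feasible"))
      stop("flux fit failed with solver status: ", sol$status)
    v <- sol$solution[paste0("pos.", ids)] - sol$solution[paste0("neg.", ids)]
    names(v) <- ids
    if (iter >= max_iter) break
    cut <- detect_min_cycle(model, v, threshold = support_threshold,
                            tolerance = tolerance)
    if (is.null(cut)) break
    iter <- iter + 1L
    cuts[[iter]] <- cut
    # forbid the cycle: at least one member's directional flux must drop
    # (strictly) below the support threshold
    anames <- paste0("cut", iter, ".", cut$reactions)
    p <- lmp_add_variables(p, anames, type = "binary", lb = 0, ub = 1)
    for (m in seq_along(cut$reactions)) {
      r <- cut$reactions[m]
      side <- if (cut$directions[m] > 0) "pos." else "neg."
      p <- lmp_add_constraints(
        p, setNames(c(1, -big_m), c(paste0(side, r), anames[m])),
        "<=", support_threshold - 10 * tolerance)
    }
    p <- lmp_add_constraints(p, setNames(rep(1, length(anames)), anames),
                             "<=", cut$k - 1)
  }
  internal <- ids[!model$reactions$exchange & ids != model$biomass]
  structure(list(phenotype = phenotype, fluxes = v,
                 objective = sol$objective,
                 support = internal[abs(v[internal]) >= support_threshold],
                 cuts = cuts, iterations = iter,
                 biomass_flux = unname(v[model$biomass]),
                 targets = tg),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf(
    "Flux fit (%s): deviation %.4f, biomass %.4f, %d cycle cut(s) in %d iteration(s)\n",
    x$phenotype, x$objective, x$biomass_flux, length(x$cuts), x$iterations))
  invisible(x)
}

#' @export
summary.flux_fit <- function(object, ...) {
  cat(sprintf("Flux fit for phenotype %s\n", object$phenotype))
  cat(sprintf("  deviation objective: %.6f\n", object$objective))
  cat(sprintf("  biomass flux: %.6f\n", object$biomass_flux))
  cat(sprintf("  support size: %d\n", length(object$support)))
  if (length(object$cuts)) {
    cat("  cycle cuts:\n")
    for (ct in object$cuts)
      cat("   ", paste0(ifelse(ct$directions > 0, "+", "-"), ct$reactions,
                        collapse = " "), "\n")
  }
  invisible(object)
}

#' @export
coef.flux_fit <- function(object, ...) object$fluxes

#' Differential flux between two conditions, in percent
#'
#' 0 when the absolute fluxes agree, 100 when flux is present in exactly one
#' condition, otherwise the relative difference of the absolute fluxes
#' `| |v1| - |v2| | / max(|v1|, |v2|) * 100`. Two zero fluxes give 0 by
#' convention.
#'
#' @param v1,v2 Flux values (vectorized).
#' @return Differential flux percentage(s) in `[0, 100]`.
#' @export
differential_flux_percent <- function(v1, v2) {
  a1 <- abs(v1); a2 <- abs(v2)
  m <- pmax(a1, a2)
  ifelse(m == 0, 0, abs(a1 - a2) / m * 100)
}
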
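#' Linear / mixed-integer program container
#'
#' `lmp()` creates an empty program; variables and constraints are added with
#' [lmp_add_variables()] and [lmp_add_constraints()], and the program is solved
#' with [solve_lmp()]. The container is deliberately solver-agnostic: it stores
#' variables (with bounds and a continuous/binary kind), linear constraints in
#' triplet form, and a linear objective. All higher-level models in the package
#' (stable-set selection, flux fitting, cycle detection, regulatory-network
#' regression) are expressed through this one interface.
#'
#' Variable order is insertion order and the backend is deterministic, so
#' degenerate optima are reproduced identically across runs.
#'
#' @param sense `"min"` or `"max"`.
#' @return An object of class `lmp`.
#' @examples
#' p <- lmp("min")
#' p <- lmp_add_variables(p, "x", lb = 3)
#' p <- lmp_set_objective(p, c(x = 1))
#' solve_lmp(p)$objective  # 3
#' @export
lmp <- function(sense = c("min", "max")) {
  sense <- match.arg(sense)
  structure(list(
    sense = sense,
    name = character(), type = character(),
    lb = numeric(), ub = numeric(), obj = numeric(),
    con_names = list(), con_coefs = list(),
    dir = character(), rhs = numeric()
  ), class = "lmp")
}

#' Add variables to a program
#'
#' @param program An [lmp()] object.
#' @param name Character vector of new, unique variable names.
#' @param type `"continuous"` or `"binary"` (recycled).
#' @param lb,ub Bounds (recycled). Binary variables must keep their bounds
#'   within `[0, 1]`.
#' @param obj Objective coefficient (recycled, default 0).
#' @return The modified program.
#' @export
lmp_add_variables <- function(program, name, type = "continuous",
                              lb = -Inf, ub = Inf, obj = 0) {
  stopifnot(inherits(program, "lmp"))
  n <- length(name)
  if (anyDuplicated(name) || any(name %in% program$name))
    stop("duplicate variable name")
  type <- rep_len(type, n)
  if (!all(type %in% c("continuous", "binary")))
    stop("variable type must be 'continuous' or 'binary'")
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub)) stop("variable lower bound exceeds upper bound")
  bin <- type == "binary"
  if (any(bin & (lb < 0 | ub > 1)))
    stop("binary variables must have bounds within [0, 1]")
  program$name <- c(program$name, name)
  program$type <- c(program$type, type)
  program$lb <- c(program$lb, lb)
  program$ub <- c(program$ub, ub)
  program$obj <- c(program$obj, rep_len(as.numeric(obj), n))
  program
}

#' Add linear constraints to a program
#'
#' @param program An [lmp()] object.
#' @param coefs A named numeric vector (single constraint) or a list of them.
#'   Every name must be a declared variable.
#' @param dir Relation per constraint: `"<="`, `"=="` or `">="`.
#' @param rhs Right-hand side per constraint.
#' @return The modified program.
#' @export
lmp_add_constraints <- function(program, coefs, dir, rhs) {
  stopifnot(inherits(program, "lmp"))
  if (!is.list(coefs)) coefs <- list(coefs)
  if (!all(dir %in% c("<=", "==", ">=")))
    stop("constraint relation must be one of <=, ==, >=")
  n <- length(coefs)
  dir <- rep_len(dir, n)
  rhs <- rep_len(as.numeric(rhs), n)
  program$con_names <- c(program$con_names, lapply(coefs, names))
  program$con_coefs <- c(program$con_coefs, lapply(coefs, unname))
  program$dir <- c(program$dir, dir)
  program$rhs <- c(program$rhs, rhs)
  program
}

#' Set the objective coefficients of a program
#'
#' Unmentioned variables keep coefficient 0.
#'
#' @inheritParams lmp_add_constraints
#' @param coefs Named numeric vector of objective coefficients.
#' @return The modified program.
#' @export
lmp_set_objective <- function(program, coefs) {
  stopifnot(inherits(program, "lmp"))
  idx <- match(names(coefs), program$name)
  if (anyNA(idx)) stop("objective references undeclared variable: ",
                       paste(names(coefs)[is.na(idx)], collapse = ", "))
  program$obj[idx] <- as.numeric(coefs)
  program
}

# Flatten the named-coefficient constraint store into triplet form, validating
# that every coefficient references a declared variable.
lmp_triplets <- function(program) {
  nm <- unlist(program$con_names, use.names = FALSE)
  ja <- match(nm, program$name)
  if (anyNA(ja))
    stop("constraint references undeclared variable: ",
         paste(unique(nm[is.na(ja)]), collapse = ", "))
  lens <- lengths(program$con_coefs)
  list(ia = rep.int(seq_along(lens), lens), ja = ja,
       ar = unlist(program$con_coefs, use.names = FALSE))
}

#' Solve a linear or mixed-integer program
#'
#' Dispatches to the GLPK simplex method for pure LPs and to GLPK's
#' branch-and-cut for programs with binary variables. The backend is
#' deterministic; `seed` is accepted so that callers can treat the solver like
#' other seeded components, but it does not influence the result.
#'
#' @param program An [lmp()] object.
#' @param seed Integer, kept for interface uniformity (the backend is
#'   deterministic).
#' @param tolerance Feasibility/integrality tolerance (default `1e-6`).
#' @param time_limit Wall-clock limit in seconds (default none). If the limit
#'   stops the search with an incumbent, the status is `"feasible"`.
#' @return A list of class `lmp_solution` with elements `status`
#'   (`"optimal"`, `"feasible"`, `"infeasible"`, `"unbounded"` or `"error"`),
#'   `objective`, and `solution` (named numeric vector, present only when a
#'   solution was found).
#' @export
solve_lmp <- function(program, seed = 1L, tolerance = 1e-6, time_limit = Inf) {
  stopifnot(inherits(program, "lmp"))
  if (length(program$name) == 0L) stop("program has no variables")
  tr <- lmp_triplets(program)
  kind <- as.integer(program$type == "binary")
  res <- .Call(C_glpk_solve,
               if (program$sense == "min") 1L else -1L,
               as.numeric(program$obj),
               as.numeric(program$lb), as.numeric(program$ub), kind,
               as.integer(tr$ia), as.integer(tr$ja), as.numeric(tr$ar),
               match(program$dir, c("<=", "==", ">=")),
               as.numeric(program$rhs),
               as.numeric(tolerance),
               if (is.finite(time_limit)) time_limit * 1000 else Inf)
  if (!is.null(res$solution)) names(res$solution) <- program$name
  res$seed <- as.integer(seed)
  class(res) <- "lmp_solution"
  res
}

#' Export a program in CPLEX LP format (debugging aid)
#'
#' @inheritParams solve_lmp
#' @param path Output file path.
#' @return `TRUE` invisibly on success.
#' @export
write_lp <- function(program, path) {
  stopifnot(inherits(program, "lmp"))
  tr <- lmp_triplets(program)
  ok <- .Call(C_glpk_write_lp,
              if (program$sense == "min") 1L else -1L,
              as.numeric(program$obj),
              as.numeric(program$lb), as.numeric(program$ub),
              as.integer(program$type == "binary"),
              as.integer(tr$ia), as.integer(tr$ja), as.numeric(tr$ar),
              match(program$dir, c("<=", "==", ">=")),
              as.numeric(program$rhs), program$name, path.expand(path))
  if (!ok) stop("failed to write LP file: ", path)
  invisible(TRUE)
}

#' @export
print.lmp <- function(x, ...) {
  cat(sprintf("Linear mixed program (%s): %d variables (%d binary), %d constraints\n",
              x$sense, length(x$name), sum(x$type == "binary"), length(x$rhs)))
  invisible(x)
}

#' @export
print.lmp_solution <- function(x, ...) {
  cat("Solver status:", x$status, "\n")
  if (x$status %in% c("optimal", "feasible"))
    cat("Objective:", format(x$objective), "\n")
  invisible(x)
}
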
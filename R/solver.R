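INF <- 1e30

#' Construct an LP/MILP problem container
#'
#' A lightweight description of a (mixed-integer) linear program:
#' column bounds, 0/1 integrality flags, and a sparse constraint matrix
#' in triplet form with per-row lower/upper bounds.  Objectives are not
#' part of the container; they are supplied to [solve_lp()] as staged or
#' batched query objectives.
#'
#' @param ncol number of columns (variables).
#' @param lb,ub numeric column bounds (use `Inf`/`-Inf` for free).
#' @param integrality integer 0/1 vector; 1 marks an integer variable.
#' @param vnames optional character vector of variable names.
#' @return an object of class `"lp_problem"`.
#' @export
lp_problem <- function(ncol, lb = rep(0, ncol), ub = rep(Inf, ncol),
                       integrality = rep(0L, ncol), vnames = NULL) {
  stopifnot(length(lb) == ncol, length(ub) == ncol, length(integrality) == ncol)
  structure(list(
    ncol = as.integer(ncol), lb = as.numeric(lb), ub = as.numeric(ub),
    integrality = as.integer(integrality),
    vnames = vnames,
    ai = integer(0), aj = integer(0), ax = numeric(0),
    nrow = 0L, rlb = numeric(0), rub = numeric(0), rnames = character(0)
  ), class = "lp_problem")
}

#' Append constraint rows to an LP problem
#'
#' @param prob an [lp_problem()].
#' @param ind list of integer index vectors (one per row).
#' @param val list of numeric coefficient vectors (one per row).
#' @param rlb,rub row bounds (recycled).
#' @param names optional row names.
#' @return the updated problem.
#' @export
lp_add_rows <- function(prob, ind, val, rlb, rub, names = NULL) {
  stopifnot(inherits(prob, "lp_problem"), length(ind) == length(val))
  n <- length(ind)
  if (n == 0L) return(prob)
  rlb <- rep_len(as.numeric(rlb), n)
  rub <- rep_len(as.numeric(rub), n)
  lens <- lengths(ind)
  rows <- rep(prob$nrow + seq_len(n), lens)
  prob$ai <- c(prob$ai, rows)
  prob$aj <- c(prob$aj, unlist(ind, use.names = FALSE))
  prob$ax <- c(prob$ax, unlist(val, use.names = FALSE))
  prob$nrow <- prob$nrow + as.integer(n)
  prob$rlb <- c(prob$rlb, rlb)
  prob$rub <- c(prob$rub, rub)
  prob$rnames <- c(prob$rnames, if (is.null(names)) rep("", n) else names)
  prob
}

#' Define a linear objective over a subset of variables
#'
#' @param ind integer variable indices.
#' @param val coefficients.
#' @param sense `"min"` or `"max"`.
#' @param fix for staged objectives: append the achieved optimum as a
#'   constraint before subsequent solves (lexicographic optimization).
#' @param tol absolute slack used when fixing the optimum.
#' @return a list describing the objective.
#' @export
lp_objective <- function(ind, val, sense = c("min", "max"), fix = FALSE,
                         tol = 1e-9) {
  sense <- match.arg(sense)
  list(ind = as.integer(ind), val = as.numeric(val), sense = sense,
       fix = isTRUE(fix), tol = tol)
}

.encode_inf <- function(x) {
  x[x == Inf] <- INF
  x[x == -Inf] <- -INF
  x
}

.python_bin <- function() {
  p <- Sys.getenv("THERMOFLUX_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no python interpreter found for the MILP backend")
  unname(p)
}

.bridge_script <- function() {
  s <- system.file("python", "milp_batch.py", package = "thermoflux")
  if (!nzchar(s)) stop("milp_batch.py not found; is the package installed?")
  s
}

.problem_payload <- function(prob, stages, queries) {
  list(
    ncol = prob$ncol,
    lb = .encode_inf(prob$lb), ub = .encode_inf(prob$ub),
    integrality = prob$integrality,
    A = list(i = prob$ai, j = prob$aj, x = prob$ax, nrow = prob$nrow),
    rlb = .encode_inf(prob$rlb), rub = .encode_inf(prob$rub),
    stages = lapply(stages, function(s) s[c("ind", "val", "sense", "fix", "tol")]),
    queries = lapply(queries, function(q) q[c("ind", "val", "sense")])
  )
}

#' Solve a batch of LP/MILP jobs through the HiGHS backend
#'
#' Each job is a list with elements `problem` (an [lp_problem()]),
#' `stages` (list of [lp_objective()]s applied lexicographically) and
#' `queries` (list of objectives solved independently under the final
#' constraint set).  All jobs in the batch are dispatched in a single
#' backend invocation.
#'
#' @param jobs list of jobs.
#' @return list (one element per job) with `stages` and `queries`, each a
#'   list of results holding `status`, `objective` and the solution
#'   vector `x` when the solve was optimal.
#' @export
solve_lp <- function(jobs) {
  stopifnot(is.list(jobs), length(jobs) >= 1)
  payload <- list(problems = lapply(jobs, function(j) {
    .problem_payload(j$problem,
                     if (is.null(j$stages)) list() else j$stages,
                     if (is.null(j$queries)) list() else j$queries)
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  st <- system2(.python_bin(), c(.bridge_script(), fin, fout),
                stdout = TRUE, stderr = TRUE)
  code <- attr(st, "status")
  if (!is.null(code) && code != 0) {
    stop("MILP backend failed:\n", paste(st, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  res$problems
}

#' Solve a single problem (convenience wrapper around [solve_lp()])
#' @param problem an [lp_problem()].
#' @inheritParams solve_lp
#' @param stages,queries objective lists, see [solve_lp()].
#' @return the single job's result list.
#' @export
solve_lp1 <- function(problem, stages = list(), queries = list()) {
  solve_lp(list(list(problem = problem, stages = stages, queries = queries)))[[1]]
}
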
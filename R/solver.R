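#' Construct a box-constrained labeling problem
#'
#' Bundles a similarity matrix with two disjoint, nonempty seed sets: set A
#' (Class Zero, labels fixed at 0) and set B (Class One, labels fixed at
#' 1).  The model then minimizes `1/2 * sum_ij s_ij (f_i - f_j)^2` over
#' continuous labels `f` in `[0, 1]^N` subject to those seed constraints.
#' Without both seed sets the minimizer is the meaningless constant
#' labeling, so empty seeds are rejected at construction.
#'
#' Non-negative similarities make the objective convex (the Laplacian is
#' positive semi-definite).  `clip = "strict"` (the default for curated
#' unit-scale input) rejects negative entries; `clip = "permissive"` clips
#' them to zero with a logged count, which is the standard route for raw
#' Pearson and noisy simulated similarities; `clip = "unit"` applies the
#' `(s + 1) / 2` map instead of clipping.
#'
#' @param sim an [similarity_matrix()].
#' @param set_a,set_b seed indices (1-based) or sample ids; disjoint and
#'   nonempty.
#' @param clip negative-similarity policy, see Details.
#' @return object of class `otcc_problem` with the solver matrix in
#'   `$values` and seed index vectors `$set_a`, `$set_b`.
#' @export
label_problem <- function(sim, set_a, set_b,
                          clip = c("strict", "permissive", "unit")) {
  stopifnot(inherits(sim, "otcc_similarity"))
  clip <- match.arg(clip)
  n <- length(sim$sample_ids)
  as_idx <- function(x, what) {
    if (is.character(x)) {
      i <- match(x, sim$sample_ids)
      if (anyNA(i)) abort("unknown sample id(s) in ", what, ": ",
                          paste(x[is.na(i)], collapse = ", "))
      i
    } else {
      i <- as.integer(x)
      if (any(i < 1L | i > n)) abort(what, " indices out of range 1..", n)
      i
    }
  }
  a <- sort(unique(as_idx(set_a, "set_a")))
  b <- sort(unique(as_idx(set_b, "set_b")))
  if (length(a) == 0L || length(b) == 0L)
    abort("both seed sets must be nonempty; with an empty side the model ",
          "collapses to the trivial constant labeling")
  if (length(intersect(a, b)))
    abort("seed sets intersect (samples ",
          paste(sim$sample_ids[intersect(a, b)], collapse = ", "),
          "); a sample cannot carry both labels")
  structure(list(values = solver_values(sim, clip), sample_ids = sim$sample_ids,
                 set_a = a, set_b = b, clip = clip),
            class = "otcc_problem")
}

#' @export
print.otcc_problem <- function(x, ...) {
  cat(sprintf("<otcc_problem> %d samples, |A| = %d, |B| = %d, clip = %s\n",
              length(x$sample_ids), length(x$set_a), length(x$set_b), x$clip))
  invisible(x)
}

#' Graph Laplacian of a similarity matrix
#'
#' Returns `L = D - S` where `D = diag(rowSums(S))`.  The model objective
#' is the quadratic form `f' L f`; for non-negative `S`, `L` is positive
#' semi-definite, which is what makes the labeling problem convex.  Row
#' sums of `L` are exactly zero by construction.
#'
#' @param sim an `otcc_similarity` or a plain symmetric matrix.
#' @return the N x N Laplacian matrix.
#' @export
build_laplacian <- function(sim) {
  v <- if (inherits(sim, "otcc_similarity")) sim$values else sim
  check_symmetric(v, tol = 1e-8, what = "similarity matrix")
  L <- -v
  diag(L) <- diag(L) + rowSums(v)
  L
}

new_solution <- function(f, sample_ids, set_a, set_b, iterations, converged,
                         residual, objective, method,
                         objective_trace = NULL, degenerate = FALSE) {
  names(f) <- sample_ids
  structure(list(f = f, set_a = set_a, set_b = set_b,
                 iterations = iterations, converged = converged,
                 residual = residual, objective = objective,
                 objective_trace = objective_trace,
                 degenerate = degenerate, method = method),
            class = "otcc_solution")
}

#' @export
print.otcc_solution <- function(x, ...) {
  cat(sprintf(
    "<otcc_solution> %d labels (%s), %d iterations, converged = %s,\n  residual = %.3g, objective = %.6g\n",
    length(x$f), x$method, x$iterations, x$converged, x$residual, x$objective))
  invisible(x)
}

objective_value <- function(S, f) {
  # 1/2 sum_ij s_ij (f_i - f_j)^2 == f' L f
  d <- rowSums(S)
  sum(d * f * f) - drop(crossprod(f, S %*% f))
}

#' Fixed-point solver for the labeling model
#'
#' The customized iterative algorithm: initialize every unlabeled node at
#' 0 (seeds at their fixed 0/1 values), then repeat the synchronous sweep
#' `f_i <- sum_j s_ij f_j / sum_j s_ij` over unlabeled nodes until the
#' max-norm change of the iterate drops below `tol` or `max_iter` sweeps
#' have run.  At convergence each unlabeled label equals the
#' similarity-weighted average of all labels -- the harmonic / KKT fixed
#' point of the quadratic model.
#'
#' Properties the implementation relies on (and the test-suite checks):
#' iterates are convex combinations of values in `[0, 1]`, so no clamping
#' is ever needed; the constrained objective is non-increasing along the
#' iterate sequence; diagonal entries `s_ii` are kept in the row sums,
#' which damps the sweep without moving the fixed point.  An unlabeled
#' node with zero row sum (no similarity to anything) is never updated and
#' keeps its initial value 0 -- the same convention that makes nodes
#' disconnected from both seeds fall into the Class-Zero side as a
#' "pseudo-cluster", to be resolved by further recursion during class
#' discovery.
#'
#' @param problem an [label_problem()].
#' @param tol stopping threshold on `max_i |f_i^t - f_i^(t-1)|`.
#' @param max_iter sweep cap; hitting it yields `converged = FALSE` plus a
#'   warning, never an error.
#' @param record_objective keep the per-sweep objective trajectory (used by
#'   the monotonicity tests); small overhead, on by default.
#' @return an `otcc_solution`: continuous labels `$f` in `[0, 1]` with
#'   seeds exact, iteration count, convergence flag, final residual and
#'   objective.
#' @export
solve_iterative <- function(problem, tol = 1e-6, max_iter = 10000L,
                            record_objective = TRUE) {
  stopifnot(inherits(problem, "otcc_problem"))
  if (!is_number(tol) || tol <= 0) abort("tol must be > 0")
  S <- problem$values
  n <- nrow(S)
  f <- numeric(n)
  f[problem$set_b] <- 1
  u <- setdiff(seq_len(n), c(problem$set_a, problem$set_b))
  rs <- rowSums(S)
  upd <- u[rs[u] > 0]          # zero-row-sum nodes stay at their init 0
  Su <- S[upd, , drop = FALSE]
  rsu <- rs[upd]
  trace <- if (record_objective) objective_value(S, f) else NULL
  it <- 0L
  resid <- Inf
  while (length(upd) > 0L && it < max_iter) {
    fn <- f
    fn[upd] <- as.vector(Su %*% f) / rsu
    resid <- max(abs(fn - f))
    f <- fn
    it <- it + 1L
    if (record_objective) trace <- c(trace, objective_value(S, f))
    if (resid < tol) break
  }
  if (length(upd) == 0L) resid <- 0
  converged <- resid < tol
  if (!converged)
    warning("fixed-point iteration stopped at max_iter = ", max_iter,
            " with residual ", format(resid, digits = 4), call. = FALSE)
  new_solution(f, problem$sample_ids, problem$set_a, problem$set_b,
               iterations = it, converged = converged, residual = resid,
               objective = objective_value(S, f), method = "iterative",
               objective_trace = trace)
}

# Nodes reachable from `seeds` through strictly positive off-diagonal
# similarities; anything unreachable cannot feel the boundary conditions.
reachable_from <- function(S, seeds) {
  n <- nrow(S)
  seen <- logical(n)
  seen[seeds] <- TRUE
  frontier <- seeds
  A <- S > 0
  diag(A) <- FALSE
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Exact harmonic solution (linear-system oracle)
#'
#' Solves the KKT system of the labeling model directly: for the unlabeled
#' index set `U`, `(D_UU - S_UU) f_U = S_UB 1`, i.e. the harmonic
#' extension of the boundary labels.  This is the independent witness used
#' to verify the fixed-point solver; it is exact up to linear-algebra
#' round-off, with tiny excursions clamped back into `[0, 1]`.
#'
#' Unlabeled nodes with no positive-similarity path to any seed make the
#' system singular; they are detected by graph reachability, assigned the
#' minimum-norm value 0 (matching the iterative solver's initialization
#' convention), and flagged via `$degenerate`.
#'
#' @param problem an [label_problem()].
#' @return an `otcc_solution` with `method = "exact"`.
#' @export
solve_exact <- function(problem) {
  stopifnot(inherits(problem, "otcc_problem"))
  S <- problem$values
  n <- nrow(S)
  a <- problem$set_a
  b <- problem$set_b
  u <- setdiff(seq_len(n), c(a, b))
  f <- numeric(n)
  f[b] <- 1
  seen <- reachable_from(S, c(a, b))
  ur <- u[seen[u]]
  degenerate <- length(ur) < length(u)
  if (length(ur)) {
    rs <- rowSums(S)
    M <- diag(rs[ur], nrow = length(ur)) - S[ur, ur, drop = FALSE]
    rhs <- rowSums(S[ur, b, drop = FALSE])
    f[ur] <- solve(M, rhs)
  }
  f <- pmin(pmax(f, 0), 1)
  # fixed-point residual over updatable unlabeled nodes
  rs <- rowSums(S)
  upd <- u[rs[u] > 0]
  resid <- if (length(upd))
    max(abs(f[upd] - as.vector(S[upd, , drop = FALSE] %*% f) / rs[upd]))
  else 0
  new_solution(f, problem$sample_ids, a, b, iterations = 0L,
               converged = TRUE, residual = resid,
               objective = objective_value(S, f), method = "exact",
               degenerate = degenerate)
}

#' Threshold continuous labels into binary class calls
#'
#' Labels live on `[0, 1]` with Class Zero at 0 and Class One at 1, so the
#' midpoint 0.5 is the natural cutoff; a data-driven cutoff learned by
#' cross-validation (see [learn_cutoff()]) can replace it.  The tie
#' `f = cutoff` goes to Class One -- the cutoff itself is arbitrary on a
#' continuum, but the rule must be deterministic and documented.
#'
#' @param solution an `otcc_solution` (or a bare numeric vector in
#'   `[0, 1]`).
#' @param cutoff decision threshold, strictly inside (0, 1).
#' @return integer vector of 0/1 calls, named like the labels.
#' @export
binarize <- function(solution, cutoff = 0.5) {
  f <- if (inherits(solution, "otcc_solution")) solution$f else solution
  if (!is_number(cutoff) || cutoff <= 0 || cutoff >= 1)
    abort("cutoff must lie strictly inside (0, 1)")
  out <- as.integer(f >= cutoff)
  names(out) <- names(f)
  out
}
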
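# Interface to the bundled HiGHS worker (inst/python/milp_worker.py).
# Problems are exchanged as JSON through temporary files; many LP/MILP
# instances are batched per worker invocation to amortize interpreter
# start-up.  All solving is delegated to HiGHS (via scipy.optimize.milp);
# everything upstream of the matrices and downstream of the solution vectors
# lives in R.

.INF <- 1e30  # sentinel for +/- infinity in the JSON protocol

#' Locate the Python interpreter used for LP/MILP solving
#'
#' Honours `options(lumpnet.python = ...)`, then looks for `python3` and
#' `python` on the PATH.
#' @return Path to the interpreter.
#' @export
solver_python <- function() {
  opt <- getOption("lumpnet.python")
  if (!is.null(opt)) return(opt)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found; install Python with numpy+scipy ",
       "or set options(lumpnet.python = ...)")
}

#' @noRd
.worker_path <- function() {
  system.file("python", "milp_worker.py", package = "lumpnet",
              mustWork = TRUE)
}

#' @noRd
.finitize <- function(x) {
  x[x == Inf] <- .INF
  x[x == -Inf] <- -.INF
  x
}

# Build the JSON representation of a sparse constraint matrix (0-based).
#' @noRd
.matrix_spec <- function(A) {
  A <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  list(i = I(A@i), j = I(A@j), x = I(A@x),
       nrow = nrow(A), ncol = ncol(A))
}

#' Solve a list of LP/MILP problems with the bundled HiGHS worker
#'
#' Internal entry point.  Each problem is a list with fields `mode`
#' (`"batch"` or `"enumerate"`), `sense`, `c`, `A` (a sparse Matrix), row
#' bounds `rlb`/`rub`, variable bounds `lb`/`ub`, `integrality`, plus
#' mode-specific fields (`variants` for batch; `gate_idx`, `stop`,
#' `size_cap`, `max_count` for enumerate; all indices 1-based on the R side).
#'
#' @param problems List of problem lists.
#' @return List of result lists, one per problem.
#' @keywords internal
solve_problems <- function(problems) {
  payload <- list(problems = lapply(problems, function(p) {
    out <- list(
      mode = p$mode,
      sense = if (is.null(p$sense)) "min" else p$sense,
      c = I(.finitize(p$c)),
      A = .matrix_spec(p$A),
      rlb = I(.finitize(p$rlb)), rub = I(.finitize(p$rub)),
      lb = I(.finitize(p$lb)), ub = I(.finitize(p$ub)),
      integrality = I(as.integer(p$integrality)))
    if (p$mode == "batch") {
      out$variants <- lapply(p$variants, function(v) {
        vv <- list(bidx = I(as.integer(v$bidx %||% integer(0)) - 1L),
                   blb = I(.finitize(as.numeric(v$blb %||% numeric(0)))),
                   bub = I(.finitize(as.numeric(v$bub %||% numeric(0)))),
                   want_x = isTRUE(v$want_x))
        if (!is.null(v$c)) vv$c <- I(.finitize(v$c))
        if (!is.null(v$sense)) vv$sense <- v$sense
        vv
      })
    } else {
      out$gate_idx <- I(as.integer(p$gate_idx) - 1L)
      out$stop <- p$stop
      out$size_cap <- p$size_cap %||% -1L
      out$max_count <- p$max_count %||% 1000L
    }
    out
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(solver_python(), c(.worker_path(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("solver worker failed:\n", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  res$results
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Convenience: solve one problem with one variant and return the solution.
#' @noRd
solve_single <- function(p, want_x = TRUE) {
  p$mode <- "batch"
  p$variants <- list(list(want_x = want_x))
  solve_problems(list(p))[[1]]$solutions[[1]]
}
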
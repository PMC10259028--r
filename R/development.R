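# Development: the discrete-time dynamical system turning a regulatory
# genotype into an expression-profile phenotype.

#' Thresholded rectifier
#'
#' Per-gene rectifier: values strictly below the gene's activation threshold
#' are zeroed; values at or above the threshold pass unchanged (a value
#' exactly equal to `theta` passes).
#'
#' @param v Numeric vector of incoming regulatory signals.
#' @param theta Nonnegative threshold vector of the same length.
#' @return Rectified vector.
#' @export
relu_theta <- function(v, theta) {
  stopifnot(length(v) == length(theta))
  v * (v >= theta)
}

#' Develop an organism: run the gene-expression dynamics
#'
#' Starting from the seed state `q0 = (seed_quantity, 0, ..., 0)` — gene 1
#' kick-starts development — iterates for `t = 1..m`:
#'
#'   `q_t = (relu_theta(R %*% q_{t-1}, theta) + q_{t-1} * exp(-lam)) * c`
#'
#' where `c` is the coding mask: genes with an in-frame stop codon have all
#' quantities multiplied by zero. The result is the expression matrix `E`
#' (genes x steps), the phenotype on which fitness is scored. The map is
#' deterministic.
#'
#' If quantities overflow to non-finite values the run is flagged as runaway
#' (attribute `runaway`); such organisms receive the worst boundedness score
#' rather than crashing the simulation.
#'
#' @param mask Coding mask from [coding_mask()] (0/1 vector of length n).
#' @param params `grnevo_regparams`.
#' @param m Number of developmental steps (>= 1).
#' @param seed_quantity Initial quantity of gene 1 (default 1, arbitrary
#'   units).
#' @return An n x m matrix of class `grnevo_expression` with gene quantities;
#'   attribute `q0` holds the seed vector, attribute `runaway` flags
#'   numerical overflow.
#' @export
develop <- function(mask, params, m, seed_quantity = 1) {
  n <- length(params$theta)
  stopifnot(m >= 1, length(mask) == n)
  if (!all(is.finite(params$R)) || !all(is.finite(params$theta)) ||
      !all(is.finite(params$lam))) {
    stop("non-finite regulatory parameters: invalid organism", call. = FALSE)
  }
  q <- c(seed_quantity, rep(0, n - 1))
  decay <- exp(-params$lam)
  E <- matrix(0, n, m)
  runaway <- FALSE
  for (t in seq_len(m)) {
    s <- as.vector(params$R %*% q)
    q <- (s * (s >= params$theta) + q * decay) * mask
    if (anyNA(q) || any(is.infinite(q))) {
      runaway <- TRUE
      E[, t:m] <- NA_real_
      break
    }
    E[, t] <- q
  }
  structure(E,
            q0 = c(seed_quantity, rep(0, n - 1)),
            runaway = runaway,
            class = c("grnevo_expression", "matrix", "array"))
}

#' Is a gene expressed in an expression matrix?
#'
#' A gene is expressed when its quantity is positive at any developmental
#' step. The seed gene (gene 1) always counts as expressed — it is injected
#' with the seed quantity before the coding mask first applies, so it
#' kick-starts development even when its own sequence carries a stop codon.
#'
#' @param E Expression matrix from [develop()].
#' @param i 1-based gene index.
#' @return Logical scalar.
#' @export
is_expressed <- function(E, i) {
  if (i == 1L) return(TRUE)
  row <- E[i, ]
  any(row > 0, na.rm = TRUE)
}

#' @export
print.grnevo_expression <- function(x, ...) {
  cat("Expression matrix:", nrow(x), "genes x", ncol(x), "steps\n")
  if (isTRUE(attr(x, "runaway"))) cat("  [runaway growth: overflowed]\n")
  expressed <- vapply(seq_len(nrow(x)), function(i) is_expressed(x, i),
                      logical(1))
  cat("  expressed genes:", paste(which(expressed), collapse = ", "), "\n")
  invisible(x)
}

#' Export an expression matrix as delimited text
#'
#' Genes as rows, developmental steps as columns, header row of step
#' indices.
#'
#' @param E Expression matrix.
#' @param path Output file path.
#' @export
write_expression <- function(E, path) {
  m <- ncol(E)
  df <- as.data.frame(unclass(E))
  names(df) <- paste0("t", seq_len(m))
  rownames(df) <- paste0("gene", seq_len(nrow(E)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
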
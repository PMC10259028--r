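# Shared builders for small test organisms and populations.

tiny_params <- function(n = 3, l = 30, m = 10, mu = 1e-3, N = 10, p = 0.2,
                        strategy = "high_pressure", ...) {
  sim_params(n = n, l = l, m = m, mu = mu, N = N, p = p,
             strategy = strategy, ...)
}

# a 1-gene regulatory parameter set with explicit values
reg1 <- function(R = 0, theta = 0, lam = 0) {
  structure(list(R = matrix(R, 1, 1), theta = theta, lam = lam),
            class = "grnevo_regparams")
}

regn <- function(R, theta, lam) {
  structure(list(R = R, theta = theta, lam = lam),
            class = "grnevo_regparams")
}

# an expression matrix with given rows (genes x steps)
expr_mat <- function(...) {
  E <- rbind(...)
  structure(E, q0 = c(1, rep(0, nrow(E) - 1)), runaway = FALSE,
            class = c("grnevo_expression", "matrix", "array"))
}

# all single-step codon neighbours of a codon
codon_neighbours <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character()
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      nc <- codon
      substr(nc, pos, pos) <- b
      out <- c(out, nc)
    }
  }
  out
}
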
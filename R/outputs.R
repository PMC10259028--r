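# On-disk artifacts of a phylogeny run: per-gene FASTA alignments across
# tips, per-branch traces and parameter dumps, a checksummed manifest and a
# replayable log.

#' Write all outputs of a phylogeny run
#'
#' Produces, under `out_dir`:
#' * `gene<i>.fasta` — one FASTA per gene, one record per tip (record id =
#'   tip label). All sequences are equal length with no indels, so each
#'   file is a ready-made alignment.
#' * `branch_<id>/trace.tsv`, `branch_<id>/participation.tsv`,
#'   `branch_<id>/regparams.txt` — per-branch fitness trace, final
#'   per-gene participation, and (for tip branches) the representative
#'   organism's regulatory parameters.
#' * `config.txt`, `run_log.txt` — the effective configuration and master
#'   seed, echoed for exact replay.
#' * `manifest.txt` — every written file with its MD5 checksum.
#'
#' @param run `grnevo_run` from [run_phylogeny()].
#' @param cfg `grnevo_config` (or `NULL` to skip the config echo).
#' @param out_dir Output directory (created if absent).
#' @return Tibble manifest (file, md5), invisibly.
#' @export
write_outputs <- function(run, cfg, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  written <- character()
  n <- length(run$tips[[1]]$sequences)
  labs <- names(run$tips)
  for (g in seq_len(n)) {
    seqs <- Biostrings::DNAStringSet(
      vapply(run$tips, function(lr) lr$sequences[g], character(1)))
    names(seqs) <- labs
    f <- file.path(out_dir, sprintf("gene%d.fasta", g))
    Biostrings::writeXStringSet(seqs, f)
    written <- c(written, f)
  }
  for (bid in names(run$traces)) {
    bdir <- file.path(out_dir, paste0("branch_", gsub("\\|", "+", bid)))
    dir.create(bdir, showWarnings = FALSE)
    f <- file.path(bdir, "trace.tsv")
    utils::write.table(run$traces[[bid]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
    if (bid %in% labs) {
      lr <- run$tips[[bid]]
      f <- file.path(bdir, "participation.tsv")
      utils::write.table(
        data.frame(gene = seq_along(lr$participation),
                   participation = lr$participation),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
      f <- file.path(bdir, "regparams.txt")
      write_regparams(lr$reg, f, run$params$reg)
      written <- c(written, f)
    }
  }
  if (!is.null(cfg)) {
    f <- file.path(out_dir, "config.txt")
    save_config(cfg, f)
    written <- c(written, f)
  }
  f <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste("master_seed:", run$master_seed),
    paste("tips:", paste(labs, collapse = ", ")),
    paste("total_generations:", sum(run$plan$generations)),
    paste("branch_seeds:",
          paste(vapply(run$plan$branch_ids, function(b)
            paste0(b, "=", derive_seed(run$master_seed, b)), character(1)),
            collapse = "; "))
  ), f)
  written <- c(written, f)
  md5 <- tools::md5sum(written)
  manifest <- tibble::tibble(file = basename(names(md5)),
                             path = names(md5), md5 = unname(md5))
  utils::write.table(manifest[, c("file", "md5")],
                     file.path(out_dir, "manifest.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Dump regulatory parameters as delimited text
#'
#' One matrix block followed by the threshold and decay vectors, headed by
#' the gene count and sampling ranges.
#'
#' @param reg `grnevo_regparams`.
#' @param path Output path.
#' @param cfg The [reg_config()] used (recorded in the header), or `NULL`.
#' @export
write_regparams <- function(reg, path, cfg = NULL) {
  n <- length(reg$theta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# n =", n), con)
  if (!is.null(cfg)) {
    writeLines(c(
      paste("# value_range =", paste(cfg$value_range, collapse = " ")),
      paste("# theta_range =", paste(cfg$theta_range, collapse = " ")),
      paste("# lam_range =", paste(cfg$lam_range, collapse = " "))), con)
  }
  writeLines("R:", con)
  utils::write.table(reg$R, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(c("theta:", paste(sprintf("%.17g", reg$theta), collapse = "\t"),
               "lambda:", paste(sprintf("%.17g", reg$lam), collapse = "\t")),
             con)
  invisible(path)
}
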
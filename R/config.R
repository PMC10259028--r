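# Run configuration: flat key = value text files with optional per-branch
# override sections, validated against a typed schema.

.CONFIG_SCHEMA <- list(
  n = list(type = "int", default = 5L),
  l = list(type = "int", default = 3000L),
  m = list(type = "int", default = 20L),
  mu = list(type = "num", default = 5.33333e-6),
  N = list(type = "int", default = 100L),
  p = list(type = "num", default = 0.1),
  strategy = list(type = "chr", default = "high_pressure"),
  trace_every = list(type = "int", default = 100L),
  clonal_founders = list(type = "lgl", default = FALSE),
  value_min = list(type = "num", default = -2),
  value_max = list(type = "num", default = 2),
  sparseness = list(type = "num", default = 0.5),
  theta_min = list(type = "num", default = 0),
  theta_max = list(type = "num", default = 1),
  lam_min = list(type = "num", default = 0),
  lam_max = list(type = "num", default = 2),
  kernel = list(type = "chr", default = "resample"),
  marker_gene = list(type = "int", default = NA_integer_),
  maturity_threshold = list(type = "num", default = 0.5),
  stability_window = list(type = "int", default = NA_integer_),
  growth_cap = list(type = "num", default = 10),
  master_seed = list(type = "int", default = 1L),
  tree_file = list(type = "chr", default = NA_character_),
  out_dir = list(type = "chr", default = NA_character_)
)

# keys a per-branch override section may set
.BRANCH_KEYS <- c("mu", "p", "strategy", "N", "m")

.coerce_value <- function(key, raw) {
  spec <- .CONFIG_SCHEMA[[key]]
  switch(spec$type,
    int = {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v) || v != floor(v)) {
        stop("config key `", key, "`: expected an integer, got '", raw, "'",
             call. = FALSE)
      }
      as.integer(v)
    },
    num = {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) stop("config key `", key, "`: expected a number, got '",
                         raw, "'", call. = FALSE)
      v
    },
    lgl = {
      if (!raw %in% c("true", "false", "TRUE", "FALSE")) {
        stop("config key `", key, "`: expected true/false, got '", raw, "'",
             call. = FALSE)
      }
      raw %in% c("true", "TRUE")
    },
    chr = raw
  )
}

#' Load a run configuration file
#'
#' Reads a flat `key = value` text file (`#` starts a comment). Optional
#' sections headed `[branch <id>]` hold per-branch parameter overrides,
#' where `<id>` is a branch identifier as produced by
#' [parse_newick_generations()] (sorted tip labels joined with `|`);
#' branch sections may set `mu`, `p`, `strategy`, `N`, `m`. Unknown keys
#' and out-of-range values are rejected with a descriptive error; defaults
#' fill every omitted key and their provenance (file vs default) is
#' recorded in the `provenance` attribute.
#'
#' @param path Path to a configuration file.
#' @return Object of class `grnevo_config`: named list of settings plus an
#'   `overrides` element.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- lapply(.CONFIG_SCHEMA, `[[`, "default")
  provenance <- stats::setNames(rep("default", length(cfg)), names(cfg))
  overrides <- list()
  section <- NULL
  for (ln in lines) {
    sec <- regmatches(ln, regexec("^\\[branch +(.+)\\]$", ln))[[1]]
    if (length(sec) == 2L) {
      section <- trimws(sec[2])
      overrides[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z_]+) *= *(.+)$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: '", ln, "'",
                               call. = FALSE)
    key <- kv[2]; raw <- trimws(kv[3])
    if (is.null(section)) {
      if (!key %in% names(.CONFIG_SCHEMA)) {
        stop("unknown config key: `", key, "`", call. = FALSE)
      }
      cfg[[key]] <- .coerce_value(key, raw)
      provenance[[key]] <- "file"
    } else {
      if (!key %in% .BRANCH_KEYS) {
        stop("key `", key, "` is not allowed in a branch override section",
             call. = FALSE)
      }
      overrides[[section]][[key]] <- .coerce_value(key, raw)
    }
  }
  cfg$overrides <- overrides
  cfg <- structure(cfg, class = "grnevo_config", provenance = provenance)
  as_sim_params(cfg)  # range validation happens here; result discarded
  cfg
}

#' Write a configuration file
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg` exactly (numbers are written with full precision).
#'
#' @param cfg `grnevo_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.numeric(v)) return(sprintf("%.17g", v))
    as.character(v)
  }
  lines <- character()
  for (key in names(.CONFIG_SCHEMA)) {
    v <- cfg[[key]]
    if (length(v) == 1L && is.na(v)) next
    lines <- c(lines, paste0(key, " = ", fmt(v)))
  }
  for (bid in names(cfg$overrides)) {
    lines <- c(lines, paste0("[branch ", bid, "]"))
    for (key in names(cfg$overrides[[bid]])) {
      lines <- c(lines, paste0(key, " = ", fmt(cfg$overrides[[bid]][[key]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build simulation parameters from a configuration
#'
#' @param cfg `grnevo_config` from [load_config()].
#' @return A validated [sim_params()] object.
#' @export
as_sim_params <- function(cfg) {
  sim_params(
    n = cfg$n, l = cfg$l, m = cfg$m, mu = cfg$mu, N = cfg$N, p = cfg$p,
    strategy = cfg$strategy,
    reg = reg_config(value_range = c(cfg$value_min, cfg$value_max),
                     sparseness = cfg$sparseness,
                     theta_range = c(cfg$theta_min, cfg$theta_max),
                     lam_range = c(cfg$lam_min, cfg$lam_max),
                     kernel = cfg$kernel),
    fitness = fitness_config(
      marker_gene = if (is.na(cfg$marker_gene)) NULL else cfg$marker_gene,
      maturity_threshold = cfg$maturity_threshold,
      stability_window = if (is.na(cfg$stability_window)) NULL else
        cfg$stability_window,
      growth_cap = cfg$growth_cap),
    clonal_founders = cfg$clonal_founders,
    trace_every = cfg$trace_every
  )
}
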
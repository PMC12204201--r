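#' Load and validate a run configuration
#'
#' Configurations are flat named lists, optionally read from a YAML file.
#' `overrides` (typically CLI flags) replace file values key by key.
#'
#' @param config named list or path to a YAML file.
#' @param overrides named list of values taking precedence.
#' @return the merged configuration list.
#' @export
load_config <- function(config, overrides = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (k in names(overrides)) config[[k]] <- overrides[[k]]
  config
}

config_get <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) stop("missing required config key: ", key)
  default
}

# write a run manifest next to the outputs (inputs, parameters, versions)
write_manifest <- function(out_dir, command, config, inputs = character(0)) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("entropin")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# load network + expression inputs named by a config
load_run_inputs <- function(config) {
  net_path <- config_get(config, "network", required = TRUE)
  expr_path <- config_get(config, "expression", required = TRUE)
  if (!file.exists(net_path)) stop("network file not found: ", net_path)
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  list(net = read_network(net_path,
                          format = config_get(config, "network_format",
                                              "edgelist"),
                          mapping = config_get(config, "mapping")),
       expr = read_expression(expr_path),
       paths = c(net_path, expr_path))
}

#' Compute per-sample entropy rates (pipeline entry point)
#'
#' Reads the network and expression inputs named in the configuration,
#' integrates them, and writes the per-sample entropy table plus a run
#' manifest to the output directory.
#'
#' Config keys: `network`, `expression` (paths, required);
#' `network_format`, `mapping`, `measures` (default both), `out_dir`
#' (default `"."`).
#'
#' @param config named list or YAML path, see [load_config()].
#' @param overrides named list of config overrides.
#' @return the entropy table, invisibly; writes `entropy_table.tsv` and
#'   `compute_manifest.json`.
#' @export
run_compute <- function(config, overrides = list()) {
  config <- load_config(config, overrides)
  out_dir <- config_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_run_inputs(config)
  measures <- config_get(config, "measures", c("neq", "eq"))
  sys <- integrate_system(inputs$net, inputs$expr)
  tab <- entropy_table(sys, measures = measures)
  write.table(tab, file.path(out_dir, "entropy_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "compute", config, inputs$paths)
  invisible(tab)
}

#' Run a perturbation sweep (pipeline entry point)
#'
#' Applies the edge-perturbation grid to the input network and writes the
#' long-format sweep table. If a previous partial sweep table exists in the
#' output directory, completed (kind, level, replicate) cells are skipped
#' and the new rows appended, so interrupted runs can resume.
#'
#' Config keys: as [run_compute()], plus `kinds`, `levels`, `replicates`,
#' `seed`, `measures`.
#'
#' @inheritParams run_compute
#' @return the sweep table, invisibly; writes `perturbation_sweep.tsv` and
#'   `perturb_manifest.json`.
#' @export
run_perturb <- function(config, overrides = list()) {
  config <- load_config(config, overrides)
  out_dir <- config_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_run_inputs(config)
  kinds <- config_get(config, "kinds", c("add", "remove", "flip", "rewire"))
  levels <- config_get(config, "levels", seq(0.1, 0.9, by = 0.1))
  replicates <- config_get(config, "replicates", 5L)
  seed <- config_get(config, "seed", 1L)
  measures <- config_get(config, "measures", "neq")
  out_path <- file.path(out_dir, "perturbation_sweep.tsv")
  done <- NULL
  if (file.exists(out_path)) {
    done <- read.table(out_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    message("resuming: ", nrow(unique(done[c("kind", "level", "replicate")])),
            " completed cell(s) found")
  }
  rows <- if (!is.null(done)) list(done) else list()
  for (kind in kinds) for (lv in levels) for (rep in seq_len(replicates)) {
    if (!is.null(done) &&
        any(done$kind == kind & abs(done$level - lv) < 1e-12 &
            done$replicate == rep)) next
    rows[[length(rows) + 1L]] <- sweep_cell(inputs$net, inputs$expr, kind,
                                            lv, rep, seed, measures)
  }
  tab <- do.call(rbind, rows)
  write.table(tab, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "perturb", config, inputs$paths)
  invisible(tab)
}

#' Run the stabilisation benchmark (pipeline entry point)
#'
#' Builds the evaluation grid over correction methods and thresholds for a
#' two-class dataset and writes the p-value grid and error-count summary.
#'
#' Config keys: as [run_compute()], plus `classes` (path to a two-column
#' TSV sample/class, required), `score_tables` (named list method -> score
#' TSV path; three columns node1 node2 score), `string_scores` (path to a
#' STRING protein-links file), `thresholds`, `alpha`, `repetitions`,
#' `seed`, `dataset`, `pin` (labels).
#'
#' @inheritParams run_compute
#' @return the [evaluation_grid()] result, invisibly; writes
#'   `evaluation_grid.tsv`, `error_counts.tsv` and
#'   `stabilise_manifest.json`.
#' @export
run_stabilise <- function(config, overrides = list()) {
  config <- load_config(config, overrides)
  out_dir <- config_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_run_inputs(config)
  cls_path <- config_get(config, "classes", required = TRUE)
  if (!file.exists(cls_path)) stop("class file not found: ", cls_path)
  cls <- read.table(cls_path, header = FALSE, sep = "\t",
                    col.names = c("sample", "class"),
                    colClasses = "character")
  classes <- stats::setNames(cls$class, cls$sample)[colnames(inputs$expr)]
  if (anyNA(classes)) stop("class file misses sample(s): ",
                           paste(colnames(inputs$expr)[is.na(classes)][1]))
  corrections <- list()
  for (method in names(config_get(config, "score_tables", list()))) {
    p <- config$score_tables[[method]]
    df <- read.table(p, header = FALSE, sep = "\t",
                     col.names = c("node1", "node2", "score"))
    corrections[[method]] <- reliability_scores(df$node1, df$node2,
                                                df$score, method = method)
  }
  if (!is.null(config$string_scores)) {
    corrections[["string"]] <- load_string_scores(config$string_scores)
  }
  res <- evaluation_grid(
    systems = list(list(dataset = config_get(config, "dataset", "dataset"),
                        pin = config_get(config, "pin", "pin"),
                        net = inputs$net, expr = inputs$expr,
                        classes = classes)),
    corrections = corrections,
    thresholds = config_get(config, "thresholds", seq(0.1, 0.9, by = 0.1)),
    alpha = config_get(config, "alpha", 0.05),
    repetitions = config_get(config, "repetitions", 50L),
    seed = config_get(config, "seed", 1L))
  write.table(res$grid, file.path(out_dir, "evaluation_grid.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$errors, file.path(out_dir, "error_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "stabilise", config,
                 c(inputs$paths, cls_path,
                   unlist(config$score_tables, use.names = FALSE)))
  invisible(res)
}
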
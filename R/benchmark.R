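#' Benchmark grid specification
#'
#' Defines the simulation benchmark grid: condition counts, condition
#' covariance regimes and noise structuredness values, crossed with
#' `n_reps` replicates per cell. The defaults mirror the simulation study
#' design — `C` in \{10, 30, 50, 70, 100, 120\}, the four `V_C` regimes and
#' unstructured versus strongly structured noise — at a desk-scale
#' replicate count of 20 (use `n_reps = 100` for the full study).
#'
#' @param C_values integer vector of condition counts.
#' @param v_kinds subset of the four covariance regimes.
#' @param rho_values noise structuredness values in `[0, 1]`.
#' @param n_reps replicates per grid cell.
#' @param G,T_motifs dataset dimensions.
#' @param target_fraction motif-explained variance fraction.
#' @return An object of class `"benchmark_grid"`.
#' @export
benchmark_grid <- function(C_values = c(10, 30, 50, 70, 100, 120),
                           v_kinds = c("independent", "full_positive",
                                       "blocks_many", "blocks_two"),
                           rho_values = c(0, 0.7), n_reps = 20,
                           G = 978, T_motifs = 623, target_fraction = 0.2) {
  v_kinds <- match.arg(v_kinds, several.ok = TRUE)
  stopifnot(all(C_values >= 2), all(rho_values >= 0 & rho_values <= 1),
            n_reps >= 1)
  structure(list(C_values = as.integer(C_values), v_kinds = v_kinds,
                 rho_values = rho_values, n_reps = as.integer(n_reps),
                 G = as.integer(G), T_motifs = as.integer(T_motifs),
                 target_fraction = target_fraction),
            class = "benchmark_grid")
}

#' Run the simulation benchmark
#'
#' For every grid cell and replicate: simulate a dataset, fit both the
#' freeform mixed model and the ridge model, and score the posterior
#' activities against the simulated truth. Results are returned in long
#' format, one row per (cell, replicate, model); each row records the seed
#' from which its dataset regenerates. Failures in individual cells are
#' caught, recorded with `NA` scores, and do not stop the run.
#'
#' @param grid a [benchmark_grid()].
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param models models to fit.
#' @param fit_opts extra arguments for [fit_freeform()] (e.g. `max_iter`).
#' @param out optional path; when given, the table is written there as TSV.
#' @param verbose print one line per cell.
#' @return A data frame with columns `C`, `v_kind`, `rho`, `rep`, `seed`,
#'   `model`, `pearson`, `spearman`, `mse`, `converged`, `error`.
#' @export
run_benchmark <- function(grid = benchmark_grid(), seed = 1L,
                          models = c("blmm", "ridge"), fit_opts = list(),
                          out = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "benchmark_grid"))
  cells <- expand.grid(C = grid$C_values, v_kind = grid$v_kinds,
                       rho = grid$rho_values, rep = seq_len(grid$n_reps),
                       stringsAsFactors = FALSE)
  rep_seeds <- derive_seeds(seed, paste0("cell", seq_len(nrow(cells))))
  rows <- vector("list", nrow(cells) * length(models))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    cell_seed <- rep_seeds[[i]]
    base_row <- data.frame(C = cell$C, v_kind = cell$v_kind, rho = cell$rho,
                           rep = cell$rep, seed = cell_seed,
                           stringsAsFactors = FALSE)
    ds <- tryCatch(simulate_dataset(simulation_config(
      G = grid$G, C = cell$C, T_motifs = grid$T_motifs,
      v_kind = cell$v_kind, noise_rho = cell$rho,
      target_fraction = grid$target_fraction, seed = cell_seed)),
      error = function(e) e)
    pi_cache <- if (!inherits(ds, "error")) gene_similarity(ds$M) else NULL
    for (model in models) {
      k <- k + 1L
      if (inherits(ds, "error")) {
        rows[[k]] <- cbind(base_row, model = model, pearson = NA_real_,
                           spearman = NA_real_, mse = NA_real_,
                           converged = NA, error = conditionMessage(ds))
        next
      }
      fit <- tryCatch({
        if (model == "ridge") {
          fit_ridge(ds$Y, ds$M, pi = pi_cache)
        } else {
          do.call(fit_freeform,
                  c(list(y = ds$Y, m = ds$M, pi = pi_cache), fit_opts))
        }
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[k]] <- cbind(base_row, model = model, pearson = NA_real_,
                           spearman = NA_real_, mse = NA_real_,
                           converged = NA, error = conditionMessage(fit))
        next
      }
      sc <- recovery_scores(ds$omega_true, fit$omega_hat)
      rows[[k]] <- cbind(base_row, model = model, pearson = sc$pearson,
                         spearman = sc$spearman, mse = sc$mse,
                         converged = fit$converged, error = NA_character_)
      if (verbose) {
        cat(sprintf("C=%d %s rho=%.1f rep=%d %s: r=%.3f\n", cell$C,
                    cell$v_kind, cell$rho, cell$rep, model, sc$pearson))
      }
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

run_config_defaults <- list(
  command = "simulate",
  expression = NULL, motifs = NULL, out = NULL,
  G = 978L, C = 50L, T_motifs = 623L,
  v_kind = "independent", noise_rho = 0, delta = 1, target_fraction = 0.2,
  model = "blmm", reg_lambda = 1e-4, max_iter = 2000L,
  k_folds = 10L, n_perm = 1000L, groups = NULL, iqr_factor = 2.5,
  C_values = c(10L, 30L, 50L, 70L, 100L, 120L),
  v_kinds = c("independent", "full_positive", "blocks_many", "blocks_two"),
  rho_values = c(0, 0.7), n_reps = 20L,
  seed = NULL, structure_seed = NULL, cv_seed = NULL,
  log_level = "info")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration (dispatch on file extension),
#' rejects unknown keys, validates ranges and fills defaults. Seeds left
#' unset are drawn once from R's RNG and recorded, so the resulting
#' configuration always pins every source of randomness.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A named list of class `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  unknown <- setdiff(names(raw), names(run_config_defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(run_config_defaults, raw)
  if (!cfg$command %in% c("simulate", "fit", "crossval", "permute", "rank",
                          "benchmark")) {
    stop("unknown command: ", cfg$command, call. = FALSE)
  }
  if (cfg$noise_rho < 0 || cfg$noise_rho > 1) {
    stop("config error: noise_rho must be in [0, 1]", call. = FALSE)
  }
  if (cfg$target_fraction <= 0 || cfg$target_fraction >= 1) {
    stop("config error: target_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!cfg$model %in% c("blmm", "ridge")) {
    stop("config error: model must be 'blmm' or 'ridge'", call. = FALSE)
  }
  for (s in c("seed", "structure_seed", "cv_seed")) {
    if (is.null(cfg[[s]])) cfg[[s]] <- sample.int(.Machine$integer.max - 1L, 1)
    cfg[[s]] <- as.integer(cfg[[s]])
  }
  structure(cfg, class = "run_config")
}

#' Write a run manifest
#'
#' Records what a run did: a hash of the configuration, every seed used,
#' package and R versions, wall time, and the list of files produced. Two
#' runs with the same configuration produce the same hash, and the manifest
#' carries everything needed to regenerate the outputs.
#'
#' @param cfg a `"run_config"` (or any named list).
#' @param outputs character vector of output file paths.
#' @param elapsed wall time in seconds.
#' @param path optional path for the manifest JSON.
#' @return The manifest as a list, invisibly if written to `path`.
#' @export
log_run <- function(cfg, outputs = character(), elapsed = NA_real_,
                    path = NULL) {
  cfg_plain <- unclass(cfg)
  manifest <- list(
    config = cfg_plain,
    config_hash = rlang::hash(cfg_plain),
    seeds = cfg_plain[intersect(names(cfg_plain),
                                c("seed", "structure_seed", "cv_seed"))],
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("motifBLMM")),
    wall_time_sec = elapsed,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(manifest))
  }
  manifest
}
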
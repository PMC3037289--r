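#' Run the full prognosis pipeline on expression and survival files
#'
#' Orchestrates preprocessing, network and module construction,
#' representative-feature building, cross-validated TGDR fitting, prediction
#' evaluation and gene-level reporting, writing every artifact under
#' `out_dir`. The configuration may be a list or the path to a YAML/JSON file;
#' unspecified entries fall back to the defaults below, which follow the
#' method's standard constants (2000 screened genes, xi = 80%, step 1e-3,
#' 5-fold cross-validation, threshold grid 1.0, 0.95, ..., 0).
#'
#' @param config A named list or path to a YAML/JSON config file. Recognised
#'   entries: `expression`, `survival`, `out_dir` (paths; the first two
#'   required), `orientation`, `k_impute` (10), `d_keep` (2000), `power` (6),
#'   `min_module_size` (25), `cut_height` (NULL), `kind` ("R1"), `xi` (80),
#'   `v` (5), `inner_v` (5), `tau_grid`, `k_max` (2500), `delta_nu` (1e-3),
#'   `rebuild_features` (FALSE), `seed` (1).
#' @return (Invisibly) a list with the fitted objects and the paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file.path(cfg$out_dir, "run.log")
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) stopf("[%s] %s", name, conditionMessage(e)))
    msg <- sprintf("%s\tstage=%s\tseconds=%.2f\tseed=%s", format(Sys.time()), name,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   cfg$seed)
    cat(msg, "\n", file = log_con, append = TRUE)
    message(msg)
    out
  }

  x <- stage("preprocess", {
    raw <- read_expression(cfg$expression, orientation = cfg$orientation)
    preprocess_expression(raw, k = cfg$k_impute, d_keep = min(cfg$d_keep, nrow(raw)))
  })
  surv <- stage("survival", read_survival(cfg$survival, sample_ids = colnames(x)))
  net <- stage("network", build_network(x, power = cfg$power))
  mods <- stage("modules", detect_modules(net, min_module_size = cfg$min_module_size,
                                          cut_height = cfg$cut_height))
  pcas <- stage("pca", module_pca(x, mods))
  feats <- stage("features", build_features(pcas, kind = cfg$kind, xi = cfg$xi))
  fit <- stage("fit", tgdr_tune(feats, surv$time, surv$status, v = cfg$inner_v,
                                tau_grid = cfg$tau_grid, k_max = cfg$k_max,
                                delta_nu = cfg$delta_nu, seed = cfg$seed))
  evaluation <- stage("evaluate", cv_predict(
    x, surv$time, surv$status, kind = cfg$kind, v = cfg$v, seed = cfg$seed,
    power = cfg$power, min_module_size = cfg$min_module_size,
    cut_height = cfg$cut_height, xi = cfg$xi, inner_v = cfg$inner_v,
    tau_grid = cfg$tau_grid, k_max = cfg$k_max, delta_nu = cfg$delta_nu,
    rebuild_features = cfg$rebuild_features))
  gene_model <- stage("gene-level", gene_level_coefficients(fit, feats, pcas))

  paths <- stage("write", {
    p <- list()
    cfg_json <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(cfg[order(names(cfg))], cfg_json, auto_unbox = TRUE, digits = NA, null = "null")
    # hash the analysis-relevant configuration: where the artifacts land does
    # not change what was computed
    hash_src <- tempfile(fileext = ".json")
    hashable <- cfg[setdiff(sort(names(cfg)), "out_dir")]
    jsonlite::write_json(hashable, hash_src, auto_unbox = TRUE, digits = NA, null = "null")
    config_hash <- unname(tools::md5sum(hash_src))
    unlink(hash_src)
    p$modules <- file.path(cfg$out_dir, "module_assignment.tsv")
    write.table(tidy(mods), p$modules, sep = "\t", row.names = FALSE, quote = FALSE)
    p$features <- file.path(cfg$out_dir, "features.tsv")
    write.table(data.frame(sample = rownames(feats$Z), feats$Z, check.names = FALSE),
                p$features, sep = "\t", row.names = FALSE, quote = FALSE)
    p$feature_index <- file.path(cfg$out_dir, "feature_index.json")
    jsonlite::write_json(list(kind = feats$kind, index = feats$index,
                              provenance = feats$provenance, xi = feats$xi,
                              config_hash = config_hash, seed = cfg$seed),
                         p$feature_index, auto_unbox = TRUE, digits = NA, null = "null")
    p$fit <- file.path(cfg$out_dir, "fit.json")
    jsonlite::write_json(list(beta = unname(fit$beta), term = names(fit$beta),
                              tau = fit$tau, K = fit$K, delta_nu = fit$delta_nu,
                              variant = fit$variant, seed = cfg$seed,
                              config_hash = config_hash),
                         p$fit, auto_unbox = TRUE, digits = NA, null = "null")
    p$evaluation <- file.path(cfg$out_dir, "evaluation.json")
    jsonlite::write_json(list(kind = evaluation$kind,
                              logrank_statistic = evaluation$logrank$statistic,
                              logrank_p = evaluation$logrank$p_value,
                              concordance = evaluation$concordance,
                              seed = cfg$seed, config_hash = config_hash),
                         p$evaluation, auto_unbox = TRUE, digits = NA, null = "null")
    p$risk_scores <- file.path(cfg$out_dir, "risk_scores.tsv")
    write.table(evaluation$scores, p$risk_scores, sep = "\t", row.names = FALSE, quote = FALSE)
    p$top_coefficients <- file.path(cfg$out_dir, "top_coefficients.tsv")
    write.table(gene_model$ranked, p$top_coefficients, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  })
  invisible(list(expression = x, survival = surv, network = net, modules = mods,
                 pcas = pcas, features = feats, fit = fit, evaluation = evaluation,
                 gene_model = gene_model, paths = paths, config = cfg))
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stopf("`config` must be a list or a path to a YAML/JSON file")
  defaults <- list(orientation = "genes-in-rows", out_dir = "netprog-run",
                   k_impute = 10, d_keep = 2000, power = 6, min_module_size = 25,
                   cut_height = NULL, kind = "R1", xi = 80, v = 5, inner_v = 5,
                   tau_grid = seq(1, 0, by = -0.05), k_max = 2500, delta_nu = 1e-3,
                   rebuild_features = FALSE, seed = 1)
  unknown <- setdiff(names(config), c(names(defaults), "expression", "survival"))
  if (length(unknown)) stopf("unknown config entries: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (field in c("expression", "survival")) {
    if (is.null(cfg[[field]])) stopf("config is missing required entry `%s`", field)
  }
  cfg$kind <- match.arg(cfg$kind, c("R1", "R2", "R3", "R4"))
  cfg
}

#' Run the simulation study from a configuration and write its artifacts
#'
#' @param config A [sim_config()], a named list of its arguments, or a path to
#'   a YAML/JSON file of them; an `out_dir` entry (default `"netprog-sim"`)
#'   and a `fitted_kinds` entry (default all four) may be included.
#' @return (Invisibly) the `sim_result` with `paths` attached.
#' @export
run_simulation <- function(config) {
  out_dir <- "netprog-sim"
  fitted_kinds <- c("R1", "R2", "R3", "R4")
  if (inherits(config, "sim_config")) {
    cfg <- config
  } else {
    if (is.character(config) && length(config) == 1) {
      config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
        jsonlite::read_json(config, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(config)
      }
    }
    if (!is.list(config)) stopf("`config` must be a sim_config, list, or file path")
    if (!is.null(config$out_dir)) { out_dir <- config$out_dir; config$out_dir <- NULL }
    if (!is.null(config$fitted_kinds)) { fitted_kinds <- config$fitted_kinds; config$fitted_kinds <- NULL }
    cfg <- do.call(sim_config, config)
  }
  res <- run_study(cfg, fitted_kinds = fitted_kinds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_path <- file.path(out_dir, "replicates.tsv")
  write.table(res$per_replicate, per_path, sep = "\t", row.names = FALSE, quote = FALSE)
  agg_path <- file.path(out_dir, "aggregate.json")
  jsonlite::write_json(list(config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                            aggregate = res$aggregate),
                       agg_path, auto_unbox = TRUE, digits = NA)
  res$paths <- list(replicates = per_path, aggregate = agg_path)
  invisible(res)
}
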
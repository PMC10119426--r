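#' Default pipeline configuration
#'
#' Stage toggles, stage parameters and the global seed for [run_pipeline()].
#' Every stochastic stage derives its seed from `seed` so one integer
#' reproduces the whole run.
#'
#' @param seed Global integer seed.
#' @param stages Character subset of `c("hm", "gep", "comsia")`.
#' @param hm,gep,comsia Named lists of per-stage parameter overrides.
#' @param activity_csv,descriptor_csv Optional paths to user data for the
#'   linear-model stage; when `NULL` the planted-linear generator supplies
#'   the inputs.
#' @return Nested configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1L, stages = c("hm", "gep", "comsia"),
                            hm = list(), gep = list(), comsia = list(),
                            activity_csv = NULL, descriptor_csv = NULL) {
  base <- list(
    seed = as.integer(seed),
    stages = stages,
    activity_csv = activity_csv,
    descriptor_csv = descriptor_csv,
    hm = utils::modifyList(list(n = 40L, p = 20L, n_true = 3L,
                                n_test = 10L, max_size = 5L, cap = 0.8),
                           hm),
    gep = utils::modifyList(list(expression = "d0*d1+Cos(d2)", n = 50L,
                                 population = 100L, generations = 50L,
                                 head = 7L, n_genes = 3L), gep),
    comsia = utils::modifyList(list(n = 20L, spacing = 2, margin = 4,
                                    alpha = 0.3, max_comp = 6L), comsia))
  structure(base, class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full modelling pipeline
#'
#' Executes the stages in workflow order — descriptor data, heuristic
#' linear-model search, GEP symbolic regression, CoMSIA field model, then
#' external validation of the linear model — writing one JSON artifact per
#' stage plus a manifest (inputs, parameters, seed, package version) to the
#' run directory.  With no user data configured, the synthetic generators
#' supply inputs with known ground truth, so the pipeline doubles as an
#' end-to-end smoke test.
#'
#' @param config A [pipeline_config()], or a path to a YAML/JSON file with
#'   its fields.
#' @param out_dir Run directory (created if missing).
#' @return Invisibly, a list with the per-stage results and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  artifacts <- list()
  results <- list()

  if ("hm" %in% config$stages) {
    hmres <- pipeline_stage_hm(config, seed)
    path <- file.path(out_dir, "hm_model.json")
    write_stage_json(hmres$json, path)
    vpath <- file.path(out_dir, "hm_validation.json")
    write_stage_json(hmres$validation_json, vpath)
    artifacts$hm <- path; artifacts$hm_validation <- vpath
    results$hm <- hmres
  }
  if ("gep" %in% config$stages) {
    gepres <- pipeline_stage_gep(config, seed)
    path <- file.path(out_dir, "gep_model.json")
    write_stage_json(gepres$json, path)
    artifacts$gep <- path
    results$gep <- gepres
  }
  if ("comsia" %in% config$stages) {
    cres <- pipeline_stage_comsia(config, seed)
    path <- file.path(out_dir, "comsia_model.json")
    write_stage_json(cres$json, path)
    artifacts$comsia <- path
    results$comsia <- cres
  }
  manifest <- list(
    package = "qsarflow",
    version = as.character(utils::packageVersion("qsarflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stages = config$stages,
    parameters = config[c("hm", "gep", "comsia")],
    inputs = list(activity_csv = config$activity_csv,
                  descriptor_csv = config$descriptor_csv),
    artifacts = lapply(artifacts, basename))
  write_stage_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(results = results, artifacts = artifacts,
                 manifest = manifest))
}

pipeline_stage_hm <- function(config, seed) {
  p <- config$hm
  if (!is.null(config$descriptor_csv) && !is.null(config$activity_csv)) {
    X <- utils::read.csv(config$descriptor_csv, comment.char = "#",
                         stringsAsFactors = FALSE)
    act <- read_activity_csv(config$activity_csv)
    ids <- X$compound_id
    X <- as.matrix(X[, setdiff(names(X), "compound_id"), drop = FALSE])
    y <- act$activity[match(ids, act$compound_id)]
    truth <- NULL
  } else {
    gen <- gen_planted_linear(n = p$n, p = p$p, n_true = p$n_true,
                              seed = seed)
    X <- gen$X; y <- gen$y; ids <- paste0("cpd", seq_len(nrow(X)))
    truth <- gen[c("true_idx", "coefs", "intercept")]
  }
  split <- split_dataset(ids, length(ids) - p$n_test, p$n_test,
                         seed = seed + 1L)
  tr <- match(split$train_ids, ids); te <- match(split$test_ids, ids)
  cfg <- hm_config(max_size = p$max_size, cap = p$cap)
  trace <- heuristic_search(X[tr, , drop = FALSE], y[tr], cfg)
  size <- choose_model_size(trace)
  best <- trace$steps[[which(vapply(trace$steps, `[[`, 0L, "size") == size)]]
  model <- best$model
  yhat_te <- predict(model, X[te, , drop = FALSE])
  report <- validation_report(y[tr], model$fitted, y[te], yhat_te, model$k)
  json <- list(
    kind = "hm_linear_model",
    descriptors = model$descriptors,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    statistics = list(r2 = model$r2, s2 = model$s2, f = model$f,
                      r2cv = best$r2cv,
                      t_values = as.list(model$t_values)),
    train_mean_activity = mean(y[tr]),
    trace = lapply(trace$steps, function(st)
      list(size = st$size, descriptors = st$descriptors, r2 = st$r2,
           r2cv = st$r2cv, s2 = st$s2)),
    split = list(train_ids = split$train_ids, test_ids = split$test_ids,
                 seed = split$seed),
    truth = truth)
  list(model = model, trace = trace, report = report, json = json,
       validation_json = unclass_report(report))
}

unclass_report <- function(report) {
  list(r2_ext = report$r2_ext, verdict = report$verdict,
       train = report$train, test = report$test)
}

pipeline_stage_gep <- function(config, seed) {
  p <- config$gep
  gen <- gen_symbolic(expression = p$expression, n = p$n, seed = seed + 2L)
  cfg <- gep_config(population = p$population, generations = p$generations,
                    head = p$head, n_genes = p$n_genes, seed = seed + 3L)
  res <- gep_evolve(gen$X, gen$y, cfg)
  met <- summary_metrics(gen$y, res$predictions, n_params = 1L)
  json <- list(
    kind = "gep_symbolic_model",
    genes = lapply(res$best$genes, paste, collapse = " "),
    head = res$best$head, link = res$best$link,
    infix = tree_to_infix(res$best_tree),
    convention = "unary functions bind tighter than */ which bind tighter than +-; left-associative",
    fitness = res$best_fitness,
    generations_run = res$generations_run,
    metrics = met[c("r2", "pearson_r", "mae", "rmse")],
    target = gen$expression,
    terminal_binding = as.list(res$terminal_binding))
  list(result = res, metrics = met, json = json)
}

pipeline_stage_comsia <- function(config, seed) {
  p <- config$comsia
  gen <- gen_toy_molecules(n = p$n, spacing = p$spacing, margin = p$margin,
                           probe = probe_params(alpha = p$alpha),
                           seed = seed + 4L)
  fit <- comsia_fit(gen$molecules, gen$activities, template_id = NULL,
                    spacing = p$spacing, margin = p$margin,
                    probe = probe_params(alpha = p$alpha),
                    max_comp = p$max_comp)
  json <- list(
    kind = "comsia_pls_model",
    q2 = fit$q2, onc = fit$onc, r2 = fit$model$r2, see = fit$model$see,
    f = fit$model$f,
    contributions_pct = as.list(round(fit$contributions, 4)),
    grid = list(dims = fit$grid$dims, spacing = fit$grid$spacing,
                origin = fit$grid$origin),
    alpha = p$alpha, n_molecules = p$n)
  list(fit = fit, json = json, generator = gen)
}
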
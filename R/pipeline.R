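#' Run the full retention-modelling pipeline
#'
#' Read (or accept) a dataset, split it by Kennard-Stone, fit the MLR
#' control and the order-constrained model on the training subset, evaluate
#' both, build the applicability-domain report for the order-constrained
#' model, and write all artifacts to `output_dir`: `split.csv`,
#' `predictions_mlr.csv`, `predictions_mlr_nlp.csv`, `metrics.csv`,
#' `ad_report.csv` and `run_config.yaml` (all resolved parameters plus
#' solver diagnostics). Metric values are written with 6 significant digits
#' so re-runs are byte-identical.
#'
#' @param input A [retention_dataset()] or a CSV path readable by
#'   [read_retention_table()].
#' @param output_dir Directory for artifacts (created if missing).
#' @param id_col,rt_col,descriptor_cols Schema mapping for CSV input.
#' @param split_fraction Training fraction for [kennard_stone_split()].
#' @param lambda_weight,solver_tolerance Passed to [nlp_config()].
#' @param ad_variant Critical-leverage variant, see [critical_leverage()].
#' @return Invisibly, a list with the dataset, split, both models, both
#'   metrics reports and the AD report.
#' @export
run_pipeline <- function(input, output_dir,
                         id_col = "id", rt_col = "tR", descriptor_cols = NULL,
                         split_fraction = 0.70,
                         lambda_weight = 1, solver_tolerance = 1e-8,
                         ad_variant = c("k-1", "k+1")) {
  ad_variant <- match.arg(ad_variant)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  ds <- stage("read", {
    if (inherits(input, "retention_dataset")) input
    else read_retention_table(input, id_col = id_col, rt_col = rt_col,
                              descriptor_cols = descriptor_cols)
  })
  split <- stage("split", kennard_stone_split(ds, split_fraction))
  train <- subset_dataset(ds, split$train)
  validation <- subset_dataset(ds, split$validation)

  mlr <- stage("fit", fit_mlr(train))
  cfg <- nlp_config(lambda_weight = lambda_weight,
                    solver_tolerance = solver_tolerance)
  nlp <- stage("fit", fit_order_constrained(train, cfg))

  metrics <- stage("evaluate", list(
    MLR = metrics_report(mlr, ds, split),
    `MLR-NLP` = metrics_report(nlp, ds, split)
  ))
  ad <- stage("applicability",
              williams_report(nlp, train, validation, variant = ad_variant))

  stage("write", {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    p <- function(f) file.path(output_dir, f)
    write_split(ds, split, p("split.csv"))
    write_predictions(ds, predict(mlr, ds), p("predictions_mlr.csv"))
    write_predictions(ds, predict(nlp, ds), p("predictions_mlr_nlp.csv"))
    mt <- do.call(rbind, lapply(names(metrics), function(nm) {
      d <- as.data.frame(metrics[[nm]])
      cbind(model = nm, d)
    }))
    mt$value <- signif(mt$value, 6)
    utils::write.csv(mt, p("metrics.csv"), row.names = FALSE, quote = FALSE)
    ad_out <- as.data.frame(ad)
    ad_out$leverage <- signif(ad_out$leverage, 6)
    ad_out$std_residual <- signif(ad_out$std_residual, 6)
    utils::write.csv(ad_out, p("ad_report.csv"), row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(
      n_analytes = n_analytes(ds),
      n_descriptors = n_descriptors(ds),
      split_fraction = split_fraction,
      n_train = length(split$train),
      n_validation = length(split$validation),
      lambda_weight = lambda_weight,
      solver_tolerance = solver_tolerance,
      ad_variant = ad_variant,
      critical_leverage = attr(ad, "critical_leverage"),
      solver = list(
        iterations = nlp$solver_status$iterations,
        objective = nlp$solver_status$objective,
        converged = nlp$solver_status$converged
      )
    ), p("run_config.yaml"))
  })

  invisible(list(dataset = ds, split = split, mlr = mlr, nlp = nlp,
                 metrics = metrics, ad = ad))
}

#' Serialize a fitted model to YAML
#'
#' @param model A `qsrr_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "qsrr_model"))
  yaml::write_yaml(list(
    kind = model$kind,
    coefficients = as.list(model$coefficients),
    x_means = as.list(model$x_means),
    y_mean = model$y_mean,
    lambda_weight = model$lambda_weight,
    alphas = model$alphas,
    sse = model$sse,
    train_residual_sd = model$train_residual_sd,
    solver_status = model$solver_status
  ), path)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path YAML path.
#' @return A `qsrr_model`.
#' @export
read_model <- function(path) {
  m <- yaml::read_yaml(path)
  structure(
    list(coefficients = unlist(m$coefficients),
         x_means = unlist(m$x_means),
         y_mean = m$y_mean,
         kind = m$kind,
         alphas = as.numeric(unlist(m$alphas)),
         lambda_weight = m$lambda_weight,
         solver_status = m$solver_status,
         sse = m$sse,
         train_residual_sd = m$train_residual_sd),
    class = "qsrr_model"
  )
}
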
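# Model fitting. Model 1 is ordinary least squares on the sex x birth-weight
# spline design. Models 2 and 3 are elastic-net fits: the objective is
# (1/2) MSE + lambda [ alpha ||beta||_1 + (1 - alpha)/2 ||beta||_2^2 ]
# with an unpenalized intercept, delegated to glmnet (whose objective is
# identical). Hyperparameters are chosen on the internal validation
# sub-cohort by grid search over alpha and a log-spaced lambda path.

.design_values <- function(design) {
  if (inherits(design, "ga_design")) design$values else as.matrix(design)
}

.new_ga_model <- function(spec, intercept, coefficients, hyper, preprocess_ref,
                          training_n, dropped = character(0)) {
  structure(list(spec = spec, intercept = intercept,
                 coefficients = coefficients, hyperparameters = hyper,
                 preprocess_ref = preprocess_ref, training_n = training_n,
                 dropped = dropped),
            class = "ga_model")
}

#' Fit the baseline model (Model 1) by ordinary least squares
#'
#' @param design a `ga_design` (or numeric matrix whose first column is the
#'   intercept).
#' @param ga reference gestational age (decimal weeks).
#' @param spec optional `model_spec` stored for prediction.
#' @param preprocess_ref label of the preprocessing parameters the design was
#'   built under.
#' @return a `ga_model` with `penalty_strength = 0`. Rank-deficient designs
#'   have their aliased columns dropped (coefficient 0) with a warning.
#' @export
fit_baseline_model <- function(design, ga, spec = NULL,
                               preprocess_ref = "local") {
  x <- .design_values(design)
  stopifnot(nrow(x) == length(ga))
  fit <- stats::lm.fit(x, ga)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    aliased <- names(beta)[is.na(beta)]
    warning(sprintf("rank-deficient design; dropped: %s",
                    paste(aliased, collapse = ", ")))
    beta[is.na(beta)] <- 0
  } else {
    aliased <- character(0)
  }
  .new_ga_model(spec, intercept = beta[["(Intercept)"]],
                coefficients = beta[setdiff(names(beta), "(Intercept)")],
                hyper = list(l1_fraction = NA_real_, penalty_strength = 0),
                preprocess_ref = preprocess_ref, training_n = nrow(x),
                dropped = aliased)
}

#' Fit an elastic-net model at fixed hyperparameters
#'
#' @param design a `ga_design` or matrix (intercept column is removed before
#'   fitting; glmnet estimates the unpenalized intercept).
#' @param ga response, decimal weeks.
#' @param l1_fraction mixing parameter alpha in `[0, 1]` (1 = lasso).
#' @param penalty_strength lambda >= 0.
#' @param spec,preprocess_ref stored for prediction, as in
#'   [fit_baseline_model()].
#' @param thresh coordinate-descent convergence threshold.
#' @return a `ga_model`.
#' @export
fit_elastic_net <- function(design, ga, l1_fraction, penalty_strength,
                            spec = NULL, preprocess_ref = "local",
                            thresh = 1e-10) {
  stopifnot(l1_fraction >= 0, l1_fraction <= 1, penalty_strength >= 0)
  x <- .design_values(design)
  keep <- setdiff(colnames(x), "(Intercept)")
  x <- x[, keep, drop = FALSE]
  # warm-started path down to the requested lambda for a stable solution
  lam_max <- max(abs(crossprod(x, ga - mean(ga))) / nrow(x)) /
    max(l1_fraction, 0.001)
  lam_max <- max(lam_max, penalty_strength * 1.01, 1e-4)
  path <- exp(seq(log(lam_max), log(max(penalty_strength, lam_max * 1e-6)),
                  length.out = 30))
  path <- sort(unique(c(path, penalty_strength)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, ga, alpha = l1_fraction, lambda = path,
                        standardize = FALSE, thresh = thresh, maxit = 1e6)
  # penalty_strength is a member of the fitted path; read its solution off
  # the path directly
  i <- which(abs(fit$lambda - penalty_strength) <=
               1e-10 * max(1, penalty_strength))[1]
  cf <- if (!is.na(i)) {
    c(fit$a0[[i]], as.numeric(fit$beta[, i]))
  } else {
    as.numeric(stats::coef(fit, s = penalty_strength))
  }
  names(cf) <- c("(Intercept)", colnames(x))
  .new_ga_model(spec, intercept = cf[["(Intercept)"]],
                coefficients = cf[-1],
                hyper = list(l1_fraction = l1_fraction,
                             penalty_strength = penalty_strength),
                preprocess_ref = preprocess_ref, training_n = nrow(x))
}

#' Select elastic-net hyperparameters on a held-out validation design
#'
#' Fits a full lambda path per `l1_fraction` on the development design and
#' scores mean squared error on the validation design; the grid point with
#' minimal validation MSE is chosen, ties going to the larger penalty.
#'
#' @param dev_design,dev_ga development (training) design and response.
#' @param val_design,val_ga internal validation design and response.
#' @param l1_fractions alpha grid.
#' @param n_lambda points on each log-spaced lambda path.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max.
#' @return object of class `penalty_path`: data frame `grid` (alpha, lambda,
#'   val_mse) plus the `chosen` point.
#' @export
select_hyperparameters <- function(dev_design, dev_ga, val_design, val_ga,
                                   l1_fractions = c(0.1, 0.5, 0.9),
                                   n_lambda = 50, lambda_min_ratio = 1e-4) {
  if (length(l1_fractions) == 0 || n_lambda < 1) {
    stop("grid_error: empty hyperparameter grid", call. = FALSE)
  }
  xd <- .design_values(dev_design); xv <- .design_values(val_design)
  keep <- setdiff(colnames(xd), "(Intercept)")
  xd <- xd[, keep, drop = FALSE]; xv <- xv[, keep, drop = FALSE]
  lam_max <- max(abs(crossprod(xd, dev_ga - mean(dev_ga))) / nrow(xd)) /
    max(min(l1_fractions), 0.001)
  path <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = n_lambda))
  grids <- lapply(l1_fractions, function(a) {
    fit <- glmnet::glmnet(xd, dev_ga, alpha = a, lambda = path,
                          standardize = FALSE, thresh = 1e-8, maxit = 1e6)
    pred <- stats::predict(fit, newx = xv)
    mse <- colMeans((val_ga - pred)^2)
    data.frame(l1_fraction = a, penalty_strength = fit$lambda,
               val_mse = as.numeric(mse))
  })
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL
  best_mse <- min(grid$val_mse)
  cand <- grid[grid$val_mse <= best_mse + 1e-12, , drop = FALSE]
  chosen <- cand[order(-cand$penalty_strength, -cand$l1_fraction), ][1, ]
  structure(list(grid = grid, chosen = chosen), class = "penalty_path")
}

#' Predict gestational age for a cohort
#'
#' Rebuilds the model's design matrix from a preprocessed cohort and returns
#' `intercept + X beta` in decimal weeks. Estimates are not clipped;
#' completed-weeks comparison (flooring both arms) is the caller's
#' responsibility via [round_down_completed_weeks()].
#'
#' The cohort must carry the `"preprocess"` attribute set by
#' [preprocess_cohort()], making the scaling contract explicit; a model fitted
#' under training-cohort scaling refuses cohorts scaled with other parameters
#' unless `check_scaling = FALSE`.
#'
#' @param model a `ga_model`.
#' @param cohort preprocessed cohort data frame, or a `ga_design` / matrix.
#' @param check_scaling enforce the preprocessing label contract.
#' @return numeric vector of GA estimates (decimal weeks).
#' @export
predict_ga <- function(model, cohort, check_scaling = TRUE) {
  if (is.data.frame(cohort)) {
    if (check_scaling && is.null(attr(cohort, "preprocess"))) {
      stop("predict_error: cohort has not been preprocessed", call. = FALSE)
    }
    if (is.null(model$spec)) {
      stop("predict_error: model carries no spec; supply a design matrix",
           call. = FALSE)
    }
    x <- suppressWarnings(build_design_matrix(cohort, model$spec))$values
  } else {
    x <- .design_values(cohort)
  }
  beta <- model$coefficients
  absent <- setdiff(names(beta)[beta != 0], colnames(x))
  if (length(absent)) {
    stop(sprintf("predict_error: design lacks column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  common <- intersect(names(beta), colnames(x))
  as.numeric(model$intercept + x[, common, drop = FALSE] %*% beta[common])
}

#' Serialize a fitted model to JSON
#' @param model a `ga_model`.
#' @param path output path.
#' @export
write_ga_model <- function(model, path) {
  obj <- unclass(model)
  obj$spec <- if (!is.null(model$spec)) unclass(model$spec)
  obj$coefficients <- as.list(model$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ga_model
#' @export
read_ga_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  obj$coefficients <- unlist(obj$coefficients)
  if (!is.null(obj$spec)) {
    obj$spec$splined <- lapply(obj$spec$splined, unlist)
    obj$spec <- do.call(model_spec, obj$spec[c("model_id", "quantitative",
                                               "splined", "interactions",
                                               "top_k_splined")])
  }
  class(obj) <- "ga_model"
  obj
}
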
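# Gradient-boosted estimation of multilevel protection effects.
#
# Stagewise least-squares boosting of shallow regression trees (interaction
# depth 2, learning rate 0.1), with the number of trees selected by 5-fold
# cross-validation, split-gain relative influence, and partial-dependence
# marginal effects per protection category. Tree fitting is backed by the
# xgboost library under exactly this contract.

#' Configuration for the boosted protection-effect model
#'
#' @param n_trees_grid Candidate tree counts; the model is grown to the
#'   largest and the CV-optimal iteration within it is selected.
#' @param max_depth Maximum tree depth; 2 permits at most 2-way interactions
#'   between covariates.
#' @param learning_rate Shrinkage applied to every tree's contribution.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Seed fixing the fold assignment (bit-reproducible fits).
#' @return A `boosted_config` list.
#' @export
boosted_config <- function(n_trees_grid = c(10000, 20000, 30000),
                           max_depth = 2, learning_rate = 0.1,
                           cv_folds = 5, seed = 1L) {
  stopifnot(learning_rate > 0, learning_rate <= 1, max_depth >= 1,
            cv_folds >= 2, all(n_trees_grid >= 1))
  structure(list(n_trees_grid = sort(as.integer(n_trees_grid)),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "boosted_config")
}

# Numeric design for the tree ensemble: protection one-hot, quartile bins as
# ordered integers, bioanthrome one-hot. Column groups remembered so split
# gains can be re-aggregated per covariate.
boosted_design <- function(table) {
  covs <- covariate_names(table)
  prot_lev <- levels(table$protection)
  Xp <- sapply(prot_lev, function(l) as.numeric(table$protection == l))
  colnames(Xp) <- paste0("protection.", prot_lev)
  Xc <- sapply(covs, function(nm) as.numeric(table[[paste0(nm, "_bin")]]))
  colnames(Xc) <- covs
  ba_lev <- sort(unique(table$bioanthrome_id))
  Xb <- sapply(ba_lev, function(l) as.numeric(table$bioanthrome_id == l))
  colnames(Xb) <- paste0("bioanthrome.", ba_lev)
  X <- cbind(Xp, Xc, Xb)
  groups <- c(rep("protection", ncol(Xp)), covs,
              rep("bioanthrome", ncol(Xb)))
  names(groups) <- colnames(X)
  list(X = X, groups = groups, prot_levels = prot_lev)
}

#' Fit the boosted model of percent species lost
#'
#' Squared-error gradient boosting of depth-limited regression trees on
#' protection category plus the binned covariates and bioanthrome
#' indicators. The intercept is the training mean; the reported
#' `best_iteration` minimizes the cross-validated RMSE over seeded folds,
#' capped at the largest candidate tree count; the final ensemble is
#' truncated there.
#'
#' @param table A `pixel_table`.
#' @param config A [boosted_config()].
#' @return A `boosted_model`: list with the fitted booster, `best_iteration`,
#'   `cv_curve` (per-iteration train/test RMSE), `relative_influence`
#'   (percentages summing to 100), `design` bookkeeping, and `intercept`.
#' @export
fit_boosted <- function(table, config = boosted_config()) {
  if (nrow(table) < 2L * config$cv_folds)
    stop("too few rows for the requested folds", call. = FALSE)
  des <- boosted_design(table)
  y <- table$outcome_pct_lost
  n_max <- max(config$n_trees_grid)

  params <- list(max_depth = config$max_depth, eta = config$learning_rate,
                 objective = "reg:squarederror", nthread = 1,
                 subsample = 1, colsample_bytree = 1,
                 base_score = mean(y), lambda = 0, min_child_weight = 1)

  if (stats::var(y) == 0) {
    # constant outcome: intercept-only model
    model <- NULL
    best <- 0L
    cv_curve <- data.frame(iter = integer(0), train_rmse = numeric(0),
                           test_rmse = numeric(0))
    ri <- stats::setNames(rep(0, length(unique(des$groups))),
                          unique(des$groups))
    warning("constant outcome: returning intercept-only model")
    return(structure(list(booster = model, best_iteration = best,
                          cv_curve = cv_curve, relative_influence = ri,
                          design = des, intercept = mean(y),
                          config = config),
                     class = "boosted_model"))
  }

  dtrain <- xgboost::xgb.DMatrix(des$X, label = y)
  set.seed(config$seed)
  cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = n_max,
                        nfold = config$cv_folds, verbose = 0,
                        early_stopping_rounds = NULL)
  log <- cv$evaluation_log
  best <- which.min(log$test_rmse_mean)

  set.seed(config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = best, verbose = 0)

  imp <- xgboost::xgb.importance(model = booster)
  gains <- stats::setNames(rep(0, length(unique(des$groups))),
                           unique(des$groups))
  if (!is.null(imp) && nrow(imp)) {
    g <- tapply(imp$Gain, des$groups[imp$Feature], sum)
    gains[names(g)] <- g
    gains <- 100 * gains / sum(gains)
  }

  structure(list(booster = booster, best_iteration = best,
                 cv_curve = data.frame(iter = log$iter,
                                       train_rmse = log$train_rmse_mean,
                                       test_rmse = log$test_rmse_mean),
                 relative_influence = gains, design = des,
                 intercept = mean(y), config = config),
            class = "boosted_model")
}

predict_boosted <- function(model, X) {
  if (is.null(model$booster)) return(rep(model$intercept, nrow(X)))
  stats::predict(model$booster, xgboost::xgb.DMatrix(X))
}

#' Partial-dependence marginal effect of protection
#'
#' For each protection level, every unit's protection indicator is forced to
#' that level (all other covariates as observed), the model predicts, and
#' predictions are averaged: the partial-dependence mean of predicted
#' percent species lost per level.
#'
#' @param model A `boosted_model`.
#' @param table The `pixel_table` to average over.
#' @return Named numeric vector, one partial-dependence mean per protection
#'   level (NEVER, BUFFER, P15, P70).
#' @export
marginal_effects <- function(model, table) {
  des <- boosted_design(table)
  X <- des$X
  prot_cols <- paste0("protection.", model$design$prot_levels)
  out <- stats::setNames(numeric(length(prot_cols)),
                         model$design$prot_levels)
  for (l in model$design$prot_levels) {
    Xl <- X
    Xl[, prot_cols] <- 0
    Xl[, paste0("protection.", l)] <- 1
    out[l] <- mean(predict_boosted(model, Xl))
  }
  out
}

#' Relative influence of covariates in a boosted model
#'
#' The per-covariate sum of squared-error reductions across all splits in
#' the ensemble, normalized to percentages summing to 100. Indicator
#' columns (protection levels, bioanthromes) are aggregated back to their
#' parent covariate.
#'
#' @param model A `boosted_model`.
#' @return Named numeric percentages (sum 100; all zero for an
#'   intercept-only model, with a warning).
#' @export
relative_influence <- function(model) {
  ri <- model$relative_influence
  if (all(ri == 0)) warning("intercept-only model: no splits, influence 0")
  ri
}
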
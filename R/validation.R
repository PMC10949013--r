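# Internal/external validation statistics, Y-randomization, and the
# Williams-plot applicability domain.

#' Coefficient of determination
#'
#' \code{1 - SSres/SStot} around the mean of the observed values.
#'
#' @param y_obs,y_pred numeric vectors of equal length (>= 2).
#' @export
r2 <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2)
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst == 0) stop("zero variance in y_obs", call. = FALSE)
  1 - sum((y_obs - y_pred)^2) / sst
}

#' External predictivity Q2_F1
#'
#' Test-set squared error normalized by deviation from the *training* mean.
#'
#' @param y_test_obs,y_test_pred test-set observed and predicted values.
#' @param y_train_mean mean of the training responses.
#' @export
q2_f1 <- function(y_test_obs, y_test_pred, y_train_mean) {
  stopifnot(length(y_test_obs) == length(y_test_pred), length(y_test_obs) >= 2)
  den <- sum((y_test_obs - y_train_mean)^2)
  if (den == 0) stop("zero denominator in Q2F1", call. = FALSE)
  1 - sum((y_test_obs - y_test_pred)^2) / den
}

#' External predictivity Q2_F2
#'
#' As \code{\link{q2_f1}} but normalized by deviation from the *test* mean;
#' always <= Q2F1.
#'
#' @inheritParams q2_f1
#' @export
q2_f2 <- function(y_test_obs, y_test_pred) {
  stopifnot(length(y_test_obs) == length(y_test_pred), length(y_test_obs) >= 2)
  den <- sum((y_test_obs - mean(y_test_obs))^2)
  if (den == 0) stop("zero denominator in Q2F2", call. = FALSE)
  1 - sum((y_test_obs - y_test_pred)^2) / den
}

#' Leave-one-out cross-validated Q2
#'
#' Refits the model n times leaving one point out each time (the feature
#' set is held fixed; no re-selection inside the loop) and returns
#' \code{1 - PRESS/SStot}.
#'
#' @inheritParams fit_mlr
#' @param model_kind \code{"MLR"} or \code{"PLS"}.
#' @param n_latent latent variables for the PLS path.
#' @export
q2_loo <- function(table, response, features, model_kind = c("MLR", "PLS"),
                   n_latent = length(features)) {
  model_kind <- match.arg(model_kind)
  n <- nrow(table)
  stopifnot(n >= 3)
  y <- table[[response]]
  press <- 0
  for (i in seq_len(n)) {
    fold <- table[-i, , drop = FALSE]
    m <- tryCatch(
      if (model_kind == "MLR") fit_mlr(fold, response, features)
      else fit_pls(fold, response, features, n_latent),
      error = function(e) stop("LOO refit failed on fold ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    press <- press + (y[i] - predict(m, table[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Roy's modified-r2 metrics (rm2 mean and delta)
#'
#' rm2 = r2 * (1 - sqrt(r2 - r0^2)) where r0^2 comes from the
#' through-origin regression of predicted on observed; rm2' swaps the
#' roles. Both orientations are computed on min-max scaled values (the
#' metric's standard recommendation; disable with \code{scale = FALSE})
#' and their mean and absolute difference returned.
#'
#' @inheritParams r2
#' @param scale min-max scale both series first (default TRUE).
#' @return named list with \code{rm2_mean} and \code{rm2_delta}.
#' @export
rm2_metrics <- function(y_obs, y_pred, scale = TRUE) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3)
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0) {
    stop("constant series in rm2", call. = FALSE)
  }
  if (scale) {
    mm <- function(v) (v - min(v)) / (max(v) - min(v))
    y_obs <- mm(y_obs); y_pred <- mm(y_pred)
  }
  one_rm2 <- function(yo, yp) {
    r2c <- stats::cor(yo, yp)^2
    k <- sum(yo * yp) / sum(yp^2)              # slope of yo ~ 0 + yp
    r02 <- 1 - sum((yo - k * yp)^2) / sum((yo - mean(yo))^2)
    rad <- r2c - r02
    if (rad < 0) {
      if (rad < -1e-8) warning("r2 < r0^2; radicand clamped at 0", call. = FALSE)
      rad <- 0
    }
    r2c * (1 - sqrt(rad))
  }
  a <- one_rm2(y_obs, y_pred)
  b <- one_rm2(y_pred, y_obs)
  list(rm2_mean = (a + b) / 2, rm2_delta = abs(a - b))
}

#' Overall F statistic from R2
#'
#' \code{(R2/p) / ((1-R2)/(n-p-1))} with its p-value. For PLS models the
#' latent-variable count is the conventional choice of p here (it
#' reproduces published single-LV F values); the descriptor count is the
#' alternative. R2 = 1 returns \code{Inf} with p-value 0.
#'
#' @param r2 determination coefficient.
#' @param n number of training observations.
#' @param p degrees of freedom of the model (LVs or descriptors).
#' @return named list \code{f}, \code{p_value}, \code{df1}, \code{df2}.
#' @export
f_statistic <- function(r2, n, p) {
  stopifnot(n > p + 1)
  if (r2 >= 1) return(list(f = Inf, p_value = 0, df1 = p, df2 = n - p - 1))
  f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  list(f = f, p_value = stats::pf(f, p, n - p - 1, lower.tail = FALSE),
       df1 = p, df2 = n - p - 1)
}

#' Mean absolute error and root-mean-square error of prediction
#'
#' @inheritParams r2
#' @export
mae <- function(y_obs, y_pred) mean(abs(y_obs - y_pred))

#' @rdname mae
#' @export
rmsep <- function(y_obs, y_pred) sqrt(mean((y_obs - y_pred)^2))

#' Full validation report for one train/test evaluation
#'
#' Computes the training fit (R2, Q2_LOO, rm2 on the LOO predictions) and
#' external metrics (Q2F1, Q2F2, rm2, MAE, RMSEP) plus the F statistic and
#' the Golbraikh-Tropsha gate (R2 > 0.6 and Q2 > 0.5).
#'
#' @param train,test descriptor data.frames.
#' @inheritParams fit_mlr
#' @param model fitted \code{qspr_model} used for predictions; when NULL it
#'   is refit on \code{train}.
#' @param model_kind,n_latent refit controls when \code{model} is NULL.
#' @param f_convention \code{"lv"} (default, PLS latent variables) or
#'   \code{"descriptors"} for the F-statistic degrees of freedom.
#' @return named list (a \code{ValidationReport}).
#' @export
validation_report <- function(train, test, response, features, model = NULL,
                              model_kind = c("PLS", "MLR"),
                              n_latent = length(features),
                              f_convention = c("lv", "descriptors")) {
  model_kind <- match.arg(model_kind)
  f_convention <- match.arg(f_convention)
  if (is.null(model)) {
    model <- if (model_kind == "MLR") fit_mlr(train, response, features)
             else fit_pls(train, response, features, n_latent)
  }
  y_tr <- train[[response]]
  pred_tr <- predict(model, train)
  r2_tr <- r2(y_tr, pred_tr)
  q2 <- q2_loo(train, response, features, model_kind,
               if (is.na(model$n_latent)) length(features) else model$n_latent)
  p_f <- if (f_convention == "lv" && !is.na(model$n_latent)) model$n_latent
         else length(features)
  fst <- f_statistic(r2_tr, nrow(train), p_f)
  out <- list(r2 = r2_tr, q2_loo = q2, n_train = nrow(train),
              mae_train = mae(y_tr, pred_tr),
              s_train = stats::sd(y_tr - pred_tr),
              f_stat = fst$f, p_value = fst$p_value,
              f_convention = f_convention,
              gt_pass = (r2_tr > 0.6 && q2 > 0.5))
  if (!is.null(test) && nrow(test) >= 2) {
    y_te <- test[[response]]
    pred_te <- predict(model, test)
    rm2 <- rm2_metrics(y_te, pred_te)
    out <- c(out, list(q2_f1 = q2_f1(y_te, pred_te, mean(y_tr)),
                       q2_f2 = q2_f2(y_te, pred_te),
                       rm2_mean = rm2$rm2_mean, rm2_delta = rm2$rm2_delta,
                       mae_test = mae(y_te, pred_te),
                       rmsep = rmsep(y_te, pred_te),
                       n_test = nrow(test)))
  }
  out
}

#' Y-randomization test
#'
#' Shuffles the response with a seeded generator, refits, and returns the
#' distribution of permuted-model R2 together with the fraction of
#' permutations meeting or exceeding the true model's R2.
#'
#' @inheritParams fit_mlr
#' @param n_perm number of permutations (>= 10).
#' @param seed RNG seed.
#' @param model_kind,n_latent model controls as in \code{\link{q2_loo}}.
#' @return list with \code{r2_true}, \code{r2_perm} (vector), and
#'   \code{exceedance} (fraction of permuted R2 >= true R2).
#' @export
y_randomization <- function(table, response, features, n_perm = 100, seed = 1,
                            model_kind = c("MLR", "PLS"),
                            n_latent = length(features)) {
  stopifnot(n_perm >= 10)
  model_kind <- match.arg(model_kind)
  fit1 <- function(tab) {
    m <- if (model_kind == "MLR") fit_mlr(tab, response, features)
         else fit_pls(tab, response, features, n_latent)
    r2(tab[[response]], predict(m, tab))
  }
  r2_true <- fit1(table)
  set.seed(seed)
  r2_perm <- vapply(seq_len(n_perm), function(i) {
    tab <- table
    tab[[response]] <- sample(tab[[response]])
    fit1(tab)
  }, numeric(1))
  list(r2_true = r2_true, r2_perm = r2_perm,
       exceedance = mean(r2_perm >= r2_true))
}

#' Williams-plot applicability domain
#'
#' Leverages are hat values \code{h_i = x_i (X'X)^-1 x_i'} from the
#' training design (descriptor columns plus intercept; for PLS models the
#' descriptors, not the latent variables, span the domain). The warning
#' leverage is \code{h* = 3p/n} with p = number of modeled variables plus
#' one. Training points get cross-validated (LOO) standardized residuals,
#' standardized by the SD of the LOO residuals; evaluation points get plain
#' residuals standardized the same way. |standardized residual| > 3 flags a
#' response outlier; h > h* flags a structural outlier.
#'
#' @param model fitted \code{qspr_model}.
#' @param train training descriptor data.frame (must contain the response).
#' @param eval_table optional evaluation data.frame.
#' @param response response column name.
#' @return list (\code{LeverageReport}) with per-point data.frame
#'   \code{points} (id, set, h, std_residual, x_outlier, y_outlier) and
#'   \code{h_star}, \code{p}, \code{n}.
#' @export
williams <- function(model, train, eval_table = NULL, response) {
  feats <- names(model$coefficients)
  X <- cbind(1, as.matrix(train[, feats, drop = FALSE]))
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  XtXi <- tryCatch(solve(crossprod(X)),
                   error = function(e) stop("singular X'X in Williams analysis",
                                            call. = FALSE))
  h_tr <- rowSums((X %*% XtXi) * X)
  h_star <- 3 * p / n
  y <- train[[response]]
  resid_tr <- y - predict(model, train)
  # LOO residual shortcut e_i/(1-h_i) is exact for OLS; for PLS models the
  # raw-scale regression vector is used with the same formula as a
  # cross-validated approximation of the deleted residual.
  loo_resid <- resid_tr / (1 - pmin(h_tr, 1 - 1e-10))
  s_loo <- stats::sd(loo_resid)
  std_tr <- loo_resid / s_loo
  pts <- data.frame(id = if (!is.null(rownames(train))) rownames(train)
                         else as.character(seq_len(n)),
                    set = "train", h = h_tr, std_residual = std_tr,
                    stringsAsFactors = FALSE)
  if (!is.null(eval_table)) {
    Xe <- cbind(1, as.matrix(eval_table[, feats, drop = FALSE]))
    storage.mode(Xe) <- "double"
    h_ev <- rowSums((Xe %*% XtXi) * Xe)
    std_ev <- if (!is.null(response) && response %in% names(eval_table)) {
      (eval_table[[response]] - predict(model, eval_table)) / s_loo
    } else rep(NA_real_, nrow(Xe))
    pts <- rbind(pts, data.frame(
      id = if (!is.null(rownames(eval_table))) rownames(eval_table)
           else paste0("eval_", seq_len(nrow(Xe))),
      set = "eval", h = h_ev, std_residual = std_ev,
      stringsAsFactors = FALSE))
  }
  pts$x_outlier <- pts$h > h_star
  pts$y_outlier <- !is.na(pts$std_residual) & abs(pts$std_residual) > 3
  list(points = pts, h_star = h_star, p = p, n = n)
}
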
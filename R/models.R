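# MLR and PLS model fitting on descriptor tables, plus the two frozen
# published models. Both fit paths expose a raw-scale intercept +
# coefficient vector so predictions never depend on internal scaling.

new_qspr_model <- function(kind, intercept, coefficients, n_latent = NA_integer_,
                           scaling = NULL, training_ids = NULL, source = "fit") {
  structure(list(kind = kind, intercept = intercept,
                 coefficients = coefficients, n_latent = n_latent,
                 scaling = scaling, training_ids = training_ids,
                 source = source),
            class = "qspr_model")
}

#' @export
print.qspr_model <- function(x, ...) {
  cat("<qspr_model>", x$kind,
      if (!is.na(x$n_latent)) paste0("(", x$n_latent, " LV)"), "\n")
  cat("  intercept:", format(x$intercept), "\n")
  for (nm in names(x$coefficients)) {
    cat("  ", nm, ": ", format(x$coefficients[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

check_design <- function(table, response, features) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(c(response, features), names(table))
  if (length(missing) > 0) {
    stop("columns missing from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite descriptor values", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant-valued feature(s): ",
         paste(features[sds == 0], collapse = ", "), call. = FALSE)
  }
  X
}

#' Fit an ordinary least squares model on raw descriptors
#'
#' @param table descriptor data.frame.
#' @param response name of the response column.
#' @param features character vector of descriptor column names.
#' @return a \code{qspr_model}.
#' @export
fit_mlr <- function(table, response, features) {
  X <- check_design(table, response, features)
  y <- table[[response]]
  n <- nrow(X); p <- ncol(X)
  # n = p + 1 is exact interpolation (e.g. a line through two points);
  # anything smaller is underdetermined
  if (n < p + 1) stop("need n_rows >= n_features + 1", call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_fit <- qr(Xi)
  if (qr_fit$rank < ncol(Xi)) {
    drop_idx <- qr_fit$pivot[(qr_fit$rank + 1):ncol(Xi)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(Xi)[drop_idx], collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_fit, y)
  new_qspr_model("MLR", unname(beta[1]),
                 stats::setNames(beta[-1], features),
                 training_ids = rownames(table))
}

#' Fit a single-response PLS model (NIPALS)
#'
#' X is autoscaled (training mean/SD), y mean-centered; components are
#' extracted by NIPALS with deflation on X only. For one response the
#' component directions are deterministic (no iteration needed). The
#' fitted model is stored as the equivalent raw-scale regression vector,
#' so \code{predict} is identical in form to the MLR path. With
#' \code{n_latent} equal to the number of (linearly independent) features,
#' PLS predictions coincide with OLS.
#'
#' @inheritParams fit_mlr
#' @param n_latent number of latent variables, capped at the design rank
#'   (with a warning) if it exceeds it.
#' @export
fit_pls <- function(table, response, features, n_latent) {
  X <- check_design(table, response, features)
  y <- table[[response]]
  p <- ncol(X)
  stopifnot(n_latent >= 1)
  rank_x <- qr(scale(X))$rank
  if (n_latent > rank_x) {
    warning("n_latent = ", n_latent, " exceeds design rank ", rank_x,
            "; capped", call. = FALSE)
    n_latent <- rank_x
  }
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd); my <- mean(y)
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  ys <- y - my
  E <- Xs; f <- ys
  W <- matrix(0, p, n_latent); P <- matrix(0, p, n_latent)
  qv <- numeric(n_latent)
  for (a in seq_len(n_latent)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) { n_latent <- a - 1L; break }
    w <- w / wn
    t_sc <- drop(E %*% w)
    tt <- sum(t_sc^2)
    p_load <- drop(crossprod(E, t_sc)) / tt
    q <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - q * t_sc   # y residual drives the next component
    W[, a] <- w; P[, a] <- p_load; qv[a] <- q
  }
  if (n_latent < 1) stop("no usable PLS component (X'y is zero)", call. = FALSE)
  W <- W[, seq_len(n_latent), drop = FALSE]
  P <- P[, seq_len(n_latent), drop = FALSE]
  qv <- qv[seq_len(n_latent)]
  beta_scaled <- drop(W %*% solve(crossprod(P, W), qv))
  beta_raw <- beta_scaled / sx
  intercept <- my - sum(beta_raw * mx)
  new_qspr_model("PLS", intercept, stats::setNames(beta_raw, features),
                 n_latent = as.integer(n_latent),
                 scaling = list(x_mean = mx, x_sd = sx, y_mean = my),
                 training_ids = rownames(table))
}

#' Predict from a fitted or published model
#'
#' @param object \code{qspr_model}.
#' @param newdata data.frame containing every model feature.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.qspr_model <- function(object, newdata, ...) {
  feats <- names(object$coefficients)
  missing <- setdiff(feats, names(newdata))
  if (length(missing) > 0) {
    stop("columns missing from newdata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite descriptor values", call. = FALSE)
  unname(drop(object$intercept + X %*% object$coefficients))
}

#' The two frozen published models
#'
#' \code{"model1"} predicts zeta potential (mV) from chi_ox,
#' tot_metal_alpha and the valence electron potential; \code{"model2"}
#' predicts the cell-damage response from eight descriptors including
#' exposure time and (measured or imputed) zeta potential. Coefficients are
#' carried verbatim at the published precision, on the raw measurement
#' scale.
#'
#' @param which \code{"model1"} or \code{"model2"}.
#' @export
published_model <- function(which = c("model1", "model2")) {
  which <- match.arg(which)
  if (which == "model1") {
    new_qspr_model("PLS", 35.9157,
                   c(chi_ox = -8.4317, tot_metal_alpha = 2.0002, vep = -0.1854),
                   n_latent = 1L, source = "published")
  } else {
    new_qspr_model("PLS", -1.681,
                   c(sum_chi_per_nO = -1.11, sq_sum_epsilon_N = 0.295,
                     d1_metal = 0.318, metal_alpha = -0.263,
                     time_h = 0.035, zeta_mv = 0.00057,
                     electrons_active_m = 0.0057, valence = -0.079),
                   n_latent = 7L, source = "published")
  }
}

#' Forward-backward stepwise feature selection by partial F
#'
#' Classic stepwise regression: at each cycle the candidate with the
#' largest partial F above \code{f_enter} is added, then any included
#' feature whose partial F drops below \code{f_remove} is removed.
#' Deterministic given the table; ties break on column order.
#'
#' @inheritParams fit_mlr
#' @param f_enter,f_remove F-to-enter and F-to-remove (defaults 4 and 3.9).
#' @return character vector of selected features (possibly empty, with a
#'   warning).
#' @export
stepwise_select <- function(table, response, features, f_enter = 4, f_remove = 3.9) {
  stopifnot(f_enter > f_remove)
  y <- table[[response]]
  n <- length(y)
  sel <- character(0)
  sst <- sum((y - mean(y))^2)
  eps <- 1e-12 * sst   # improvements below this are numerical noise
  rss_of <- function(feats) {
    if (length(feats) == 0) return(sst)
    X <- cbind(1, as.matrix(table[, feats, drop = FALSE]))
    sum(qr.resid(qr(X), y)^2)
  }
  partial_f <- function(rss_small, rss_big, df_resid_big) {
    num <- max(rss_small - rss_big, 0)
    if (num <= eps) return(0)
    num / (max(rss_big, eps) / df_resid_big)
  }
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    if (cycles > 100L) break   # safety against enter/remove oscillation
    changed <- FALSE
    # forward step
    cand <- setdiff(features, sel)
    if (length(cand) > 0) {
      rss0 <- rss_of(sel)
      fs <- vapply(cand, function(fe) {
        feats <- c(sel, fe)
        partial_f(rss0, rss_of(feats), n - length(feats) - 1)
      }, numeric(1))
      if (max(fs) > f_enter) {
        sel <- c(sel, cand[which.max(fs)])
        changed <- TRUE
      }
    }
    # backward step
    if (length(sel) > 1) {
      rss_full <- rss_of(sel)
      fs <- vapply(sel, function(fe) {
        partial_f(rss_of(setdiff(sel, fe)), rss_full, n - length(sel) - 1)
      }, numeric(1))
      if (min(fs) < f_remove) {
        sel <- setdiff(sel, sel[which.min(fs)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(sel) == 0) warning("no feature passed f_enter", call. = FALSE)
  sel
}

#' Serialize a model to JSON
#'
#' @param model \code{qspr_model}.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(kind = model$kind, intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              n_latent = model$n_latent, source = model$source)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
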
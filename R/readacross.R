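# Similarity-based read-across: Euclidean-distance, Gaussian-kernel and
# Laplacian-kernel weighting over autoscaled descriptors, with a grid
# optimizer for the four hyperparameters.

#' Read-across configuration
#'
#' @param method \code{"ED"} (inverse Euclidean distance), \code{"GK"}
#'   (Gaussian kernel) or \code{"LK"} (Laplacian kernel).
#' @param sigma Gaussian kernel width (> 0); default 1.75.
#' @param gamma Laplacian kernel rate (> 0); default 1.75.
#' @param distance_threshold maximum distance (in autoscaled descriptor
#'   units) for a training point to be an eligible neighbor; default 1.
#' @param similarity_threshold minimum similarity for eligibility;
#'   default 0.
#' @param n_neighbors maximum number of (most similar) neighbors used;
#'   default 10.
#' @return list of class \code{ra_config}.
#' @export
ra_config <- function(method = c("ED", "GK", "LK"), sigma = 1.75, gamma = 1.75,
                      distance_threshold = 1, similarity_threshold = 0,
                      n_neighbors = 10) {
  method <- match.arg(method)
  stopifnot(sigma > 0, gamma > 0, distance_threshold >= 0,
            similarity_threshold >= 0, n_neighbors >= 1)
  structure(list(method = method, sigma = sigma, gamma = gamma,
                 distance_threshold = distance_threshold,
                 similarity_threshold = similarity_threshold,
                 n_neighbors = n_neighbors),
            class = "ra_config")
}

#' Kernel similarity between two autoscaled descriptor vectors
#'
#' With d the Euclidean distance: ED gives \code{1/(1+d)}, GK gives
#' \code{exp(-d^2/(2 sigma^2))}, LK gives \code{exp(-gamma d)}. All three
#' equal 1 iff d = 0 and decrease strictly in d.
#'
#' @param x_query,x_train numeric vectors of equal length (already scaled
#'   by the training statistics).
#' @param config \code{ra_config}.
#' @export
similarity <- function(x_query, x_train, config) {
  if (length(x_query) != length(x_train)) {
    stop("dimension mismatch in similarity", call. = FALSE)
  }
  d <- sqrt(sum((x_query - x_train)^2))
  similarity_from_distance(d, config)
}

similarity_from_distance <- function(d, config) {
  switch(config$method,
         ED = 1 / (1 + d),
         GK = exp(-d^2 / (2 * config$sigma^2)),
         LK = exp(-config$gamma * d))
}

#' Read-across prediction
#'
#' Descriptors are autoscaled by the training mean/SD. For each query the
#' eligible neighbors are the training points with distance <=
#' \code{distance_threshold} and similarity >= \code{similarity_threshold},
#' truncated to the \code{n_neighbors} most similar; the prediction is the
#' similarity-weighted mean of their responses. Queries with no eligible
#' neighbor fall back to the training mean and are flagged.
#'
#' @param query_table,train_table descriptor data.frames.
#' @param response response column name in \code{train_table}.
#' @param features descriptor columns used for similarity.
#' @param config \code{ra_config}.
#' @return list with \code{predictions} (numeric), \code{fallback}
#'   (logical), and \code{neighbors} (data.frame: query_id, neighbor_id,
#'   distance, similarity, weight).
#' @export
ra_predict <- function(query_table, train_table, response, features, config) {
  stopifnot(nrow(train_table) > 0)
  Xtr <- as.matrix(train_table[, features, drop = FALSE])
  Xq <- as.matrix(query_table[, features, drop = FALSE])
  storage.mode(Xtr) <- "double"; storage.mode(Xq) <- "double"
  mx <- colMeans(Xtr); sx <- apply(Xtr, 2, stats::sd)
  sx[sx == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mx), 2, sx, "/")
  Xq <- sweep(sweep(Xq, 2, mx), 2, sx, "/")
  y <- train_table[[response]]
  ybar <- mean(y)
  nq <- nrow(Xq)
  preds <- numeric(nq); fallback <- logical(nq)
  nb <- vector("list", nq)
  tr_ids <- if (!is.null(rownames(train_table))) rownames(train_table)
            else as.character(seq_len(nrow(Xtr)))
  q_ids <- if (!is.null(rownames(query_table))) rownames(query_table)
           else as.character(seq_len(nq))
  for (i in seq_len(nq)) {
    d <- sqrt(rowSums(sweep(Xtr, 2, Xq[i, ])^2))
    s <- similarity_from_distance(d, config)
    ok <- which(d <= config$distance_threshold & s >= config$similarity_threshold)
    if (length(ok) == 0) {
      preds[i] <- ybar; fallback[i] <- TRUE
      next
    }
    ok <- ok[order(s[ok], decreasing = TRUE)]
    ok <- ok[seq_len(min(length(ok), config$n_neighbors))]
    w <- s[ok] / sum(s[ok])
    preds[i] <- sum(w * y[ok])
    nb[[i]] <- data.frame(query_id = q_ids[i], neighbor_id = tr_ids[ok],
                          distance = d[ok], similarity = s[ok], weight = w,
                          stringsAsFactors = FALSE)
  }
  neighbors <- if (any(!vapply(nb, is.null, logical(1)))) {
    do.call(rbind, nb[!vapply(nb, is.null, logical(1))])
  } else {
    data.frame(query_id = character(0), neighbor_id = character(0),
               distance = numeric(0), similarity = numeric(0),
               weight = numeric(0))
  }
  rownames(neighbors) <- NULL
  list(predictions = preds, fallback = fallback, neighbors = neighbors)
}

#' Grid optimization of read-across hyperparameters
#'
#' Splits the training table 70/30 (seeded shuffle) into sub-training and
#' sub-test sets and exhaustively searches the grid, maximizing Q2F1 of the
#' sub-test predictions. Ties break on grid order (first wins), so the
#' search is deterministic given the seed.
#'
#' @inheritParams ra_predict
#' @param grid data.frame of candidate hyperparameters; columns among
#'   sigma, gamma, distance_threshold, similarity_threshold, n_neighbors
#'   (absent columns take the \code{ra_config} defaults).
#' @param methods which similarity methods to tune.
#' @param seed RNG seed for the sub-split.
#' @return named list (per method) of \code{list(config, q2f1)}.
#' @export
optimize_hyperparams <- function(train_table, response, features, grid,
                                 methods = c("ED", "GK", "LK"), seed = 1) {
  stopifnot(nrow(grid) > 0)
  set.seed(seed)
  n <- nrow(train_table)
  idx <- sample(n)
  n_sub <- floor(0.7 * n)
  if (n - n_sub < 2) stop("degenerate sub-test set (< 2 points)", call. = FALSE)
  sub_tr <- train_table[idx[seq_len(n_sub)], , drop = FALSE]
  sub_te <- train_table[idx[(n_sub + 1):n], , drop = FALSE]
  defaults <- unclass(ra_config())
  out <- list()
  for (m in methods) {
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      args <- defaults
      for (col in intersect(names(grid), names(defaults))) {
        args[[col]] <- grid[[col]][g]
      }
      cfg <- ra_config(method = m, sigma = args$sigma, gamma = args$gamma,
                       distance_threshold = args$distance_threshold,
                       similarity_threshold = args$similarity_threshold,
                       n_neighbors = args$n_neighbors)
      pr <- ra_predict(sub_te, sub_tr, response, features, cfg)
      q <- q2_f1(sub_te[[response]], pr$predictions, mean(sub_tr[[response]]))
      if (is.null(best) || q > best$q2f1) best <- list(config = cfg, q2f1 = q)
    }
    out[[m]] <- best
  }
  out
}
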
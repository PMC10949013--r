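# Full two-stage analysis: descriptors -> zeta model -> imputation ->
# damage model -> validation, applicability domain, read-across, and the
# zeta-ablation comparison. Every stage is an exported function; run_full
# orchestrates them and (optionally) writes deterministic CSV/JSON output.

model1_features <- function() c("chi_ox", "tot_metal_alpha", "vep")

model2_features <- function() c("sum_chi_per_nO", "sq_sum_epsilon_N",
                                "d1_metal", "metal_alpha", "time_h",
                                "zeta_mv", "electrons_active_m", "valence")

#' Pipeline configuration
#'
#' @param dataset1,dataset2 data.frames (or CSV paths) with the zeta and
#'   cell-damage tables. Required columns: \code{formula} plus
#'   \code{zeta_mv} (dataset 1) and \code{damage}, \code{time_h}
#'   (dataset 2); optional \code{set_label} with values train/test.
#' @param split_mode \code{"from_file"} (use \code{set_label}; error if
#'   absent) or \code{"seeded_random"} (seeded 7:3 split).
#' @param model_source \code{"refit"} (PLS refit on the training split;
#'   1 LV for the zeta model, 7 LV for the damage model) or
#'   \code{"published"} (frozen printed coefficients).
#' @param ra read-across settings: a list of \code{\link{ra_config}}s (one
#'   per method) or NULL to use defaults for ED, GK, LK.
#' @param output_dir directory for CSV/JSON artifacts (NULL = in-memory
#'   only).
#' @param seed RNG seed, recorded in all outputs.
#' @export
pipeline_config <- function(dataset1, dataset2,
                            split_mode = c("from_file", "seeded_random"),
                            model_source = c("refit", "published"),
                            ra = NULL, output_dir = NULL, seed = 1) {
  split_mode <- match.arg(split_mode)
  model_source <- match.arg(model_source)
  if (is.character(dataset1)) dataset1 <- utils::read.csv(dataset1, stringsAsFactors = FALSE)
  if (is.character(dataset2)) dataset2 <- utils::read.csv(dataset2, stringsAsFactors = FALSE)
  if (is.null(ra)) {
    ra <- list(ED = ra_config("ED"), GK = ra_config("GK"), LK = ra_config("LK"))
  }
  list(dataset1 = dataset1, dataset2 = dataset2, split_mode = split_mode,
       model_source = model_source, ra = ra, output_dir = output_dir,
       seed = seed)
}

#' Impute zeta potential into a descriptor table
#'
#' Rows whose \code{zeta_mv} is missing (or all rows, when the column is
#' absent) receive zeta-model predictions; measured values take precedence.
#' A \code{zeta_source} provenance column records measured/imputed.
#'
#' @param model1 fitted or published zeta model.
#' @param table2 descriptor table for the damage dataset.
#' @export
impute_zeta <- function(model1, table2) {
  if (!"zeta_mv" %in% names(table2)) table2$zeta_mv <- NA_real_
  miss <- is.na(table2$zeta_mv)
  table2$zeta_source <- ifelse(miss, "imputed", "measured")
  if (any(miss)) {
    table2$zeta_mv[miss] <- predict(model1, table2[miss, , drop = FALSE])
  }
  table2
}

ensure_split <- function(data, split_mode, seed) {
  if (split_mode == "from_file") {
    if (!"set_label" %in% names(data)) {
      stop("split_mode 'from_file' but no set_label column", call. = FALSE)
    }
    return(data)
  }
  set.seed(seed)
  data$set_label <- split_labels(nrow(data))
  data
}

#' Robust data-quality screen
#'
#' Flags numeric values more than 3 robust SDs (MAD) from the column
#' median — e.g. implausible zeta entries — without altering anything.
#'
#' @param data data.frame.
#' @param columns numeric columns to screen (default: all numeric).
#' @return data.frame (column, row, value) of flagged entries.
#' @export
data_quality_report <- function(data, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  out <- list()
  for (cl in columns) {
    v <- data[[cl]]
    med <- stats::median(v, na.rm = TRUE)
    rsd <- stats::mad(v, na.rm = TRUE)
    if (!is.finite(rsd) || rsd == 0) next
    bad <- which(!is.na(v) & abs(v - med) > 3 * rsd)
    if (length(bad) > 0) {
      out[[cl]] <- data.frame(column = cl, row = bad, value = v[bad],
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(column = character(0), row = integer(0),
                      value = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full two-stage analysis
#'
#' Stage sequence: descriptor tables for both datasets; train/test split;
#' zeta model (stage 1) with its validation report; zeta imputation into
#' the damage table; damage model (stage 2) with validation; the ablation
#' refit without the zeta descriptor; Williams applicability-domain
#' analysis of the damage model; read-across (ED/GK/LK) on the damage
#' dataset; and a robust data-quality screen. Any stage failure aborts
#' with the stage name.
#'
#' @param config from \code{\link{pipeline_config}}.
#' @return list (\code{PipelineResult}); see the vignette for the layout.
#' @export
run_full <- function(config) {
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("pipeline stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  d1 <- stage("split_dataset1",
              ensure_split(config$dataset1, config$split_mode, config$seed))
  d2 <- stage("split_dataset2",
              ensure_split(config$dataset2, config$split_mode, config$seed + 1L))
  t1 <- stage("descriptors_dataset1", descriptor_table(d1))
  t2 <- stage("descriptors_dataset2", descriptor_table(d2))
  tr1 <- t1[t1$set_label == "train", , drop = FALSE]
  te1 <- t1[t1$set_label == "test", , drop = FALSE]

  m1 <- stage("model1", {
    if (config$model_source == "published") published_model("model1")
    else fit_pls(tr1, "zeta_mv", model1_features(), n_latent = 1)
  })
  v1 <- stage("validate_model1",
              validation_report(tr1, te1, "zeta_mv", model1_features(),
                                model = m1,
                                n_latent = if (is.na(m1$n_latent)) 1 else m1$n_latent))

  t2 <- stage("impute_zeta", impute_zeta(m1, t2))
  tr2 <- t2[t2$set_label == "train", , drop = FALSE]
  te2 <- t2[t2$set_label == "test", , drop = FALSE]

  m2 <- stage("model2", {
    if (config$model_source == "published") published_model("model2")
    else fit_pls(tr2, "damage", model2_features(), n_latent = 7)
  })
  v2 <- stage("validate_model2",
              validation_report(tr2, te2, "damage", model2_features(),
                                model = m2,
                                n_latent = if (is.na(m2$n_latent)) 7 else m2$n_latent))

  abl_features <- setdiff(model2_features(), "zeta_mv")
  m2_abl <- stage("ablation_model", fit_pls(tr2, "damage", abl_features, n_latent = 7))
  v_abl <- stage("validate_ablation",
                 validation_report(tr2, te2, "damage", abl_features,
                                   model = m2_abl, n_latent = 7))

  wil <- stage("williams", williams(m2, tr2, te2, "damage"))

  ra_reports <- stage("readacross", {
    lapply(config$ra, function(cfg) {
      pr <- ra_predict(te2, tr2, "damage", model2_features(), cfg)
      list(config = cfg,
           q2_f1 = q2_f1(te2$damage, pr$predictions, mean(tr2$damage)),
           q2_f2 = q2_f2(te2$damage, pr$predictions),
           mae = mae(te2$damage, pr$predictions),
           rmsep = rmsep(te2$damage, pr$predictions),
           n_fallback = sum(pr$fallback),
           predictions = pr$predictions, neighbors = pr$neighbors)
    })
  })

  dq <- stage("data_quality",
              data_quality_report(d2, intersect(names(d2),
                                                c("damage", "zeta_mv"))))

  result <- list(seed = config$seed, model_source = config$model_source,
                 table1 = t1, table2 = t2, model1 = m1, model2 = m2,
                 ablation_model = m2_abl,
                 validation_model1 = v1, validation_model2 = v2,
                 validation_ablation = v_abl,
                 ablation_r2_drop = v2$r2 - v_abl$r2,
                 williams = wil, readacross = ra_reports,
                 data_quality = dq)
  if (!is.null(config$output_dir)) write_pipeline_result(result, config$output_dir)
  result
}

#' Write pipeline artifacts to disk
#'
#' Emits descriptor tables and Williams data as CSV and all reports/models
#' as JSON with pinned formatting, so identical results give
#' byte-identical files.
#'
#' @param result from \code{\link{run_full}}.
#' @param output_dir directory (created if absent).
#' @export
write_pipeline_result <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  wjson <- function(x, name) {
    jsonlite::write_json(x, file.path(output_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  wcsv(result$table1, "descriptors_dataset1.csv")
  wcsv(result$table2, "descriptors_dataset2.csv")
  wcsv(result$williams$points, "williams.csv")
  wcsv(result$data_quality, "data_quality.csv")
  write_model_json(result$model1, file.path(output_dir, "model1.json"))
  write_model_json(result$model2, file.path(output_dir, "model2.json"))
  reports <- list(seed = result$seed, model_source = result$model_source,
                  model1 = result$validation_model1,
                  model2 = result$validation_model2,
                  ablation = result$validation_ablation,
                  ablation_r2_drop = result$ablation_r2_drop,
                  williams_h_star = result$williams$h_star,
                  readacross = lapply(result$readacross, function(r) {
                    r[c("q2_f1", "q2_f2", "mae", "rmsep", "n_fallback")]
                  }))
  wjson(reports, "reports.json")
  ra_nb <- do.call(rbind, lapply(names(result$readacross), function(m) {
    nb <- result$readacross[[m]]$neighbors
    if (nrow(nb) > 0) cbind(method = m, nb) else NULL
  }))
  if (!is.null(ra_nb)) wcsv(ra_nb, "readacross_neighbors.csv")
  invisible(output_dir)
}
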
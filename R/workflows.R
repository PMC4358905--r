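# Build and predict workflows, retraining, and the stage-override registry.
#
# Both workflows share the same normalize and extract stage implementations
# recorded for the model, which guarantees that a query compound is
# submitted to exactly the protocol used for the training series. Any of
# the four named stages (normalize, extract, build, predict) can be
# replaced per tag; unregistered stages resolve to the built-ins and a
# model built or predicted through an override is flagged "custom".

STAGE_NAMES <- c("normalize", "extract", "build", "predict")

# per-session stage-override registry, keyed tag -> stage -> function
.stage_registry <- new.env(parent = emptyenv())

#' Register a stage override for a tag
#'
#' The replacement must honour the built-in stage's contract:
#' \describe{
#'   \item{normalize}{function(records, settings) -> records}
#'   \item{extract}{function(series, config) -> `DescriptorMatrix`}
#'   \item{build}{function(X, y, config) -> model object}
#'   \item{predict}{function(model, X_aligned) -> numeric predictions}
#' }
#' @param tag model tag
#' @param stage_name one of `"normalize"`, `"extract"`, `"build"`,
#'   `"predict"`
#' @param fun replacement function, or NULL to clear the override
#' @return invisibly, the previous override (or NULL)
#' @export
register_stage <- function(tag, stage_name, fun) {
  if (!stage_name %in% STAGE_NAMES)
    qstop("unknown stage '%s' (stages: %s)", stage_name,
          paste(STAGE_NAMES, collapse = ", "))
  key <- paste0(tag, ":", stage_name)
  prev <- if (exists(key, envir = .stage_registry))
    get(key, envir = .stage_registry) else NULL
  if (is.null(fun)) {
    if (!is.null(prev)) rm(list = key, envir = .stage_registry)
  } else assign(key, fun, envir = .stage_registry)
  invisible(prev)
}

#' Resolve a stage implementation for a tag
#'
#' @param tag model tag
#' @param stage_name stage to resolve
#' @return the registered override, or the built-in implementation
#' @export
resolve_stage <- function(tag, stage_name) {
  if (!stage_name %in% STAGE_NAMES)
    qstop("unknown stage '%s' (stages: %s)", stage_name,
          paste(STAGE_NAMES, collapse = ", "))
  key <- paste0(tag, ":", stage_name)
  if (exists(key, envir = .stage_registry))
    return(get(key, envir = .stage_registry))
  switch(stage_name,
         normalize = stage_normalize_builtin,
         extract = stage_extract_builtin,
         build = stage_build_builtin,
         predict = stage_predict_builtin)
}

has_override <- function(tag, stage_name)
  exists(paste0(tag, ":", stage_name), envir = .stage_registry)

# ---- built-in stage implementations ---------------------------------------

stage_normalize_builtin <- function(series, settings = list())
  normalize_series(series, settings)

stage_extract_builtin <- function(series, config)
  extract_descriptors(series,
                      embedded_fields = config$embedded_fields %||%
                        character(0))

# Fit scaling + PLS + LOO CV (+ optional FFD + discriminant cutoff) on the
# variance-masked descriptor matrix. Returns a PLSModel.
stage_build_builtin <- function(X, y, config) {
  n <- nrow(X); p_all <- ncol(X)
  var_names <- colnames(X)
  # near-constant variables would make autoscaling divide by ~0
  variances <- apply(X, 2L, stats::var)
  mask <- variances > 1e-12
  if (!any(mask)) qstop("all descriptor variables are (near-)constant")
  A_max <- min(config$A_max %||% 10L, n - 2L, sum(mask))
  scaling_mode <- config$scaling %||% "autoscale"
  seed <- config$seed %||% 1L

  cv <- loo_cv(X[, mask, drop = FALSE], y, A_max, scaling_mode)
  A_opt <- select_A_opt(cv$q2)

  ffd <- NULL
  if (isTRUE(config$ffd_enabled) && sum(mask) >= 4L) {
    ffd <- ffd_select(X[, mask, drop = FALSE], y, A_opt,
                      threshold_factor = config$ffd_threshold %||% 2.0,
                      seed = seed, scaling_mode = scaling_mode)
    if (ffd$applied && !all(ffd$mask)) {
      mask[which(mask)[!ffd$mask]] <- FALSE
      A_max <- min(A_max, sum(mask))
      cv <- loo_cv(X[, mask, drop = FALSE], y, A_max, scaling_mode)
      A_opt <- select_A_opt(cv$q2)
    }
  }

  Xm <- X[, mask, drop = FALSE]
  sc <- scale_fit(Xm, scaling_mode)
  y_mean <- mean(y)
  fit <- fit_pls(sc$Xs, y - y_mean, A_max)
  A_ach <- fit$A
  A_opt <- min(A_opt, A_ach)
  fitted <- sweep(sc$Xs %*% fit$b, 2L, -y_mean)  # n x A, fitted per A
  rss <- colSums((fitted - y)^2)
  tss <- sum((y - y_mean)^2)
  b_opt <- fit$b[, A_opt]
  coef_raw <- b_opt / sc$state$scales
  intercept_raw <- y_mean - sum(b_opt * sc$state$means / sc$state$scales)

  model <- list(
    W = fit$W, P = fit$P, c = fit$c, T = fit$T, b = fit$b,
    A_max = A_ach, A_opt = A_opt,
    r2 = 1 - rss / tss, SDEC = sqrt(rss / n),
    q2 = cv$q2[seq_len(A_ach)], SDEP = cv$SDEP[seq_len(A_ach)],
    loo_pred = cv$loo_pred[, seq_len(A_ach), drop = FALSE],
    scaling = sc$state, var_names = var_names, var_mask = mask,
    y_mean = y_mean, intercept_raw = intercept_raw,
    coefficients_raw = coef_raw,
    mode = if (identical(config$activity_type, "qualitative"))
      "discriminant" else "regression",
    descriptor_set_id = config$descriptor_set_id %||%
      BUILTIN_DESCRIPTOR_SET_ID,
    ffd = ffd,
    cutoff = NA_real_, sensitivity = NA_real_, specificity = NA_real_)
  class(model) <- "PLSModel"

  if (model$mode == "discriminant") {
    # cutoff from cross-validated scores at A_opt, not fitted scores, to
    # avoid an optimistic balance point
    ct <- estimate_cutoff(cv$loo_pred[, A_opt], y)
    model$cutoff <- ct$cutoff
    model$sensitivity <- ct$sensitivity
    model$specificity <- ct$specificity
  }
  model
}

stage_predict_builtin <- function(model, X_aligned) {
  sc <- scale_apply(X_aligned, model$scaling)
  as.numeric(sc %*% model$b[, model$A_opt] + model$y_mean)
}

#' Predict from a fitted PLS model
#'
#' @param object a `PLSModel`
#' @param newdata raw descriptor matrix aligned to the model's retained
#'   variables (see [align_to_model()])
#' @param A dimensionality (default the model's A_opt)
#' @param ... unused
#' @return numeric predictions
#' @export
predict.PLSModel <- function(object, newdata, A = object$A_opt, ...) {
  sc <- scale_apply(as.matrix(newdata), object$scaling)
  as.numeric(sc %*% object$b[, A] + object$y_mean)
}

# ---- configuration --------------------------------------------------------

default_build_config <- function() {
  list(activity_field = "activity", activity_type = "quantitative",
       label0 = "0", label1 = "1",
       scaling = "autoscale", A_max = 10L,
       embedded_fields = character(0),
       ffd_enabled = FALSE, ffd_threshold = 2.0,
       detect_training_copy = TRUE, confidential = FALSE,
       descriptor_set_id = BUILTIN_DESCRIPTOR_SET_ID,
       k_nn = 5L, seed = 1L)
}

#' Read a flat key=value build-configuration file
#'
#' Unknown keys are rejected; values are coerced to the defaults' types.
#' @param path config file (UTF-8, `key=value` lines, `#` comments)
#' @return named list merged over the defaults
#' @export
read_config_file <- function(path) {
  cfg <- default_build_config()
  if (is.null(path) || !file.exists(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) qstop("config line without '=': %s", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (!key %in% names(cfg)) qstop("unknown config key '%s'", key)
    cfg[[key]] <- coerce_config_value(cfg[[key]], val, key)
  }
  cfg
}

coerce_config_value <- function(template, val, key) {
  if (key == "embedded_fields")
    return(if (nzchar(val)) trimws(strsplit(val, ",")[[1]]) else character(0))
  if (is.logical(template)) {
    out <- as.logical(val)
    if (is.na(out)) qstop("config key '%s': not a logical: '%s'", key, val)
    return(out)
  }
  if (is.integer(template)) return(as.integer(val))
  if (is.numeric(template)) return(as.numeric(val))
  val
}

write_config_file <- function(cfg, path) {
  writeLines(vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, "=", if (length(v) > 1L) paste(v, collapse = ",")
           else as.character(v))
  }, character(1)), path)
  invisible(path)
}

# ---- build workflow --------------------------------------------------------

#' Build a model from an SDF training series
#'
#' Runs normalize, extract and build (scaling, PLS fit, LOO
#' cross-validation, optional FFD selection, dimensionality selection,
#' discriminant cutoff for qualitative series, applicability-domain fit)
#' and persists the result as version 0 of `tag`.
#'
#' @param tag model tag
#' @param sdf_path training SDF
#' @param config named list of build settings (see
#'   [read_config_file()] for keys); missing keys take defaults
#' @param root store root
#' @return a `BuildReport`: per-dimensionality quality table plus model
#'   summary, invisibly the fitted artifacts as attributes
#' @export
build_workflow <- function(tag, sdf_path, config = list(),
                           root = store_root()) {
  check_tag(tag)
  cfg <- utils::modifyList(default_build_config(), config)
  label_map <- stats::setNames(c(0, 1), c(cfg$label0, cfg$label1))
  series <- read_sdf(sdf_path, cfg$activity_field, cfg$activity_type,
                     label_map)
  n <- length(series$records)
  if (n < 5L) qstop("training series too small (n = %d, need >= 5)", n)
  if (cfg$activity_type == "qualitative" &&
      length(unique(series$activities)) < 2L)
    qstop("single-class qualitative series")

  series <- resolve_stage(tag, "normalize")(series, list())
  keys <- vapply(series$records, function(r) r$structure_key, character(1))
  dup <- which(duplicated(keys))
  if (length(dup) > 0L)
    message(sprintf("note: %d duplicate structure(s) in training series (records %s)",
                    length(dup), paste(dup, collapse = ", ")))

  dm <- resolve_stage(tag, "extract")(series, cfg)
  custom <- any(vapply(STAGE_NAMES, has_override, logical(1), tag = tag))
  model <- resolve_stage(tag, "build")(dm$values, series$activities, cfg)

  adan_state <- NULL
  if (inherits(model, "PLSModel") && n >= 10L) {
    Xm <- dm$values[, model$var_mask, drop = FALSE]
    Xs <- scale_apply(Xm, model$scaling)
    T_opt <- model$T[, seq_len(model$A_opt), drop = FALSE]
    loo_resid <- model$loo_pred[, model$A_opt] - series$activities
    adan_state <- fit_adan(Xs, T_opt, series$activities,
                           model$P[, seq_len(model$A_opt), drop = FALSE],
                           loo_resid, model$SDEP[model$A_opt],
                           k_nn = min(cfg$k_nn, n - 1L))
  }

  meta <- list(n_compounds = n, activity_type = cfg$activity_type,
               custom = custom, confidential = isTRUE(cfg$confidential))
  if (inherits(model, "PLSModel")) {
    meta$A_opt <- model$A_opt
    meta$r2_opt <- model$r2[model$A_opt]
    meta$q2_opt <- model$q2[model$A_opt]
    meta$SDEP_opt <- model$SDEP[model$A_opt]
  }

  if (isTRUE(cfg$confidential)) {
    if (!inherits(model, "PLSModel"))
      qstop("confidential mode requires the built-in PLS build stage")
    dir <- version_dir(root, tag, 0L)
    unlink(dir, recursive = TRUE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_config_file(cfg, file.path(dir, "config.txt"))
    writeLines(confidential_lines(model, tag),
               file.path(dir, "confidential.txt"), useBytes = TRUE)
    jsonlite::write_json(utils::modifyList(list(
      tag = tag, version = 0L,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), notes = ""), meta),
      file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    tag_log(root, tag, "saved confidential version 0")
  } else {
    cfg_flat <- cfg
    cfg_flat$embedded_fields <- paste(cfg$embedded_fields, collapse = ",")
    save_version(tag, 0L, model = model, adan_state = adan_state,
                 training_sdf = sdf_path, config = cfg_flat, meta = meta,
                 root = root)
  }

  report <- list(tag = tag, n = n, config = cfg, custom = custom)
  if (inherits(model, "PLSModel")) {
    report$quality <- data.frame(A = seq_len(model$A_max),
                                 r2 = model$r2, SDEC = model$SDEC,
                                 q2 = model$q2, SDEP = model$SDEP)
    report$A_opt <- model$A_opt
    report$mode <- model$mode
    if (model$mode == "discriminant") {
      report$cutoff <- model$cutoff
      report$sensitivity <- model$sensitivity
      report$specificity <- model$specificity
    }
    if (all(model$q2 < 0)) report$flag <- "no predictive model"
  }
  attr(report, "model") <- model
  attr(report, "adan_state") <- adan_state
  attr(report, "descriptors") <- dm
  attr(report, "series") <- series
  class(report) <- "BuildReport"
  report
}

#' @export
print.BuildReport <- function(x, ...) {
  cat(sprintf("Model '%s': n = %d, %s mode%s\n", x$tag, x$n,
              x$mode %||% "custom", if (x$custom) " [custom stages]" else ""))
  if (!is.null(x$quality)) {
    q <- x$quality
    q[, -1] <- round(q[, -1], 4)
    print(q, row.names = FALSE)
    cat(sprintf("A_opt = %d (q2 = %.4f, SDEP = %.4f)\n", x$A_opt,
                x$quality$q2[x$A_opt], x$quality$SDEP[x$A_opt]))
    if (!is.null(x$cutoff) && !is.na(x$cutoff))
      cat(sprintf("cutoff = %.4f (sensitivity %.3f, specificity %.3f)\n",
                  x$cutoff, x$sensitivity, x$specificity))
    if (!is.null(x$flag)) cat("warning:", x$flag, "\n")
  }
  invisible(x)
}

# ---- predict workflow ------------------------------------------------------

#' Predict a query SDF against a stored model version
#'
#' Queries are normalized and described by the same stage implementations
#' used at build time. When training-copy detection is enabled, a query
#' whose canonical structure key matches a training compound is reported
#' with its experimental value. ADAN category and 95% CI half-width are
#' attached (category NA and global-SDEP CI for confidential models).
#'
#' @param tag model tag
#' @param version stored version number
#' @param sdf_path query SDF (the activity field is not required)
#' @param root store root
#' @return data.frame of prediction results (one row per query compound)
#'   with attribute `mol_text` for SDF output
#' @export
predict_workflow <- function(tag, version, sdf_path, root = store_root()) {
  v <- load_version(tag, version, root)
  cfg <- v$config
  lines <- readLines(sdf_path, warn = FALSE)
  recs <- parse_sdf_records(lines)
  if (length(recs) == 0L) qstop("no records in %s", sdf_path)
  qseries <- structure(list(records = recs,
                            activities = rep(NA_real_, length(recs)),
                            activity_field = cfg$activity_field,
                            activity_type = cfg$activity_type),
                       class = "TrainingSeries")
  qseries <- resolve_stage(tag, "normalize")(qseries, list())
  dm <- resolve_stage(tag, "extract")(qseries, cfg)
  nq <- length(qseries$records)

  if (v$confidential) {
    cm <- v$confidential_model
    if (!identical(dm$descriptor_set_id, cm$descriptor_set_id))
      qstop("descriptor set mismatch: query '%s' vs model '%s'",
            dm$descriptor_set_id, cm$descriptor_set_id)
    y_pred <- predict(cm, dm$values)
    res <- data.frame(compound_id = dm$compound_ids, y_pred = y_pred,
                      is_training_copy = FALSE,
                      experimental_value = NA_real_,
                      adan_category = NA_integer_,
                      ci95 = 1.96 * cm$global_sdep,
                      stringsAsFactors = FALSE)
    if (cm$mode == "discriminant")
      res$class_pred <- as.integer(y_pred >= cm$cutoff)
    attr(res, "mol_text") <- vapply(qseries$records,
                                    function(r) r$mol_text, character(1))
    return(res)
  }

  model <- v$model
  Xq <- align_to_model(dm, model$var_names, model$var_mask,
                       model$descriptor_set_id)
  y_pred <- resolve_stage(tag, "predict")(model, Xq)

  adan_cat <- rep(NA_integer_, nq); ci <- rep(NA_real_, nq)
  if (!is.null(v$adan_state) && inherits(model, "PLSModel")) {
    Xs <- scale_apply(Xq, model$scaling)
    proj <- pls_project(Xs, model)
    Tq <- proj$T[, seq_len(model$A_opt), drop = FALSE]
    adan_cat <- adan_assess(Xs, Tq, v$adan_state)
    ci <- adan_ci95(adan_cat, v$adan_state)
  }

  is_copy <- rep(FALSE, nq); exp_val <- rep(NA_real_, nq)
  if (isTRUE(cfg$detect_training_copy) && !is.null(v$training_sdf)) {
    label_map <- stats::setNames(c(0, 1), c(cfg$label0, cfg$label1))
    tr <- read_sdf(v$training_sdf, cfg$activity_field, cfg$activity_type,
                   label_map)
    tr <- resolve_stage(tag, "normalize")(tr, list())
    for (i in seq_len(nq)) {
      hit <- find_in_training(qseries$records[[i]]$structure_key, tr)
      if (!is.na(hit)) {
        is_copy[i] <- TRUE
        exp_val[i] <- tr$activities[hit]
        y_pred[i] <- exp_val[i]  # report the experimental value
      }
    }
  }

  res <- data.frame(compound_id = dm$compound_ids, y_pred = y_pred,
                    is_training_copy = is_copy,
                    experimental_value = exp_val,
                    adan_category = adan_cat, ci95 = ci,
                    stringsAsFactors = FALSE)
  if (inherits(model, "PLSModel") && model$mode == "discriminant")
    res$class_pred <- as.integer(y_pred >= model$cutoff)
  attr(res, "mol_text") <- vapply(qseries$records,
                                  function(r) r$mol_text, character(1))
  res
}

# ---- retraining ------------------------------------------------------------

#' Retrain a model with additional compounds
#'
#' Concatenates the stored training series of the latest version holding a
#' training copy with the new SDF (duplicates by canonical structure key
#' are dropped with a warning, keeping the original record) and re-runs the
#' build workflow under the stored configuration, producing a fresh
#' version 0. Published versions are untouched.
#'
#' @param tag model tag
#' @param new_sdf_path SDF with the additional compounds
#' @param root store root
#' @return the `BuildReport` of the new sandbox build
#' @export
retrain <- function(tag, new_sdf_path, root = store_root()) {
  check_tag(tag)
  if (!dir.exists(file.path(root, tag))) qstop("unknown tag '%s'", tag)
  vs <- rev(list_version_numbers(root, tag))
  src <- NULL
  for (v in vs) {
    cand <- load_version(tag, v, root)
    if (!cand$confidential && !is.null(cand$training_sdf)) {
      src <- cand; break
    }
  }
  if (is.null(src))
    qstop("tag '%s' retains no training series (confidential-only); cannot retrain",
          tag)
  cfg <- src$config
  label_map <- stats::setNames(c(0, 1), c(cfg$label0, cfg$label1))
  old <- read_sdf(src$training_sdf, cfg$activity_field, cfg$activity_type,
                  label_map)
  new <- read_sdf(new_sdf_path, cfg$activity_field, cfg$activity_type,
                  label_map)
  old_n <- resolve_stage(tag, "normalize")(old, list())
  new_n <- resolve_stage(tag, "normalize")(new, list())
  old_keys <- vapply(old_n$records, function(r) r$structure_key, character(1))
  new_keys <- vapply(new_n$records, function(r) r$structure_key, character(1))
  dup <- new_keys %in% old_keys | duplicated(new_keys)
  if (any(dup))
    warning(sprintf("%d duplicate compound(s) dropped at retrain", sum(dup)),
            call. = FALSE)
  # concatenate the ORIGINAL (un-normalized) records so the stored training
  # copy keeps full provenance
  combined <- c(old$records, new$records[!dup])
  tmp <- tempfile(fileext = ".sdf")
  write_sdf(combined, tmp)
  build_workflow(tag, tmp, config = cfg, root = root)
}
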
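# Versioned on-disk model repository.
#
# Layout: <root>/<tag>/version-NNNN/ with version 0 as the development
# sandbox; publication copies the sandbox to the next sequential integer.
# Removed version numbers are never reused (forensic traceability): the
# next number is kept in <tag>/.next_version. Each version directory is a
# self-contained package: config, training-series copy, serialized model,
# applicability-domain state and a JSON metadata file. Confidential
# versions store a coefficient-only text file instead of model + training
# data.

CONFIDENTIAL_MAGIC <- "QSARKIT-CONFIDENTIAL 1"

#' Default model store root
#'
#' `getOption("qsarkit.store")` if set, else `"./models"`.
#' @return path
#' @export
store_root <- function() getOption("qsarkit.store", "./models")

check_tag <- function(tag) {
  if (!is_string(tag) || !grepl("^[A-Za-z0-9_-]+$", tag))
    qstop("invalid model tag '%s' (allowed: letters, digits, '_', '-')",
          as.character(tag))
  tag
}

version_dir <- function(root, tag, version)
  file.path(root, tag, sprintf("version-%04d", as.integer(version)))

tag_log <- function(root, tag, msg) {
  dir.create(file.path(root, tag), recursive = TRUE, showWarnings = FALSE)
  cat(sprintf("%s\t%s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg),
      file = file.path(root, tag, "log.txt"), append = TRUE)
}

list_version_numbers <- function(root, tag) {
  d <- list.dirs(file.path(root, tag), recursive = FALSE, full.names = FALSE)
  sort(as.integer(sub("^version-", "", d[grepl("^version-[0-9]{4}$", d)])))
}

#' Save model artifacts as a version
#'
#' Writes (or overwrites) a version directory containing the config, a copy
#' of the training SDF, the serialized model, the applicability-domain
#' state and a metadata file. Version 0 is the development sandbox; it is
#' the normal target of a build.
#'
#' @param tag model tag (`[A-Za-z0-9_-]+`)
#' @param version integer version (default 0)
#' @param model a fitted `PLSModel` (or custom model object)
#' @param adan_state an `ADANState` or NULL
#' @param training_sdf path to the training SDF to copy, or NULL
#' @param config named list of build settings
#' @param meta named list merged into the version metadata
#' @param root store root directory
#' @return invisibly, the version directory path
#' @export
save_version <- function(tag, version = 0L, model, adan_state = NULL,
                         training_sdf = NULL, config = list(),
                         meta = list(), root = store_root()) {
  check_tag(tag)
  dir <- version_dir(root, tag, version)
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(vapply(names(config), function(k)
    paste0(k, "=", as.character(config[[k]])), character(1)),
    file.path(dir, "config.txt"))
  if (!is.null(training_sdf))
    file.copy(training_sdf, file.path(dir, "training.sdf"), overwrite = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  if (!is.null(adan_state)) saveRDS(adan_state, file.path(dir, "adan.rds"))
  info <- utils::modifyList(list(
    tag = tag, version = as.integer(version),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    confidential = FALSE, custom = FALSE, notes = ""), meta)
  jsonlite::write_json(info, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tag_log(root, tag, sprintf("saved version %d", as.integer(version)))
  invisible(dir)
}

#' Load a stored model version
#'
#' @param tag model tag
#' @param version integer version
#' @param root store root
#' @return list with `model`, `adan_state`, `config`, `meta`,
#'   `training_sdf` (path or NULL), `confidential` flag and, for
#'   confidential versions, `confidential_model`
#' @export
load_version <- function(tag, version, root = store_root()) {
  dir <- version_dir(root, tag, version)
  if (!dir.exists(dir))
    qstop("model '%s' version %s not found", tag, as.character(version))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  conf_file <- file.path(dir, "confidential.txt")
  if (isTRUE(meta$confidential) || file.exists(conf_file)) {
    return(list(model = NULL,
                confidential_model = read_confidential(conf_file),
                adan_state = NULL, config = read_config_file(
                  file.path(dir, "config.txt")),
                meta = meta, training_sdf = NULL, confidential = TRUE))
  }
  adan_file <- file.path(dir, "adan.rds")
  tr <- file.path(dir, "training.sdf")
  list(model = readRDS(file.path(dir, "model.rds")),
       adan_state = if (file.exists(adan_file)) readRDS(adan_file) else NULL,
       config = read_config_file(file.path(dir, "config.txt")),
       meta = meta,
       training_sdf = if (file.exists(tr)) tr else NULL,
       confidential = FALSE)
}

#' Publish the sandbox as the next sequential version
#'
#' Copies version 0 to the next integer (1 if none published yet); version
#' 0 is retained and all previously published versions remain loadable.
#'
#' @param tag model tag
#' @param root store root
#' @return the new version number
#' @export
publish_version <- function(tag, root = store_root()) {
  check_tag(tag)
  sandbox <- version_dir(root, tag, 0L)
  if (!dir.exists(sandbox))
    qstop("no sandbox (version 0) to publish for tag '%s'", tag)
  counter_file <- file.path(root, tag, ".next_version")
  nxt <- if (file.exists(counter_file))
    as.integer(readLines(counter_file, n = 1L))
  else max(c(0L, list_version_numbers(root, tag))) + 1L
  dest <- version_dir(root, tag, nxt)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  file.copy(list.files(sandbox, full.names = TRUE), dest, overwrite = TRUE)
  # published metadata carries its own version number
  meta <- jsonlite::read_json(file.path(dest, "meta.json"),
                              simplifyVector = TRUE)
  meta$version <- nxt
  jsonlite::write_json(meta, file.path(dest, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(as.character(nxt + 1L), counter_file)
  tag_log(root, tag, sprintf("published version %d", nxt))
  nxt
}

#' List all versions of a tag
#'
#' @param tag model tag
#' @param root store root
#' @return data.frame of `ModelVersionInfo`, sorted by version
#' @export
list_versions <- function(tag, root = store_root()) {
  check_tag(tag)
  if (!dir.exists(file.path(root, tag))) qstop("unknown tag '%s'", tag)
  vs <- list_version_numbers(root, tag)
  if (length(vs) == 0L) qstop("tag '%s' has no versions", tag)
  rows <- lapply(vs, function(v) {
    m <- jsonlite::read_json(file.path(version_dir(root, tag, v),
                                       "meta.json"), simplifyVector = TRUE)
    data.frame(tag = tag, version = v,
               created = m$created %||% NA_character_,
               n_compounds = as.integer(m$n_compounds %||% NA),
               activity_type = m$activity_type %||% NA_character_,
               A_opt = as.integer(m$A_opt %||% NA),
               r2_opt = as.numeric(m$r2_opt %||% NA),
               q2_opt = as.numeric(m$q2_opt %||% NA),
               SDEP_opt = as.numeric(m$SDEP_opt %||% NA),
               confidential = isTRUE(m$confidential),
               custom = isTRUE(m$custom),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove a stored version
#'
#' Version numbers of removed versions are never reassigned.
#' @param tag model tag
#' @param version version to delete
#' @param root store root
#' @return invisibly TRUE
#' @export
remove_version <- function(tag, version, root = store_root()) {
  check_tag(tag)
  dir <- version_dir(root, tag, version)
  if (!dir.exists(dir))
    qstop("model '%s' version %s not found", tag, as.character(version))
  vs <- list_version_numbers(root, tag)
  if (identical(vs, as.integer(version)))
    qstop("refusing to remove the only remaining version")
  unlink(dir, recursive = TRUE)
  tag_log(root, tag, sprintf("removed version %d", as.integer(version)))
  invisible(TRUE)
}

#' Export a version as a single archive
#'
#' @param tag model tag
#' @param version version to export
#' @param dest destination archive path (tar)
#' @param root store root
#' @return invisibly `dest`
#' @export
export_version <- function(tag, version, dest, root = store_root()) {
  dir <- version_dir(root, tag, version)
  if (!dir.exists(dir))
    qstop("model '%s' version %s not found", tag, as.character(version))
  old <- setwd(dir); on.exit(setwd(old))
  utils::tar(file.path(normalizePath(dirname(dest), mustWork = FALSE),
                       basename(dest)),
             files = ".", tar = "internal")
  invisible(dest)
}

#' Import an exported version archive
#'
#' @param archive archive produced by [export_version()]
#' @param tag destination tag
#' @param version destination version number
#' @param root store root
#' @return invisibly the version directory
#' @export
import_version <- function(archive, tag, version, root = store_root()) {
  check_tag(tag)
  dir <- version_dir(root, tag, version)
  if (dir.exists(dir)) qstop("destination version already exists")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::untar(archive, exdir = dir, tar = "internal")
  tag_log(root, tag, sprintf("imported version %d from %s",
                             as.integer(version), basename(archive)))
  invisible(dir)
}

# ---- confidential coefficient-only export ---------------------------------

#' Export a version as a confidential coefficient-only model file
#'
#' The file is UTF-8 tab-separated text: a magic line, `KEY<TAB>VALUE`
#' header lines and one `VAR<TAB>name<TAB>mean<TAB>scale<TAB>coef` line per
#' retained descriptor variable. It contains per-variable aggregates only:
#' no structures, no structure keys, no scores, no per-compound values, and
#' its size is independent of the training-series size. Numbers are printed
#' with 17 significant digits so predictions survive the round trip
#' bit-exactly.
#'
#' @param tag model tag
#' @param version version to export
#' @param dest destination text file
#' @param root store root
#' @return invisibly `dest`
#' @export
export_confidential <- function(tag, version, dest, root = store_root()) {
  v <- load_version(tag, version, root)
  if (v$confidential) qstop("version is already confidential")
  model <- v$model
  if (!inherits(model, "PLSModel") || isTRUE(v$meta$custom))
    qstop("confidential export undefined for overridden predict stage")
  writeLines(confidential_lines(model, tag), dest, useBytes = TRUE)
  invisible(dest)
}

# Text content of a confidential coefficient-only model: per-variable
# aggregates only, no per-compound information of any kind.
confidential_lines <- function(model, tag) {
  keep <- which(model$var_mask)
  names_keep <- model$var_names[keep]
  lines <- c(
    CONFIDENTIAL_MAGIC,
    paste0("TAG\t", tag),
    paste0("MODE\t", model$mode),
    paste0("DESCRIPTOR_SET\t", model$descriptor_set_id),
    paste0("SCALING\t", model$scaling$mode),
    paste0("A_OPT\t", model$A_opt),
    paste0("N_VARS\t", length(keep)),
    paste0("INTERCEPT\t", fmt_num(model$intercept_raw)),
    paste0("GLOBAL_SDEP\t", fmt_num(model$SDEP[model$A_opt])))
  if (model$mode == "discriminant")
    lines <- c(lines, paste0("CUTOFF\t", fmt_num(model$cutoff)))
  c(lines, vapply(seq_along(keep), function(j)
    paste("VAR", names_keep[j],
          fmt_num(model$scaling$means[j]),
          fmt_num(model$scaling$scales[j]),
          fmt_num(model$coefficients_raw[j]), sep = "\t"),
    character(1)))
}

#' Read a confidential model file
#'
#' @param path file written by [export_confidential()]
#' @return a `ConfidentialModel`: header fields plus per-variable names,
#'   means, scales and raw coefficients
#' @export
read_confidential <- function(path) {
  if (!file.exists(path)) qstop("confidential model file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != CONFIDENTIAL_MAGIC)
    qstop("not a confidential model file (bad magic line)")
  header <- list(); vars <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (parts[1] == "VAR") {
      vars[[length(vars) + 1L]] <- parts[-1]
    } else header[[parts[1]]] <- parts[2]
  }
  vm <- do.call(rbind, vars)
  obj <- list(tag = header$TAG, mode = header$MODE,
              descriptor_set_id = header$DESCRIPTOR_SET,
              scaling_mode = header$SCALING,
              A_opt = as.integer(header$A_OPT),
              intercept_raw = as.numeric(header$INTERCEPT),
              global_sdep = as.numeric(header$GLOBAL_SDEP),
              cutoff = if (!is.null(header$CUTOFF))
                as.numeric(header$CUTOFF) else NA_real_,
              var_names = vm[, 1],
              means = as.numeric(vm[, 2]),
              scales = as.numeric(vm[, 3]),
              coefficients_raw = as.numeric(vm[, 4]))
  if (length(obj$var_names) != as.integer(header$N_VARS))
    qstop("confidential file corrupt: variable count mismatch")
  class(obj) <- "ConfidentialModel"
  obj
}

#' Predict from a confidential coefficient-only model
#'
#' @param object a `ConfidentialModel`
#' @param newdata raw descriptor matrix with columns named as the model's
#'   retained variables (order-corrected automatically)
#' @param ... unused
#' @return numeric predictions (discriminant mode: the score; compare with
#'   `object$cutoff` for the class)
#' @export
predict.ConfidentialModel <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$var_names, colnames(X))
    if (length(missing) > 0L)
      qstop("missing variable(s): %s", paste(missing, collapse = ", "))
    X <- X[, object$var_names, drop = FALSE]
  } else if (ncol(X) != length(object$var_names))
    qstop("column count mismatch")
  as.numeric(object$intercept_raw + X %*% object$coefficients_raw)
}
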
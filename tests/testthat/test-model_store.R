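# Versioned model store: sandbox, publication, forensics, confidential
# export.

build_demo <- function(root, tag = "DEMO", n = 20, seed = 7,
                       config = list()) {
  toy <- gen_toy_sdf(n, seed = seed)
  suppressMessages(build_workflow(tag, toy$path,
                                  utils::modifyList(list(seed = 1L), config),
                                  root = root))
  toy
}

test_that("save/publish produce sequential versions; sandbox retained", {
  with_store(function(root) {
    build_demo(root)
    expect_equal(publish_version("DEMO", root), 1L)
    build_demo(root, seed = 8)
    expect_equal(publish_version("DEMO", root), 2L)
    df <- list_versions("DEMO", root)
    expect_equal(df$version, c(0L, 1L, 2L))
    # publishing twice without rebuilding is allowed
    expect_equal(publish_version("DEMO", root), 3L)
    expect_error(publish_version("NOPE", root), "no sandbox")
    expect_error(save_version("a/b", model = list()), "invalid model tag")
    expect_error(list_versions("UNKNOWN", root), "unknown tag")
  })
})

test_that("removal never compacts or reuses version numbers", {
  with_store(function(root) {
    build_demo(root)
    publish_version("DEMO", root)  # 1
    publish_version("DEMO", root)  # 2
    remove_version("DEMO", 1L, root)
    expect_equal(list_versions("DEMO", root)$version, c(0L, 2L))
    expect_equal(publish_version("DEMO", root), 3L)  # 1 never reused
    expect_error(remove_version("DEMO", 99L, root), "not found")
  })
})

test_that("export/import round trip preserves metadata and predictions", {
  with_store(function(root) {
    build_demo(root)
    publish_version("DEMO", root)
    q <- gen_toy_sdf(6, seed = 50)
    before <- predict_workflow("DEMO", 1L, q$path, root = root)
    arch <- tempfile(fileext = ".tar")
    export_version("DEMO", 1L, arch, root)
    import_version(arch, "COPY", 1L, root)
    after <- predict_workflow("COPY", 1L, q$path, root = root)
    expect_identical(after$y_pred, before$y_pred)
    m1 <- list_versions("DEMO", root); m2 <- list_versions("COPY", root)
    cols <- c("n_compounds", "A_opt", "r2_opt", "q2_opt", "SDEP_opt")
    a <- m1[m1$version == 1L, cols]; rownames(a) <- NULL
    b <- m2[, cols]; rownames(b) <- NULL
    expect_identical(a, b)
    expect_error(import_version(arch, "COPY", 1L, root), "already exists")
  })
})

test_that("archived predictions are bit-identical across later publishes", {
  with_store(function(root) {
    build_demo(root)
    publish_version("DEMO", root)
    q <- gen_toy_sdf(5, seed = 60)
    p1 <- predict_workflow("DEMO", 1L, q$path, root = root)
    build_demo(root, seed = 9)      # new sandbox
    publish_version("DEMO", root)   # version 2
    p1b <- predict_workflow("DEMO", 1L, q$path, root = root)
    expect_identical(p1b$y_pred, p1$y_pred)
    expect_identical(p1b$adan_category, p1$adan_category)
    expect_identical(p1b$ci95, p1$ci95)
  })
})

test_that("confidential export holds aggregates only and predicts identically", {
  with_store(function(root) {
    toy <- build_demo(root)
    publish_version("DEMO", root)
    dest <- tempfile(fileext = ".txt")
    export_confidential("DEMO", 1L, dest, root)
    cm <- read_confidential(dest)
    v <- load_version("DEMO", 1L, root)
    p_retained <- sum(v$model$var_mask)
    lines <- readLines(dest)
    expect_equal(sum(startsWith(lines, "VAR\t")), p_retained)
    # predictions equal the full model's at A_opt on fresh queries
    q <- gen_toy_sdf(10, seed = 70)
    full <- predict_workflow("DEMO", 1L, q$path, root = root)
    s <- normalize_series(read_sdf(q$path))
    dm <- extract_descriptors(s)
    conf <- predict(cm, dm$values)
    expect_lt(max(abs(full$y_pred - conf)), 1e-10)
    # no token of the training SDF leaks into the file
    sdf_lines <- readLines(toy$path)
    atom_or_value <- c(
      trimws(grep("^ {2,}[0-9-]", sdf_lines, value = TRUE)),
      trimws(sdf_lines[which(grepl("^> <", sdf_lines)) + 1L]))
    atom_or_value <- unique(atom_or_value[nchar(atom_or_value) > 3])
    blob <- paste(lines, collapse = "\n")
    for (tok in atom_or_value)
      expect_false(grepl(tok, blob, fixed = TRUE))
  })
})

test_that("confidential file size is independent of the training size", {
  with_store(function(root) {
    build_demo(root, tag = "SMALL", n = 20, seed = 3)
    build_demo(root, tag = "LARGE", n = 200, seed = 3)
    f1 <- tempfile(); f2 <- tempfile()
    export_confidential("SMALL", 0L, f1, root)
    export_confidential("LARGE", 0L, f2, root)
    l1 <- readLines(f1); l2 <- readLines(f2)
    # same retained variable set -> identical line counts
    expect_equal(sum(startsWith(l1, "VAR\t")), sum(startsWith(l2, "VAR\t")))
    expect_equal(length(l1), length(l2))
  })
})

test_that("a confidential version predicts with NA category and global CI", {
  with_store(function(root) {
    toy <- gen_toy_sdf(20, seed = 7)
    suppressMessages(build_workflow("CONF", toy$path,
                                    list(confidential = TRUE), root = root))
    # no model.rds / training.sdf in the version tree
    vdir <- file.path(root, "CONF", "version-0000")
    expect_false(file.exists(file.path(vdir, "model.rds")))
    expect_false(file.exists(file.path(vdir, "training.sdf")))
    expect_true(file.exists(file.path(vdir, "confidential.txt")))
    res <- predict_workflow("CONF", 0L, toy$path, root = root)
    expect_true(all(is.na(res$adan_category)))
    expect_true(all(res$ci95 > 0))
    expect_false(any(res$is_training_copy))
    expect_error(retrain("CONF", toy$path, root = root),
                 "cannot retrain")
    expect_error(export_confidential("CONF", 0L, tempfile(), root),
                 "already confidential")
  })
})
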
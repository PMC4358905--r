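# Build/predict workflows, retraining, stage overrides, config parsing.

test_that("config files parse with defaults, coercion and unknown-key rejection", {
  p <- tempfile()
  writeLines(c("# comment", "A_max=6", "ffd_enabled=TRUE",
               "embedded_fields=logP,pKa", "scaling=center"), p)
  cfg <- read_config_file(p)
  expect_identical(cfg$A_max, 6L)
  expect_true(cfg$ffd_enabled)
  expect_equal(cfg$embedded_fields, c("logP", "pKa"))
  expect_equal(cfg$scaling, "center")
  expect_equal(cfg$activity_field, "activity")  # default survives
  writeLines("frobnicate=1", p)
  expect_error(read_config_file(p), "unknown config key")
})

test_that("build_workflow validates its inputs", {
  with_store(function(root) {
    small <- gen_toy_sdf(3, seed = 1)
    expect_error(build_workflow("T1", small$path, root = root), "too small")
    # single-class qualitative
    recs <- replicate(6, ethanol_rec(), simplify = FALSE)
    path <- write_fixture_sdf(recs, activities = rep("1", 6))
    expect_error(build_workflow("T1", path,
                                list(activity_type = "qualitative"),
                                root = root), "single-class")
  })
})

test_that("noise-free toy build is near-exact and deterministic", {
  with_store(function(root) {
    toy <- gen_toy_sdf(30, seed = 7)
    r1 <- suppressMessages(build_workflow("TOY", toy$path,
                                          list(seed = 5L), root = root))
    expect_gte(max(r1$quality$r2), 0.99)
    expect_gte(r1$quality$q2[r1$A_opt], 0.99)
    r2 <- suppressMessages(build_workflow("TOY", toy$path,
                                          list(seed = 5L), root = root))
    expect_identical(r1$quality, r2$quality)
    expect_identical(r1$A_opt, r2$A_opt)
  })
})

test_that("training descriptor rows are bit-identical at predict time", {
  with_store(function(root) {
    toy <- gen_toy_sdf(15, seed = 30)
    rep_ <- suppressMessages(build_workflow("CONS", toy$path, root = root))
    dm_build <- attr(rep_, "descriptors")
    s <- normalize_series(read_sdf(toy$path))
    dm_pred <- extract_descriptors(s)
    expect_identical(dm_pred$values, dm_build$values)
    # recalculated values match the build report through the predict path
    v <- load_version("CONS", 0L, root)
    Xq <- align_to_model(dm_pred, v$model$var_names, v$model$var_mask)
    y_hat <- predict(v$model, Xq)
    fitted_build <- as.numeric(
      scale_apply(Xq, v$model$scaling) %*% v$model$b[, v$model$A_opt] +
        v$model$y_mean)
    expect_identical(y_hat, fitted_build)
  })
})

test_that("training copies are detected and given their experimental value", {
  with_store(function(root) {
    toy <- gen_toy_sdf(12, seed = 40)
    suppressMessages(build_workflow("DUP", toy$path, root = root))
    res <- predict_workflow("DUP", 0L, toy$path, root = root)
    expect_true(all(res$is_training_copy))
    acts <- read_sdf(toy$path)$activities
    expect_equal(res$y_pred, acts)
    expect_equal(res$experimental_value, acts)
    # detection off: predictions are model output, not lookups
    suppressMessages(build_workflow("DUP2", toy$path,
                                    list(detect_training_copy = FALSE),
                                    root = root))
    res2 <- predict_workflow("DUP2", 0L, toy$path, root = root)
    expect_false(any(res2$is_training_copy))
  })
})

test_that("an element unseen in training still predicts, flagged by the AD", {
  with_store(function(root) {
    toy <- gen_toy_sdf(20, seed = 44)
    suppressMessages(build_workflow("OUT", toy$path, root = root))
    # query: a large phosphorus-rich chain, far outside the training space
    q <- mk_record("weird", c("P", "P", "P", rep("C", 9)),
                   lapply(1:11, function(j) c(j, j + 1L, 1L)))
    qpath <- write_fixture_sdf(list(q), activities = 0)
    res <- predict_workflow("OUT", 0L, qpath, root = root)
    expect_true(is.finite(res$y_pred))
    expect_gte(res$adan_category, 1)
  })
})

test_that("discriminant mode estimates a cutoff with sensible balance", {
  with_store(function(root) {
    da <- gen_da_set(12, separation = 1.5, seed = 3, format = "sdf")
    rep_ <- suppressMessages(build_workflow(
      "DA", da$path, list(activity_type = "qualitative"), root = root))
    expect_equal(rep_$mode, "discriminant")
    expect_true(is.finite(rep_$cutoff))
    expect_gte(rep_$sensitivity + rep_$specificity, 1.5)
    res <- predict_workflow("DA", 0L, da$path, root = root)
    expect_true(all(res$class_pred %in% 0:1))
  })
})

test_that("retrain concatenates, deduplicates and rebuilds version 0", {
  with_store(function(root) {
    toy <- gen_toy_sdf(30, seed = 7)   # contains 2 internal duplicates
    suppressMessages(build_workflow("RT", toy$path, root = root))
    publish_version("RT", root)
    extra <- gen_toy_sdf(10, seed = 7)  # first 10 are exact copies
    expect_warning(
      rep2 <- suppressMessages(retrain("RT", extra$path, root = root)),
      "duplicate")
    expect_equal(rep2$n, 30)            # all 10 dropped as duplicates
    fresh <- gen_toy_sdf(10, seed = 555)
    rep3 <- suppressMessages(retrain("RT", fresh$path, root = root))
    expect_gte(rep3$n, 38)              # new compounds appended
    expect_equal(publish_version("RT", root), 2L)
  })
})

test_that("stage overrides participate and leave other stages untouched", {
  with_store(function(root) {
    toy <- gen_toy_sdf(15, seed = 90)
    suppressMessages(build_workflow("BASE", toy$path, root = root))
    base_res <- predict_workflow("BASE", 0L, toy$path, root = root)

    # a hand-specified 2-rule decision tree on two descriptors
    tree_predict <- function(model, X)
      ifelse(X[, "n_heavy"] > 7, ifelse(X[, "wiener"] > 40, 3, 2), 1)
    register_stage("TREE", "predict", tree_predict)
    on.exit(register_stage("TREE", "predict", NULL), add = TRUE)
    suppressMessages(build_workflow("TREE", toy$path,
                                    list(detect_training_copy = FALSE),
                                    root = root))
    res <- predict_workflow("TREE", 0L, toy$path, root = root)
    expect_true(all(res$y_pred %in% 1:3))
    expect_true(list_versions("TREE", root)$custom[1])
    # differential: normalize/extract unchanged by the predict override
    s <- normalize_series(read_sdf(toy$path))
    expect_identical(extract_descriptors(s)$values,
                     attr(suppressMessages(build_workflow(
                       "BASE", toy$path, root = root)), "descriptors")$values)
    # resolution falls back to built-ins where unregistered
    expect_identical(resolve_stage("TREE", "normalize"),
                     qsarkit:::stage_normalize_builtin)
    expect_error(register_stage("TREE", "foo", identity), "unknown stage")
    # confidential export refuses custom models
    expect_error(export_confidential("TREE", 0L, tempfile(), root),
                 "confidential export undefined")
  })
})
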
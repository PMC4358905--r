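# SDF parsing, normalization, canonical keys, prediction writers.

test_that("read_sdf parses records, activities and data fields", {
  recs <- list(ethanol_rec(), benzene_rec(),
               mk_record("propane", c("C", "C", "C"),
                         list(c(1L, 2L, 1L), c(2L, 3L, 1L)),
                         fields = list(logP = "2.3")))
  path <- write_fixture_sdf(recs, activities = c(1.2, 3.4, 5.6))
  s <- read_sdf(path)
  expect_s3_class(s, "TrainingSeries")
  expect_length(s$records, 3)
  expect_equal(s$activities, c(1.2, 3.4, 5.6))
  # extra fields preserved verbatim
  expect_equal(s$records[[3]]$extra_fields$logP, "2.3")
  # record order preserved
  expect_equal(vapply(s$records, `[[`, "", "name"),
               c("ethanol", "benzene", "propane"))
})

test_that("read_sdf errors carry the record index", {
  recs <- list(ethanol_rec(), benzene_rec(), ethanol_rec())
  path <- write_fixture_sdf(recs, activities = c(1, 2, 3))
  # drop the field from record 2 only
  txt <- readLines(path)
  i <- grep("^> <activity>", txt)[2]
  txt <- txt[-c(i, i + 1L)]
  path2 <- tempfile(fileext = ".sdf"); writeLines(txt, path2)
  expect_error(read_sdf(path2), "activity field missing in record 2")
  # non-numeric quantitative activity
  path3 <- write_fixture_sdf(list(ethanol_rec()), activities = "high")
  expect_error(read_sdf(path3), "record 1.*not numeric")
})

test_that("qualitative activities map through the declared labels", {
  recs <- replicate(6, ethanol_rec(), simplify = FALSE)
  labels <- c("pos", "neg", "pos", "pos", "neg", "pos")
  path <- write_fixture_sdf(recs, activities = labels)
  s <- read_sdf(path, activity_type = "qualitative",
                label_map = c(neg = 0, pos = 1))
  # oracle: count labels by scanning the fixture file text
  n_pos <- sum(grepl("^pos$", readLines(path)))
  expect_equal(sum(s$activities == 1), n_pos)
  expect_true(all(s$activities %in% c(0, 1)))
  expect_error(read_sdf(path, activity_type = "qualitative"),
               "label 'pos' not in declared labels")
})

test_that("V3000 records are rejected", {
  txt <- c("name", "", "", "  0  0  0     0  0            999 V3000",
           "M  END", "$$$$")
  path <- tempfile(fileext = ".sdf"); writeLines(txt, path)
  expect_error(read_sdf(path), "V3000")
})

test_that("normalize keeps the largest fragment and strips hydrogens", {
  r <- normalize_record(sodium_acetate_rec())
  g <- qsarkit:::parse_molblock(strsplit(r$mol_text, "\n")[[1]])
  expect_equal(length(g$elem), 4)          # acetate heavy atoms
  expect_false("Na" %in% g$elem)
  # idempotence
  r2 <- normalize_record(r)
  expect_identical(r2$mol_text, r$mol_text)
  expect_identical(r2$structure_key, r$structure_key)
  # single-fragment molecule untouched in heavy-atom count
  e <- normalize_record(ethanol_rec())
  ge <- qsarkit:::parse_molblock(strsplit(e$mol_text, "\n")[[1]])
  expect_equal(length(ge$elem), 3)
  # explicit hydrogens are removed
  rh <- mk_record("methanol-H", c("C", "O", "H", "H", "H", "H"),
                  list(c(1L, 2L, 1L), c(1L, 3L, 1L), c(1L, 4L, 1L),
                       c(1L, 5L, 1L), c(2L, 6L, 1L)))
  gh <- qsarkit:::parse_molblock(
    strsplit(normalize_record(rh)$mol_text, "\n")[[1]])
  expect_equal(sort(gh$elem), c("C", "O"))
})

test_that("structure_key is invariant under atom-order permutation", {
  recs <- list(ethanol_rec(), benzene_rec(),
               mk_record("thiazoline-ish", c("C", "N", "C", "S", "C", "O"),
                         list(c(1L, 2L, 1L), c(2L, 3L, 2L), c(3L, 4L, 1L),
                              c(4L, 5L, 1L), c(5L, 1L, 1L), c(3L, 6L, 1L))))
  set.seed(4711)
  for (rec in recs) {
    key0 <- normalize_record(rec)$structure_key
    g <- qsarkit:::parse_molblock(strsplit(rec$mol_text, "\n")[[1]])
    for (rep_i in 1:8) {
      perm <- sample(length(g$elem))
      rec2 <- rec
      rec2$mol_text <- permute_molblock(rec$mol_text, perm)
      expect_identical(normalize_record(rec2)$structure_key, key0)
    }
  }
  # different molecules get different keys
  k1 <- normalize_record(ethanol_rec())$structure_key
  k2 <- normalize_record(benzene_rec())$structure_key
  expect_false(identical(k1, k2))
})

test_that("find_in_training matches by key, first occurrence wins", {
  recs <- list(ethanol_rec(), benzene_rec(), ethanol_rec())
  path <- write_fixture_sdf(recs, activities = 1:3)
  s <- normalize_series(read_sdf(path))
  qkey <- normalize_record(ethanol_rec())$structure_key
  expect_equal(find_in_training(qkey, s), 1L)   # duplicate at 3, first wins
  expect_equal(find_in_training(
    normalize_record(benzene_rec())$structure_key, s), 2L)
  absent <- normalize_record(sodium_acetate_rec())$structure_key
  expect_true(is.na(find_in_training(absent, s)))
})

test_that("SDF read-write-read round trip preserves structure and fields", {
  toy <- gen_toy_sdf(12, seed = 20)
  s1 <- read_sdf(toy$path)
  out <- tempfile(fileext = ".sdf")
  qsarkit:::write_sdf(s1$records, out)
  s2 <- read_sdf(out)
  expect_length(s2$records, 12)
  for (i in seq_len(12)) {
    g1 <- qsarkit:::parse_molblock(strsplit(s1$records[[i]]$mol_text,
                                            "\n")[[1]])
    g2 <- qsarkit:::parse_molblock(strsplit(s2$records[[i]]$mol_text,
                                            "\n")[[1]])
    expect_equal(g2$n_atoms, g1$n_atoms)
    expect_equal(g2$n_bonds, g1$n_bonds)
    expect_identical(s2$records[[i]]$extra_fields,
                     s1$records[[i]]$extra_fields)
  }
})

test_that("write_predictions emits CSV and round-trippable SDF", {
  recs <- list(ethanol_rec(), benzene_rec())
  res <- data.frame(compound_id = c("a", "b"),
                    y_pred = c(1.25, -0.5),
                    is_training_copy = c(FALSE, TRUE),
                    experimental_value = c(NA, -0.5),
                    adan_category = c(2L, NA_integer_),
                    ci95 = c(0.75, NA_real_))
  attr(res, "mol_text") <- vapply(recs, `[[`, "", "mol_text")
  csv <- tempfile(fileext = ".csv")
  write_predictions(res, "csv", csv)
  df <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 2)
  expect_equal(df$prediction[1], 1.25)
  expect_true(is.na(df$AD_category[2]))     # literal NA sentinel
  sdf <- tempfile(fileext = ".sdf")
  write_predictions(res, "sdf", sdf)
  back <- read_sdf(sdf, activity_field = "prediction")
  expect_equal(back$activities, res$y_pred)
  expect_equal(back$records[[1]]$extra_fields$AD_category, "2")
  expect_equal(back$records[[2]]$extra_fields$AD_category, "NA")
  expect_error(write_predictions(res[0, ], "csv", csv), "no prediction")
})
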
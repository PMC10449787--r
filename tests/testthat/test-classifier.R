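test_that("70:30 split is stratified, disjoint, exhaustive and seeded", {
  # n = 857 with near-balanced classes: train must round to 600
  tab <- make_toy_table(1L, n_noise = 1L, planted = FALSE)[0, ]
  n1 <- 428L
  n2 <- 429L
  tab <- tibble::tibble(
    contig_id = sprintf("c%03d", 1:(n1 + n2)),
    x = rnorm(n1 + n2),
    label = c(rep("archaeal_virus", n1), rep("phage", n2)))
  parts <- split_train_test(tab, seed = 3L)
  expect_equal(nrow(parts$train), 600L)
  expect_equal(nrow(parts$test), 257L)
  expect_length(intersect(parts$train$contig_id, parts$test$contig_id), 0L)
  expect_setequal(c(parts$train$contig_id, parts$test$contig_id),
                  tab$contig_id)
  # stratification: class proportions preserved to within one row
  expect_equal(sum(parts$train$label == "archaeal_virus"), 300L)

  again <- split_train_test(tab, seed = 3L)
  expect_equal(again$train$contig_id, parts$train$contig_id)

  small <- tibble::tibble(contig_id = sprintf("c%02d", 1:10),
                          x = rnorm(10),
                          label = rep(c("archaeal_virus", "phage"), 5))
  p10 <- split_train_test(small, seed = 1L)
  expect_equal(nrow(p10$train), 7L)
  expect_true(all(table(p10$train$label) >= 1))
  expect_true(all(table(p10$test$label) >= 1))

  lopsided <- tibble::tibble(contig_id = sprintf("c%02d", 1:12),
                             x = rnorm(12),
                             label = c(rep("archaeal_virus", 3),
                                       rep("phage", 9)))
  expect_error(split_train_test(lopsided, seed = 1L), "fewer than 5")
})

test_that("forest training is seeded-deterministic with unit-sum Gini", {
  tab <- make_toy_table(30L, seed = 2L)
  parts <- split_train_test(tab, seed = 1L)
  m1 <- train_forest(parts$train, n_trees = 101L, seed = 7L)
  m2 <- train_forest(parts$train, n_trees = 101L, seed = 7L)
  p1 <- predict_contigs(m1, parts$test)
  p2 <- predict_contigs(m2, parts$test)
  expect_equal(p1$p_archaeal, p2$p_archaeal)
  expect_equal(sum(m1$gini_importances), 1, tolerance = 1e-9)
  expect_true(is.finite(m1$oob_error))

  single <- dplyr::filter(parts$train, label == "phage")
  expect_error(train_forest(single, seed = 1L), "both classes")
})

test_that("planted-signal data are learned; permuted labels are not", {
  ds <- simulate_dataset(sim_config(n_per_class = 80L, seed = 21L,
                                    realize_sequence = FALSE))
  ft <- dataset_features(ds)
  parts <- split_train_test(ft, seed = 2L)
  m <- train_forest(parts$train, n_trees = 300L, seed = 2L)
  pred <- predict_contigs(m, parts$test, threshold = 0.5)
  expect_gte(arcvir:::f1_score(parts$test$label, pred$predicted_class),
             0.95)

  set.seed(99)
  null_f1 <- replicate(5, {
    shuffled <- parts$train
    shuffled$label <- sample(shuffled$label)
    mn <- train_forest(shuffled, n_trees = 150L,
                       seed = sample.int(1e6, 1))
    pn <- predict_contigs(mn, parts$test, threshold = 0.5)
    arcvir:::f1_score(parts$test$label, pn$predicted_class)
  })
  expect_lt(mean(null_f1), 0.65)
})

test_that("prediction probability equals the per-tree vote recount", {
  fx <- fixture_model()
  te <- fx$parts$test
  pred <- predict_contigs(fx$model, te, threshold = 0.8)
  per_tree <- predict(fx$model$forest,
                      newdata = as.data.frame(te[, fx$model$feature_names]),
                      predict.all = TRUE)$individual
  recount <- rowMeans(per_tree == "archaeal_virus")
  expect_equal(pred$p_archaeal, unname(recount), tolerance = 1e-12)
  expect_equal(pred$p_archaeal + pred$p_phage, rep(1, nrow(te)))
  expect_equal(pred$predicted_class,
               ifelse(pred$p_archaeal >= 0.8, "archaeal_virus", "phage"))
})

test_that("threshold behaviour: zero calls everything, positives nest", {
  fx <- fixture_model()
  te <- fx$parts$test
  all_pos <- predict_contigs(fx$model, te, threshold = 0)
  expect_true(all(all_pos$predicted_class == "archaeal_virus"))
  p5 <- predict_contigs(fx$model, te, threshold = 0.5)
  p8 <- predict_contigs(fx$model, te, threshold = 0.8)
  pos8 <- p8$contig_id[p8$predicted_class == "archaeal_virus"]
  pos5 <- p5$contig_id[p5$predicted_class == "archaeal_virus"]
  expect_true(all(pos8 %in% pos5))
})

test_that("prediction validates the feature contract", {
  fx <- fixture_model()
  te <- fx$parts$test
  expect_error(predict_contigs(fx$model, dplyr::select(te, -gc_content)),
               "gc_content")
  extra <- dplyr::mutate(te, mystery = 1)
  expect_warning(predict_contigs(fx$model, extra), "mystery")
  wrong <- te
  attr(wrong, "catalog_version") <- "other-catalog"
  expect_error(predict_contigs(fx$model, wrong), "catalog mismatch")
})

test_that("feature elimination traces to the floor and keeps the signal", {
  tab <- make_toy_table(30L, n_noise = 9L, seed = 5L)
  rfe <- rfe_select(tab, seed = 3L, n_trees = 80L)
  expect_equal(nrow(rfe$trace), 6L)            # 10 -> 5 features
  expect_equal(rfe$trace$n_features, 10:5)
  expect_gte(length(rfe$selected), 5L)
  expect_true(all(rfe$trace$cv_f1 >= 0 & rfe$trace$cv_f1 <= 1))
  expect_true("signal" %in% rfe$selected)
  # selection never materially hurts relative to the all-features step
  expect_gte(max(rfe$trace$cv_f1), rfe$trace$cv_f1[1] - 0.02)
})

test_that("proximity matrix is symmetric with unit diagonal; twins cohere", {
  fx <- fixture_model()
  te <- fx$parts$test[1:20, ]
  twin <- te[1, ]
  twin$contig_id <- "twin"
  tab <- dplyr::bind_rows(te, twin)
  prox <- proximity_outliers(fx$model, tab)
  m <- prox$matrix
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, nrow(tab)))
  expect_equal(m["twin", te$contig_id[1]], 1)
  expect_error(proximity_outliers(fx$model, te[1:2, ]), "at least 3")
})

test_that("a planted mislabeled row is flagged as a proximity outlier", {
  flagged <- 0L
  for (seed in 1:5) {
    ds <- simulate_dataset(sim_config(n_per_class = 25L,
                                      seed = 300L + seed,
                                      realize_sequence = FALSE))
    ft <- dataset_features(ds)
    victim <- ft$contig_id[ft$label == "phage"][1]
    ft$label[ft$contig_id == victim] <- "archaeal_virus"
    m <- train_forest(ft, n_trees = 200L, seed = seed)
    prox <- proximity_outliers(m, ft)
    if (victim %in% prox$outliers$contig_id) flagged <- flagged + 1L
  }
  expect_gte(flagged, 4L)
})

test_that("models round-trip through disk and refuse foreign catalogs", {
  fx <- fixture_model()
  te <- fx$parts$test
  before <- predict_contigs(fx$model, te)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fx$model, path)
  loaded <- load_model(path)
  expect_equal(predict_contigs(loaded, te), before)
  expect_equal(loaded$seed, fx$model$seed)
  expect_equal(loaded$n_trees, fx$model$n_trees)

  alien <- fx$model
  alien$catalog_version <- "arcvir-catalog-0"
  save_model(alien, path)
  expect_error(load_model(path), "Refusing model")
  expect_s3_class(load_model(path, catalog_version = NULL), "av_model")
})

test_that("tidiers expose importances, model summary and augmented rows", {
  fx <- fixture_model()
  td <- tidy(fx$model)
  expect_equal(names(td), c("feature", "gini_importance"))
  expect_equal(sum(td$gini_importance), 1, tolerance = 1e-9)
  gl <- glance(fx$model)
  expect_equal(gl$n_trees, 200L)
  aug <- augment(fx$model, fx$parts$test)
  expect_true(all(c(".p_archaeal", ".predicted_class") %in% names(aug)))
})
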
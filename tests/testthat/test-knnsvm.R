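test_that("cosine distance matches its closed form", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(-2, 0)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "undefined direction")
  expect_error(cosine_distance(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("the rough KNN stage shortlists by summed similarity", {
  # 2-D features on the unit circle make cosine geometry explicit
  ang <- function(a) c(cos(a), sin(a))
  feats <- rbind(ang(0), ang(0.05), ang(pi / 3), ang(pi / 2),
                 ang(pi), ang(3))
  labs <- c("LH", "LH", "RF", "RF", "RS", "R")
  model <- knnsvm_fit(rbind(feats, feats + 1e-9), rep(labs, 2), k = 3,
                      standardize = FALSE)
  rough <- knn_rough(ang(0.01), model)
  # neighbours: both LH copies at ~0 distance and one more LH/RF
  expect_identical(rough$shortlist[1], "LH")
  expect_true(all(diff(rough$weights) <= 0))
  # K = 3 enumeration at a point between the LH pair and an RF point:
  # weights are the summed cosine similarities of each class's neighbours
  q <- ang(pi / 6)
  model2 <- knnsvm_fit(rbind(feats, feats + 1e-9), rep(labs, 2), k = 3,
                       standardize = FALSE)
  rough2 <- knn_rough(q, model2)
  d <- apply(rbind(feats, feats + 1e-9), 1, cosine_distance, v = q)
  nn <- order(d)[1:3]
  wexp <- tapply(pmax(1 - d[nn], 0), rep(labs, 2)[nn], sum)
  expect_equal(sort(unname(rough2$weights), decreasing = TRUE),
               sort(unname(wexp), decreasing = TRUE), tolerance = 1e-12)

  # unanimous neighbourhood returns a single class
  rough1 <- knn_rough(ang(0.02), knnsvm_fit(rbind(feats, feats + 1e-9),
                                            rep(labs, 2), k = 2,
                                            standardize = FALSE))
  expect_identical(rough1$shortlist, "LH")
})

test_that("weight ties break by canonical class order", {
  # RS and LH trials symmetric about the query direction: equal weights
  feats <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  feats <- rbind(feats, feats)  # two trials per class
  labs <- rep(c("RS", "LH", "RF", "R"), 2)
  model <- knnsvm_fit(feats, labs, k = 4, standardize = FALSE)
  rough <- knn_rough(c(1, 0), model)
  # neighbours: both RS and both LH copies, tied at similarity 1/sqrt(2);
  # canonical order (R, RF, LH, RS) puts LH first
  expect_identical(rough$shortlist, c("LH", "RS"))
  expect_equal(unname(rough$weights[1]), unname(rough$weights[2]))
})

test_that("fitting validates inputs and trains six pair classifiers", {
  cl <- separable_clouds(10, seed = 91)
  model <- knnsvm_fit(cl$x, cl$y, k = 5)
  expect_length(model$pair_classifiers, 6)
  expect_error(knnsvm_fit(cl$x, cl$y, k = 100), "between 1 and")
  expect_error(knnsvm_fit(cl$x[1:12, ], cl$y[1:12]),
               "incomplete training set")
  # separable classes: every pair classifier fits its training subset
  for (key in names(model$pair_classifiers)) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    keep <- cl$y %in% pair
    xs <- mibci:::apply_standardize(cl$x[keep, ], model$standardize)
    pred <- as.character(predict(model$pair_classifiers[[key]], xs))
    expect_gte(mean(pred == cl$y[keep]), 0.95)
  }
})

test_that("hybrid prediction uses the direct branch and the pair SVM", {
  cl <- separable_clouds(25, seed = 92)
  model <- knnsvm_fit(cl$x, cl$y, k = 5)
  # a training vector deep inside a class: unanimous neighbourhood
  idx <- which(cl$y == "LH")[1]
  expect_identical(unname(predict(model, cl$x[idx, ])), "LH")
  te <- separable_clouds(10, seed = 93)
  expect_gte(mean(predict(model, te$x) == te$y), 0.9)
  # determinism
  expect_identical(predict(model, te$x), predict(model, te$x))
})

test_that("an ambiguous query is resolved by the matching pair classifier", {
  # R and RF occupy adjacent angular sectors; LH and RS are far away.
  # A query between the sectors, slightly on RF's side, gets a mixed
  # neighbourhood and must fall through to the R|RF pair SVM.
  ang <- function(a, r = 1) r * c(cos(a), sin(a))
  x <- rbind(ang(-0.30), ang(-0.25, 1.2), ang(-0.20, 0.9),
             ang(0.20), ang(0.25, 1.1), ang(0.30, 0.8),
             ang(2.5), ang(2.6), ang(4.0), ang(4.1))
  y <- c(rep("R", 3), rep("RF", 3), "LH", "LH", "RS", "RS")
  model <- knnsvm_fit(x, y, k = 6, kernel = "linear",
                      standardize = FALSE)
  q <- ang(0.08)  # between the sectors, nearer RF
  rough <- knn_rough(q, model)
  expect_setequal(rough$shortlist, c("R", "RF"))
  expect_identical(unname(predict(model, q)), "RF")
})

test_that("prediction is invariant to positive scaling of the query", {
  cl <- separable_clouds(15, sd = 0.5, seed = 95)
  model <- knnsvm_fit(cl$x, cl$y, k = 5, kernel = "linear",
                      standardize = FALSE)
  te <- separable_clouds(5, sd = 0.5, seed = 96)
  base <- predict_knn(model, te$x)
  expect_identical(predict_knn(model, 7.3 * te$x), base)
})

test_that("KNN-only and SVM-only baselines work from the same model", {
  cl <- separable_clouds(25, seed = 97)
  te <- separable_clouds(10, seed = 98)
  model <- knnsvm_fit(cl$x, cl$y, k = 5)
  expect_gte(mean(predict_knn(model, te$x) == te$y), 0.9)
  expect_gte(mean(predict_svm(model, te$x) == te$y), 0.9)
})

test_that("accuracy exceeds 0.9 on well-separated clouds across seeds", {
  ok <- vapply(1:10, function(s) {
    tr <- separable_clouds(50, sd = 1, sep = 6, seed = 200 + s)
    te <- separable_clouds(10, sd = 1, sep = 6, seed = 300 + s)
    model <- knnsvm_fit(tr$x, tr$y, k = 5)
    mean(predict(model, te$x) == te$y)
  }, numeric(1))
  expect_true(all(ok >= 0.9))
})

test_that("a serialized model predicts identically after reload", {
  cl <- separable_clouds(12, seed = 99)
  te <- separable_clouds(4, seed = 100)
  model <- knnsvm_fit(cl$x, cl$y, k = 3)
  path <- tempfile(fileext = ".json")
  write_knnsvm(model, path)
  back <- read_knnsvm(path)
  expect_identical(predict(back, te$x), predict(model, te$x))
  expect_equal(back$k, model$k)
})
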
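test_that("the stratified split is exact, seeded, and a partition", {
  labeled <- tibble::tibble(
    protein_id = sprintf("p%03d", 1:90),
    label = rep(c("a", "b", "c"), each = 30))
  cfg <- svm_config(grid_preset = "coarse", cv_folds = 10, seed = 3)
  sp1 <- split_markers(labeled, cfg)
  sp2 <- split_markers(labeled, cfg)
  expect_identical(sp1, sp2)
  expect_equal(unname(table(sp1$train$label)), rep(20L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp1$test$label)), rep(10L, 3),
               ignore_attr = TRUE)
  expect_setequal(c(sp1$train$protein_id, sp1$test$protein_id),
                  labeled$protein_id)
  expect_length(intersect(sp1$train$protein_id, sp1$test$protein_id), 0)
})

test_that("a class smaller than the fold count is refused with advice", {
  labeled <- tibble::tibble(protein_id = sprintf("p%02d", 1:15),
                            label = rep(c("a", "b", "c"), times = c(8, 4, 3)))
  expect_error(split_markers(labeled, svm_config(cv_folds = 5)),
               "merge clusters|cv_folds")
})

# two linearly separable profile clusters across 3 replicates
separable_profiles <- function(n_per = 30, seed = 6) {
  set.seed(seed)
  rows <- list()
  ids <- sprintf("p%03d", seq_len(2 * n_per))
  grp <- rep(c("1", "2"), each = n_per)
  for (r in 1:3) {
    m <- matrix(0.05, 2 * n_per, 4)
    m[grp == "1", 1] <- 1
    m[grp == "2", 2] <- 1
    m <- abs(m + matrix(rnorm(length(m), sd = 0.01), nrow(m)))
    m <- m / rowSums(m)
    colnames(m) <- paste0("f", 1:4)
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(protein_id = ids, replicate = r),
      tibble::as_tibble(m), tibble::tibble(flagged = FALSE))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "features") <- paste0("f", 1:4)
  list(profiles = out, truth = tibble::tibble(protein_id = ids, label = grp))
}

test_that("separable clusters are classified perfectly with in-grid parameters", {
  fx <- separable_profiles()
  cfg <- svm_config(grid_preset = "coarse", cv_folds = 5, seed = 6)
  sp <- split_markers(fx$truth, cfg)
  fit <- train_predict(fx$profiles, sp$train, cfg)
  expect_true(all(abs(rowSums(fit$prob[fit$classes]) - 1) < 1e-6))
  sel <- fit$tuning[fit$tuning$best, ]
  expect_true(all(sel$cost %in% cfg$cost_grid))
  expect_true(all(sel$gamma %in% cfg$gamma_grid))
  merged <- merge_replicates(fit)
  held <- merged |> dplyr::inner_join(sp$test, by = "protein_id")
  expect_equal(mean(held$top_class == held$label), 1)
})

test_that("replicate voting keeps 2-of-3 agreement and averages probabilities", {
  classes <- c("c1", "c2", "c3")
  mk_row <- function(id, r, p) {
    tibble::tibble(protein_id = id, replicate = r, c1 = p[1], c2 = p[2], c3 = p[3])
  }
  prob <- dplyr::bind_rows(
    mk_row("agree21", 1, c(0.6, 0.3, 0.1)),
    mk_row("agree21", 2, c(0.7, 0.2, 0.1)),
    mk_row("agree21", 3, c(0.2, 0.7, 0.1)), # votes c1, c1, c2
    mk_row("split3", 1, c(0.9, 0.05, 0.05)),
    mk_row("split3", 2, c(0.05, 0.9, 0.05)),
    mk_row("split3", 3, c(0.05, 0.05, 0.9)), # votes all distinct
    mk_row("single", 1, c(0.5, 0.3, 0.2))) # only one replicate
  attr(prob, "classes") <- classes
  merged <- merge_replicates(prob)
  m <- merged[match(c("agree21", "split3", "single"), merged$protein_id), ]
  expect_equal(m$modal_class, c("c1", NA, NA))
  expect_equal(m$consistency, c(2L, 1L, 1L))
  expect_equal(m$c1[1], 0.5) # mean(0.6, 0.7, 0.2)
  # two-replicate average: [0.6, 0.4] and [0.8, 0.2] -> [0.7, 0.3]
  two <- dplyr::bind_rows(
    tibble::tibble(protein_id = "x", replicate = 1:2,
                   a = c(0.6, 0.8), b = c(0.4, 0.2)))
  attr(two, "classes") <- c("a", "b")
  m2 <- merge_replicates(two)
  expect_equal(c(m2$a, m2$b), c(0.7, 0.3))
  expect_equal(m2$modal_class, "a")
})

test_that("threshold calibration reproduces the worked example", {
  # probabilities/labels {(0.9,+),(0.8,+),(0.7,-),(0.6,+)}, floor 0.9
  pred <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    top_class = "pos", top_prob = c(0.9, 0.8, 0.7, 0.6),
    pos = c(0.9, 0.8, 0.7, 0.6), neg = 1 - c(0.9, 0.8, 0.7, 0.6))
  attr(pred, "classes") <- c("pos", "neg")
  truth <- tibble::tibble(protein_id = c("a", "b", "c", "d"),
                          label = c("pos", "pos", "neg", "pos"))
  thr <- calibrate_thresholds(pred, truth, level = "cluster",
                              precision_floor = 0.9)
  row <- thr[thr$class == "pos", ]
  expect_equal(row$threshold, 0.8)
  expect_equal(row$precision, 1)
  expect_equal(row$recall, 2 / 3)
  expect_equal(row$mode, "precision-floor")
})

test_that("calibration agrees with the quadratic brute-force oracle", {
  set.seed(10)
  for (i in 1:12) {
    n <- 40
    score <- round(runif(n), 2)
    is_true <- runif(n) < 0.5
    floor <- sample(c(0.6, 0.8, 0.9, 0.99), 1)
    pred <- tibble::tibble(
      protein_id = sprintf("p%02d", 1:n),
      top_class = "pos", top_prob = score, pos = score, neg = 1 - score)
    attr(pred, "classes") <- c("pos", "neg")
    truth <- tibble::tibble(protein_id = pred$protein_id,
                            label = ifelse(is_true, "pos", "neg"))
    thr <- calibrate_thresholds(pred, truth, level = "cluster",
                                precision_floor = floor)
    row <- thr[thr$class == "pos", ]
    oracle <- brute_force_threshold(score, rep(TRUE, n), is_true, floor)
    expect_equal(row$threshold, unname(oracle["t"]))
    expect_equal(row$recall, unname(oracle["rec"]))
    expect_equal(row$mode == "F1-max", unname(oracle["mode"]) == 2)
  }
})

test_that("an unattainable precision floor falls back to the F1 optimum", {
  # the positive class never exceeds precision 0.6
  pred <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:10),
    top_class = "pos", top_prob = seq(0.91, 0.1, length.out = 10))
  pred$pos <- pred$top_prob
  pred$neg <- 1 - pred$pos
  attr(pred, "classes") <- c("pos", "neg")
  truth <- tibble::tibble(protein_id = pred$protein_id,
                          label = rep(c("neg", "pos"), 5)) # top score is neg
  thr <- calibrate_thresholds(pred, truth, level = "cluster",
                              precision_floor = 0.9)
  row <- thr[thr$class == "pos", ]
  oracle <- brute_force_threshold(pred$pos, rep(TRUE, 10),
                                  truth$label == "pos", 0.9)
  expect_equal(row$mode, "F1-max")
  expect_equal(unname(oracle["mode"]), 2)
  expect_equal(row$threshold, unname(oracle["t"]))
})

test_that("raising the precision floor never raises the selected recall", {
  set.seed(11)
  score <- runif(60)
  is_true <- runif(60) < 0.6
  pred <- tibble::tibble(protein_id = sprintf("p%02d", 1:60),
                         top_class = "pos", top_prob = score,
                         pos = score, neg = 1 - score)
  attr(pred, "classes") <- c("pos", "neg")
  truth <- tibble::tibble(protein_id = pred$protein_id,
                          label = ifelse(is_true, "pos", "neg"))
  recalls <- vapply(c(0.5, 0.7, 0.9, 0.95), function(f) {
    thr <- calibrate_thresholds(pred, truth, precision_floor = f)
    thr$recall[thr$class == "pos"]
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("a class absent from the test markers emits no threshold", {
  pred <- tibble::tibble(protein_id = c("a", "b"), top_class = c("x", "x"),
                         top_prob = c(0.9, 0.8), x = c(0.9, 0.8),
                         y = c(0.1, 0.2))
  attr(pred, "classes") <- c("x", "y")
  truth <- tibble::tibble(protein_id = c("a", "b"), label = c("x", "x"))
  thr <- calibrate_thresholds(pred, truth)
  expect_equal(thr$mode[thr$class == "y"], "absent")
  expect_true(is.na(thr$threshold[thr$class == "y"]))
  calls <- apply_thresholds(pred, thr, require_consistency = FALSE)
  expect_equal(calls$call, c("x", "x"))
})

test_that("neighborhood aggregation conserves probability mass", {
  nb_map <- default_neighborhood_map(18) |>
    dplyr::mutate(cluster = as.character(cluster))
  probs <- setNames(rep(0, 18), as.character(1:18))
  probs[c("1", "2", "9")] <- c(0.3, 0.4, 0.3)
  merged <- dplyr::bind_cols(
    tibble::tibble(protein_id = "p1", top_class = "2", top_prob = 0.4),
    tibble::as_tibble(as.list(probs)))
  attr(merged, "classes") <- as.character(1:18)
  nb <- aggregate_neighborhood(merged, nb_map)
  expect_equal(nb$secretory, 0.7)
  expect_equal(nb$nuclear, 0.3)
  expect_equal(sum(as.matrix(nb[organsort_neighborhoods()])), 1)
  expect_equal(nb$top_class, "secretory")
  probs2 <- probs * 0
  probs2["18"] <- 1
  merged2 <- dplyr::bind_cols(
    tibble::tibble(protein_id = "p2", top_class = "18", top_prob = 1),
    tibble::as_tibble(as.list(probs2)))
  attr(merged2, "classes") <- as.character(1:18)
  nb2 <- aggregate_neighborhood(merged2, nb_map)
  expect_equal(nb2$ribosome, 1)
})

test_that("cluster/neighborhood reconciliation follows the unclassified rule", {
  nb_map <- default_neighborhood_map(18) |>
    dplyr::mutate(cluster = as.character(cluster))
  cl <- tibble::tibble(
    protein_id = c("keep", "drop", "rescue", "conflict"),
    call = c("10", "10", NA, "10"),
    call_prob = c(0.9, 0.9, NA, 0.9))
  nb <- tibble::tibble(
    protein_id = c("keep", "drop", "rescue", "conflict"),
    call = c("nuclear", NA, "secretory", "cytosol"),
    call_prob = c(0.95, NA, 0.9, 0.9))
  suppressMessages(a <- reconcile_levels(cl, nb, nb_map))
  a <- a[match(c("keep", "drop", "rescue", "conflict"), a$protein_id), ]
  expect_equal(a$cluster, c("10", NA, NA, NA))
  expect_equal(a$neighborhood, c("nuclear", NA, "secretory", NA))
  expect_equal(attr(a, "n_reconciled"), 2L)
  # invariant: any protein with both calls maps consistently
  both <- !is.na(a$cluster) & !is.na(a$neighborhood)
  map <- setNames(nb_map$neighborhood, nb_map$cluster)
  expect_true(all(map[a$cluster[both]] == a$neighborhood[both]))
})
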
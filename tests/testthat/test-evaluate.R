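test_that("reference compartments map to neighborhoods; unknowns drop", {
  ref <- tibble::tibble(
    protein_id = c("a", "b", "c"),
    compartment = c("lysosome", "mitochondrion", "vesicle-X"))
  suppressMessages(mapped <- map_reference_to_neighborhoods(ref))
  expect_equal(mapped$neighborhood, c("secretory", "mitochondria"))
  expect_equal(nrow(mapped), 2)
})

test_that("agreement is the fraction of matching neighborhood calls", {
  mk_assign <- function(nb) {
    tibble::tibble(protein_id = sprintf("p%02d", seq_along(nb)),
                   cluster = NA_character_, cluster_prob = NA_real_,
                   neighborhood = nb, neighborhood_prob = 1)
  }
  nbs <- rep(c("secretory", "cytosol"), each = 5)
  ref <- tibble::tibble(protein_id = sprintf("p%02d", 1:10), neighborhood = nbs)
  expect_equal(agreement(mk_assign(nbs), ref)$overall$agreement, 1)
  flipped <- ifelse(nbs == "secretory", "cytosol", "secretory")
  expect_equal(agreement(mk_assign(flipped), ref)$overall$agreement, 0)
  seven <- nbs
  seven[1:3] <- ifelse(nbs[1:3] == "secretory", "nuclear", "secretory")
  rep7 <- agreement(mk_assign(seven), ref)
  expect_equal(rep7$overall$agreement, 0.7)
  expect_equal(rep7$overall$n, 10L)
  # per-stratum counts sum to the overlap count
  ref$grade <- rep(c("high", "low"), 5)
  strat <- agreement(mk_assign(seven), ref, stratify_by = "grade")
  expect_equal(sum(strat$by_stratum$n), strat$overall$n)
})

test_that("agreement is symmetric for single-label tables over one protein set", {
  nbs_a <- c("secretory", "cytosol", "nuclear", "cytosol")
  nbs_b <- c("secretory", "nuclear", "nuclear", "cytosol")
  ids <- sprintf("p%d", 1:4)
  a <- tibble::tibble(protein_id = ids, cluster = NA_character_,
                      cluster_prob = NA_real_, neighborhood = nbs_a,
                      neighborhood_prob = 1)
  b_ref <- tibble::tibble(protein_id = ids, neighborhood = nbs_b)
  b <- tibble::tibble(protein_id = ids, cluster = NA_character_,
                      cluster_prob = NA_real_, neighborhood = nbs_b,
                      neighborhood_prob = 1)
  a_ref <- tibble::tibble(protein_id = ids, neighborhood = nbs_a)
  expect_equal(agreement(a, b_ref)$overall, agreement(b, a_ref)$overall)
})

test_that("zero overlap reports n = 0 without fractions", {
  a <- tibble::tibble(protein_id = "x", cluster = NA_character_,
                      cluster_prob = NA_real_, neighborhood = "cytosol",
                      neighborhood_prob = 1)
  ref <- tibble::tibble(protein_id = "y", neighborhood = "cytosol")
  rep0 <- agreement(a, ref)
  expect_equal(rep0$overall$n, 0L)
  expect_true(is.na(rep0$overall$agreement))
})

test_that("marker metrics match an independently tallied confusion matrix", {
  fx <- classify_fixture()
  test_pred <- fx$merged |>
    dplyr::filter(protein_id %in% fx$split$test$protein_id)
  attr(test_pred, "classes") <- attr(fx$merged, "classes")
  thr <- calibrate_thresholds(test_pred, fx$split$test, level = "cluster")
  m <- marker_metrics(test_pred, fx$split$test, thr)

  # independent tally: plain vector arithmetic on the joined table
  joined <- merge(as.data.frame(test_pred[c("protein_id", "top_class",
                                            "top_prob", "modal_class")]),
                  as.data.frame(fx$split$test), by = "protein_id")
  thr_vec <- setNames(thr$threshold, thr$class)
  called <- !is.na(joined$top_class) &
    !is.na(joined$modal_class) & joined$modal_class == joined$top_class &
    joined$top_prob >= thr_vec[joined$top_class]
  acc_pre <- mean(joined$top_class[!is.na(joined$top_class)] ==
                    joined$label[!is.na(joined$top_class)])
  acc_post <- mean(joined$top_class[called] == joined$label[called])
  expect_equal(m$summary$accuracy_pre, acc_pre)
  expect_equal(m$summary$accuracy_post, acc_post)
  expect_equal(m$summary$n_post, sum(called))
  for (cl in unique(joined$label)) {
    expect_equal(
      m$per_class$n_predicted[m$per_class$class == cl],
      sum(called & joined$label == cl & joined$top_class == cl))
  }
})

test_that("perfect predictions score 1 and all-unclassified reports n = 0", {
  pred <- tibble::tibble(protein_id = c("a", "b"), top_class = c("1", "2"),
                         top_prob = c(0.8, 0.7),
                         `1` = c(0.8, 0.3), `2` = c(0.2, 0.7))
  attr(pred, "classes") <- c("1", "2")
  truth <- tibble::tibble(protein_id = c("a", "b"), label = c("1", "2"))
  m <- marker_metrics(pred, truth)
  expect_equal(m$summary$accuracy_pre, 1)
  expect_equal(m$summary$accuracy_post, 1)
  impossible <- tibble::tibble(level = "cluster", class = c("1", "2"),
                               threshold = 1, mode = "precision-floor",
                               precision = NA, recall = NA, f1 = NA,
                               n_true = 1L, n_predicted = 0L)
  m2 <- marker_metrics(pred, truth, impossible)
  expect_equal(m2$summary$n_post, 0L)
  expect_true(is.na(m2$summary$accuracy_post))
})
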
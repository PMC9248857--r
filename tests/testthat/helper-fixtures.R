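# Shared fixtures, lazily built and cached so expensive simulations and
# classifier fits run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small simulated experiment for structural tests
sim_small <- function() {
  memo("sim_small", simulate_experiment(generator_config(n_proteins = 300, seed = 5)))
}

# a clean, noise-controlled experiment plus a fitted classifier on planted
# labels; used by classification / evaluation tests
classify_fixture <- function() {
  memo("classify_fixture", {
    sim <- simulate_experiment(generator_config(n_proteins = 700, seed = 9))
    norm <- median_normalize(sim$quant)
    profiles <- build_profiles(norm)
    ms <- select_markers(norm)
    labeled <- dplyr::tibble(protein_id = ms$marker_ids) |>
      dplyr::inner_join(sim$truth, by = "protein_id") |>
      dplyr::filter(!is_multiloc) |>
      dplyr::transmute(protein_id, label = as.character(true_cluster))
    cfg <- svm_config(grid_preset = "coarse", cv_folds = 5, seed = 9)
    sp <- split_markers(labeled, cfg)
    fit <- train_predict(profiles, sp$train, cfg)
    merged <- merge_replicates(fit)
    list(sim = sim, norm = norm, profiles = profiles, markers = ms,
         labeled = labeled, split = sp, fit = fit, merged = merged,
         nb_map = default_neighborhood_map(18) |>
           dplyr::mutate(cluster = as.character(cluster)))
  })
}

# the full-scale benchmark run used by the acceptance checks: planted-label
# classification on the default generator (2000 proteins, contamination
# 0.05, low noise), stratified 2/3 split, coarse grid, 10-fold CV
acceptance_fixture <- function(seed = 42) {
  memo(paste0("acceptance_", seed), {
    sim <- simulate_experiment(generator_config(n_proteins = 2000, seed = seed))
    norm <- median_normalize(sim$quant)
    profiles <- build_profiles(norm)
    ms <- select_markers(norm)
    labeled <- dplyr::tibble(protein_id = ms$marker_ids) |>
      dplyr::inner_join(sim$truth, by = "protein_id") |>
      dplyr::filter(!is_multiloc) |>
      dplyr::transmute(protein_id, label = as.character(true_cluster))
    cfg <- svm_config(grid_preset = "coarse", cv_folds = 10, seed = seed)
    sp <- split_markers(labeled, cfg)
    fit <- train_predict(profiles, sp$train, cfg)
    merged <- merge_replicates(fit)
    nb_map <- default_neighborhood_map(sim$config$n_clusters) |>
      dplyr::mutate(cluster = as.character(cluster))
    test_pred <- merged |>
      dplyr::filter(protein_id %in% sp$test$protein_id)
    attr(test_pred, "classes") <- attr(merged, "classes")
    thr_cluster <- calibrate_thresholds(test_pred, sp$test, level = "cluster",
                                        precision_floor = 0.9)
    nb_pred <- aggregate_neighborhood(merged, nb_map)
    nb_test <- nb_pred |> dplyr::filter(protein_id %in% sp$test$protein_id)
    attr(nb_test, "classes") <- attr(nb_pred, "classes")
    nb_truth <- sp$test |>
      dplyr::mutate(label = nb_map$neighborhood[match(label, nb_map$cluster)])
    thr_nb <- calibrate_thresholds(nb_test, nb_truth, level = "neighborhood",
                                   precision_floor = 0.95)
    list(sim = sim, norm = norm, profiles = profiles, markers = ms,
         labeled = labeled, split = sp, fit = fit, merged = merged,
         nb_map = nb_map, test_pred = test_pred, thr_cluster = thr_cluster,
         nb_pred = nb_pred, nb_test = nb_test, nb_truth = nb_truth,
         thr_nb = thr_nb)
  })
}

# independent quadratic-time oracle for threshold calibration: exhaustive
# search over candidate thresholds, selecting max recall subject to the
# precision floor (F1-max fallback), ties to higher precision then smaller
# threshold; deliberately coded without reference to the package internals
brute_force_threshold <- function(score, is_top, is_true, floor) {
  cand <- sort(unique(c(0, 1, score)))
  stats <- t(vapply(cand, function(t) {
    pred <- is_top & score >= t
    tp <- sum(pred & is_true); fp <- sum(pred & !is_true)
    fn <- sum(is_true & !pred)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- tp / (tp + fn)
    f1 <- if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(t = t, prec = prec, rec = rec, f1 = f1)
  }, numeric(4)))
  ok <- !is.na(stats[, "prec"]) & stats[, "prec"] >= floor
  if (any(ok)) {
    s <- stats[ok, , drop = FALSE]
    s <- s[order(-s[, "rec"], -s[, "prec"], s[, "t"]), , drop = FALSE]
    c(s[1, ], mode = 1)
  } else {
    s <- stats[order(-stats[, "f1"], -stats[, "prec"], stats[, "t"]), , drop = FALSE]
    c(s[1, ], mode = 2)
  }
}

# exact hypergeometric upper tail by summation of the counting formula
# (independent of phyper); valid for any N, used for N <= 60
enum_hyper_tail <- function(b, n, B, N) {
  ks <- b:min(n, B)
  sum(choose(B, ks) * choose(N - B, n - ks)) / choose(N, n)
}

# hand-computed Benjamini-Hochberg step-up, from the definition
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# assignment table straight from the planted truth (for downstream tests
# that need perfect localization calls)
truth_assignments <- function(sim) {
  dplyr::tibble(
    protein_id = sim$truth$protein_id,
    cluster = as.character(sim$truth$true_cluster),
    cluster_prob = 1,
    neighborhood = sim$truth$true_neighborhood,
    neighborhood_prob = 1
  )
}
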
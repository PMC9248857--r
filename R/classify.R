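#' SVM classifier configuration
#'
#' Holds the radial-basis-function SVM settings: the cost and gamma grids
#' searched by 10-fold cross-validation, the train fraction of the
#' stratified marker split, and the seed. The `"paper"` preset spans cost
#' `10^-10..10^10` (21 log-spaced points) and gamma `10^-10..10` (12
#' log-spaced points); the `"coarse"` preset (5 x 3 points around the
#' useful region) trades grid resolution for speed and is the sensible
#' choice for simulated benchmarks.
#'
#' @param grid_preset `"paper"` or `"coarse"`; ignored when both grids are
#'   given explicitly.
#' @param cost_grid,gamma_grid Optional explicit numeric grids.
#' @param cv_folds Cross-validation folds (default 10).
#' @param train_fraction Stratified train fraction (default 2/3).
#' @param seed Integer seed.
#' @return A list of class `organsort_svm_config`.
#' @export
svm_config <- function(grid_preset = c("paper", "coarse"),
                       cost_grid = NULL, gamma_grid = NULL,
                       cv_folds = 10, train_fraction = 2 / 3, seed = 1) {
  grid_preset <- match.arg(grid_preset)
  if (is.null(cost_grid)) {
    cost_grid <- switch(grid_preset,
      paper = 10^seq(-10, 10, length.out = 21),
      coarse = 10^seq(-1, 5, length.out = 5))
  }
  if (is.null(gamma_grid)) {
    gamma_grid <- switch(grid_preset,
      paper = 10^seq(-10, 1, length.out = 12),
      coarse = 10^c(-2, -1, 0))
  }
  if (!length(cost_grid) || !length(gamma_grid)) abort("grids must be non-empty")
  if (cv_folds < 2) abort("`cv_folds` must be >= 2")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1)")
  }
  structure(list(cost_grid = cost_grid, gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "organsort_svm_config")
}

#' Stratified train/test split of labeled markers
#'
#' Splits labeled markers into disjoint, exhaustive train and test sets,
#' stratified by class at `cfg$train_fraction` (per class,
#' `round(fraction * n)` proteins go to training). Seeded and reproducible.
#'
#' @param labeled Tibble `protein_id`, `label`.
#' @param cfg An `organsort_svm_config`.
#' @return List with tibbles `train` and `test`.
#' @export
split_markers <- function(labeled, cfg = svm_config()) {
  counts <- labeled |> count(.data$label)
  too_small <- counts |> dplyr::filter(.data$n < cfg$cv_folds)
  if (nrow(too_small)) {
    abort(sprintf(
      paste0("classes with fewer markers than cv folds (%s): ",
             "merge clusters or reduce `cv_folds`"),
      paste(too_small$label, collapse = ", ")))
  }
  set.seed(cfg$seed)
  train_idx <- labeled |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$label) |>
    group_map(function(d, key) {
      n_tr <- max(1L, round(cfg$train_fraction * nrow(d)))
      d$.row[sample.int(nrow(d), n_tr)]
    }) |>
    unlist()
  list(train = labeled[sort(train_idx), c("protein_id", "label")],
       test = labeled[-sort(train_idx), c("protein_id", "label")])
}

#' Train per-replicate RBF-SVMs and predict class probabilities
#'
#' For each replicate, searches the cost x gamma grid by k-fold
#' cross-validated accuracy on the training markers (grid order:
#' cost-major; first maximum wins), refits the best model on the full
#' training set with probability estimates (pairwise-coupled Platt
#' scaling), and emits class probabilities for every protein with a
#' non-flagged profile in that replicate.
#'
#' @param profiles [build_profiles()] output (default scheme).
#' @param train Tibble `protein_id`, `label` (training markers).
#' @param cfg An `organsort_svm_config`.
#' @return An object of class `organsort_svmfit`: list with `prob` (tibble
#'   `protein_id`, `replicate`, one probability column per class; rows sum
#'   to 1), `tuning` (per replicate, the CV accuracy surface and the chosen
#'   point), and `classes`.
#' @export
train_predict <- function(profiles, train, cfg = svm_config()) {
  feats <- attr(profiles, "features")
  classes <- sort(unique(as.character(train$label)))
  if (length(classes) < 2) abort("training data must contain >= 2 classes")
  reps <- sort(unique(profiles$replicate))
  prob_rows <- list()
  tuning <- list()
  for (r in reps) {
    pr <- profiles |> dplyr::filter(.data$replicate == r, !.data$flagged)
    tr <- inner_join(pr, train, by = "protein_id")
    if (nrow(tr) < nrow(train)) {
      inform(sprintf("replicate %d: %d training markers lack a profile",
                     r, nrow(train) - nrow(tr)))
    }
    x <- as.matrix(tr[feats])
    y <- factor(as.character(tr$label), levels = classes)
    grid <- expand.grid(gamma = cfg$gamma_grid, cost = cfg$cost_grid,
                        KEEP.OUT.ATTRS = FALSE)  # cost-major order
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      set.seed(cfg$seed + r)
      fit <- suppressWarnings(e1071::svm(
        x, y, kernel = "radial", cost = grid$cost[g], gamma = grid$gamma[g],
        cross = cfg$cv_folds, scale = FALSE))
      acc[g] <- fit$tot.accuracy
    }
    best <- which.max(acc)
    set.seed(cfg$seed + r)
    model <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                        gamma = grid$gamma[best], probability = TRUE,
                        scale = FALSE)
    newx <- as.matrix(pr[feats])
    pred <- predict(model, newx, probability = TRUE)
    pmat <- attr(pred, "probabilities")[, classes, drop = FALSE]
    prob_rows[[length(prob_rows) + 1]] <- bind_cols(
      tibble(protein_id = pr$protein_id, replicate = r),
      as_tibble(pmat))
    tuning[[length(tuning) + 1]] <- bind_cols(
      tibble(replicate = r), as_tibble(grid),
      tibble(cv_accuracy = acc, best = seq_along(acc) == best))
  }
  structure(list(prob = bind_rows(prob_rows), tuning = bind_rows(tuning),
                 classes = classes, cfg = cfg),
            class = "organsort_svmfit")
}

#' @export
print.organsort_svmfit <- function(x, ...) {
  sel <- x$tuning |> dplyr::filter(.data$best)
  cat(sprintf("<organsort_svmfit> %d classes, %d replicates\n",
              length(x$classes), nrow(sel)))
  print(sel)
  invisible(x)
}

#' Merge per-replicate predictions by majority vote
#'
#' Takes the per-replicate argmax cluster of each protein, keeps the modal
#' cluster when it occurs in at least two replicates (otherwise the protein
#' is unclassified), and averages the probability vectors over the
#' available replicates. A protein predicted in fewer than two replicates
#' is unclassified. Ties for the within-replicate argmax withhold that
#' replicate's vote; a two-way tie in the averaged argmax leaves
#' `top_class` `NA` (conservative).
#'
#' @param fit An `organsort_svmfit` (or its `prob` tibble with a `classes`
#'   attribute).
#' @return A prediction tibble: `protein_id`, `n_replicates`,
#'   `consistency` (votes for the modal cluster), `modal_class`,
#'   `top_class` (argmax of the averaged vector), `top_prob`, plus one
#'   averaged-probability column per class; classes recorded in
#'   `attr(, "classes")`.
#' @export
merge_replicates <- function(fit) {
  if (inherits(fit, "organsort_svmfit")) {
    prob <- fit$prob
    classes <- fit$classes
  } else {
    prob <- fit
    classes <- attr(fit, "classes") %||%
      setdiff(names(fit), c("protein_id", "replicate"))
  }
  pm <- as.matrix(prob[classes])
  argmax_one <- function(v) {
    m <- max(v)
    w <- which(v >= m - 1e-12)
    if (length(w) == 1) classes[w] else NA_character_
  }
  votes <- apply(pm, 1, argmax_one)
  merged <- prob |>
    mutate(.vote = votes) |>
    group_by(.data$protein_id) |>
    group_map(function(d, key) {
      avg <- colMeans(as.matrix(d[classes]))
      v <- d$.vote[!is.na(d$.vote)]
      tab <- if (length(v)) table(v) else integer(0)
      consistency <- if (length(tab)) max(tab) else 0L
      modal <- if (nrow(d) >= 2 && length(tab) && max(tab) >= 2) {
        names(tab)[which.max(tab)]
      } else NA_character_
      top <- argmax_one(avg)
      bind_cols(
        tibble(protein_id = key$protein_id, n_replicates = nrow(d),
               consistency = as.integer(consistency),
               modal_class = modal, top_class = top,
               top_prob = if (!is.na(top)) unname(avg[top]) else max(avg)),
        as_tibble(as.list(avg)))
    }, .keep = TRUE) |>
    bind_rows()
  attr(merged, "classes") <- classes
  merged
}

#' Sum cluster probabilities into neighborhood probabilities
#'
#' Each neighborhood's probability is the sum of its member clusters'
#' averaged probabilities; the preliminary neighborhood call is the argmax
#' (ties give `NA`). Probability mass is conserved.
#'
#' @param merged A prediction tibble from [merge_replicates()].
#' @param nb_map Tibble `cluster`, `neighborhood`.
#' @return A prediction tibble at neighborhood level: `protein_id`,
#'   `top_class`, `top_prob`, one probability column per neighborhood;
#'   neighborhoods in `attr(, "classes")`.
#' @export
aggregate_neighborhood <- function(merged, nb_map) {
  classes <- attr(merged, "classes")
  map <- setNames(nb_map$neighborhood, as.character(nb_map$cluster))
  unknown <- setdiff(classes, names(map))
  if (length(unknown)) {
    abort(paste0("clusters missing from neighborhood map: ",
                 paste(unknown, collapse = ", ")))
  }
  nbs <- unique(unname(map[classes]))
  pm <- as.matrix(merged[classes])
  nb_mat <- vapply(nbs, function(nb) {
    rowSums(pm[, classes[map[classes] == nb], drop = FALSE])
  }, numeric(nrow(pm)))
  if (is.null(dim(nb_mat))) {
    nb_mat <- matrix(nb_mat, nrow = nrow(pm), dimnames = list(NULL, nbs))
  }
  argmax_one <- function(v) {
    m <- max(v)
    w <- which(v >= m - 1e-12)
    if (length(w) == 1) nbs[w] else NA_character_
  }
  top <- apply(nb_mat, 1, argmax_one)
  out <- bind_cols(
    tibble(protein_id = merged$protein_id, top_class = top,
           top_prob = apply(nb_mat, 1, max)),
    as_tibble(nb_mat))
  attr(out, "classes") <- nbs
  out
}

#' Calibrate per-class probability thresholds to a precision floor
#'
#' For every class, builds the one-vs-rest precision/recall curve over all
#' candidate thresholds — the observed distinct predicted probabilities for
#' that class plus 0 and 1 (precision-recall curves are step functions, so
#' this search is exact) — where a protein counts as predicted for the
#' class when the class holds its maximal (averaged) probability **and**
#' that probability is at least the threshold. The selected threshold
#' maximizes recall subject to precision >= `precision_floor`; when the
#' floor is unattainable the threshold maximizing F1 is selected and the
#' calibration mode is recorded as `"F1-max"`. Ties prefer higher
#' precision, then the smaller threshold. A class absent from the test set
#' gets no threshold and only emits unclassified.
#'
#' @param pred A prediction tibble ([merge_replicates()] or
#'   [aggregate_neighborhood()] output) on test markers.
#' @param truth Tibble `protein_id`, `label` (true classes of the test
#'   markers, in the same vocabulary as the prediction classes).
#' @param level `"cluster"` or `"neighborhood"` (annotation only).
#' @param precision_floor Precision floor (0.9 at cluster level, 0.95 at
#'   neighborhood level in the reference setting).
#' @return A threshold tibble: `level`, `class`, `threshold`, `mode`
#'   (`"precision-floor"`, `"F1-max"`, or `"absent"`), achieved
#'   `precision`, `recall`, `f1`, `n_true`, `n_predicted`. The full PR
#'   curves are in `attr(, "pr_curves")`.
#' @export
calibrate_thresholds <- function(pred, truth,
                                 level = c("cluster", "neighborhood"),
                                 precision_floor = NULL) {
  level <- match.arg(level)
  precision_floor <- precision_floor %||% if (level == "cluster") 0.9 else 0.95
  classes <- attr(pred, "classes")
  d <- inner_join(pred, truth, by = "protein_id")
  if (nrow(d) == 0) abort("no overlap between predictions and truth")
  rows <- list()
  curves <- list()
  for (cl in classes) {
    is_true <- d$label == cl
    n_true <- sum(is_true)
    if (n_true == 0) {
      rows[[cl]] <- tibble(level = level, class = cl, threshold = NA_real_,
                           mode = "absent", precision = NA_real_,
                           recall = NA_real_, f1 = NA_real_,
                           n_true = 0L, n_predicted = 0L)
      next
    }
    score <- d[[cl]]
    is_top <- !is.na(d$top_class) & d$top_class == cl
    cand <- sort(unique(c(0, 1, score)))
    pr <- lapply(cand, function(t) {
      predicted <- is_top & score >= t
      tp <- sum(predicted & is_true)
      fp <- sum(predicted & !is_true)
      fn <- sum(is_true & !predicted)
      precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      recall <- tp / (tp + fn)
      f1 <- if (!is.na(precision) && precision + recall > 0) {
        2 * precision * recall / (precision + recall)
      } else 0
      tibble(threshold = t, tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f1 = f1)
    }) |> bind_rows()
    curves[[cl]] <- bind_cols(tibble(level = level, class = cl), pr)
    ok <- !is.na(pr$precision) & pr$precision >= precision_floor
    if (any(ok)) {
      sub <- pr[ok, ]
      sel <- sub[order(-sub$recall, -sub$precision, sub$threshold), ][1, ]
      mode <- "precision-floor"
    } else {
      sel <- pr[order(-pr$f1, -pr$precision, pr$threshold), ][1, ]
      mode <- "F1-max"
    }
    rows[[cl]] <- tibble(level = level, class = cl,
                         threshold = sel$threshold, mode = mode,
                         precision = sel$precision, recall = sel$recall,
                         f1 = sel$f1, n_true = as.integer(n_true),
                         n_predicted = as.integer(sel$tp + sel$fp))
  }
  out <- bind_rows(rows)
  attr(out, "pr_curves") <- bind_rows(curves)
  attr(out, "precision_floor") <- precision_floor
  out
}

#' Apply calibrated thresholds to a prediction table
#'
#' A protein receives a call when its top class is unambiguous, the class
#' has a calibrated threshold, and the class probability reaches it. At
#' cluster level, when `require_consistency` is `TRUE` (the default for
#' tables carrying a `modal_class` column), the call additionally requires
#' the 2-of-3 replicate-consistent modal cluster to exist and agree with
#' the averaged argmax.
#'
#' @param pred Prediction tibble.
#' @param thresholds Threshold tibble from [calibrate_thresholds()].
#' @param require_consistency Enforce replicate-consistency (only
#'   meaningful for tables with `modal_class`).
#' @return Tibble `protein_id`, `call` (class or `NA`), `call_prob`.
#' @export
apply_thresholds <- function(pred, thresholds,
                             require_consistency = "modal_class" %in% names(pred)) {
  thr <- setNames(thresholds$threshold, thresholds$class)
  call <- pred$top_class
  prob <- pred$top_prob
  ok <- !is.na(call)
  t_of <- unname(thr[call])
  ok <- ok & !is.na(t_of) & prob >= t_of
  if (require_consistency) {
    ok <- ok & !is.na(pred$modal_class) & pred$modal_class == call
  }
  tibble(protein_id = pred$protein_id,
         call = ifelse(ok, call, NA_character_),
         call_prob = ifelse(ok, prob, NA_real_))
}

#' Reconcile cluster- and neighborhood-level calls
#'
#' A protein with a cluster call whose mapped neighborhood differs from its
#' neighborhood call — or that has a cluster call but no neighborhood call
#' — becomes unclassified at both levels. A protein with only a
#' neighborhood call keeps it (neighborhood-level rescue).
#'
#' @param cluster_calls,neighborhood_calls Output of [apply_thresholds()]
#'   at the two levels.
#' @param nb_map Tibble `cluster`, `neighborhood`.
#' @return An assignment tibble: `protein_id`, `cluster`, `cluster_prob`,
#'   `neighborhood`, `neighborhood_prob`, `reconciled` (logical: calls
#'   dropped by this rule). The number reconciled is reported via a
#'   message and stored in `attr(, "n_reconciled")`.
#' @export
reconcile_levels <- function(cluster_calls, neighborhood_calls, nb_map) {
  map <- setNames(nb_map$neighborhood, as.character(nb_map$cluster))
  d <- full_join(
    cluster_calls |> rename(cluster = "call", cluster_prob = "call_prob"),
    neighborhood_calls |> rename(neighborhood = "call",
                                 neighborhood_prob = "call_prob"),
    by = "protein_id")
  mapped <- unname(map[d$cluster])
  bad <- !is.na(d$cluster) & (is.na(d$neighborhood) | mapped != d$neighborhood)
  d$cluster[bad] <- NA_character_
  d$cluster_prob[bad] <- NA_real_
  d$neighborhood[bad] <- NA_character_
  d$neighborhood_prob[bad] <- NA_real_
  d$reconciled <- bad
  inform(sprintf("%d protein(s) inconsistent between levels set to unclassified",
                 sum(bad)))
  attr(d, "n_reconciled") <- sum(bad)
  d
}
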
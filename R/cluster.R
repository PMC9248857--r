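#' Embed marker profiles in three dimensions with t-SNE
#'
#' Embeds replicate-averaged marker profiles into a 3-D space with
#' Barnes-Hut t-SNE. Defaults follow the organelle-profiling setting:
#' perplexity 50, theta (speed/accuracy trade-off) 0.5, three output
#' dimensions. The run is seeded, so identical input and seed give
#' identical coordinates.
#'
#' @param profiles Tibble `protein_id` + feature columns (e.g. from
#'   [average_profiles()] restricted to markers).
#' @param perplexity t-SNE perplexity; requires `nrow(profiles) - 1 >=
#'   3 * perplexity`.
#' @param theta Barnes-Hut accuracy trade-off in \[0, 1\] (0 = exact).
#' @param dims Output dimensionality (default 3).
#' @param seed Integer seed.
#' @param max_iter Gradient-descent iterations.
#' @return A tibble `protein_id`, `TSNE1..TSNEd`, with the configuration in
#'   `attr(, "tsne_config")`.
#' @export
embed_tsne <- function(profiles, perplexity = 50, theta = 0.5, dims = 3,
                       seed = 1, max_iter = 1000) {
  feats <- attr(profiles, "features") %||% setdiff(names(profiles), "protein_id")
  x <- as.matrix(profiles[feats])
  n <- nrow(x)
  if (n - 1 < 3 * perplexity) {
    abort(sprintf(
      "too few proteins (%d) for perplexity %g: need n - 1 >= 3 * perplexity",
      n, perplexity))
  }
  if (theta < 0 || theta > 1) abort("`theta` must lie in [0, 1]")
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = dims, perplexity = perplexity, theta = theta,
                      pca = FALSE, check_duplicates = FALSE,
                      max_iter = max_iter, verbose = FALSE)
  out <- bind_cols(
    tibble(protein_id = profiles$protein_id),
    as_tibble(fit$Y, .name_repair = ~ paste0("TSNE", seq_len(dims))))
  attr(out, "tsne_config") <- list(perplexity = perplexity, theta = theta,
                                   dims = dims, seed = seed,
                                   max_iter = max_iter)
  out
}

#' Fit a Gaussian mixture to the embedding, selecting k by BIC
#'
#' Fits Gaussian mixture models by expectation-maximization (via mclust,
#' which initializes EM from deterministic model-based hierarchical
#' agglomeration) for each candidate number of components and selects the
#' number of clusters attaining the best BIC; ties break toward the smaller
#' k. Components with degenerate covariance are handled by mclust's
#' Bayesian regularization fallback and excluded from selection when the
#' fit fails.
#'
#' @param embedding Tibble `protein_id` + coordinate columns (from
#'   [embed_tsne()]).
#' @param k_candidates Integer vector of candidate component counts
#'   (default `1:25`).
#' @param seed Integer seed (mclust's initialization is deterministic, but
#'   the seed is fixed anyway for full reproducibility of downstream calls).
#' @return An object of class `organsort_gmm`: list with `k` (selected),
#'   `model_name`, `bic` (tibble `k`, `model`, `bic`), `labels` (tibble
#'   `protein_id`, `cluster` — the argmax membership), `membership`
#'   (probability matrix, rows summing to 1), `means`, and `loglik`.
#' @export
fit_gmm_bic <- function(embedding, k_candidates = 1:25, seed = 1) {
  coord_cols <- grep("^TSNE", names(embedding), value = TRUE)
  if (!length(coord_cols)) {
    coord_cols <- setdiff(names(embedding), "protein_id")
  }
  x <- as.matrix(embedding[coord_cols])
  if (!length(k_candidates)) abort("`k_candidates` must be non-empty")
  if (max(k_candidates) >= nrow(x)) abort("max k must be < number of points")
  set.seed(seed)
  bic <- suppressWarnings(
    mclust::mclustBIC(x, G = k_candidates, verbose = FALSE))
  bic_mat <- matrix(as.numeric(bic), nrow = nrow(bic), dimnames = dimnames(bic))
  best_per_k <- apply(bic_mat, 1, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  if (all(is.na(best_per_k))) abort("no mixture model could be fitted")
  top <- max(best_per_k, na.rm = TRUE)
  k_sel_row <- which(!is.na(best_per_k) & best_per_k >= top - 1e-8)[1]
  k_sel <- as.integer(rownames(bic_mat)[k_sel_row])
  model_sel <- colnames(bic_mat)[which.max(bic_mat[k_sel_row, ])]
  fit <- mclust::Mclust(x, G = k_sel, modelNames = model_sel, verbose = FALSE)
  z <- fit$z
  if (is.null(z)) z <- matrix(1, nrow(x), 1)
  bic_tbl <- as_tibble(bic_mat, rownames = "k") |>
    tidyr::pivot_longer(-"k", names_to = "model", values_to = "bic") |>
    mutate(k = as.integer(.data$k)) |>
    dplyr::filter(!is.na(.data$bic))
  structure(list(
    k = k_sel,
    model_name = model_sel,
    bic = bic_tbl,
    labels = tibble(protein_id = embedding$protein_id,
                    cluster = as.integer(fit$classification)),
    membership = z,
    means = fit$parameters$mean,
    loglik = fit$loglik,
    n = nrow(x)
  ), class = "organsort_gmm")
}

#' @export
print.organsort_gmm <- function(x, ...) {
  cat(sprintf("<organsort_gmm> k = %d (%s), BIC = %.1f over %d points\n",
              x$k, x$model_name,
              max(x$bic$bic[x$bic$k == x$k]), x$n))
  invisible(x)
}

#' Turn an organsort fit into a tidy tibble
#'
#' Broom-style verbs: `tidy()` returns one row per model component,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object (e.g. `organsort_gmm`).
#' @param ... Passed to methods.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidiers
#' @return For `tidy.organsort_gmm`, one row per cluster: size and mean
#'   coordinates.
#' @export
tidy.organsort_gmm <- function(x, ...) {
  sizes <- x$labels |> count(.data$cluster, name = "size")
  mu <- t(x$means)
  colnames(mu) <- paste0("mean_", seq_len(ncol(mu)))
  bind_cols(sizes, as_tibble(mu))
}

#' @rdname tidiers
#' @export
glance.organsort_gmm <- function(x, ...) {
  tibble(k = x$k, model = x$model_name,
         bic = max(x$bic$bic[x$bic$k == x$k]),
         loglik = x$loglik, n = x$n)
}
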
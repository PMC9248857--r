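#' Map reference compartment annotations to neighborhoods
#'
#' Replaces each single-compartment reference annotation with its
#' neighborhood under the same fixed dictionary used by
#' [define_neighborhoods()]. Annotations whose compartment is not in the
#' dictionary are dropped (with a message).
#'
#' @param ref Tibble `protein_id`, `compartment` (extra columns such as
#'   `source` or `reliability` are kept).
#' @param dictionary Named character vector compartment -> neighborhood.
#' @return The same tibble with a `neighborhood` column, unmappable rows
#'   removed.
#' @export
map_reference_to_neighborhoods <- function(ref,
                                           dictionary = compartment_neighborhood_dictionary()) {
  nb <- unname(dictionary[ref$compartment])
  dropped <- sum(is.na(nb))
  if (dropped > 0) {
    inform(sprintf("%d annotation(s) with unmappable compartments dropped",
                   dropped))
  }
  ref |>
    mutate(neighborhood = nb) |>
    dplyr::filter(!is.na(.data$neighborhood))
}

#' Agreement between assignments and a reference annotation
#'
#' Computed over proteins classified to a single neighborhood **and**
#' present in the reference: the fraction whose assigned neighborhood
#' equals the reference neighborhood, overall, per neighborhood (of the
#' assignment), and optionally per stratum of a reference column (e.g. a
#' reliability grade).
#'
#' @param assignments Assignment tibble (from [reconcile_levels()]), with
#'   columns `protein_id`, `neighborhood`.
#' @param ref Neighborhood-mapped reference
#'   ([map_reference_to_neighborhoods()] output); one row per protein.
#' @param stratify_by Optional name of a reference column to stratify by.
#' @return An object of class `organsort_agreement`: list with `overall`
#'   (tibble `n`, `agreement`), `by_neighborhood`, and `by_stratum` (NULL
#'   unless requested). Zero overlap gives `n = 0` and no fractions.
#' @export
agreement <- function(assignments, ref, stratify_by = NULL) {
  if (nrow(assignments) == 0 || nrow(ref) == 0) abort("inputs must be non-empty")
  ref <- distinct(ref, .data$protein_id, .keep_all = TRUE)
  d <- assignments |>
    dplyr::filter(!is.na(.data$neighborhood)) |>
    inner_join(ref, by = "protein_id", suffix = c("", "_ref"))
  if (nrow(d) == 0) {
    return(structure(list(
      overall = tibble(n = 0L, agreement = NA_real_),
      by_neighborhood = tibble(), by_stratum = NULL),
      class = "organsort_agreement"))
  }
  d$match <- d$neighborhood == d$neighborhood_ref
  overall <- tibble(n = nrow(d), agreement = mean(d$match))
  by_nb <- d |>
    group_by(neighborhood = .data$neighborhood) |>
    summarise(n = dplyr::n(), agreement = mean(.data$match), .groups = "drop")
  by_stratum <- NULL
  if (!is.null(stratify_by)) {
    if (!stratify_by %in% names(d)) {
      abort(sprintf("stratification column '%s' not found", stratify_by))
    }
    by_stratum <- d |>
      group_by(stratum = .data[[stratify_by]]) |>
      summarise(n = dplyr::n(), agreement = mean(.data$match), .groups = "drop")
  }
  structure(list(overall = overall, by_neighborhood = by_nb,
                 by_stratum = by_stratum),
            class = "organsort_agreement")
}

#' @export
print.organsort_agreement <- function(x, ...) {
  cat(sprintf("<organsort_agreement> n = %d, agreement = %s\n",
              x$overall$n,
              ifelse(is.na(x$overall$agreement), "NA",
                     sprintf("%.1f%%", 100 * x$overall$agreement))))
  if (nrow(x$by_neighborhood)) print(x$by_neighborhood)
  if (!is.null(x$by_stratum)) print(x$by_stratum)
  invisible(x)
}

#' Marker-protein classification metrics, before and after thresholding
#'
#' Scores predictions on labeled (test) markers: accuracy of the
#' preliminary argmax call before thresholding, accuracy over the proteins
#' retained after thresholding, and per-class counts in the
#' "classified / predicted" sense (classified: markers of the class
#' retained after thresholding; predicted: of those, correctly predicted).
#'
#' @param pred Prediction tibble ([merge_replicates()] or
#'   [aggregate_neighborhood()] output) on labeled markers.
#' @param truth Tibble `protein_id`, `label`.
#' @param thresholds Threshold tibble from [calibrate_thresholds()];
#'   omit (`NULL`) for pre-threshold metrics only.
#' @return List with `summary` (tibble: `n_pre`, `accuracy_pre`, `n_post`,
#'   `accuracy_post`) and `per_class` (precision/recall/F1 and counts per
#'   class, post-threshold when thresholds are given). When every protein
#'   is unclassified post-threshold, `n_post = 0` and the accuracy is `NA`.
#' @export
marker_metrics <- function(pred, truth, thresholds = NULL) {
  d <- inner_join(pred, truth, by = "protein_id")
  pre <- d |> dplyr::filter(!is.na(.data$top_class))
  acc_pre <- if (nrow(pre)) mean(pre$top_class == pre$label) else NA_real_
  if (is.null(thresholds)) {
    calls <- tibble(protein_id = pre$protein_id, call = pre$top_class)
  } else {
    calls <- apply_thresholds(d, thresholds)
  }
  dc <- d |>
    left_join(calls, by = "protein_id") |>
    dplyr::filter(!is.na(.data$call))
  acc_post <- if (nrow(dc)) mean(dc$call == dc$label) else NA_real_
  per_class <- d |>
    left_join(calls, by = "protein_id") |>
    group_by(class = .data$label) |>
    summarise(
      n_true = dplyr::n(),
      n_classified = sum(!is.na(.data$call)),
      n_predicted = sum(!is.na(.data$call) & .data$call == .data$label),
      .groups = "drop")
  fp_by_class <- d |>
    left_join(calls, by = "protein_id") |>
    dplyr::filter(!is.na(.data$call)) |>
    group_by(class = .data$call) |>
    summarise(n_called = dplyr::n(),
              tp = sum(.data$call == .data$label), .groups = "drop")
  per_class <- per_class |>
    left_join(fp_by_class, by = "class") |>
    mutate(
      n_called = tidyr::replace_na(.data$n_called, 0L),
      tp = tidyr::replace_na(.data$tp, 0L),
      precision = ifelse(.data$n_called > 0, .data$tp / .data$n_called, NA_real_),
      recall = .data$n_predicted / .data$n_true,
      f1 = ifelse(!is.na(.data$precision) & .data$precision + .data$recall > 0,
                  2 * .data$precision * .data$recall /
                    (.data$precision + .data$recall), 0))
  list(
    summary = tibble(n_pre = nrow(pre), accuracy_pre = acc_pre,
                     n_post = nrow(dc), accuracy_post = acc_post),
    per_class = per_class
  )
}
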
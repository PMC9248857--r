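#' Read a protein quantification table
#'
#' Reads a tab-separated protein-by-sample abundance table whose sample
#' columns are keyed `<organelle>_<condition>_R<replicate>` (e.g.
#' `MT_parental_R2`). Zero and missing are distinct: empty cells / `NA`
#' denote a measurement that is absent, `0` a measured zero.
#'
#' @param path Path to a TSV file with a header row; first column must be
#'   `protein_id` and ids must be unique.
#' @param dialect Column-naming scheme; only `"default"`
#'   (`organelle_condition_Rk`) is currently defined.
#' @return A tibble (`protein_id` + sample columns) whose parsed sample keys
#'   are available through [sample_info()].
#' @export
read_quant_table <- function(path, dialect = "default") {
  dialect <- match.arg(dialect)
  q <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(q)[1] != "protein_id") {
    names(q)[1] <- "protein_id"
  }
  validate_quant_table(q)
  q
}

#' Parse sample keys of a quantification table
#'
#' @param q A quantification tibble (`protein_id` + sample columns).
#' @return A tibble with one row per sample column: `sample`, `organelle`,
#'   `condition`, `replicate`.
#' @export
sample_info <- function(q) {
  keys <- setdiff(names(q), "protein_id")
  m <- regmatches(keys, regexec("^([^_]+)_([^_]+)_R([0-9]+)$", keys))
  bad <- keys[vapply(m, length, integer(1)) != 4L]
  if (length(bad)) {
    abort(paste0("unparseable sample keys: ", paste(bad, collapse = ", ")))
  }
  tibble(
    sample = keys,
    organelle = vapply(m, `[`, character(1), 2),
    condition = vapply(m, `[`, character(1), 3),
    replicate = as.integer(vapply(m, `[`, character(1), 4))
  )
}

validate_quant_table <- function(q) {
  if (anyDuplicated(q$protein_id)) {
    dup <- unique(q$protein_id[duplicated(q$protein_id)])
    abort(paste0("duplicated protein ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  info <- sample_info(q)
  if (anyDuplicated(info$sample)) abort("duplicated sample keys")
  vals <- as.matrix(q[info$sample])
  if (!is.numeric(vals)) abort("abundance columns must be numeric")
  if (any(vals < 0, na.rm = TRUE)) abort("negative abundances found")
  invisible(info)
}

#' Median-normalize each sample column
#'
#' Divides every sample column by its median over present (non-missing)
#' values, so each sample's median becomes 1. Missing entries are preserved.
#'
#' @param q Quantification tibble.
#' @return The normalized tibble, same shape.
#' @examples
#' q <- tibble::tibble(protein_id = c("a", "b", "c"),
#'                     MT_parental_R1 = c(2, 4, 6))
#' median_normalize(q)$MT_parental_R1
#' @export
median_normalize <- function(q) {
  info <- validate_quant_table(q)
  for (s in info$sample) {
    v <- q[[s]]
    if (all(is.na(v))) abort(paste0("sample column entirely missing: ", s))
    q[[s]] <- v / median(v, na.rm = TRUE)
  }
  q
}

#' Build per-replicate relative-abundance profiles
#'
#' Converts a (normalized) quantification table into the feature vectors fed
#' to the embedding and the classifiers. Under the default scheme each
#' protein contributes one row per replicate whose features are its
#' abundances across the six organelles in both conditions (12 features),
#' renormalized to sum to 1. Missing entries are imputed as 0 before
#' renormalization — absence from an organelle fraction is informative in an
#' enrichment design — and a replicate with no signal at all is flagged and
#' excluded from classification for that replicate.
#'
#' @param q Normalized quantification tibble.
#' @param scheme `"concat"` (12 features per replicate, conditions
#'   concatenated; default) or `"per_condition"` (6 features per replicate
#'   and condition).
#' @return A tibble with `protein_id`, `replicate` (and `condition` under
#'   `"per_condition"`), the feature columns, and a logical `flagged` column
#'   marking rows with no observed signal. Feature columns are recorded in
#'   `attr(, "features")`.
#' @export
build_profiles <- function(q, scheme = c("concat", "per_condition")) {
  scheme <- match.arg(scheme)
  info <- validate_quant_table(q)
  orgs <- unique(info$organelle)
  conds <- unique(info$condition)
  reps <- sort(unique(info$replicate))
  out <- list()
  for (r in reps) {
    if (scheme == "concat") {
      feat_grid <- expand.grid(organelle = orgs, condition = conds,
                               stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      cols <- sprintf("%s_%s_R%d", feat_grid$organelle, feat_grid$condition, r)
      feat_names <- sprintf("%s_%s", feat_grid$organelle, feat_grid$condition)
      missing_cols <- setdiff(cols, info$sample)
      if (length(missing_cols)) {
        abort(paste0("missing sample columns: ", paste(missing_cols, collapse = ", ")))
      }
      m <- as.matrix(q[cols])
      m[is.na(m)] <- 0
      tot <- rowSums(m)
      flagged <- tot <= 0
      m <- m / ifelse(flagged, 1, tot)
      colnames(m) <- feat_names
      out[[length(out) + 1]] <- bind_cols(
        tibble(protein_id = q$protein_id, replicate = r),
        as_tibble(m), tibble(flagged = flagged))
    } else {
      for (cond in conds) {
        cols <- sprintf("%s_%s_R%d", orgs, cond, r)
        m <- as.matrix(q[cols])
        m[is.na(m)] <- 0
        tot <- rowSums(m)
        flagged <- tot <= 0
        m <- m / ifelse(flagged, 1, tot)
        colnames(m) <- orgs
        out[[length(out) + 1]] <- bind_cols(
          tibble(protein_id = q$protein_id, replicate = r, condition = cond),
          as_tibble(m), tibble(flagged = flagged))
      }
    }
  }
  res <- bind_rows(out)
  attr(res, "features") <- setdiff(names(res),
                                   c("protein_id", "replicate", "condition", "flagged"))
  res
}

#' Average profiles across replicates
#'
#' Averages each protein's non-flagged replicate profiles and renormalizes
#' to sum 1, giving one feature vector per protein (used for the t-SNE
#' embedding and complex-member correlations).
#'
#' @param profiles Output of [build_profiles()] (default scheme).
#' @return A tibble `protein_id` + feature columns; proteins flagged in
#'   every replicate are dropped.
#' @export
average_profiles <- function(profiles) {
  feats <- attr(profiles, "features")
  res <- profiles |>
    dplyr::filter(!.data$flagged) |>
    group_by(.data$protein_id) |>
    summarise(across(all_of(feats), mean), .groups = "drop")
  m <- as.matrix(res[feats])
  m <- m / rowSums(m)
  res[feats] <- as_tibble(m)
  attr(res, "features") <- feats
  res
}
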
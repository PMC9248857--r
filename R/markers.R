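#' Select reproducible, condition-stable marker proteins
#'
#' Applies the four-stage marker filter to a median-normalized
#' quantification table with two conditions and (at least) three replicates:
#'
#' 1. median normalization (assumed already applied; see
#'    [median_normalize()]);
#' 2. keep proteins quantified in both conditions;
#' 3. keep proteins whose *minimum* pairwise Pearson correlation among the
#'    three replicate organelle profiles is at least `pcc_rep`, within each
#'    condition (the strictest reading of "replicable in triplicate");
#' 4. keep proteins whose replicate-mean profiles in the two conditions have
#'    Pearson correlation at least `pcc_cond` **and** Spearman correlation at
#'    least `scc_cond`.
#'
#' Correlations that are undefined (a constant or too-sparse profile) fail
#' the stage conservatively. The filters are conjunctive, so the final set
#' does not depend on stage order, though the per-stage retention counts do.
#'
#' @param q Median-normalized quantification tibble.
#' @param pcc_rep Minimum within-condition replicate PCC (default 0.8).
#' @param pcc_cond Minimum cross-condition PCC (default 0.8).
#' @param scc_cond Minimum cross-condition Spearman correlation (default 0.6).
#' @param pool_replicates If `TRUE`, stage 3 correlates pooled 12-dimensional
#'   profiles (both conditions concatenated) instead of per-condition
#'   6-dimensional profiles.
#' @param keep_rule Stage-4 combination: `"both"` (default; keep only
#'   proteins passing PCC and SCC, the literal reading of "filtered if
#'   PCC < 0.8 or SCC < 0.6") or `"either"`.
#' @return An object of class `organsort_markers`: a list with
#'   `marker_ids` (character), `records` (one row per protein: the
#'   correlations and `passed_stage`, the highest stage passed), and
#'   `stage_counts`.
#' @examples
#' sim <- simulate_experiment(generator_config(n_proteins = 200, seed = 3))
#' ms <- select_markers(median_normalize(sim$quant))
#' ms$stage_counts
#' @export
select_markers <- function(q, pcc_rep = 0.8, pcc_cond = 0.8, scc_cond = 0.6,
                           pool_replicates = FALSE,
                           keep_rule = c("both", "either")) {
  keep_rule <- match.arg(keep_rule)
  info <- validate_quant_table(q)
  conds <- unique(info$condition)
  reps <- sort(unique(info$replicate))
  orgs <- unique(info$organelle)
  if (length(conds) != 2) abort("marker selection requires exactly 2 conditions")
  if (length(reps) < 3) abort("marker selection requires at least 3 replicates")

  n <- nrow(q)
  # arr[protein, organelle, replicate, condition]
  arr <- array(NA_real_, dim = c(n, length(orgs), length(reps), 2))
  for (ci in 1:2) for (ri in seq_along(reps)) {
    cols <- sprintf("%s_%s_R%d", orgs, conds[ci], reps[ri])
    arr[, , ri, ci] <- as.matrix(q[cols])
  }

  safe_cor <- function(x, y, method = "pearson") {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok], method = method))
  }

  pairs <- utils::combn(seq_along(reps), 2)
  min_pcc <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (ci in 1:2) {
      if (pool_replicates && ci == 2) next
      cc <- apply(pairs, 2, function(pr) {
        if (pool_replicates) {
          x <- c(arr[i, , pr[1], 1], arr[i, , pr[1], 2])
          y <- c(arr[i, , pr[2], 1], arr[i, , pr[2], 2])
        } else {
          x <- arr[i, , pr[1], ci]
          y <- arr[i, , pr[2], ci]
        }
        safe_cor(x, y)
      })
      min_pcc[i, ci] <- if (any(is.na(cc))) NA_real_ else min(cc)
    }
  }
  if (pool_replicates) min_pcc[, 2] <- min_pcc[, 1]

  mean_prof <- function(ci) {
    apply(arr[, , , ci, drop = FALSE], c(1, 2), function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  }
  mp1 <- mean_prof(1)
  mp2 <- mean_prof(2)
  cross_pcc <- vapply(seq_len(n), function(i) safe_cor(mp1[i, ], mp2[i, ]),
                      numeric(1))
  cross_scc <- vapply(seq_len(n), function(i) {
    safe_cor(mp1[i, ], mp2[i, ], method = "spearman")
  }, numeric(1))

  present_both <- vapply(seq_len(n), function(i) {
    any(is.finite(arr[i, , , 1])) && any(is.finite(arr[i, , , 2]))
  }, logical(1))

  pass2 <- present_both
  pass3 <- pass2 & !is.na(min_pcc[, 1]) & !is.na(min_pcc[, 2]) &
    min_pcc[, 1] >= pcc_rep & min_pcc[, 2] >= pcc_rep
  s4_pcc <- !is.na(cross_pcc) & cross_pcc >= pcc_cond
  s4_scc <- !is.na(cross_scc) & cross_scc >= scc_cond
  pass4 <- pass3 & if (keep_rule == "both") s4_pcc & s4_scc else s4_pcc | s4_scc

  passed_stage <- 1L + pass2 + (pass2 & pass3) + pass4
  records <- tibble(
    protein_id = q$protein_id,
    present_both_conditions = present_both,
    min_replicate_pcc_cond1 = min_pcc[, 1],
    min_replicate_pcc_cond2 = min_pcc[, 2],
    min_replicate_pcc = pmin(min_pcc[, 1], min_pcc[, 2]),
    cross_condition_pcc = cross_pcc,
    cross_condition_scc = cross_scc,
    passed_stage = as.integer(passed_stage)
  )
  stage_counts <- tibble(
    stage = 1:4,
    description = c("normalized input", "present in both conditions",
                    sprintf("replicate PCC >= %.2f", pcc_rep),
                    sprintf("cross-condition PCC >= %.2f & SCC >= %.2f",
                            pcc_cond, scc_cond)),
    retained = c(n, sum(pass2), sum(pass3), sum(pass4))
  )
  structure(list(
    marker_ids = q$protein_id[pass4],
    records = records,
    stage_counts = stage_counts,
    thresholds = c(pcc_rep = pcc_rep, pcc_cond = pcc_cond, scc_cond = scc_cond)
  ), class = "organsort_markers")
}

#' @export
print.organsort_markers <- function(x, ...) {
  cat("<organsort_markers>\n")
  print(x$stage_counts)
  invisible(x)
}
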
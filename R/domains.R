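# expand a domain table (list-column `domains` + the three topology flags)
# into long (protein_id, domain) rows; flags become pseudo-accessions
domain_long <- function(domains) {
  base <- tibble(
    protein_id = rep(domains$protein_id,
                     vapply(domains$domains, length, integer(1))),
    domain = unlist(domains$domains) %||% character(0)
  )
  flags <- list(signal_peptide = "signal_peptide",
                transit_peptide = "transit_peptide",
                transmembrane = "transmembrane")
  extra <- lapply(names(flags), function(f) {
    if (!f %in% names(domains)) return(NULL)
    tibble(protein_id = domains$protein_id[domains[[f]] %in% TRUE],
           domain = flags[[f]])
  })
  bind_rows(base, extra) |> distinct()
}

#' Domain enrichment per localization class
#'
#' Tests every (domain, class) pair for enrichment of domain carriers
#' within the class against all assigned proteins, using the
#' hypergeometric test with Benjamini-Hochberg correction across all
#' tests. Signal-peptide, transit-peptide and transmembrane flags are
#' included as pseudo-domains. A pair is reported enriched when
#' `log2(fc) >= log2fc_cutoff` (or `fc >= fc_cutoff` with
#' `use_log2 = FALSE`), `q < q_cutoff`, and the domain occurs at least
#' `min_occurrence` times in the class.
#'
#' @param domains Domain tibble: `protein_id`, list-column `domains`,
#'   logical `signal_peptide`, `transit_peptide`, `transmembrane`.
#' @param assignments Assignment tibble ([reconcile_levels()] output).
#' @param level `"neighborhood"` or `"cluster"`.
#' @param log2fc_cutoff Log2 fold-change cutoff (default 2).
#' @param q_cutoff BH-adjusted significance cutoff (default 0.05).
#' @param min_occurrence Minimum in-class carriers (default 3).
#' @param use_log2 If `FALSE`, apply the cutoff on the plain fold change
#'   instead of its log2.
#' @return Tibble `domain`, `class`, `b`, `n`, `B`, `N`, `fc`, `log2fc`,
#'   `p`, `q`, `enriched`.
#' @export
domain_enrichment <- function(domains, assignments,
                              level = c("neighborhood", "cluster"),
                              log2fc_cutoff = 2, q_cutoff = 0.05,
                              min_occurrence = 3, use_log2 = TRUE) {
  level <- match.arg(level)
  long <- domain_long(domains)
  if (nrow(long) == 0) abort("empty domain table")
  call_col <- if (level == "neighborhood") "neighborhood" else "cluster"
  assigned <- assignments |>
    dplyr::filter(!is.na(.data[[call_col]])) |>
    select("protein_id", class = all_of(call_col))
  N <- nrow(assigned)
  if (N == 0) abort(sprintf("no %s-level calls in `assignments`", level))
  long <- inner_join(long, assigned, by = "protein_id")
  dom_tot <- long |> distinct(.data$protein_id, .data$domain) |>
    count(.data$domain, name = "B")
  class_tot <- assigned |> count(.data$class, name = "n_class")
  grid <- long |>
    count(.data$class, .data$domain, name = "b") |>
    left_join(dom_tot, by = "domain") |>
    left_join(class_tot, by = "class")
  et <- suppressWarnings(enrichment_test(grid$b, grid$n_class, grid$B, N))
  out <- bind_cols(grid |> select("domain", "class"), et)
  out$log2fc <- log2(out$fc)
  out$q <- bh_adjust(out$p)
  # use_log2 = TRUE follows the Methods reading (log2 FC >= cutoff, i.e.
  # FC >= 4 at the default); FALSE follows the figure-legend reading of a
  # plain two-fold enrichment
  stat_ok <- if (use_log2) {
    !is.na(out$log2fc) & out$log2fc >= log2fc_cutoff
  } else {
    !is.na(out$fc) & out$fc >= 2
  }
  out$enriched <- stat_ok & !is.na(out$q) & out$q < q_cutoff &
    out$b >= min_occurrence
  arrange(out, dplyr::desc(.data$enriched), .data$q)
}

#' Colocalization of protein-complex members
#'
#' For each complex: classifies its coverage (`full` if every member has a
#' profile, `partial` if some do, `none` otherwise), computes all pairwise
#' Pearson correlations between member profiles, prefilters members whose
#' mean correlation to their co-members falls below `pcc_cutoff` (greedily:
#' the worst member is dropped and the means recomputed, so one aberrant
#' member does not disqualify the rest), and — for
#' full-coverage complexes whose members all survive the prefilter — calls
#' the complex colocalized when every retained member shares one
#' neighborhood call.
#'
#' @param complexes Tibble `complex_id`, list-column `members`.
#' @param profiles Averaged profiles ([average_profiles()] output).
#' @param assignments Assignment tibble with `neighborhood` calls.
#' @param pcc_cutoff Member mean-correlation prefilter (default 0.8).
#' @return Tibble with one row per complex: `complex_id`, `n_members`,
#'   `n_identified`, `coverage`, `n_retained`, `full_after_filter`,
#'   `min_pcc`, `mean_pcc`, `neighborhoods` (collapsed calls of retained
#'   members), `colocalized`. Pairwise member correlations are in
#'   `attr(, "pairs")`.
#' @export
complex_colocalization <- function(complexes, profiles, assignments,
                                   pcc_cutoff = 0.8) {
  feats <- attr(profiles, "features") %||% setdiff(names(profiles), "protein_id")
  pm <- as.matrix(profiles[feats])
  rownames(pm) <- profiles$protein_id
  nb_of <- setNames(assignments$neighborhood, assignments$protein_id)
  rows <- list()
  pair_rows <- list()
  for (j in seq_len(nrow(complexes))) {
    cid <- complexes$complex_id[j]
    members <- unique(complexes$members[[j]])
    ident <- members[members %in% rownames(pm)]
    coverage <- if (length(ident) == length(members)) "full"
      else if (length(ident) > 0) "partial" else "none"
    if (length(ident) < 2) {
      rows[[j]] <- tibble(complex_id = cid, n_members = length(members),
                          n_identified = length(ident), coverage = coverage,
                          n_retained = length(ident),
                          full_after_filter = FALSE,
                          min_pcc = NA_real_, mean_pcc = NA_real_,
                          neighborhoods = NA_character_, colocalized = FALSE)
      next
    }
    cm <- suppressWarnings(cor(t(pm[ident, , drop = FALSE])))
    diag(cm) <- NA
    # greedy prefilter: repeatedly drop the member with the lowest mean
    # correlation to its co-members, so one aberrant member does not drag
    # every other member below the cutoff
    retained <- ident
    while (length(retained) >= 2) {
      sub <- cm[retained, retained, drop = FALSE]
      means <- rowMeans(sub, na.rm = TRUE)
      means[is.na(means)] <- -Inf
      if (all(means >= pcc_cutoff)) break
      retained <- retained[-which.min(means)]
    }
    if (length(retained) == 1) retained <- character(0)
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    pair_rows[[j]] <- tibble(complex_id = cid,
                             protein_1 = ident[ut[, 1]],
                             protein_2 = ident[ut[, 2]],
                             pcc = cm[ut])
    full_after <- coverage == "full" && length(retained) == length(members)
    nbs <- unname(nb_of[retained])
    coloc <- full_after && length(retained) >= 2 &&
      !anyNA(nbs) && length(unique(nbs)) == 1
    rows[[j]] <- tibble(
      complex_id = cid, n_members = length(members),
      n_identified = length(ident), coverage = coverage,
      n_retained = length(retained), full_after_filter = full_after,
      min_pcc = min(cm, na.rm = TRUE), mean_pcc = mean(cm, na.rm = TRUE),
      neighborhoods = paste(unique(nbs[!is.na(nbs)]), collapse = ";"),
      colocalized = coloc)
  }
  out <- bind_rows(rows)
  attr(out, "pairs") <- bind_rows(pair_rows)
  out
}

#' Null distribution of correlations for random non-complex protein pairs
#'
#' Samples protein pairs that are not co-members of any complex, computes
#' their profile correlations, and compares them with the complex-member
#' pair correlations via the two-sample Kolmogorov-Smirnov statistic.
#'
#' @param profiles Averaged profiles ([average_profiles()] output).
#' @param n_pairs Number of null pairs to sample.
#' @param complexes Complex tibble (`complex_id`, list-column `members`);
#'   its co-member pairs are excluded from the null and form the
#'   comparison sample.
#' @param seed Integer seed.
#' @return An object of class `organsort_null`: list with `null_pairs`
#'   (tibble `protein_1`, `protein_2`, `pcc`), `complex_pairs`,
#'   `ks_statistic`, `ks_p`.
#' @export
random_pair_null <- function(profiles, n_pairs, complexes, seed = 1) {
  feats <- attr(profiles, "features") %||% setdiff(names(profiles), "protein_id")
  pm <- as.matrix(profiles[feats])
  rownames(pm) <- profiles$protein_id
  ids <- profiles$protein_id
  n <- length(ids)
  if (n < 2) abort("need at least 2 proteins")
  excluded <- new.env(hash = TRUE)
  comember <- list()
  for (j in seq_len(nrow(complexes))) {
    members <- unique(complexes$members[[j]])
    members <- members[members %in% ids]
    if (length(members) < 2) next
    prs <- utils::combn(sort(members), 2)
    for (q in seq_len(ncol(prs))) {
      assign(paste(prs[1, q], prs[2, q], sep = "|"), TRUE, envir = excluded)
    }
    comember[[j]] <- tibble(protein_1 = prs[1, ], protein_2 = prs[2, ])
  }
  comember <- bind_rows(comember)
  if (nrow(comember) == 0) {
    comember <- tibble(protein_1 = character(0), protein_2 = character(0))
  }
  total_pairs <- n * (n - 1) / 2
  if (n_pairs > total_pairs - length(ls(excluded))) {
    abort("`n_pairs` exceeds the number of available non-complex pairs")
  }
  set.seed(seed)
  got <- 0L
  p1 <- character(n_pairs); p2 <- character(n_pairs)
  while (got < n_pairs) {
    i <- sample.int(n, 1); k <- sample.int(n, 1)
    if (i == k) next
    a <- ids[min(i, k)]; b <- ids[max(i, k)]
    if (!is.null(excluded[[paste(a, b, sep = "|")]])) next
    got <- got + 1L
    p1[got] <- a; p2[got] <- b
    # mark as used so the sample is without replacement
    assign(paste(a, b, sep = "|"), TRUE, envir = excluded)
  }
  pair_cor <- function(a, b) {
    vapply(seq_along(a), function(q) {
      suppressWarnings(cor(pm[a[q], ], pm[b[q], ]))
    }, numeric(1))
  }
  null_pairs <- tibble(protein_1 = p1, protein_2 = p2,
                       pcc = pair_cor(p1, p2))
  complex_pairs <- comember |>
    mutate(pcc = pair_cor(.data$protein_1, .data$protein_2))
  if (nrow(complex_pairs) > 0) {
    ks <- suppressWarnings(ks.test(complex_pairs$pcc, null_pairs$pcc))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
  } else {
    ks_stat <- NA_real_
    ks_p <- NA_real_
  }
  structure(list(null_pairs = null_pairs, complex_pairs = complex_pairs,
                 ks_statistic = ks_stat, ks_p = ks_p),
            class = "organsort_null")
}

#' @export
print.organsort_null <- function(x, ...) {
  cat(sprintf(
    "<organsort_null> %d null pairs (mean PCC %.3f) vs %d complex pairs (mean PCC %.3f); KS D = %.3f\n",
    nrow(x$null_pairs), mean(x$null_pairs$pcc, na.rm = TRUE),
    nrow(x$complex_pairs), mean(x$complex_pairs$pcc, na.rm = TRUE),
    x$ks_statistic))
  invisible(x)
}
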
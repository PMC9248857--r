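#' Hypergeometric enrichment of a compartment within a cluster
#'
#' Computes the fold change `FC = (b/n) / (B/N)` and the upper-tail
#' hypergeometric probability `P(X >= b)` of seeing `b` or more annotated
#' proteins when drawing `n` of `N` proteins of which `B` are annotated.
#' Vectorized over its arguments.
#'
#' @param b Annotated proteins in the cluster.
#' @param n Cluster size.
#' @param B Annotated proteins overall.
#' @param N All annotated proteins.
#' @return A tibble `b, n, B, N, fc, p`. `fc` is `NA` (with a warning) when
#'   `B = 0` or `n = 0`.
#' @examples
#' enrichment_test(10, 50, 20, 500)$fc # 5
#' @export
enrichment_test <- function(b, n, B, N) {
  len <- max(length(b), length(n), length(B), length(N))
  b <- rep_len(as.numeric(b), len); n <- rep_len(as.numeric(n), len)
  B <- rep_len(as.numeric(B), len); N <- rep_len(as.numeric(N), len)
  if (any(b < 0 | n < 0 | B < 0 | N < 0)) abort("counts must be non-negative")
  if (any(b > pmin(n, B))) abort("b must be <= min(n, B)")
  if (any(n > N | B > N)) abort("n and B must be <= N")
  undef <- B == 0 | n == 0
  if (any(undef)) warn("fold change undefined where B = 0 or n = 0")
  fc <- ifelse(undef, NA_real_, (b / n) / (B / N))
  p <- ifelse(undef, NA_real_, phyper(b - 1, B, N - B, n, lower.tail = FALSE))
  tibble(b = b, n = n, B = B, N = N, fc = fc, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper over `stats::p.adjust(method = "BH")`: monotone
#' step-up adjusted values, capped at 1, invariant to input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed, passed
#'   through).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# strategy maps: protein_id -> single compartment, per the five voting
# strategies over the three reference sources
annotation_strategy_maps <- function(references,
                                     source_roles = c(uniprot = "uniprot",
                                                      go = "go",
                                                      mouse = "mouse")) {
  one <- function(role) {
    references |>
      dplyr::filter(.data$source == source_roles[[role]]) |>
      distinct(.data$protein_id, .keep_all = TRUE) |>
      select("protein_id", "compartment")
  }
  u <- one("uniprot"); g <- one("go"); m <- one("mouse")
  # union: either source; when both annotate and disagree, drop the protein
  both <- inner_join(u, g, by = "protein_id", suffix = c("_u", "_g"))
  agree <- both |> dplyr::filter(.data$compartment_u == .data$compartment_g) |>
    transmute(protein_id = .data$protein_id, compartment = .data$compartment_u)
  conflict_ids <- both$protein_id[both$compartment_u != both$compartment_g]
  union_map <- bind_rows(u, anti_join(g, u, by = "protein_id")) |>
    dplyr::filter(!.data$protein_id %in% conflict_ids)
  mouse_hit <- inner_join(union_map, m, by = "protein_id",
                          suffix = c("_un", "_m")) |>
    dplyr::filter(.data$compartment_un == .data$compartment_m) |>
    transmute(protein_id = .data$protein_id, compartment = .data$compartment_un)
  list(
    uniprot_only = u,
    go_only = g,
    union = union_map,
    intersection = agree,
    union_and_mouse = mouse_hit
  )
}

#' Annotate clusters with subcellular compartments by enrichment voting
#'
#' For each of five annotation strategies — (i) proteins single-localized in
#' the UniProt-like source; (ii) in the GO-like source; (iii) in their union
#' (conflicting double annotations dropped); (iv) in their intersection
#' (both sources agree); (v) in the union restricted to proteins the
#' mouse-marker-like source confirms — every cluster x compartment pair is
#' tested for enrichment ([enrichment_test()]) and corrected by
#' Benjamini-Hochberg within the strategy. A compartment is assigned under a
#' strategy when `fc >= fc_cutoff` (inclusive) and `q < q_cutoff` (strict);
#' the final annotation requires agreement in at least `min_agree` of the 5
#' strategies (a strategy with no annotated markers is skipped but the
#' denominator stays 5).
#'
#' An optional second round re-uses the same hypergeometric machinery on a
#' protein-to-term table (`terms`) as a target-versus-background enrichment
#' per cluster; its results are appended as supplementary annotations and do
#' not participate in the vote.
#'
#' @param labels Tibble `protein_id`, `cluster` (e.g. `fit$labels` from
#'   [fit_gmm_bic()], restricted to markers).
#' @param references Long tibble `source`, `protein_id`, `compartment`.
#' @param source_roles Named character mapping the roles `uniprot`, `go`,
#'   `mouse` onto the source ids present in `references`.
#' @param fc_cutoff,q_cutoff Assignment cutoffs (defaults 2 and 0.05).
#' @param min_agree Strategies that must agree (default 3 of 5).
#' @param terms Optional tibble `protein_id`, `term` for the supplementary
#'   target-vs-background round.
#' @return An object of class `organsort_annotation`: list with `tests`
#'   (all strategy x cluster x compartment tests), `votes` (per
#'   cluster x compartment agreement counts), `annotation` (per cluster, the
#'   assigned compartment set), `majority` (each cluster's plurality
#'   reference compartment, useful as a fallback for unannotated clusters),
#'   and `supplementary`.
#' @export
annotate_clusters <- function(labels, references,
                              source_roles = c(uniprot = "uniprot",
                                               go = "go", mouse = "mouse"),
                              fc_cutoff = 2, q_cutoff = 0.05, min_agree = 3,
                              terms = NULL) {
  maps <- annotation_strategy_maps(references, source_roles)
  clusters <- sort(unique(labels$cluster))
  tests <- list()
  for (s in names(maps)) {
    ann <- inner_join(labels, maps[[s]], by = "protein_id")
    if (nrow(ann) == 0) {
      inform(sprintf("strategy '%s' has no annotated markers; skipped", s))
      next
    }
    N <- nrow(ann)
    comp_tot <- ann |> count(.data$compartment, name = "B")
    grid <- tidyr::expand_grid(cluster = clusters,
                               compartment = comp_tot$compartment) |>
      left_join(comp_tot, by = "compartment") |>
      left_join(ann |> count(.data$cluster, name = "n_cluster"),
                by = "cluster") |>
      left_join(ann |> count(.data$cluster, .data$compartment, name = "b"),
                by = c("cluster", "compartment")) |>
      mutate(b = tidyr::replace_na(.data$b, 0L),
             n_cluster = tidyr::replace_na(.data$n_cluster, 0L))
    et <- suppressWarnings(
      enrichment_test(grid$b, grid$n_cluster, grid$B, N))
    res <- bind_cols(tibble(strategy = s, cluster = grid$cluster,
                            compartment = grid$compartment), et)
    res$q <- bh_adjust(res$p)
    res$assigned <- !is.na(res$fc) & res$fc >= fc_cutoff &
      !is.na(res$q) & res$q < q_cutoff
    tests[[s]] <- res
  }
  tests <- bind_rows(tests)
  votes <- tests |>
    group_by(.data$cluster, .data$compartment) |>
    summarise(n_strategies = sum(.data$assigned), .groups = "drop") |>
    mutate(assigned = .data$n_strategies >= min_agree)
  annotation <- votes |>
    dplyr::filter(.data$assigned) |>
    group_by(.data$cluster) |>
    summarise(compartments = list(.data$compartment), .groups = "drop")
  annotation <- tibble(cluster = clusters) |>
    left_join(annotation, by = "cluster") |>
    mutate(compartments = lapply(.data$compartments, function(x) x %||% character(0)))
  majority <- inner_join(labels, maps$union, by = "protein_id") |>
    count(.data$cluster, .data$compartment) |>
    group_by(.data$cluster) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("cluster", majority_compartment = "compartment")

  supplementary <- NULL
  if (!is.null(terms)) {
    ann <- inner_join(labels, terms, by = "protein_id")
    if (nrow(ann)) {
      N <- dplyr::n_distinct(ann$protein_id)
      term_tot <- ann |> distinct(.data$protein_id, .data$term) |>
        count(.data$term, name = "B")
      grid <- ann |> distinct(.data$protein_id, .data$cluster, .data$term) |>
        count(.data$cluster, .data$term, name = "b") |>
        left_join(term_tot, by = "term") |>
        left_join(ann |> distinct(.data$protein_id, .data$cluster) |>
                    count(.data$cluster, name = "n_cluster"), by = "cluster")
      et <- suppressWarnings(
        enrichment_test(grid$b, grid$n_cluster, grid$B, N))
      supplementary <- bind_cols(grid |> select("cluster", "term"), et)
      supplementary$q <- bh_adjust(supplementary$p)
    }
  }
  structure(list(tests = tests, votes = votes, annotation = annotation,
                 majority = majority, supplementary = supplementary,
                 params = list(fc_cutoff = fc_cutoff, q_cutoff = q_cutoff,
                               min_agree = min_agree)),
            class = "organsort_annotation")
}

#' @export
print.organsort_annotation <- function(x, ...) {
  cat("<organsort_annotation>\n")
  ann <- x$annotation |>
    mutate(compartments = vapply(.data$compartments, paste, character(1),
                                 collapse = ", "))
  print(ann, n = Inf)
  invisible(x)
}

#' Collapse cluster compartment annotations to neighborhoods
#'
#' Maps each cluster's assigned compartment set through the fixed
#' compartment-to-neighborhood dictionary
#' ([compartment_neighborhood_dictionary()]). A cluster whose compartments
#' span two or more neighborhoods is an error (the conflict is listed);
#' clusters with no assigned compartment must be covered by `extra_map`.
#'
#' @param annotation An `organsort_annotation` (or a tibble `cluster`,
#'   `compartments` list-column).
#' @param extra_map Optional tibble `cluster`, `neighborhood` supplying
#'   explicit mappings for unannotated clusters.
#' @param dictionary Named character vector compartment -> neighborhood.
#' @return A tibble `cluster`, `neighborhood` covering every cluster.
#' @export
define_neighborhoods <- function(annotation, extra_map = NULL,
                                 dictionary = compartment_neighborhood_dictionary()) {
  ann <- if (inherits(annotation, "organsort_annotation")) {
    annotation$annotation
  } else annotation
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    comps <- ann$compartments[[i]]
    cl <- ann$cluster[i]
    unknown <- setdiff(comps, names(dictionary))
    if (length(unknown)) {
      abort(sprintf("cluster %s: compartments not in dictionary: %s",
                    cl, paste(unknown, collapse = ", ")))
    }
    nbs <- unique(unname(dictionary[comps]))
    if (length(nbs) > 1) {
      abort(sprintf(
        "cluster %s annotated across neighborhoods (%s); resolve manually",
        cl, paste(sprintf("%s->%s", comps, dictionary[comps]), collapse = ", ")))
    }
    if (length(nbs) == 0) {
      hit <- if (is.null(extra_map)) NA_character_ else
        extra_map$neighborhood[match(cl, extra_map$cluster)]
      if (length(hit) != 1 || is.na(hit)) {
        abort(sprintf(
          "cluster %s has no compartment annotation; supply it via `extra_map`", cl))
      }
      nbs <- hit
    }
    out[[i]] <- tibble(cluster = cl, neighborhood = nbs)
  }
  bind_rows(out)
}
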
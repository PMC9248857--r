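#' Default pipeline configuration
#'
#' Returns the full nested list of stage parameters with their reference
#' defaults: marker thresholds PCC 0.8 / SCC 0.6, t-SNE perplexity 50 and
#' theta 0.5, BIC candidates 1..25, enrichment FC >= 2 and q < 0.05 with a
#' 3-of-5 vote, 10-fold CV, a stratified 2/3 train split, and precision
#' floors 0.9 (cluster) / 0.95 (neighborhood).
#'
#' @param seed Global seed.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulate = list(n_proteins = 2000),
    markers = list(pcc_rep = 0.8, pcc_cond = 0.8, scc_cond = 0.6),
    embed = list(perplexity = 50, theta = 0.5, dims = 3),
    cluster = list(kmax = 25),
    annotate = list(fc_cutoff = 2, q_cutoff = 0.05, min_agree = 3,
                    unannotated = "majority"),
    classify = list(grid_preset = "coarse", cv_folds = 10,
                    train_fraction = 2 / 3,
                    precision_floor_cluster = 0.9,
                    precision_floor_neighborhood = 0.95),
    domains = list(level = "neighborhood", log2fc_cutoff = 2,
                   q_cutoff = 0.05, min_occurrence = 3),
    complexes = list(pcc_cutoff = 0.8, n_null_pairs = 500)
  )
}

#' Read a pipeline configuration file
#'
#' Reads a flat per-stage YAML file and merges it over
#' [default_pipeline_config()]; keys present in the file override the
#' defaults, everything else keeps its reference value.
#'
#' @param path Path to a YAML file.
#' @return A validated nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = user$seed %||% 1)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], user[[nm]])
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) abort("config field missing: seed")
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    abort("config field missing: either `simulate` or `input` is required")
  }
  if (!is.null(cfg$input)) {
    for (f in c("quant")) {
      if (is.null(cfg$input[[f]])) {
        abort(sprintf("config field missing: input$%s", f))
      }
    }
  }
  invisible(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          parent = e)
  })
}

#' Run the full localization pipeline
#'
#' Orchestrates every stage end-to-end: simulate (or read) the
#' quantification table, median-normalize, build profiles, select markers,
#' embed and cluster the markers, annotate the clusters and define
#' neighborhoods, train the per-replicate SVMs, merge and calibrate at
#' both levels, reconcile the final assignments, evaluate against the
#' reference annotations, run the domain and complex analyses, and write a
#' reproducibility manifest. All stage randomness derives from
#' `config$seed`; two runs with the same configuration are identical.
#'
#' When the Gaussian-mixture clustering leaves a cluster without a
#' compartment annotation, `annotate$unannotated = "majority"` (default)
#' maps it through its plurality reference compartment; `"error"` aborts
#' instead, matching the strict behavior of [define_neighborhoods()].
#'
#' @param config Nested configuration list ([default_pipeline_config()] or
#'   [read_pipeline_config()]).
#' @param outdir Optional output directory; when given, stage tables, the
#'   network export, and `manifest.yml` are written there.
#' @return An object of class `organsort_run`: list with the simulated (or
#'   read) data, markers, embedding, cluster model, annotation,
#'   neighborhood map, classifier fit, threshold tables, assignments,
#'   evaluation, domain/complex results, and the manifest of counts.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  validate_pipeline_config(config)
  seed <- config$seed

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    sim <- run_stage("simulate",
                     simulate_experiment(do.call(generator_config, sim_args)))
    quant <- sim$quant
    references <- sim$references
    domains_tbl <- sim$domains
    complexes_tbl <- sim$complexes
  } else {
    sim <- NULL
    quant <- run_stage("read", read_quant_table(config$input$quant))
    references <- if (!is.null(config$input$references)) {
      readr::read_tsv(config$input$references, show_col_types = FALSE)
    } else NULL
    domains_tbl <- if (!is.null(config$input$domains)) {
      d <- readr::read_tsv(config$input$domains, show_col_types = FALSE)
      d$domains <- strsplit(d$domains %||% "", ";", fixed = TRUE)
      d
    } else NULL
    complexes_tbl <- if (!is.null(config$input$complexes)) {
      d <- readr::read_tsv(config$input$complexes, show_col_types = FALSE)
      d$members <- strsplit(d$members, ";", fixed = TRUE)
      d
    } else NULL
  }

  norm <- run_stage("normalize", median_normalize(quant))
  profiles <- run_stage("profiles", build_profiles(norm))

  mk <- config$markers
  markers <- run_stage("markers", select_markers(
    norm, pcc_rep = mk$pcc_rep, pcc_cond = mk$pcc_cond,
    scc_cond = mk$scc_cond))

  avg <- average_profiles(profiles)
  marker_avg <- avg |> dplyr::filter(.data$protein_id %in% markers$marker_ids)
  attr(marker_avg, "features") <- attr(avg, "features")

  em <- config$embed
  embedding <- run_stage("embed", embed_tsne(
    marker_avg, perplexity = em$perplexity, theta = em$theta,
    dims = em$dims, seed = seed))

  gmm <- run_stage("cluster", fit_gmm_bic(
    embedding, k_candidates = seq_len(config$cluster$kmax), seed = seed))

  an <- config$annotate
  annotation <- run_stage("annotate", annotate_clusters(
    gmm$labels, references,
    fc_cutoff = an$fc_cutoff, q_cutoff = an$q_cutoff,
    min_agree = an$min_agree,
    terms = references |> select(protein_id = "protein_id",
                                 term = "compartment")))
  extra_map <- NULL
  if (identical(an$unannotated, "majority")) {
    dict <- compartment_neighborhood_dictionary()
    extra_map <- annotation$majority |>
      mutate(neighborhood = unname(dict[.data$majority_compartment])) |>
      select("cluster", "neighborhood")
  }
  nb_map <- run_stage("neighborhoods",
                      define_neighborhoods(annotation, extra_map = extra_map))

  cl <- config$classify
  labeled <- gmm$labels |>
    transmute(protein_id = .data$protein_id,
              label = as.character(.data$cluster))
  # a discovered cluster smaller than the fold count cannot support CV;
  # reduce folds rather than abort, and record the choice in the manifest
  min_class <- min(table(labeled$label))
  cv_folds <- min(cl$cv_folds, max(2L, as.integer(min_class)))
  if (cv_folds < cl$cv_folds) {
    inform(sprintf("smallest marker cluster has %d members; using %d-fold CV",
                   min_class, cv_folds))
  }
  cfg_svm <- svm_config(grid_preset = cl$grid_preset, cv_folds = cv_folds,
                        train_fraction = cl$train_fraction, seed = seed)
  split <- run_stage("split", split_markers(labeled, cfg_svm))
  fit <- run_stage("svm", train_predict(profiles, split$train, cfg_svm))
  merged <- run_stage("merge", merge_replicates(fit))

  test_truth <- split$test
  test_pred <- merged |> dplyr::filter(.data$protein_id %in% test_truth$protein_id)
  attr(test_pred, "classes") <- attr(merged, "classes")
  thr_cluster <- run_stage("calibrate-cluster", calibrate_thresholds(
    test_pred, test_truth, level = "cluster",
    precision_floor = cl$precision_floor_cluster))

  nb_map_chr <- nb_map |> mutate(cluster = as.character(.data$cluster))
  nb_pred_all <- run_stage("aggregate", aggregate_neighborhood(merged, nb_map_chr))
  nb_test_pred <- nb_pred_all |>
    dplyr::filter(.data$protein_id %in% test_truth$protein_id)
  attr(nb_test_pred, "classes") <- attr(nb_pred_all, "classes")
  nb_truth <- test_truth |>
    mutate(label = nb_map_chr$neighborhood[match(.data$label, nb_map_chr$cluster)])
  thr_nb <- run_stage("calibrate-neighborhood", calibrate_thresholds(
    nb_test_pred, nb_truth, level = "neighborhood",
    precision_floor = cl$precision_floor_neighborhood))

  cluster_calls <- apply_thresholds(merged, thr_cluster)
  nb_calls <- apply_thresholds(nb_pred_all, thr_nb)
  assignments <- run_stage("reconcile",
                           reconcile_levels(cluster_calls, nb_calls, nb_map_chr))

  evaluation <- NULL
  if (!is.null(references)) {
    ref_nb <- references |>
      distinct(.data$protein_id, .keep_all = TRUE) |>
      map_reference_to_neighborhoods()
    evaluation <- run_stage("evaluate", agreement(assignments, ref_nb))
  }
  metrics_cluster <- run_stage("metrics", marker_metrics(
    test_pred, test_truth, thr_cluster))
  metrics_nb <- marker_metrics(nb_test_pred, nb_truth, thr_nb)

  domain_res <- NULL
  if (!is.null(domains_tbl)) {
    dom_cfg <- config$domains
    domain_res <- run_stage("domains", domain_enrichment(
      domains_tbl, assignments, level = dom_cfg$level,
      log2fc_cutoff = dom_cfg$log2fc_cutoff, q_cutoff = dom_cfg$q_cutoff,
      min_occurrence = dom_cfg$min_occurrence))
  }
  complex_res <- NULL
  null_res <- NULL
  if (!is.null(complexes_tbl)) {
    cx <- config$complexes
    complex_res <- run_stage("complexes", complex_colocalization(
      complexes_tbl, avg, assignments, pcc_cutoff = cx$pcc_cutoff))
    null_res <- run_stage("null", random_pair_null(
      avg, n_pairs = cx$n_null_pairs, complexes = complexes_tbl, seed = seed))
  }

  network <- localization_network(assignments, nb_map_chr)

  n_prot <- nrow(quant)
  manifest <- list(
    package_version = as.character(utils::packageVersion("organsort")),
    seed = seed,
    parameters = config,
    counts = list(
      proteins = n_prot,
      markers = length(markers$marker_ids),
      clusters = gmm$k,
      train = nrow(split$train), test = nrow(split$test),
      cv_folds = cv_folds,
      classified_cluster = sum(!is.na(assignments$cluster)),
      classified_neighborhood = sum(!is.na(assignments$neighborhood)),
      pct_cluster = round(100 * sum(!is.na(assignments$cluster)) / n_prot, 1),
      pct_neighborhood = round(100 * sum(!is.na(assignments$neighborhood)) / n_prot, 1),
      reconciled = attr(assignments, "n_reconciled")
    )
  )

  res <- structure(list(
    sim = sim, quant = norm, profiles = profiles, markers = markers,
    embedding = embedding, gmm = gmm, annotation = annotation,
    nb_map = nb_map, svm = fit, merged = merged,
    thresholds = bind_rows(thr_cluster, thr_nb),
    assignments = assignments, evaluation = evaluation,
    metrics = list(cluster = metrics_cluster, neighborhood = metrics_nb),
    domain_enrichment = domain_res, complexes = complex_res,
    complex_null = null_res, network = network, manifest = manifest
  ), class = "organsort_run")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(markers$records, file.path(outdir, "marker_records.tsv"))
    readr::write_tsv(embedding, file.path(outdir, "embedding.tsv"))
    readr::write_tsv(gmm$labels, file.path(outdir, "cluster_membership.tsv"))
    readr::write_tsv(annotation$tests, file.path(outdir, "annotation_tests.tsv"))
    readr::write_tsv(nb_map, file.path(outdir, "neighborhood_map.tsv"))
    readr::write_tsv(fit$prob, file.path(outdir, "replicate_probabilities.tsv"))
    readr::write_tsv(res$thresholds, file.path(outdir, "thresholds.tsv"))
    readr::write_tsv(assignments, file.path(outdir, "assignments.tsv"))
    if (!is.null(domain_res)) {
      readr::write_tsv(domain_res, file.path(outdir, "domain_enrichment.tsv"))
    }
    if (!is.null(complex_res)) {
      readr::write_tsv(complex_res, file.path(outdir, "complexes.tsv"))
    }
    write_network(network, file.path(outdir, "network"))
    yaml::write_yaml(manifest_serializable(manifest),
                     file.path(outdir, "manifest.yml"))
  }
  res
}

manifest_serializable <- function(m) {
  rapply(m, function(x) {
    if (inherits(x, "data.frame")) as.list(x) else x
  }, how = "replace")
}

#' @export
print.organsort_run <- function(x, ...) {
  ct <- x$manifest$counts
  cat("<organsort_run>\n")
  cat(sprintf("  proteins: %d | markers: %d | clusters: %d\n",
              ct$proteins, ct$markers, ct$clusters))
  cat(sprintf("  classified: %d (%.1f%%) at cluster level, %d (%.1f%%) at neighborhood level\n",
              ct$classified_cluster, ct$pct_cluster,
              ct$classified_neighborhood, ct$pct_neighborhood))
  cat(sprintf("  reconciled to unclassified: %d\n", ct$reconciled))
  invisible(x)
}
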
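#' Configuration for the synthetic fractionation-experiment generator
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' defaults describe a desk-scale version of a six-organelle enrichment
#' design: six fractions (plasma membrane, ER, endosome, lysosome, Golgi,
#' mitochondria), technical triplicate, and two biological conditions
#' (parental and knock-out), with 18 planted profile clusters grouped into
#' five compartment neighborhoods.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_clusters Number of planted profile clusters (default 18).
#' @param neighborhood_map Tibble with columns `cluster`, `neighborhood`
#'   mapping every cluster to one of the five neighborhoods; defaults to
#'   [default_neighborhood_map()] (1-3 secretory, 4-8 mitochondria, 9-11
#'   nuclear, 12-17 cytosol, 18 ribosome).
#' @param organelles Ordered character vector of six distinct fraction labels.
#' @param n_replicates Technical replicates per condition (default 3).
#' @param conditions Two condition labels.
#' @param marker_fraction Proportion of proteins that are low-noise,
#'   condition-stable, single-localized marker candidates.
#' @param unstable_fraction Proportion with condition-dependent profiles (an
#'   independent cluster is drawn for the second condition).
#' @param multiloc_fraction Proportion mixing two cluster profiles 50/50, the
#'   second cluster drawn from a different neighborhood.
#' @param contamination_rate Proportion of each protein's signal redistributed
#'   across all organelles. The redistribution is uniform in expectation, but
#'   each protein draws one fixed contamination direction (symmetric
#'   Dirichlet) shared across replicates and conditions, mirroring the fact
#'   that a protein's cross-contamination pattern is a reproducible property
#'   of its biochemistry.
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   lognormal measurement noise applied to marker-candidate proteins.
#' @param nonmarker_noise_multiplier Noise inflation factor for proteins that
#'   are not marker candidates (default 3).
#' @param missing_rate Per-entry probability that a measurement is absent.
#' @param annotation_coverage Named numeric, per reference source, giving the
#'   probability that a protein carries an annotation in that source.
#' @param annotation_error Named numeric, per source, giving the probability
#'   that an annotation is wrong (a different compartment drawn uniformly).
#' @param n_complexes,complex_size_range Number of simulated protein
#'   complexes and the inclusive range of member counts.
#' @param colocalized_fraction Fraction of complexes whose members are all
#'   drawn from a single planted cluster (hence truly colocalized).
#' @param n_domains,n_planted_domains Total number of domain accessions, and
#'   how many of them are planted as neighborhood-specific.
#' @param domain_rate_in Carrier probability of a planted domain inside its
#'   neighborhood; outside it the rate is `domain_rate_in / domain_fold`.
#' @param domain_fold Enrichment factor of planted domains (default 10).
#' @param seed Integer seed; every stochastic step of the generator derives
#'   its stream from it, so runs are byte-identical for identical seeds.
#'
#' @return A validated list of class `organsort_config`.
#' @seealso [simulate_experiment()]
#' @export
generator_config <- function(n_proteins = 2000,
                             n_clusters = 18,
                             neighborhood_map = default_neighborhood_map(n_clusters),
                             organelles = organsort_organelles(),
                             n_replicates = 3,
                             conditions = c("parental", "KO"),
                             marker_fraction = 0.33,
                             unstable_fraction = 0.10,
                             multiloc_fraction = 0.05,
                             contamination_rate = 0.05,
                             noise_sd = 0.2,
                             nonmarker_noise_multiplier = 3,
                             missing_rate = 0.05,
                             annotation_coverage = c(uniprot = 0.6, go = 0.6, mouse = 0.4),
                             annotation_error = c(uniprot = 0.05, go = 0.05, mouse = 0.05),
                             n_complexes = 30,
                             complex_size_range = c(3, 6),
                             colocalized_fraction = 0.8,
                             n_domains = 24,
                             n_planted_domains = 5,
                             domain_rate_in = 0.15,
                             domain_fold = 10,
                             seed = 1) {
  check_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != as.integer(x)) {
      abort(sprintf("`%s` must be a single integer >= %d", name, min))
    }
  }
  check_prop <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      abort(sprintf("`%s` must lie in [0, 1]", name))
    }
  }
  check_count(n_proteins, "n_proteins")
  check_count(n_clusters, "n_clusters", min = 5)
  check_count(n_replicates, "n_replicates")
  check_count(n_complexes, "n_complexes", min = 0)
  for (nm in c("marker_fraction", "unstable_fraction", "multiloc_fraction",
               "contamination_rate", "missing_rate", "colocalized_fraction")) {
    check_prop(get(nm), nm)
  }
  check_prop(annotation_coverage, "annotation_coverage")
  check_prop(annotation_error, "annotation_error")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (length(organelles) != 6 || anyDuplicated(organelles)) {
    abort("`organelles` must be 6 distinct labels")
  }
  if (length(conditions) != 2 || anyDuplicated(conditions)) {
    abort("`conditions` must be 2 distinct labels")
  }
  if (!all(c("cluster", "neighborhood") %in% names(neighborhood_map)) ||
      !setequal(neighborhood_map$cluster, seq_len(n_clusters))) {
    abort("`neighborhood_map` must map clusters 1..n_clusters to neighborhoods")
  }
  if (!all(neighborhood_map$neighborhood %in% organsort_neighborhoods())) {
    abort("unknown neighborhood label in `neighborhood_map`")
  }
  if (n_clusters < length(unique(neighborhood_map$neighborhood))) {
    abort("`n_clusters` must be at least the number of neighborhoods")
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins), n_clusters = as.integer(n_clusters),
    neighborhood_map = neighborhood_map, organelles = organelles,
    n_replicates = as.integer(n_replicates), conditions = conditions,
    marker_fraction = marker_fraction, unstable_fraction = unstable_fraction,
    multiloc_fraction = multiloc_fraction,
    contamination_rate = contamination_rate, noise_sd = noise_sd,
    nonmarker_noise_multiplier = nonmarker_noise_multiplier,
    missing_rate = missing_rate,
    annotation_coverage = annotation_coverage,
    annotation_error = annotation_error,
    n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    colocalized_fraction = colocalized_fraction,
    n_domains = as.integer(n_domains),
    n_planted_domains = as.integer(n_planted_domains),
    domain_rate_in = domain_rate_in, domain_fold = domain_fold,
    seed = as.integer(seed)
  )
  structure(cfg, class = "organsort_config")
}

# Seed offsets per generator step. Each step re-seeds from config$seed plus
# its offset so that a change in one step's parameters (e.g. noise_sd) never
# perturbs the draws of any other step.
.sim_seed_offsets <- c(
  profiles = 1L, assignments = 2L, contamination = 3L, annotations = 4L,
  domains = 5L, complexes = 6L, noise = 7L, missing = 8L
)

#' Simulate an organelle-fractionation experiment with full ground truth
#'
#' Generates a protein-by-sample abundance table with the statistical
#' structure the localization pipeline assumes, plus matching reference
#' annotations (three sources), a protein-domain table, a protein-complex
#' table, and a ground-truth table recording every planted label.
#'
#' The sampling order is fixed and each step draws from its own seeded
#' stream (`config$seed` plus a documented per-step offset):
#' 1. *Cluster profiles*: one core organelle per neighborhood (sampled
#'    without replacement), then per cluster a characteristic profile
#'    supported on the core organelle alone (probability 0.3) or on the core
#'    plus one partner organelle, with the core weight drawn uniformly
#'    shaped over \[0.6, 0.95\] so the core always dominates; profiles are
#'    rejection-sampled to keep every pair of clusters at L1 distance at
#'    least 0.25.
#' 2. *Protein assignments*: `true_cluster ~ Uniform(1..K)`; independent
#'    uniforms against `unstable_fraction`, `multiloc_fraction` and
#'    `marker_fraction` set the flags (unstable excludes multi-localized,
#'    both exclude marker candidacy); total abundance per protein is
#'    lognormal; multi-localized proteins draw a partner cluster from a
#'    different neighborhood; unstable proteins draw an independent cluster
#'    for the second condition.
#' 3. *Contamination directions*: one symmetric-Dirichlet(1) direction per
#'    protein, shared by all replicates and conditions.
#' 4. *Reference annotations*: per cluster a planted compartment consistent
#'    with its neighborhood; per source, coverage and error Bernoulli draws.
#' 5. *Domains*: signal/transit/transmembrane flags tied to the secretory and
#'    mitochondrial neighborhoods; planted neighborhood-specific domain
#'    accessions at `domain_rate_in` inside versus `domain_rate_in /
#'    domain_fold` outside; uniform background domains.
#' 6. *Complexes*: a `colocalized_fraction` of complexes sample all members
#'    from the marker candidates of a single cluster; the remainder span at
#'    least two neighborhoods.
#' 7. *Noise*: standard-normal draws scaled by the protein's noise sd
#'    (markers: `noise_sd`; others: `noise_sd * nonmarker_noise_multiplier`)
#'    and applied as multiplicative lognormal noise.
#' 8. *Missingness*: per-entry Bernoulli(`missing_rate`) masking.
#'
#' The expected (noise-free) profile of a protein in a condition is
#' `(1 - contamination_rate) * cluster_profile + contamination_rate *
#' contamination_direction`, scaled by its total abundance.
#'
#' @param config An `organsort_config` from [generator_config()].
#' @return A list of class `organsort_sim` with elements `quant` (wide
#'   tibble: `protein_id` plus one `<organelle>_<condition>_R<k>` column per
#'   sample), `truth`, `references` (long tibble over the three sources),
#'   `domains`, `complexes`, `cluster_profiles`, `planted_domains`, and
#'   `config`.
#' @examples
#' sim <- simulate_experiment(generator_config(n_proteins = 150, seed = 7))
#' dim(sim$quant)
#' dplyr::count(sim$truth, true_neighborhood)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "organsort_config")) {
    abort("`config` must come from generator_config()")
  }
  cfg <- config
  n <- cfg$n_proteins
  K <- cfg$n_clusters
  orgs <- cfg$organelles
  conds <- cfg$conditions
  R <- cfg$n_replicates
  nb_of_cluster <- setNames(cfg$neighborhood_map$neighborhood,
                            cfg$neighborhood_map$cluster)
  protein_id <- sprintf("P%05d", seq_len(n))

  ## step 1: cluster characteristic profiles -------------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["profiles"]])
  nbs <- organsort_neighborhoods()
  core <- setNames(sample(orgs, length(nbs)), nbs)
  profiles <- matrix(0, K, 6, dimnames = list(NULL, orgs))
  dominant <- vector("list", K)
  for (k in seq_len(K)) {
    ck <- core[[nb_of_cluster[[as.character(k)]]]]
    best <- NULL
    best_d <- -Inf
    for (try in seq_len(200L)) {
      p <- setNames(numeric(6), orgs)
      if (runif(1) < 0.3) {
        p[ck] <- 1
        dom <- ck
      } else {
        partner <- sample(setdiff(orgs, ck), 1)
        # the core organelle always dominates (w in [0.6, 0.95]) so that
        # neighborhoods are well separated while clusters sharing a core
        # stay adjacent
        w <- 0.6 + 0.35 * rbeta(1, 2, 2)
        p[ck] <- w
        p[partner] <- 1 - w
        dom <- c(ck, partner)
      }
      d <- if (k == 1) Inf else min(colSums(abs(t(profiles[seq_len(k - 1), , drop = FALSE]) - p)))
      if (d > best_d) {
        best <- list(p = p, dom = dom)
        best_d <- d
      }
      if (d >= 0.25) break
    }
    profiles[k, ] <- best$p
    dominant[[k]] <- best$dom
  }

  ## step 2: protein assignments and flags ---------------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["assignments"]])
  true_cluster <- sample.int(K, n, replace = TRUE)
  u_unstable <- runif(n)
  u_multi <- runif(n)
  u_marker <- runif(n)
  is_unstable <- u_unstable < cfg$unstable_fraction
  is_multiloc <- !is_unstable & u_multi < cfg$multiloc_fraction
  is_marker <- !is_unstable & !is_multiloc & u_marker < cfg$marker_fraction
  base_abundance <- rlnorm(n, meanlog = log(1e6), sdlog = 1)
  second_cluster <- rep(NA_integer_, n)
  for (i in which(is_multiloc)) {
    other <- which(nb_of_cluster != nb_of_cluster[[as.character(true_cluster[i])]])
    second_cluster[i] <- other[sample.int(length(other), 1)]
  }
  ko_cluster <- rep(NA_integer_, n)
  idx_unstable <- which(is_unstable)
  if (length(idx_unstable)) {
    ko_cluster[idx_unstable] <- sample.int(K, length(idx_unstable), replace = TRUE)
  }

  ## step 3: per-protein contamination directions --------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["contamination"]])
  contam <- matrix(rgamma(n * 6, shape = 1), n, 6)
  contam <- contam / rowSums(contam)

  # expected profile per protein per condition (noise-free, pre-missingness)
  base_profile <- function(i, cond_index) {
    k1 <- true_cluster[i]
    if (is_unstable[i] && cond_index == 2L) k1 <- ko_cluster[i]
    p <- profiles[k1, ]
    if (is_multiloc[i]) p <- 0.5 * p + 0.5 * profiles[second_cluster[i], ]
    (1 - cfg$contamination_rate) * p + cfg$contamination_rate * contam[i, ]
  }
  expected <- array(0, dim = c(n, 6, 2))
  for (ci in 1:2) {
    for (i in seq_len(n)) expected[i, , ci] <- base_profile(i, ci)
  }

  ## step 4: reference annotations -----------------------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["annotations"]])
  pools <- neighborhood_compartment_pool()
  cluster_comp <- character(K)
  for (nb in nbs) {
    ks <- cfg$neighborhood_map$cluster[cfg$neighborhood_map$neighborhood == nb]
    pool <- pools[[nb]]
    perm <- if (length(pool) > 1) sample(pool) else pool
    cluster_comp[ks] <- rep(perm, length.out = length(ks))
  }
  true_comp <- cluster_comp[true_cluster]
  all_comp <- organsort_compartments()
  sources <- names(cfg$annotation_coverage)
  grades <- c("Enhanced", "Supported", "Approved", "Uncertain")
  ref_list <- list()
  for (s in sources) {
    u_cov <- runif(n)
    u_err <- runif(n)
    wrong_idx <- sample.int(length(all_comp) - 1L, n, replace = TRUE)
    reliability <- if (s == sources[[1]]) {
      sample(grades, n, replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
    } else rep(NA_character_, n)
    keep <- u_cov < cfg$annotation_coverage[[s]]
    lab <- true_comp
    err <- u_err < cfg$annotation_error[[s]]
    lab[err] <- vapply(which(err), function(i) {
      setdiff(all_comp, true_comp[i])[wrong_idx[i]]
    }, character(1))
    ref_list[[s]] <- tibble(
      source = s, protein_id = protein_id[keep], compartment = lab[keep],
      reliability = reliability[keep]
    )
  }
  references <- bind_rows(ref_list)

  ## step 5: domain table ---------------------------------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["domains"]])
  true_nb <- unname(nb_of_cluster[as.character(true_cluster)])
  signal_peptide <- runif(n) < ifelse(true_nb == "secretory", 0.5, 0.02)
  transit_peptide <- runif(n) < ifelse(true_nb == "mitochondria", 0.4, 0.01)
  transmembrane <- runif(n) < ifelse(true_nb == "secretory", 0.5, 0.1)
  domain_ids <- sprintf("PF%05d", seq_len(cfg$n_domains))
  planted_nb <- rep(nbs, length.out = cfg$n_planted_domains)
  carrier <- matrix(FALSE, n, cfg$n_domains)
  for (d in seq_len(cfg$n_domains)) {
    if (d <= cfg$n_planted_domains) {
      rate <- ifelse(true_nb == planted_nb[d],
                     cfg$domain_rate_in, cfg$domain_rate_in / cfg$domain_fold)
    } else {
      rate <- 0.05
    }
    carrier[, d] <- runif(n) < rate
  }
  domains <- tibble(
    protein_id = protein_id,
    domains = lapply(seq_len(n), function(i) domain_ids[carrier[i, ]]),
    signal_peptide = signal_peptide,
    transit_peptide = transit_peptide,
    transmembrane = transmembrane
  )
  planted_domains <- tibble(
    domain = domain_ids[seq_len(cfg$n_planted_domains)],
    neighborhood = planted_nb
  )

  ## step 6: complex table --------------------------------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["complexes"]])
  complexes <- NULL
  if (cfg$n_complexes > 0) {
    sizes <- sample(seq(cfg$complex_size_range[1], cfg$complex_size_range[2]),
                    cfg$n_complexes, replace = TRUE)
    coloc <- runif(cfg$n_complexes) < cfg$colocalized_fraction
    rows <- vector("list", cfg$n_complexes)
    for (j in seq_len(cfg$n_complexes)) {
      if (coloc[j]) {
        sizes_by_cluster <- vapply(seq_len(K), function(k) {
          sum(true_cluster == k & is_marker)
        }, integer(1))
        ok <- which(sizes_by_cluster >= sizes[j])
        if (length(ok) == 0) ok <- which(tabulate(true_cluster, K) >= sizes[j])
        if (length(ok) == 0) ok <- which.max(tabulate(true_cluster, K))
        k <- ok[sample.int(length(ok), 1)]
        elig <- which(true_cluster == k & is_marker)
        if (length(elig) < sizes[j]) elig <- which(true_cluster == k)
        members <- protein_id[sample(elig, min(sizes[j], length(elig)))]
        rows[[j]] <- tibble(complex_id = sprintf("CPX%03d", j),
                            members = list(members),
                            planted_colocalized = TRUE, planted_cluster = k)
      } else {
        for (try in seq_len(20L)) {
          members_i <- sample.int(n, sizes[j])
          if (length(unique(true_nb[members_i])) >= 2) break
        }
        rows[[j]] <- tibble(complex_id = sprintf("CPX%03d", j),
                            members = list(protein_id[members_i]),
                            planted_colocalized = FALSE,
                            planted_cluster = NA_integer_)
      }
    }
    complexes <- bind_rows(rows)
  }

  ## step 7: measurement noise ---------------------------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["noise"]])
  n_samples <- 6L * R * 2L
  z <- matrix(rnorm(n * n_samples), n, n_samples)
  sd_i <- ifelse(is_marker, cfg$noise_sd,
                 cfg$noise_sd * cfg$nonmarker_noise_multiplier)
  sample_grid <- expand.grid(organelle = orgs, replicate = seq_len(R),
                             condition = conds, stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
  sample_names <- sprintf("%s_%s_R%d", sample_grid$organelle,
                          sample_grid$condition, sample_grid$replicate)
  abund <- matrix(0, n, n_samples, dimnames = list(NULL, sample_names))
  for (j in seq_len(n_samples)) {
    o <- match(sample_grid$organelle[j], orgs)
    ci <- match(sample_grid$condition[j], conds)
    abund[, j] <- base_abundance * expected[, o, ci] * exp(sd_i * z[, j])
  }

  ## step 8: missingness ----------------------------------------------------
  set.seed(cfg$seed + .sim_seed_offsets[["missing"]])
  miss <- matrix(runif(n * n_samples) < cfg$missing_rate, n, n_samples)
  abund[miss] <- NA_real_

  quant <- bind_cols(tibble(protein_id = protein_id), as_tibble(abund))
  truth <- tibble(
    protein_id = protein_id,
    true_cluster = true_cluster,
    second_cluster = second_cluster,
    ko_cluster = ko_cluster,
    true_neighborhood = true_nb,
    true_compartment = true_comp,
    is_stable_marker_candidate = is_marker,
    is_unstable = is_unstable,
    is_multiloc = is_multiloc,
    noise_sd = sd_i,
    base_abundance = base_abundance
  )
  structure(list(
    quant = quant, truth = truth, references = references, domains = domains,
    complexes = complexes,
    cluster_profiles = as_tibble(profiles) |>
      mutate(cluster = seq_len(K),
             neighborhood = unname(nb_of_cluster[as.character(cluster)]),
             compartment = cluster_comp,
             dominant = vapply(dominant, paste, character(1), collapse = ";"),
             .before = 1),
    planted_domains = planted_domains,
    config = cfg
  ), class = "organsort_sim")
}

#' @export
print.organsort_sim <- function(x, ...) {
  cat(sprintf(
    "<organsort_sim> %d proteins x %d samples, %d clusters, seed %d\n",
    nrow(x$quant), ncol(x$quant) - 1L, x$config$n_clusters, x$config$seed))
  cat(sprintf("  markers %d | unstable %d | multi-localized %d\n",
              sum(x$truth$is_stable_marker_candidate),
              sum(x$truth$is_unstable), sum(x$truth$is_multiloc)))
  invisible(x)
}

#' Write a simulated experiment to tab-separated files
#'
#' Writes the quantification table, ground truth, the three reference
#' annotation tables, the domain and complex tables, and a YAML manifest
#' recording the generator configuration and seed.
#'
#' @param sim An `organsort_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "organsort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    quant = file.path(dir, "quant.tsv"),
    truth = file.path(dir, "truth.tsv"),
    domains = file.path(dir, "domains.tsv"),
    complexes = file.path(dir, "complexes.tsv"),
    manifest = file.path(dir, "manifest.yml")
  )
  readr::write_tsv(sim$quant, paths[["quant"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  readr::write_tsv(
    sim$domains |>
      mutate(domains = vapply(.data$domains, paste, character(1), collapse = ";")),
    paths[["domains"]])
  readr::write_tsv(
    sim$complexes |>
      mutate(members = vapply(.data$members, paste, character(1), collapse = ";")),
    paths[["complexes"]])
  for (s in unique(sim$references$source)) {
    p <- file.path(dir, sprintf("reference_%s.tsv", s))
    readr::write_tsv(dplyr::filter(sim$references, .data$source == s), p)
    paths[[paste0("reference_", s)]] <- p
  }
  cfg <- sim$config
  cfg$neighborhood_map <- as.list(setNames(cfg$neighborhood_map$neighborhood,
                                           cfg$neighborhood_map$cluster))
  yaml::write_yaml(list(generator = unclass(cfg)), paths[["manifest"]])
  invisible(paths)
}
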
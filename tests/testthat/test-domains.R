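test_that("domain fold change follows the direct formula and the occurrence rule", {
  # 400 assigned proteins, 40 secretory; domain in 8/40 secretory vs 10/400
  ids <- sprintf("p%03d", 1:400)
  nb <- c(rep("secretory", 40), rep("cytosol", 360))
  assignments <- tibble::tibble(protein_id = ids, cluster = NA_character_,
                                cluster_prob = NA_real_, neighborhood = nb,
                                neighborhood_prob = 1)
  carries <- c(ids[1:8], ids[41:42]) # B = 10
  rare <- ids[1:2] # b = 2 everywhere it appears
  domains <- tibble::tibble(
    protein_id = ids,
    domains = lapply(ids, function(i) {
      c(if (i %in% carries) "PFX" else character(0),
        if (i %in% rare) "PFRARE" else character(0))
    }),
    signal_peptide = FALSE, transit_peptide = FALSE, transmembrane = FALSE)
  res <- domain_enrichment(domains, assignments, level = "neighborhood")
  row <- res[res$domain == "PFX" & res$class == "secretory", ]
  expect_equal(row$fc, (8 / 40) / (10 / 400)) # = 8, log2 = 3
  expect_equal(row$log2fc, 3)
  expect_true(row$enriched)
  rare_row <- res[res$domain == "PFRARE" & res$class == "secretory", ]
  expect_false(rare_row$enriched) # b = 2 < min_occurrence
  # p matches the independent 2x2 enumeration
  expect_equal(row$p, enum_hyper_tail(8, 40, 10, 400), tolerance = 1e-10)
})

test_that("planted domain-neighborhood associations are recovered", {
  sim <- simulate_experiment(generator_config(n_proteins = 1500, seed = 23))
  res <- domain_enrichment(sim$domains, truth_assignments(sim),
                           level = "neighborhood", use_log2 = FALSE)
  for (i in seq_len(nrow(sim$planted_domains))) {
    row <- res[res$domain == sim$planted_domains$domain[i] &
                 res$class == sim$planted_domains$neighborhood[i], ]
    expect_true(row$enriched,
                info = paste(sim$planted_domains$domain[i], "->",
                             sim$planted_domains$neighborhood[i]))
  }
  # no planted domain is called in the wrong neighborhood
  wrong <- res |>
    dplyr::inner_join(sim$planted_domains, by = "domain") |>
    dplyr::filter(.data$class != .data$neighborhood, .data$enriched)
  expect_equal(nrow(wrong), 0)
})

test_that("identical profiles colocalize; an orthogonal member is prefiltered", {
  feats <- paste0("f", 1:6)
  mk_prof <- function(ids, v) {
    m <- matrix(rep(v, each = length(ids)), length(ids))
    colnames(m) <- feats
    dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(m))
  }
  base <- c(5, 4, 3, 2, 1, 0.5)
  prof <- dplyr::bind_rows(
    mk_prof(c("m1", "m2", "m3"), base),
    mk_prof("odd", rev(base)))
  attr(prof, "features") <- feats
  assignments <- tibble::tibble(
    protein_id = c("m1", "m2", "m3", "odd"),
    cluster = NA_character_, cluster_prob = NA_real_,
    neighborhood = "mitochondria", neighborhood_prob = 1)
  cohesive <- tibble::tibble(complex_id = "CPXA",
                             members = list(c("m1", "m2", "m3")))
  res <- complex_colocalization(cohesive, prof, assignments)
  expect_equal(res$coverage, "full")
  expect_true(res$colocalized)
  expect_equal(res$min_pcc, 1)
  with_odd <- tibble::tibble(complex_id = "CPXB",
                             members = list(c("m1", "m2", "m3", "odd")))
  res2 <- complex_colocalization(with_odd, prof, assignments)
  expect_equal(res2$n_retained, 3)
  expect_false(res2$full_after_filter)
  # a complex with members missing from the profiles
  missing <- tibble::tibble(complex_id = c("CPXC", "CPXD"),
                            members = list(c("m1", "nowhere1", "nowhere2"),
                                           c("nowhere1", "nowhere2")))
  res3 <- complex_colocalization(missing, prof, assignments)
  expect_equal(res3$coverage, c("partial", "none"))
})

test_that("coverage classes partition the complex table", {
  fx <- classify_fixture()
  sim <- fx$sim
  avg <- average_profiles(fx$profiles)
  res <- complex_colocalization(sim$complexes, avg, truth_assignments(sim))
  expect_equal(nrow(res), nrow(sim$complexes))
  expect_true(all(res$coverage %in% c("full", "partial", "none")))
})

test_that("planted colocalized complexes show high member correlation at low noise", {
  sim <- simulate_experiment(generator_config(
    n_proteins = 800, noise_sd = 0.05, missing_rate = 0, seed = 31))
  avg <- average_profiles(build_profiles(median_normalize(sim$quant)))
  res <- complex_colocalization(sim$complexes, avg, truth_assignments(sim))
  planted <- res[sim$complexes$planted_colocalized, ]
  expect_true(all(planted$min_pcc > 0.8))
  expect_true(all(planted$colocalized))
})

test_that("the random-pair null is seeded and matches full enumeration on a subset", {
  fx <- classify_fixture()
  avg <- average_profiles(fx$profiles)
  n1 <- random_pair_null(avg, 200, fx$sim$complexes, seed = 3)
  n2 <- random_pair_null(avg, 200, fx$sim$complexes, seed = 3)
  expect_identical(n1$null_pairs, n2$null_pairs)

  # on 50 proteins, request every available non-complex pair: the sampled
  # mean must equal the mean over an independent full enumeration
  sub <- avg[1:50, ]
  attr(sub, "features") <- attr(avg, "features")
  no_complex <- tibble::tibble(complex_id = character(0), members = list())
  all_pairs <- random_pair_null(sub, choose(50, 2), no_complex, seed = 1)
  cm <- cor(t(as.matrix(sub[attr(avg, "features")])))
  expect_equal(mean(all_pairs$null_pairs$pcc), mean(cm[upper.tri(cm)]),
               tolerance = 1e-12)
  expect_error(random_pair_null(sub, choose(50, 2) + 1, no_complex),
               "exceeds")
})

test_that("complex-member correlations stochastically dominate the null", {
  fx <- classify_fixture()
  avg <- average_profiles(fx$profiles)
  res <- random_pair_null(avg, 400, fx$sim$complexes, seed = 5)
  expect_gt(mean(res$complex_pairs$pcc, na.rm = TRUE),
            mean(res$null_pairs$pcc, na.rm = TRUE))
  expect_gt(res$ks_statistic, 0.3)
  # ECDF of member correlations sits below (right of) the null everywhere
  grid <- seq(-0.9, 0.9, by = 0.1)
  ecdf_c <- stats::ecdf(res$complex_pairs$pcc)
  ecdf_n <- stats::ecdf(res$null_pairs$pcc)
  expect_true(all(ecdf_c(grid) <= ecdf_n(grid) + 0.05))
})
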
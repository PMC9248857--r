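test_that("fold change follows (b/n)/(B/N)", {
  expect_equal(enrichment_test(10, 50, 20, 500)$fc, 5)
  expect_equal(enrichment_test(4, 20, 80, 400)$fc, 1) # b/n == B/N
  expect_warning(et <- enrichment_test(0, 0, 5, 10), "undefined")
  expect_true(is.na(et$fc))
})

test_that("hypergeometric tail equals exhaustive enumeration", {
  # printed case: N = 10, B = 4, n = 5, b = 3
  expected <- sum(choose(4, 3:4) * choose(6, 5 - (3:4))) / choose(10, 5)
  expect_equal(enrichment_test(3, 5, 4, 10)$p, expected, tolerance = 1e-12)
  # full subset enumeration for the same case: draw every 5-subset of 10
  draws <- utils::combn(10, 5)
  hits <- colSums(draws <= 4) # elements 1..4 are the annotated ones
  expect_equal(enrichment_test(3, 5, 4, 10)$p, mean(hits >= 3),
               tolerance = 1e-12)
  # random instances up to N = 60 against the counting formula
  set.seed(1)
  for (i in 1:25) {
    N <- sample(5:60, 1)
    B <- sample.int(N, 1)
    n <- sample.int(N, 1)
    b <- sample(0:min(n, B), 1)
    expect_equal(enrichment_test(b, n, B, N)$p, enum_hyper_tail(b, n, B, N),
                 tolerance = 1e-10)
  }
})

test_that("count constraints are enforced", {
  expect_error(enrichment_test(6, 5, 10, 20), "b must be")
  expect_error(enrichment_test(1, 5, 30, 20), "<= N")
  expect_error(enrichment_test(-1, 5, 3, 20), "non-negative")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), hand_bh(p), tolerance = 1e-12)
    # order invariance
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), bh_adjust(p)[o])
    # monotone after sorting by p
    expect_true(all(diff(bh_adjust(p)[order(p)]) > -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

# 400 labeled markers: cluster 1 holds 20 markers of which 15 are
# mitochondrial; 30 mitochondrial markers exist overall
toy_annotation_inputs <- function(sources = c("uniprot", "go", "mouse")) {
  ids <- sprintf("m%03d", 1:400)
  cluster <- c(rep(1L, 20), rep(2L, 380))
  comp <- rep("cytosol", 400)
  comp[1:15] <- "mitochondrion"          # in cluster 1
  comp[21:35] <- "mitochondrion"         # background mito -> B = 30
  labels <- tibble::tibble(protein_id = ids, cluster = cluster)
  refs <- dplyr::bind_rows(lapply(sources, function(s) {
    tibble::tibble(source = s, protein_id = ids, compartment = comp)
  }))
  list(labels = labels, refs = refs, compartment = comp)
}

test_that("a strongly enriched compartment is annotated under all strategies", {
  inp <- toy_annotation_inputs()
  ann <- annotate_clusters(inp$labels, inp$refs)
  v <- ann$votes[ann$votes$cluster == 1 & ann$votes$compartment == "mitochondrion", ]
  expect_equal(v$n_strategies, 5L)
  expect_true("mitochondrion" %in% ann$annotation$compartments[[1]])
  # and the enrichment numbers match the direct computation
  t1 <- ann$tests[ann$tests$strategy == "uniprot_only" &
                    ann$tests$cluster == 1 &
                    ann$tests$compartment == "mitochondrion", ]
  expect_equal(t1$fc, (15 / 20) / (30 / 400))
  expect_equal(t1$p, enum_hyper_tail(15, 20, 30, 400), tolerance = 1e-10)
})

test_that("agreement in fewer than three strategies assigns nothing", {
  # annotations only in the UniProt-like source: strategies (ii), (iv), (v)
  # have no annotated markers, so at most 2 of 5 can agree
  inp <- toy_annotation_inputs(sources = "uniprot")
  refs <- dplyr::bind_rows(
    inp$refs,
    tibble::tibble(source = c("go", "mouse"), protein_id = "none",
                   compartment = "cytosol"))
  suppressMessages(ann <- annotate_clusters(inp$labels, refs))
  v <- ann$votes[ann$votes$cluster == 1 & ann$votes$compartment == "mitochondrion", ]
  expect_equal(v$n_strategies, 2L) # uniprot_only and union
  expect_false("mitochondrion" %in% ann$annotation$compartments[[1]])
})

test_that("the fold-change boundary is inclusive", {
  # fc exactly 2: cluster of 100 with 20 annotated, background 40/400
  ids <- sprintf("m%03d", 1:400)
  cluster <- c(rep(1L, 100), rep(2L, 300))
  comp <- rep("cytosol", 400)
  comp[1:20] <- "mitochondrion"
  comp[101:120] <- "mitochondrion" # B = 40, fc = (20/100)/(40/400) = 2
  labels <- tibble::tibble(protein_id = ids, cluster = cluster)
  refs <- dplyr::bind_rows(lapply(c("uniprot", "go", "mouse"), function(s) {
    tibble::tibble(source = s, protein_id = ids, compartment = comp)
  }))
  ann <- annotate_clusters(labels, refs)
  t1 <- ann$tests[ann$tests$strategy == "uniprot_only" &
                    ann$tests$cluster == 1 &
                    ann$tests$compartment == "mitochondrion", ]
  expect_equal(t1$fc, 2)
  expect_lt(t1$q, 0.05)
  expect_true(t1$assigned)
})

test_that("compartments collapse to neighborhoods through the fixed dictionary", {
  ann <- tibble::tibble(
    cluster = 1:2,
    compartments = list(c("ER", "lysosome", "plasma membrane"),
                        "mitochondrion"))
  nb <- define_neighborhoods(ann)
  expect_equal(nb$neighborhood, c("secretory", "mitochondria"))
  bad <- tibble::tibble(cluster = 1, compartments = list(c("nucleus", "cytosol")))
  expect_error(define_neighborhoods(bad), "across neighborhoods")
  empty <- tibble::tibble(cluster = 1, compartments = list(character(0)))
  expect_error(define_neighborhoods(empty), "extra_map")
  expect_equal(
    define_neighborhoods(
      empty, extra_map = tibble::tibble(cluster = 1, neighborhood = "cytosol")
    )$neighborhood, "cytosol")
})

test_that("planted compartments are recovered on error-free generator annotations", {
  sim <- simulate_experiment(generator_config(
    n_proteins = 600,
    annotation_error = c(uniprot = 0, go = 0, mouse = 0),
    seed = 17))
  labels <- sim$truth |>
    dplyr::transmute(protein_id, cluster = true_cluster)
  ann <- annotate_clusters(labels, sim$references)
  planted <- sim$cluster_profiles
  for (k in planted$cluster) {
    got <- ann$annotation$compartments[[which(ann$annotation$cluster == k)]]
    expect_true(planted$compartment[planted$cluster == k] %in% got,
                info = paste("cluster", k))
  }
})
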
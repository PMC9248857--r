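#' Controlled vocabularies: organelle fractions, compartments, neighborhoods
#'
#' The pipeline works with three nested vocabularies: the six membrane-bound
#' organelle fractions that are physically enriched and quantified; the eleven
#' subcellular compartments used by reference annotation sources; and the five
#' compartment neighborhoods that related compartments collapse into.
#'
#' @return Character vectors (`organsort_organelles()`,
#'   `organsort_compartments()`, `organsort_neighborhoods()`) or a named
#'   character vector mapping compartment to neighborhood
#'   (`compartment_neighborhood_dictionary()`).
#' @examples
#' organsort_organelles()
#' compartment_neighborhood_dictionary()[["lysosome"]]
#' @name vocab
NULL

#' @rdname vocab
#' @export
organsort_organelles <- function() {
  c("PM", "ER", "ED", "LY", "GA", "MT")
}

#' @rdname vocab
#' @export
organsort_compartments <- function() {
  c("cytoskeleton", "cytosol", "nucleus", "endosome", "ER", "Golgi",
    "lysosome", "plasma membrane", "mitochondrion", "peroxisome", "ribosome")
}

#' @rdname vocab
#' @export
organsort_neighborhoods <- function() {
  c("secretory", "mitochondria", "nuclear", "cytosol", "ribosome")
}

#' @rdname vocab
#' @export
compartment_neighborhood_dictionary <- function() {
  c(
    "ER"              = "secretory",
    "Golgi"           = "secretory",
    "endosome"        = "secretory",
    "lysosome"        = "secretory",
    "plasma membrane" = "secretory",
    "peroxisome"      = "secretory",
    "mitochondrion"   = "mitochondria",
    "nucleus"         = "nuclear",
    "cytosol"         = "cytosol",
    "cytoskeleton"    = "cytosol",
    "ribosome"        = "ribosome"
  )
}

#' Default cluster-to-neighborhood layout
#'
#' The default synthetic design uses 18 clusters grouped as clusters 1-3
#' secretory, 4-8 mitochondria, 9-11 nuclear, 12-17 cytosol and 18 ribosome.
#'
#' @param n_clusters Number of clusters; layouts other than 18 spread the
#'   extra/missing clusters proportionally over the five neighborhoods.
#' @return A tibble with columns `cluster` (integer) and `neighborhood`.
#' @export
default_neighborhood_map <- function(n_clusters = 18) {
  if (n_clusters == 18) {
    nb <- c(rep("secretory", 3), rep("mitochondria", 5), rep("nuclear", 3),
            rep("cytosol", 6), rep("ribosome", 1))
  } else {
    if (n_clusters < 5) abort("need at least one cluster per neighborhood (>= 5)")
    base <- c(3, 5, 3, 6, 1) / 18
    sizes <- pmax(1, round(base * n_clusters))
    while (sum(sizes) > n_clusters) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
    while (sum(sizes) < n_clusters) sizes[which.max(base - sizes / n_clusters)] <-
        sizes[which.max(base - sizes / n_clusters)] + 1
    nb <- rep(organsort_neighborhoods(), times = sizes)
  }
  tibble(cluster = seq_len(n_clusters), neighborhood = nb)
}

# compartments that are plausible planted identities for each neighborhood
neighborhood_compartment_pool <- function() {
  list(
    secretory    = c("ER", "Golgi", "endosome", "lysosome", "plasma membrane",
                     "peroxisome"),
    mitochondria = "mitochondrion",
    nuclear      = "nucleus",
    cytosol      = c("cytosol", "cytoskeleton"),
    ribosome     = "ribosome"
  )
}
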
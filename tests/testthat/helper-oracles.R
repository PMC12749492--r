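# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# Zeta by direct set enumeration over explicit taxon-name sets.
oracle_zeta <- function(site_sets, i, jaccard = FALSE) {
  combos <- utils::combn(length(site_sets), i, simplify = FALSE)
  vals <- sapply(combos, function(s) {
    inter <- Reduce(intersect, site_sets[s])
    if (!jaccard) return(length(inter))
    uni <- Reduce(union, site_sets[s])
    if (length(uni) == 0) 0 else length(inter) / length(uni)
  })
  mean(vals)
}

# The worked three-site community used in several oracle tests.
three_site_sets <- list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"),
                        s3 = c("C", "D", "E"))

sets_to_incidence <- function(site_sets, coords = NULL) {
  taxa <- sort(unique(unlist(site_sets)))
  m <- sapply(site_sets, function(s) taxa %in% s)
  rownames(m) <- taxa
  incidence_matrix(m * 1, coords = coords)
}

# Small abundance fixture with metadata.
toy_abundance <- function() {
  counts <- matrix(
    c(20, 40, 60,
      10, 10, 10,
      5, 0, 0,
      1, 2, 3),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("t", 1:4), paste0("s", 1:3))
  )
  md <- data.frame(sample = paste0("s", 1:3), glacier = "g",
                   age_class = c("A", "A", "B"), age_years = c(1, 2, 10),
                   lat = c(0, 0.01, 0.02), lon = 0)
  abundance_matrix(counts, md)
}
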
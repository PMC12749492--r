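mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], family = r[[2]], pct_identity = r[[3]],
               alignment_length_aa = r[[4]], evalue = 1e-10,
               bitscore = r[[5]], query_cov_pct = r[[6]],
               subject_cov_pct = r[[7]], stringsAsFactors = FALSE)
  }))
}

test_that("read-mode filtering applies per-family identity thresholds", {
  man <- default_marker_manifest()
  hits <- mk_hits(
    list("r1", "rho", 42, 50, 100, 85, 50),   # rho threshold 40 -> retained
    list("r2", "sqr", 42, 50, 100, 85, 50),   # default 50 -> removed
    list("r3", "psaA", 75, 50, 100, 85, 50),  # psaA threshold 80 -> removed
    list("r4", "hbsT", 76, 50, 100, 85, 50),  # hbsT threshold 75 -> retained
    list("r5", "coxL", 62, 50, 100, 70, 50)   # qcov below 80 -> removed
  )
  out <- filter_read_hits(hits, man)
  expect_setequal(out$id, c("r1", "r4"))
  expect_error(filter_read_hits(mk_hits(list("r", "noSuchFam", 90, 50, 100, 90, 50)), man),
               "noSuchFam")
})

test_that("MAG-mode filtering uses the length-or-coverage rule with protein thresholds", {
  man <- default_marker_manifest()
  hits <- mk_hits(
    list("p1", "sqr", 55, 35, 100, 50, 85),   # short but scov 85 -> retained
    list("p2", "cyc2", 36, 50, 100, 50, 50),  # cyc2 protein threshold 35 -> retained
    list("p3", "sqr", 90, 30, 100, 50, 50),   # all three disjuncts fail -> removed
    list("p4", "rho", 32, 45, 100, 50, 50),   # rho protein threshold 30 -> retained
    list("p5", "atpA", 62, 45, 100, 50, 50)   # atpA protein threshold 60 -> retained
  )
  out <- filter_mag_hits(hits, man)
  expect_setequal(out$id, c("p1", "p2", "p4", "p5"))
})

test_that("best hit per read resolves by bitscore before filtering", {
  man <- default_marker_manifest()
  hits <- mk_hits(
    list("r1", "sqr", 90, 50, 120, 85, 50),
    list("r1", "coxL", 90, 50, 200, 85, 50), # higher bitscore wins
    list("r2", "sqr", 90, 50, 100, 85, 50),
    list("r2", "dsrA", 90, 50, 100, 85, 50)  # tie: first after family sort
  )
  out <- filter_read_hits(hits, man)
  expect_equal(out$family[out$id == "r1"], "coxL")
  expect_equal(nrow(out[out$id == "r2", ]), 1)
  expect_equal(out$family[out$id == "r2"], "dsrA") # dsrA < sqr alphabetically
})

test_that("filtering is idempotent", {
  man <- default_marker_manifest()
  set.seed(3)
  hits <- generate_marker_hits(
    generate_community(default_designs(3)$antarctic,
                       default_community_truths(), 1e4, seed = 3),
    man, reads_total = 1e5, fail_fraction = 0.3, seed = 3)
  once <- filter_read_hits(hits, man)
  twice <- filter_read_hits(once, man)
  expect_equal(twice, once)
})

test_that("every retained row satisfies its predicate, every removed row violates it", {
  man <- default_marker_manifest()
  cm <- generate_community(default_designs(4)$antarctic,
                           default_community_truths(), 1e4, seed = 4)
  hits <- generate_marker_hits(cm, man, reads_total = 1e5,
                               fail_fraction = 0.25, seed = 4)
  out <- filter_read_hits(hits, man)
  idx_out <- match(out$family, man$family)
  expect_true(all(out$query_cov_pct >= man$min_query_cov_pct[idx_out]))
  expect_true(all(out$pct_identity >= man$min_identity_pct[idx_out]))
  removed <- hits[!hits$id %in% out$id, ]
  idx_rm <- match(removed$family, man$family)
  expect_true(all(removed$query_cov_pct < man$min_query_cov_pct[idx_rm] |
                    removed$pct_identity < man$min_identity_pct[idx_rm]))
  # planted failures are exactly the rows 10 points below threshold
  planted <- hits$pct_identity == man$min_identity_pct[match(hits$family, man$family)] - 10
  expect_setequal(out$id, hits$id[!planted])
})

test_that("rpkm arithmetic and proportionality", {
  expect_equal(rpkm(30, 500, 2e6), 10)
  expect_equal(rpkm(0, 500, 2e6), 0)
  expect_equal(rpkm(30, 500, 4e6), 5) # doubling depth halves rpkm
  expect_error(rpkm(1, 0, 1e6), "zero-length")
  expect_error(rpkm(1, 500, 0), "positive")
})

test_that("copies per organism normalises by mean ribosomal rpkm", {
  man <- marker_manifest(data.frame(
    family = c("geneA", "riboA", "riboB"),
    min_identity_pct = 50, min_identity_pct_protein = 50,
    min_query_cov_pct = 80, mean_ref_length_aa = c(500, 200, 200),
    category = c("metabolic", "ribosomal", "ribosomal"),
    is_single_copy_ribosomal = c(FALSE, TRUE, TRUE)
  ))
  # geneA rpkm 10 (30 hits / 1.5 kb / 2M), ribo mean 40 (48 hits / 0.6 kb each)
  hits <- data.frame(
    id = sprintf("r%03d", 1:126),
    family = rep(c("geneA", "riboA", "riboB"), c(30, 48, 48)),
    pct_identity = 90, alignment_length_aa = 50, evalue = 1e-10,
    bitscore = 100, query_cov_pct = 90, subject_cov_pct = 50
  )
  prof <- gene_profile(hits, man, total_reads = 2e6)
  expect_equal(prof$rpkm[prof$family == "geneA"], 10)
  expect_equal(attr(prof, "ribosomal_mean_rpkm"), 40)
  expect_equal(prof$copies_per_organism[prof$family == "geneA"], 0.25)
  expect_equal(prof$percent_of_cells[prof$family == "geneA"], 25)
  expect_equal(prof$copies_per_organism[prof$family == "riboA"], 1)
  expect_false(any(prof$multicopy_flag))
})

test_that("copies per organism is invariant to sequencing depth", {
  man <- default_marker_manifest()
  cm <- generate_community(default_designs(5)$antarctic,
                           default_community_truths(), 1e4, seed = 5)
  hits <- generate_marker_hits(cm, man, reads_total = 1e6, seed = 5)
  p1 <- gene_profile(filter_read_hits(hits, man), man, total_reads = 1e6)
  p2 <- gene_profile(filter_read_hits(hits, man), man, total_reads = 5e6)
  expect_equal(p2$copies_per_organism, p1$copies_per_organism,
               tolerance = 1e-12)
})

test_that("planted carrier fractions are recovered within Monte-Carlo error", {
  man <- default_marker_manifest()
  # community where carriers of coxL hold ~half the abundance
  truths <- rbind(
    community_truth("c1", "generalist", 0.25, 0.1, c("coxL", "nuoF")),
    community_truth("c2", "generalist", 0.25, 0.1, c("coxL", "nuoF")),
    community_truth("e1", "early_opportunist", 0.25, 0.1, "sqr"),
    community_truth("l1", "late_specialist", 0.25, 0.1, "pmoA")
  )
  des <- default_designs(6)$antarctic
  cm <- generate_community(des, truths, 1e5, seed = 6)
  hits <- generate_marker_hits(cm, man, reads_total = 1e6, seed = 6)
  prof <- gene_profile(filter_read_hits(hits, man), man, total_reads = 1e6)
  planted <- attr(hits, "carrier_fraction")[["coxL"]]
  got <- prof$copies_per_organism[prof$family == "coxL"]
  expect_equal(got, planted, tolerance = 0.1)
  expect_equal(planted, 0.5, tolerance = 0.1)
  # saturation / absence
  expect_equal(prof$copies_per_organism[prof$family == "mmoX"], 0)
})

test_that("MAG signature summary applies completeness correction", {
  ann <- data.frame(
    mag_id = c("m1", "m2", "m3", "m4"),
    completeness_pct = c(50, 100, 80, 90),
    signature_gene_count = c(6, 8, 4, 5),
    glacier = "antarctic"
  )
  spec <- data.frame(taxon = c("m1", "m2", "m3"),
                     habitat_class = c("generalist", "generalist", "specialist"))
  expect_warning(out <- mag_signature_summary(ann, spec), "1 MAG")
  gen <- out$mean_corrected_count[out$habitat_class == "generalist"]
  expect_equal(gen, mean(c(6 / 0.5, 8 / 1)))   # corrected 12 and 8
  spc <- out$mean_corrected_count[out$habitat_class == "specialist"]
  expect_equal(spc, 4 / 0.8)
  expect_error(
    mag_signature_summary(transform(ann, completeness_pct = c(0, 100, 80, 90)), spec),
    "completeness")
})

test_that("planted generalists carry more signature genes than specialists", {
  truths <- default_community_truths()
  ann <- data.frame(mag_id = truths$taxon_id, completeness_pct = 100,
                    signature_gene_count = truths$genes_per_genome)
  spec <- data.frame(
    taxon = truths$taxon_id,
    habitat_class = ifelse(truths$guild == "generalist", "generalist",
                           "specialist"))
  out <- mag_signature_summary(ann, spec)
  expect_gt(out$mean_corrected_count[out$habitat_class == "generalist"],
            out$mean_corrected_count[out$habitat_class == "specialist"])
})

test_that("hit tables round-trip through the outfmt-6 reader", {
  rows <- data.frame(
    q = c("r1", "r2"), s = c("rho", "sqr"), pid = c(42.5, 88),
    alen = c(50, 45), mm = 0, go = 0, qs = 1, qe = 150, ss = 1, se = 50,
    ev = 1e-10, bits = c(100, 120), qcov = c(85, 92), scov = c(40, 60))
  f <- tempfile(fileext = ".tsv")
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  hits <- read_marker_hits(f)
  expect_equal(hits$family, c("rho", "sqr"))
  expect_equal(hits$pct_identity, c(42.5, 88))
  expect_equal(hits$query_cov_pct, c(85, 92))
  expect_equal(hits$subject_cov_pct, c(40, 60))
})
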
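#' Marker-gene family manifest
#'
#' Per-family filtering thresholds and reference lengths for profiling
#' metabolic marker genes from homology-search hit tables. Two threshold
#' columns exist: `min_identity_pct` for short-read profiling and
#' `min_identity_pct_protein` for predicted proteins from genome bins (MAG
#' mode). Universal single-copy ribosomal protein families are flagged with
#' `is_single_copy_ribosomal` and anchor the copies-per-organism
#' normalisation.
#'
#' @param df data.frame with columns `family`, `min_identity_pct`,
#'   `min_identity_pct_protein`, `min_query_cov_pct`, `mean_ref_length_aa`,
#'   `category`, `is_single_copy_ribosomal`.
#' @return data.frame of class `marker_manifest`.
#' @export
marker_manifest <- function(df) {
  need <- c("family", "min_identity_pct", "min_identity_pct_protein",
            "min_query_cov_pct", "mean_ref_length_aa", "category",
            "is_single_copy_ribosomal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$family)) stop("duplicate families in manifest")
  if (any(df$min_identity_pct <= 0 | df$min_identity_pct > 100)) {
    stop("identity thresholds must be in (0, 100]")
  }
  if (any(df$mean_ref_length_aa <= 0)) stop("mean_ref_length_aa must be positive")
  if (!any(df$is_single_copy_ribosomal)) {
    stop("at least one ribosomal single-copy family must be flagged")
  }
  structure(as.data.frame(df), class = c("marker_manifest", "data.frame"))
}

#' Default marker manifest
#'
#' Built-in manifest covering the signature metabolic gene families used for
#' community metabolic profiling. Read-mode identity thresholds default to 50
#' with per-family overrides (rho 40; nuoF, NiFe group 4, mmoX, FeFe
#' hydrogenase, coxL, amoA, nxrA, rbcL 60; psbA, isoA, atpA, aro, ygfK 70;
#' hbsT 75; psaA 80). MAG-mode thresholds reuse the read-mode values except
#' atpA 60, psbA 60, rdhA 45, cyc2 35, and rho 30. Fifteen universal
#' ribosomal protein families are flagged single-copy. Reference lengths are
#' representative mean protein lengths per family.
#'
#' @return A `marker_manifest`.
#' @export
default_marker_manifest <- function() {
  fam <- c(
    # energy / carbon acquisition markers
    "hhyL", "hylL", "nife_group4", "fefe_hydrogenase", "coxL", "mmoX", "pmoA",
    "amoA", "nxrA", "rbcL", "rbcL_IE", "psaA", "psbA", "rho", "nuoF", "sqr",
    "dsrA", "soxB", "hbsT", "cyc2", "rdhA", "isoA", "atpA", "aro", "ygfK",
    "nifH", "narG", "nirS", "nosZ", "mcrA", "acsB", "fccB",
    # universal single-copy ribosomal proteins
    paste0("rpl", c("2", "3", "4", "5", "6", "14", "15", "16", "18", "22", "24")),
    paste0("rps", c("3", "8", "10", "17"))
  )
  n <- length(fam)
  ident <- rep(50, n)
  overrides <- c(rho = 40, nuoF = 60, nife_group4 = 60, mmoX = 60,
                 fefe_hydrogenase = 60, coxL = 60, amoA = 60, nxrA = 60,
                 rbcL = 60, rbcL_IE = 60, psaA = 80, psbA = 70, isoA = 70,
                 atpA = 70, aro = 70, ygfK = 70, hbsT = 75)
  ident[match(names(overrides), fam)] <- overrides
  prot <- ident
  prot_overrides <- c(atpA = 60, psbA = 60, rdhA = 45, cyc2 = 35, rho = 30)
  prot[match(names(prot_overrides), fam)] <- prot_overrides
  ribo <- grepl("^rp[ls]", fam)
  len <- rep(400, n)
  len[fam %in% c("rbcL", "rbcL_IE")] <- 470
  len[fam == "coxL"] <- 790
  len[fam %in% c("hhyL", "hylL")] <- 560
  len[fam == "pmoA"] <- 250
  len[fam == "amoA"] <- 270
  len[ribo] <- 150
  cat_lbl <- ifelse(ribo, "ribosomal", "metabolic")
  marker_manifest(data.frame(
    family = fam, min_identity_pct = ident, min_identity_pct_protein = prot,
    min_query_cov_pct = 80, mean_ref_length_aa = len, category = cat_lbl,
    is_single_copy_ribosomal = ribo, stringsAsFactors = FALSE
  ))
}

#' Read a marker manifest TSV
#' @param path TSV with the columns described in [marker_manifest()].
#' @return A `marker_manifest`.
#' @export
read_marker_manifest <- function(path) {
  marker_manifest(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a homology-search hit table
#'
#' Accepts 12-column BLAST/DIAMOND tabular output (outfmt 6 column order)
#' with two appended coverage columns (query coverage and subject coverage,
#' percent). The subject id is parsed for the family label unless a
#' dedicated `family` column is present.
#'
#' @param path Path to the tabular hits file (no header).
#' @param family_from How to obtain the family: "sseqid" (subject id is the
#'   family label) or "sseqid_prefix" (text before the first '|').
#' @return data.frame with columns `id`, `family`, `pct_identity`,
#'   `alignment_length_aa`, `query_cov_pct`, `subject_cov_pct`, `bitscore`,
#'   `evalue`.
#' @export
read_marker_hits <- function(path, family_from = c("sseqid", "sseqid_prefix")) {
  family_from <- match.arg(family_from)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 14) stop("expected 12 BLAST columns plus 2 coverage columns")
  fam <- if (family_from == "sseqid_prefix") sub("\\|.*$", "", df[[2]]) else df[[2]]
  data.frame(
    id = df[[1]], family = fam, pct_identity = df[[3]],
    alignment_length_aa = df[[4]], evalue = df[[11]], bitscore = df[[12]],
    query_cov_pct = df[[13]], subject_cov_pct = df[[14]],
    stringsAsFactors = FALSE
  )
}

check_families <- function(hits, manifest) {
  unknown <- setdiff(unique(hits$family), manifest$family)
  if (length(unknown)) {
    stop("families absent from manifest: ", paste(unknown, collapse = ", "))
  }
}

# Best hit per query id: highest bitscore, ties broken deterministically by
# a stable sort on family then id.
best_hit_per_query <- function(hits) {
  ord <- order(hits$family, hits$id)
  hits <- hits[ord, , drop = FALSE]
  ord2 <- order(hits$id, -hits$bitscore)
  hits <- hits[ord2, , drop = FALSE]
  hits[!duplicated(hits$id), , drop = FALSE]
}

#' Filter short-read marker hits
#'
#' Resolves the best hit per read (highest bitscore) and then retains hits
#' with query coverage at or above the family minimum (default 80%) and
#' percent identity at or above the family read-mode threshold.
#'
#' @param hits Hit table as returned by [read_marker_hits()].
#' @param manifest A `marker_manifest`.
#' @return The filtered hit table (same columns).
#' @export
filter_read_hits <- function(hits, manifest) {
  check_families(hits, manifest)
  hits <- best_hit_per_query(hits)
  idx <- match(hits$family, manifest$family)
  keep <- hits$query_cov_pct >= manifest$min_query_cov_pct[idx] &
    hits$pct_identity >= manifest$min_identity_pct[idx]
  hits[keep, , drop = FALSE]
}

#' Filter MAG protein marker hits
#'
#' Retains hits that satisfy the length-or-coverage rule (alignment length at
#' least 40 amino acids, or at least 80% query coverage, or at least 80%
#' subject coverage) and the family's protein-mode identity threshold.
#'
#' @inheritParams filter_read_hits
#' @return The filtered hit table.
#' @export
filter_mag_hits <- function(hits, manifest) {
  check_families(hits, manifest)
  hits <- best_hit_per_query(hits)
  idx <- match(hits$family, manifest$family)
  keep <- (hits$alignment_length_aa >= 40 |
             hits$query_cov_pct >= 80 |
             hits$subject_cov_pct >= 80) &
    hits$pct_identity >= manifest$min_identity_pct_protein[idx]
  hits[keep, , drop = FALSE]
}

#' Reads per kilobase of reference per million reads (RPKM)
#'
#' The reference length is the family's mean protein length converted to
#' nucleotide kilobases (aa x 3 / 1000).
#'
#' @param count Filtered hit count for the family.
#' @param mean_ref_length_aa Mean reference protein length (amino acids).
#' @param total_reads Total sequenced reads in the sample.
#' @return RPKM value.
#' @export
rpkm <- function(count, mean_ref_length_aa, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(mean_ref_length_aa <= 0)) stop("zero-length family")
  count / ((mean_ref_length_aa * 3 / 1000) * (total_reads / 1e6))
}

#' Community gene profile: RPKM and average gene copies per organism
#'
#' Counts filtered hits per family, converts to RPKM, and normalises by the
#' mean RPKM of the flagged universal single-copy ribosomal protein families.
#' The resulting "average gene copy per organism" is interpretable as the
#' fraction of community cells carrying the gene; values above 1 (above 100%
#' of cells) indicate multi-copy genes and are reported uncapped with a flag.
#'
#' @param filtered_hits Output of [filter_read_hits()].
#' @param manifest A `marker_manifest`.
#' @param total_reads Total reads sequenced in the sample.
#' @return data.frame of class `gene_profile` with one row per manifest
#'   family: `filtered_hit_count`, `rpkm`, `copies_per_organism`,
#'   `percent_of_cells`, `multicopy_flag`; attribute `ribosomal_mean_rpkm`.
#' @export
gene_profile <- function(filtered_hits, manifest, total_reads) {
  check_families(filtered_hits, manifest)
  counts <- table(factor(filtered_hits$family, levels = manifest$family))
  counts <- as.numeric(counts)
  rp <- rpkm(counts, manifest$mean_ref_length_aa, total_reads)
  ribo <- manifest$is_single_copy_ribosomal
  denom <- mean(rp[ribo])
  if (!is.finite(denom) || denom <= 0) {
    stop("all ribosomal single-copy RPKM are zero; cannot normalise")
  }
  copies <- rp / denom
  out <- data.frame(
    family = manifest$family, category = manifest$category,
    filtered_hit_count = counts, rpkm = rp, copies_per_organism = copies,
    percent_of_cells = 100 * copies, multicopy_flag = copies > 1,
    stringsAsFactors = FALSE
  )
  structure(out, ribosomal_mean_rpkm = denom,
            class = c("gene_profile", "data.frame"))
}

#' Per-class signature-gene content of genome bins
#'
#' Joins MAG annotations with a habitat classification and reports the mean
#' completeness-corrected signature-gene count per habitat class (and per
#' glacier when a `glacier` column is present). Corrected count =
#' raw count / (completeness / 100).
#'
#' @param annotations data.frame with columns `mag_id`, `completeness_pct`,
#'   `signature_gene_count` and optionally `glacier`.
#' @param specialisation Classified `specialisation_table` whose `taxon`
#'   column holds MAG ids.
#' @return data.frame with columns `glacier` (if present), `habitat_class`,
#'   `n_mags`, `mean_corrected_count`.
#' @export
mag_signature_summary <- function(annotations, specialisation) {
  if (any(annotations$completeness_pct <= 0 | annotations$completeness_pct > 100)) {
    stop("completeness must be in (0, 100]")
  }
  cls <- specialisation$habitat_class[match(annotations$mag_id, specialisation$taxon)]
  unmatched <- sum(is.na(cls))
  if (unmatched > 0) {
    warning(unmatched, " MAG id(s) without a habitat classification dropped")
  }
  keep <- !is.na(cls)
  ann <- annotations[keep, , drop = FALSE]
  ann$habitat_class <- cls[keep]
  ann$corrected <- ann$signature_gene_count / (ann$completeness_pct / 100)
  by_vars <- intersect(c("glacier", "habitat_class"), names(ann))
  agg <- stats::aggregate(ann$corrected, by = ann[by_vars], FUN = mean)
  cnt <- stats::aggregate(ann$corrected, by = ann[by_vars], FUN = length)
  names(agg)[ncol(agg)] <- "mean_corrected_count"
  agg$n_mags <- cnt$x
  agg
}

#' Write a gene profile as TSV
#' @param profile A `gene_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
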
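#' Chronosequence sampling design
#'
#' Describes a glacier foreland sampling campaign: ordered, non-overlapping
#' soil-age classes, sites per class laid out along a transect away from the
#' glacier front, and optional depth intervals.
#'
#' @param glacier_id Label for the glacier.
#' @param age_classes data.frame with columns `label`, `min_years`,
#'   `max_years`; classes must be ordered and non-overlapping.
#' @param n_sites_per_class Integer, recycled to one value per class.
#' @param depth_intervals Optional data.frame with `top_cm`, `bottom_cm`;
#'   must be ordered and non-overlapping.
#' @param origin Named numeric c(lat, lon) of the glacier front (degrees).
#' @param seed Integer seed used for site placement.
#' @return List of class `chronosequence_design` with a per-site `sites`
#'   data.frame (site, age_class, age_years, lat, lon).
#' @export
chronosequence_design <- function(glacier_id, age_classes, n_sites_per_class,
                                  depth_intervals = NULL,
                                  origin = c(lat = 0, lon = 0), seed = 1) {
  ac <- as.data.frame(age_classes)
  stopifnot(all(c("label", "min_years", "max_years") %in% names(ac)))
  if (any(ac$min_years > ac$max_years)) stop("age class min exceeds max")
  if (nrow(ac) > 1 &&
      any(ac$min_years[-1] <= ac$max_years[-nrow(ac)])) {
    stop("age classes must be ordered and non-overlapping")
  }
  n_per <- rep_len(n_sites_per_class, nrow(ac))
  if (sum(n_per) < 2) stop("need at least 2 sites in total")
  if (!is.null(depth_intervals)) {
    di <- as.data.frame(depth_intervals)
    stopifnot(all(c("top_cm", "bottom_cm") %in% names(di)))
    if (any(di$top_cm >= di$bottom_cm)) stop("depth interval top must be above bottom")
    if (nrow(di) > 1 && any(di$top_cm[-1] < di$bottom_cm[-nrow(di)])) {
      stop("depth intervals must be ordered and non-overlapping")
    }
    depth_intervals <- di
  }
  sites <- with_stream_seed(seed, "design", {
    rows <- list()
    for (ci in seq_len(nrow(ac))) {
      ages <- sort(stats::runif(n_per[ci], ac$min_years[ci], ac$max_years[ci]))
      for (si in seq_len(n_per[ci])) {
        # transect layout: distance from the front grows with soil age,
        # with a little lateral scatter (~10 m per year of exposure)
        dist_m <- ages[si] * 10 + stats::runif(1, 0, 20)
        lateral_m <- stats::runif(1, -30, 30)
        rows[[length(rows) + 1]] <- data.frame(
          site = sprintf("%s_%s%d", glacier_id, ac$label[ci], si),
          age_class = ac$label[ci], age_years = ages[si],
          lat = origin[["lat"]] + dist_m / 111320,
          lon = origin[["lon"]] + lateral_m /
            (111320 * cos(origin[["lat"]] * pi / 180)),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
  structure(list(glacier_id = glacier_id, age_classes = ac,
                 n_sites_per_class = n_per, depth_intervals = depth_intervals,
                 origin = origin, seed = seed, sites = sites),
            class = "chronosequence_design")
}

#' Default two-glacier study designs
#'
#' The Antarctic foreland has three soil-age classes (<5, 10, 21 years since
#' deglaciation) with three topsoil sites each (n = 9); the Swiss foreland
#' has four classes (0-7, 8-27, 28-57, 58-127 years) with 15 topsoil sites
#' and 10-cm depth intervals down to 50 cm.
#'
#' @param seed Integer seed.
#' @return Named list with elements `antarctic` and `swiss`.
#' @export
default_designs <- function(seed = 1) {
  list(
    antarctic = chronosequence_design(
      "antarctic",
      data.frame(label = c("A", "B", "C"),
                 min_years = c(0, 6, 16), max_years = c(5, 12, 21)),
      n_sites_per_class = 3,
      origin = c(lat = -62.6996, lon = -60.4156),
      seed = stream_seed(seed, "antarctic")
    ),
    swiss = chronosequence_design(
      "swiss",
      data.frame(label = c("A", "B", "C", "D"),
                 min_years = c(0, 8, 28, 58),
                 max_years = c(7, 27, 57, 127)),
      n_sites_per_class = c(4, 4, 4, 3),
      depth_intervals = data.frame(top_cm = seq(0, 40, 10),
                                   bottom_cm = seq(10, 50, 10)),
      origin = c(lat = 46.84299, lon = 8.82746),
      seed = stream_seed(seed, "swiss")
    )
  )
}

#' Planted community composition with known ecological guilds
#'
#' @param taxon_id Label.
#' @param guild One of "generalist", "early_opportunist", "late_specialist".
#'   Guild determines the direction of the abundance-age trend: generalists
#'   are trend-free with low variability, early opportunists peak in the
#'   youngest soils, late specialists in the oldest.
#' @param mean_relative_abundance Mean relative abundance in (0, 1).
#' @param cv_target Targeted coefficient of variation of relative abundance
#'   across samples (>= 0).
#' @param marker_genes Character vector of marker families the taxon carries.
#' @param genes_per_genome Number of signature metabolic genes encoded.
#' @return One-row data.frame (marker_genes as a list column).
#' @export
community_truth <- function(taxon_id, guild, mean_relative_abundance,
                            cv_target, marker_genes = character(),
                            genes_per_genome = length(marker_genes)) {
  guild <- match.arg(guild, c("generalist", "early_opportunist",
                              "late_specialist"))
  if (mean_relative_abundance <= 0 || mean_relative_abundance >= 1) {
    stop("mean_relative_abundance must be in (0, 1)")
  }
  if (cv_target < 0) stop("cv_target must be >= 0")
  out <- data.frame(taxon_id = taxon_id, guild = guild,
                    mean_relative_abundance = mean_relative_abundance,
                    cv_target = cv_target,
                    genes_per_genome = genes_per_genome,
                    stringsAsFactors = FALSE)
  out$marker_genes <- list(marker_genes)
  out
}

#' Default planted community
#'
#' Eight habitat generalists (cv 0.3, jointly 64% of the community, carrying
#' broad suites of trace-gas and sulfur oxidation genes), six early
#' opportunists (cv 2.0, peaking in the youngest soils, sulfide oxidisers),
#' and six late specialists (cv 2.0, peaking in the oldest soils,
#' methanotrophs/nitrifiers/phototrophs).
#'
#' @return data.frame of stacked [community_truth()] rows.
#' @export
default_community_truths <- function() {
  gen_genes <- list(
    c("hhyL", "coxL", "sqr", "rbcL", "rho", "nuoF", "atpA"),
    c("hhyL", "coxL", "soxB", "rbcL", "nuoF", "atpA"),
    c("hhyL", "sqr", "rho", "nuoF", "atpA", "narG"),
    c("coxL", "sqr", "rbcL_IE", "nuoF", "atpA", "rho", "soxB"),
    c("hhyL", "coxL", "hylL", "nuoF", "atpA", "sqr"),
    c("hhyL", "rbcL", "rho", "nuoF", "atpA", "soxB", "narG"),
    c("coxL", "sqr", "rho", "nuoF", "atpA"),
    c("hhyL", "coxL", "sqr", "rbcL", "nuoF", "atpA", "nosZ")
  )
  early_genes <- list(
    c("sqr", "hbsT", "nuoF", "atpA"), c("sqr", "soxB", "nuoF"),
    c("sqr", "hhyL", "nuoF"), c("sqr", "dsrA", "nuoF", "atpA"),
    c("sqr", "nuoF", "atpA"), c("hbsT", "sqr", "nuoF")
  )
  late_genes <- list(
    c("pmoA", "nuoF"), c("amoA", "nxrA", "nuoF"), c("psaA", "psbA", "nuoF"),
    c("pmoA", "mmoX", "nuoF"), c("amoA", "nuoF"), c("rdhA", "nuoF", "atpA")
  )
  rows <- list()
  for (i in 1:8) {
    rows[[length(rows) + 1]] <- community_truth(
      sprintf("gen%02d", i), "generalist", 0.08, 0.3, gen_genes[[i]])
  }
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- community_truth(
      sprintf("early%02d", i), "early_opportunist", 0.03, 2.0, early_genes[[i]])
  }
  for (i in 1:6) {
    rows[[length(rows) + 1]] <- community_truth(
      sprintf("late%02d", i), "late_specialist", 0.03, 2.0, late_genes[[i]])
  }
  do.call(rbind, rows)
}

# Rescale positive weights to mean 1 and coefficient of variation cv_target
# (clipped at a small positive floor, which slightly compresses extreme
# targets).
scale_to_cv <- function(w, cv_target) {
  w <- w / mean(w)
  c0 <- stats::sd(w)
  if (c0 == 0 || cv_target == 0) return(rep(1, length(w)))
  w <- 1 + (w - 1) * (cv_target / c0)
  w <- pmax(w, 1e-9)
  w / mean(w)
}

#' Generate a synthetic community abundance table
#'
#' Builds per-sample expected relative abundances from the planted guild
#' structure (generalists: lognormal sample-to-sample variation with no age
#' trend; early opportunists: exponential decline with soil age; late
#' specialists: the mirrored increase; each taxon's spread rescaled towards
#' its cv_target), renormalises each sample, and draws read counts by
#' multinomial sampling.
#'
#' @param design A `chronosequence_design`.
#' @param truths data.frame of [community_truth()] rows, at least one taxon
#'   per guild.
#' @param total_reads_per_sample Reads per sample (>= 1000).
#' @param seed Integer seed (named streams derived internally).
#' @return An `abundance_matrix` with design metadata and attributes
#'   `truth` (the truths table), `expected_rel` (the expected relative
#'   abundance matrix before multinomial noise).
#' @export
generate_community <- function(design, truths, total_reads_per_sample = 1e5,
                               seed = 1) {
  if (total_reads_per_sample < 1000) stop("total_reads_per_sample must be >= 1000")
  guilds <- c("generalist", "early_opportunist", "late_specialist")
  if (!all(guilds %in% truths$guild)) {
    stop("configuration error: every guild needs at least one taxon")
  }
  if (sum(truths$mean_relative_abundance) > 1 + 1e-12) {
    stop("configuration error: planted mean abundances sum above 1")
  }
  sites <- design$sites
  ages <- sites$age_years
  amin <- min(ages); amax <- max(ages)
  tau <- max((amax - amin) / 3, 1e-9)
  n_s <- nrow(sites); n_t <- nrow(truths)
  expected <- with_stream_seed(seed, "community_weights", {
    e <- matrix(0, n_t, n_s, dimnames = list(truths$taxon_id, sites$site))
    for (t in seq_len(n_t)) {
      w <- switch(
        truths$guild[t],
        generalist = {
          sdlog <- sqrt(log(1 + truths$cv_target[t]^2))
          stats::rlnorm(n_s, -sdlog^2 / 2, sdlog)
        },
        early_opportunist = exp(-(ages - amin) / tau),
        late_specialist = exp((ages - amax) / tau)
      )
      e[t, ] <- truths$mean_relative_abundance[t] *
        scale_to_cv(w, truths$cv_target[t])
    }
    sweep(e, 2, colSums(e), "/")
  })
  counts <- with_stream_seed(seed, "community_counts", {
    apply(expected, 2, function(p) {
      stats::rmultinom(1, total_reads_per_sample, p)[, 1]
    })
  })
  dimnames(counts) <- dimnames(expected)
  md <- data.frame(sample = sites$site, glacier = design$glacier_id,
                   age_class = sites$age_class, age_years = sites$age_years,
                   depth_top_cm = 0, depth_bottom_cm = 10,
                   lat = sites$lat, lon = sites$lon,
                   stringsAsFactors = FALSE)
  out <- abundance_matrix(counts, md)
  attr(out, "truth") <- truths
  attr(out, "expected_rel") <- expected
  out
}

#' Generate a synthetic marker-gene hit table
#'
#' Emits homology-search hit rows per marker family with expected counts
#' proportional to the family's reference length (in nucleotide kilobases)
#' and the summed relative abundance of taxa carrying it; ribosomal
#' single-copy families are carried by every taxon. A configurable fraction
#' of extra rows is planted with identity 10 points below the family
#' threshold, which the read filter must remove exactly.
#'
#' @param community An `abundance_matrix` from [generate_community()] (its
#'   `truth` attribute supplies gene content), or NULL if `truths` and
#'   `rel_abund` are given directly.
#' @param manifest A `marker_manifest`.
#' @param reads_total Total sequenced reads represented by the table.
#' @param marker_read_fraction Sequencing depth constant: expected passing
#'   hits per family = reads_total x this x length_kb x carrier fraction.
#' @param fail_fraction Fraction of additional planted below-threshold rows.
#' @param sample Optional sample id; default profiles the mean community.
#' @param seed Integer seed.
#' @return Hit table data.frame (schema of [read_marker_hits()]) with
#'   attributes `carrier_fraction` (named, the planted truth) and
#'   `reads_total`.
#' @export
generate_marker_hits <- function(community, manifest, reads_total = 1e6,
                                 marker_read_fraction = 1e-3,
                                 fail_fraction = 0, sample = NULL, seed = 1) {
  truths <- attr(community, "truth")
  if (is.null(truths)) stop("community carries no truth registry")
  fams <- unique(unlist(truths$marker_genes))
  unknown <- setdiff(fams, manifest$family)
  if (length(unknown)) {
    stop("unknown marker families in truths: ", paste(unknown, collapse = ", "))
  }
  rel <- to_relative(community)
  ab <- if (is.null(sample)) rowMeans(rel) else rel[, sample]
  ab <- ab[truths$taxon_id]
  ribo <- manifest$family[manifest$is_single_copy_ribosomal]
  carrier <- vapply(manifest$family, function(f) {
    if (f %in% ribo) return(1)
    sum(ab * vapply(truths$marker_genes, function(g) f %in% g, logical(1)))
  }, numeric(1))
  names(carrier) <- manifest$family
  len_kb <- manifest$mean_ref_length_aa * 3 / 1000
  lambda <- reads_total * marker_read_fraction * len_kb * carrier
  rows <- with_stream_seed(seed, "marker_hits", {
    out <- list()
    for (fi in seq_along(manifest$family)) {
      fam <- manifest$family[fi]
      thr <- manifest$min_identity_pct[fi]
      n_pass <- stats::rpois(1, lambda[fi])
      n_fail <- round(fail_fraction * n_pass)
      n <- n_pass + n_fail
      if (n == 0) next
      ident <- c(stats::runif(n_pass, thr, 100), rep(thr - 10, n_fail))
      out[[fam]] <- data.frame(
        id = sprintf("%s_read_%06d", fam, seq_len(n)),
        family = fam,
        pct_identity = ident,
        alignment_length_aa = round(stats::runif(n, 40, 50)),
        evalue = 1e-10,
        bitscore = round(stats::runif(n, 60, 200), 1),
        query_cov_pct = stats::runif(n, 85, 100),
        subject_cov_pct = stats::runif(n, 5, 15),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
  structure(rows, carrier_fraction = carrier, reads_total = reads_total)
}

#' Generate microcosm trace-gas concentration time series
#'
#' Live series follow c(t) = c_atm exp(-(k_true + k_abiotic) t) plus Gaussian
#' noise; heat-killed series decay with k_abiotic only. Negative simulated
#' mixing ratios are truncated at zero (detector floor).
#'
#' @param gas Gas label.
#' @param k_true Biotic first-order rate constant (per hour, >= 0).
#' @param c_atm Starting mixing ratio (ppmv, > 0).
#' @param k_abiotic Abiotic loss rate constant (per hour).
#' @param noise_sd Gaussian noise standard deviation (ppmv).
#' @param times Sampling times (hours), strictly increasing, >= 5 points.
#' @param replicates Live replicates (and killed, when included).
#' @param include_killed Emit heat-killed control series.
#' @param seed Integer seed.
#' @return data.frame (series_id, treatment, replicate, time_h, ppmv) with a
#'   `truth` attribute.
#' @export
generate_gas_timeseries <- function(gas = "h2", k_true = 0.1, c_atm = 0.5,
                                    k_abiotic = 0, noise_sd = 0.01,
                                    times = c(0, 3, 6, 12, 24),
                                    replicates = 3, include_killed = TRUE,
                                    seed = 1) {
  if (any(times < 0)) stop("negative times")
  if (length(times) < 5 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing with >= 5 points")
  }
  if (k_true < 0 || c_atm <= 0 || noise_sd < 0) stop("invalid kinetics truth")
  mk <- function(k, treatment, r, noise) {
    mu <- c_atm * exp(-k * times)
    data.frame(series_id = sprintf("%s_%s_%d", gas, treatment, r),
               treatment = treatment, replicate = r, time_h = times,
               ppmv = pmax(mu + noise, 0), stringsAsFactors = FALSE)
  }
  out <- with_stream_seed(seed, paste0("gas_", gas), {
    rows <- list()
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1]] <- mk(k_true + k_abiotic, "live", r,
                                     stats::rnorm(length(times), 0, noise_sd))
    }
    if (include_killed) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- mk(k_abiotic, "heat_killed", r,
                                       stats::rnorm(length(times), 0, noise_sd))
      }
    }
    do.call(rbind, rows)
  })
  structure(out, truth = list(gas = gas, k_true = k_true, c_atm = c_atm,
                              k_abiotic = k_abiotic, noise_sd = noise_sd))
}

#' Generate a nutrient concentration time series
#'
#' @param model "linear" (c0 + slope t) or "exponential" (c0 exp(rate t)).
#' @param params Named list: `c0` plus `slope` (uM/day) or `rate` (per day).
#' @param times Sampling times (days), increasing.
#' @param noise_sd Gaussian noise sd (uM).
#' @param seed Integer seed.
#' @return data.frame (time_days, conc_uM) with a `truth` attribute.
#' @export
generate_nutrient_series <- function(model = c("linear", "exponential"),
                                     params = list(c0 = 50, slope = -2),
                                     times = 0:10, noise_sd = 0, seed = 1) {
  model <- match.arg(model)
  if (is.unsorted(times)) stop("times must be increasing")
  mu <- switch(model,
    linear = params$c0 + params$slope * times,
    exponential = params$c0 * exp(params$rate * times)
  )
  if (any(mu < 0)) stop("truth trajectory goes negative; adjust params")
  conc <- with_stream_seed(seed, "nutrient",
                           pmax(mu + stats::rnorm(length(times), 0, noise_sd), 0))
  structure(data.frame(time_days = times, conc_uM = conc),
            truth = c(list(model = model), params, list(noise_sd = noise_sd)))
}

#' Generate qPCR Cp tables with a standard dilution series
#'
#' Cp = intercept + slope x log10(copies) + Gaussian noise. Standards span
#' six decades (10^3 to 10^8 copies) in duplicate.
#'
#' @param true_copies Named numeric vector of unknown template copies (> 0).
#' @param slope Standard-curve slope (< 0; -3.3219 is 100% efficiency).
#' @param intercept Standard-curve intercept (Cp at 1 copy).
#' @param noise_sd_cp Gaussian Cp noise.
#' @param seed Integer seed.
#' @return List with `standards` (copies, cp) and `unknowns` (sample, cp),
#'   plus a `truth` attribute.
#' @export
generate_qpcr <- function(true_copies, slope = -3.3219, intercept = 38,
                          noise_sd_cp = 0, seed = 1) {
  if (slope >= 0) stop("slope must be negative")
  if (any(true_copies <= 0)) stop("copies must be positive")
  std_copies <- rep(10^(3:8), each = 2)
  out <- with_stream_seed(seed, "qpcr", {
    std <- data.frame(
      copies = std_copies,
      cp = intercept + slope * log10(std_copies) +
        stats::rnorm(length(std_copies), 0, noise_sd_cp)
    )
    unk <- data.frame(
      sample = if (is.null(names(true_copies))) {
        sprintf("unknown%02d", seq_along(true_copies))
      } else names(true_copies),
      cp = intercept + slope * log10(true_copies) +
        stats::rnorm(length(true_copies), 0, noise_sd_cp),
      stringsAsFactors = FALSE
    )
    list(standards = std, unknowns = unk)
  })
  structure(out, truth = list(true_copies = true_copies, slope = slope,
                              intercept = intercept, noise_sd_cp = noise_sd_cp))
}

#' Simulate incidence matrices under contrasting assembly processes
#'
#' "uniform_random" places each taxon at each site independently with
#' probability `p` (stochastic assembly; zeta declines exponentially).
#' "niche_gradient" gives each taxon a contiguous range of sites along the
#' transect (niche breadth uniform on 1..n_sites, centred uniformly), the
#' classic deterministic-assembly structure whose zeta decline follows a
#' power law.
#'
#' @param type Assembly process.
#' @param n_taxa,n_sites Dimensions.
#' @param p Occupancy probability for the random process.
#' @param seed Integer seed.
#' @return An `incidence_matrix` (sites evenly spaced 1 km apart on a planar
#'   transect in the `coords` attribute).
#' @export
simulate_incidence <- function(type = c("uniform_random", "niche_gradient"),
                               n_taxa = 50, n_sites = 10, p = 0.3, seed = 1) {
  type <- match.arg(type)
  inc <- with_stream_seed(seed, paste0("incidence_", type), {
    m <- matrix(FALSE, n_taxa, n_sites,
                dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                                sprintf("s%02d", seq_len(n_sites))))
    if (type == "uniform_random") {
      m[] <- stats::runif(n_taxa * n_sites) < p
    } else {
      for (t in seq_len(n_taxa)) {
        breadth <- sample.int(n_sites, 1)
        start <- sample.int(n_sites - breadth + 1, 1)
        m[t, start:(start + breadth - 1)] <- TRUE
      }
    }
    m
  })
  coords <- data.frame(site = colnames(inc), lat = seq_len(n_sites), lon = 0)
  structure(inc, coords = coords, class = c("incidence_matrix", "matrix"))
}
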
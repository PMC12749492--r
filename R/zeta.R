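#' Build a presence/absence incidence matrix
#'
#' @param x Abundance matrix (any value above `threshold` counts as present)
#'   or an already-logical matrix, taxa x sites.
#' @param threshold Detection threshold (default 0).
#' @param coords Optional data.frame with columns `site`, `lat`, `lon`
#'   (decimal degrees); taken from the abundance metadata when present.
#' @return Logical matrix of class `incidence_matrix` with a `coords`
#'   attribute.
#' @export
incidence_matrix <- function(x, threshold = 0, coords = NULL) {
  inc <- unclass(x) > threshold
  if (ncol(inc) < 2) stop("need at least 2 sites")
  if (is.null(coords) && inherits(x, "abundance_matrix")) {
    md <- sample_metadata(x)
    if (!is.null(md) && all(c("lat", "lon") %in% names(md))) {
      coords <- data.frame(site = md$sample, lat = md$lat, lon = md$lon)
    }
  }
  structure(inc, coords = coords, class = c("incidence_matrix", "matrix"))
}

# All i-site combinations if tractable, else NULL.
all_combos <- function(n_sites, i, cap) {
  if (choose(n_sites, i) > cap) return(NULL)
  utils::combn(n_sites, i, simplify = FALSE)
}

# Shared (and optionally union) taxon counts for a list of site combinations.
zeta_values <- function(inc, combos, normalization) {
  vapply(combos, function(s) {
    sub <- inc[, s, drop = FALSE]
    rs <- rowSums(sub)
    shared <- sum(rs == length(s))
    if (normalization == "jaccard") {
      union <- sum(rs > 0)
      if (union == 0) 0 else shared / union
    } else {
      shared
    }
  }, numeric(1))
}

#' Zeta diversity of a given order
#'
#' Raw zeta of order i is the mean number of taxa jointly present across i
#' sites, averaged over site combinations; Jaccard normalisation divides each
#' combination's intersection size by its union size (empty unions contribute
#' 0). Combinations are enumerated exhaustively when their number is below
#' `exhaustive_cap`, otherwise sampled by Monte Carlo (uniform combinations,
#' distinct sites within a draw, draws independent across samples).
#'
#' @param inc An `incidence_matrix`.
#' @param i Zeta order (1 <= i <= number of sites).
#' @param mode "auto", "exhaustive", or "monte_carlo".
#' @param n_subsamples Monte-Carlo draws (default 1000).
#' @param normalization "none" (raw counts) or "jaccard".
#' @param seed RNG seed, required for Monte-Carlo mode.
#' @param exhaustive_cap Max combinations enumerated exhaustively.
#' @return List with `mean`, `sd`, `n_evaluated`, `mode`.
#' @export
zeta_order <- function(inc, i, mode = c("auto", "exhaustive", "monte_carlo"),
                       n_subsamples = 1000,
                       normalization = c("none", "jaccard"),
                       seed = NULL, exhaustive_cap = 5000) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  n_sites <- ncol(inc)
  if (i < 1) stop("zeta order must be >= 1")
  if (i > n_sites) stop("zeta order exceeds number of sites")
  combos <- NULL
  if (mode != "monte_carlo") combos <- all_combos(n_sites, i, exhaustive_cap)
  if (mode == "exhaustive" && is.null(combos)) {
    stop("exhaustive enumeration exceeds cap; use monte_carlo")
  }
  if (is.null(combos)) {
    draw <- function() sort(sample.int(n_sites, i))
    combos <- if (is.null(seed)) {
      replicate(n_subsamples, draw(), simplify = FALSE)
    } else {
      with_stream_seed(seed, paste0("zeta", i),
                       replicate(n_subsamples, draw(), simplify = FALSE))
    }
    used_mode <- "monte_carlo"
  } else {
    used_mode <- "exhaustive"
  }
  z <- zeta_values(inc, combos, normalization)
  list(mean = mean(z), sd = stats::sd(z), n_evaluated = length(z),
       mode = used_mode)
}

# log-scale decline fits: exponential = OLS of ln(zeta) on i,
# power law = OLS of ln(zeta) on ln(i); Gaussian AIC with k = 3.
fit_decline_models <- function(orders, zeta) {
  lz <- log(zeta)
  fits <- list(
    exponential = stats::lm(lz ~ orders),
    power = stats::lm(lz ~ log(orders))
  )
  out <- lapply(fits, function(f) {
    co <- stats::coef(f)
    list(intercept = unname(co[1]), slope = unname(co[2]),
         aic = gaussian_aic(stats::residuals(f), k = 3))
  })
  aics <- vapply(out, `[[`, numeric(1), "aic")
  out$selected_model <- names(which.min(aics))
  out$delta_aic <- abs(diff(unname(aics)))
  out$indistinguishable <- out$delta_aic < 2
  out
}

#' Zeta decline across orders with power-law vs exponential model selection
#'
#' Computes mean zeta for orders 1..i_max (raw and Jaccard-normalised) and
#' fits power-law and exponential decline models to the raw means, choosing
#' between them by AIC (Gaussian likelihood, ML variance, 3 parameters each).
#' A power-law decline is the classic signature of deterministic (niche)
#' community assembly; exponential decline indicates stochastic assembly.
#'
#' @inheritParams zeta_order
#' @param i_max Highest zeta order (default 6).
#' @return Object of class `zeta_decline`: list with `orders` data.frame
#'   (order, zeta, zeta_sd, zeta_jaccard, n_evaluated, mode), `fits`,
#'   `selected_model`, and `ratio_z2_z1` (retention-based two-site sharing).
#' @export
zeta_decline <- function(inc, i_max = 6, mode = "auto", n_subsamples = 1000,
                         seed = NULL, exhaustive_cap = 5000) {
  i_max <- min(i_max, ncol(inc))
  rows <- lapply(seq_len(i_max), function(i) {
    raw <- zeta_order(inc, i, mode = mode, n_subsamples = n_subsamples,
                      normalization = "none", seed = seed,
                      exhaustive_cap = exhaustive_cap)
    jac <- zeta_order(inc, i, mode = mode, n_subsamples = n_subsamples,
                      normalization = "jaccard", seed = seed,
                      exhaustive_cap = exhaustive_cap)
    data.frame(order = i, zeta = raw$mean, zeta_sd = raw$sd,
               zeta_jaccard = jac$mean, n_evaluated = raw$n_evaluated,
               mode = raw$mode, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pos <- tab$zeta > 0
  if (sum(pos) < 3) stop("fewer than 3 positive zeta values; fitting refused")
  if (any(!pos)) warning("zero zeta values dropped from decline fitting")
  fits <- fit_decline_models(tab$order[pos], tab$zeta[pos])
  structure(list(orders = tab, fits = fits,
                 selected_model = fits$selected_model,
                 ratio_z2_z1 = tab$zeta[2] / tab$zeta[1]),
            class = "zeta_decline")
}

#' @export
print.zeta_decline <- function(x, ...) {
  cat("zeta decline (orders 1..", max(x$orders$order), ")\n", sep = "")
  print(x$orders, row.names = FALSE)
  cat(sprintf("power AIC %.2f, exponential AIC %.2f -> %s%s\n",
              x$fits$power$aic, x$fits$exponential$aic, x$selected_model,
              if (x$fits$indistinguishable) " (delta AIC < 2, indistinguishable)" else ""))
  invisible(x)
}

# Great-circle distance in km (haversine, sphere radius 6371.0088 km).
site_distances_km <- function(coords, planar = FALSE) {
  n <- nrow(coords)
  d <- matrix(0, n, n, dimnames = list(coords$site, coords$site))
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      d[a, b] <- d[b, a] <- if (planar) {
        sqrt((coords$lat[a] - coords$lat[b])^2 + (coords$lon[a] - coords$lon[b])^2)
      } else {
        geosphere::distHaversine(c(coords$lon[a], coords$lat[a]),
                                 c(coords$lon[b], coords$lat[b]),
                                 r = 6371.0088)
      }
    }
  }
  d
}

#' Zeta distance decay
#'
#' For sampled i-site combinations, records the Jaccard-normalised zeta and
#' the mean pairwise great-circle distance among the sites, then fits an
#' ordinary least squares regression zeta = a + b * distance. The slope b
#' (per km) is the distance-decay coefficient.
#'
#' @inheritParams zeta_order
#' @param planar Treat coordinates as planar (distance in coordinate units)
#'   instead of WGS84 lat/lon.
#' @return Object of class `zeta_decay`: list with `order`, `records`
#'   data.frame (zeta, distance_km), `slope`, `intercept`, `r2`.
#' @export
zeta_distance_decay <- function(inc, i = 2, n_subsamples = 1000, seed = NULL,
                                planar = FALSE, exhaustive_cap = 5000) {
  coords <- attr(inc, "coords")
  if (is.null(coords)) stop("incidence matrix has no site coordinates")
  if (i < 2) stop("distance decay needs order >= 2")
  dmat <- site_distances_km(coords[match(colnames(inc), coords$site), ],
                            planar = planar)
  if (all(dmat == 0)) stop("all sites co-located: zero distance variance")
  combos <- all_combos(ncol(inc), i, exhaustive_cap)
  if (is.null(combos)) {
    combos <- with_stream_seed(
      if (is.null(seed)) 0L else seed, paste0("ddecay", i),
      replicate(n_subsamples, sort(sample.int(ncol(inc), i)), simplify = FALSE))
  }
  z <- zeta_values(inc, combos, "jaccard")
  dist_mean <- vapply(combos, function(s) {
    mean(dmat[s, s][upper.tri(dmat[s, s])])
  }, numeric(1))
  records <- data.frame(zeta = z, distance_km = dist_mean)
  if (stats::var(z) == 0) {
    return(structure(list(order = i, records = records, slope = 0,
                          intercept = mean(z), r2 = NA_real_,
                          r2_defined = FALSE),
                     class = "zeta_decay"))
  }
  fit <- stats::lm(zeta ~ distance_km, data = records)
  structure(list(order = i, records = records,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared, r2_defined = TRUE),
            class = "zeta_decay")
}

#' @export
print.zeta_decay <- function(x, ...) {
  cat(sprintf("zeta_%d distance decay: slope %.4g per km, intercept %.4g, r2 %s (%d combinations)\n",
              x$order, x$slope, x$intercept,
              if (isTRUE(x$r2_defined)) sprintf("%.3f", x$r2) else "undefined",
              nrow(x$records)))
  invisible(x)
}

#' Two-group variation partitioning of pairwise zeta
#'
#' Partitions the variance of pairwise (order 2) Jaccard-normalised zeta into
#' the pure contribution of two predictor groups, their shared fraction, and
#' the unexplained remainder, using adjusted R-squared from three linear
#' models (group1 only, group2 only, both). Predictors are the absolute
#' between-site differences of each site variable. Negative fractions are
#' floored at zero and the set renormalised; raw values are retained.
#'
#' @param inc An `incidence_matrix`.
#' @param site_env data.frame of site variables (rows in site order of
#'   `inc`'s columns).
#' @param group1,group2 Character vectors naming disjoint, non-empty column
#'   groups of `site_env` (e.g. soil age vs physicochemistry).
#' @return Object of class `zeta_varpart`: fractions `a` (pure group1), `b`
#'   (shared), `c` (pure group2), `d` (unexplained), plus `raw` values and
#'   `adj_r2_full`.
#' @export
zeta_varpart <- function(inc, site_env, group1, group2) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  n <- ncol(inc)
  pairs <- utils::combn(n, 2, simplify = FALSE)
  if (length(pairs) < 6) stop("need at least 6 site pairs")
  z <- zeta_values(inc, pairs, "jaccard")
  diffs <- function(vars) {
    sapply(vars, function(v) {
      vapply(pairs, function(p) abs(site_env[[v]][p[1]] - site_env[[v]][p[2]]),
             numeric(1))
    })
  }
  x1 <- as.data.frame(diffs(group1))
  x2 <- as.data.frame(diffs(group2))
  adj <- function(df, strict = FALSE) {
    f <- stats::lm(z ~ ., data = df)
    if (strict && any(is.na(stats::coef(f)))) {
      stop("collinear predictors within a group; run collinearity_filter() first")
    }
    # aliased coefficients across the two groups (perfectly shared variables)
    # are dropped by lm; that is exactly the shared fraction b
    summary(f)$adj.r.squared
  }
  r1 <- adj(x1, strict = TRUE)
  r2 <- adj(x2, strict = TRUE)
  rf <- adj(cbind(x1, x2))
  raw <- c(a = rf - r2, b = r1 + r2 - rf, c = rf - r1, d = 1 - rf)
  fl <- pmax(raw, 0)
  fr <- fl / sum(fl)
  structure(list(a = unname(fr["a"]), b = unname(fr["b"]),
                 c = unname(fr["c"]), d = unname(fr["d"]),
                 raw = raw, adj_r2_full = rf,
                 group1 = group1, group2 = group2),
            class = "zeta_varpart")
}

#' @export
print.zeta_varpart <- function(x, ...) {
  cat(sprintf(paste0("zeta variation partitioning (pairwise):\n",
                     "  pure %s: %.3f\n  shared: %.3f\n  pure %s: %.3f\n",
                     "  unexplained: %.3f (full-model adj R2 %.3f)\n"),
              paste(x$group1, collapse = "+"), x$a, x$b,
              paste(x$group2, collapse = "+"), x$c, x$d, x$adj_r2_full))
  invisible(x)
}
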
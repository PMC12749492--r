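#' Construct a taxon-by-sample abundance matrix with sample metadata
#'
#' The basic container for community data: a numeric matrix of counts (or
#' relative abundances) with taxa as rows and samples as columns, plus a
#' per-sample metadata table (glacier, soil-age class, age in years, depth
#' interval, coordinates, physicochemistry).
#'
#' @param counts Numeric matrix, taxa x samples, non-negative, with unique
#'   dimnames.
#' @param metadata Optional data.frame keyed by a `sample` column (or row
#'   names) covering every sample in `counts`.
#' @return An object of class `abundance_matrix`: the counts matrix with a
#'   `metadata` attribute.
#' @export
abundance_matrix <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon labels")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample labels")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample" %in% names(metadata)) {
      if (is.null(rownames(metadata))) stop("metadata needs a 'sample' column")
      metadata$sample <- rownames(metadata)
    }
    missing <- setdiff(colnames(counts), metadata$sample)
    if (length(missing)) {
      stop("metadata missing samples: ", paste(missing, collapse = ", "))
    }
    metadata <- metadata[match(colnames(counts), metadata$sample), , drop = FALSE]
    rownames(metadata) <- metadata$sample
  }
  structure(counts, metadata = metadata, class = c("abundance_matrix", "matrix"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d taxa x %d samples\n", nrow(x), ncol(x)))
  md <- attr(x, "metadata")
  if (!is.null(md)) {
    cat("metadata fields:", paste(setdiff(names(md), "sample"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample metadata of an abundance matrix
#' @param x An `abundance_matrix`.
#' @return The per-sample metadata data.frame (or NULL).
#' @export
sample_metadata <- function(x) attr(x, "metadata")

#' Convert counts to relative abundance
#'
#' Divides every column by its total so each sample sums to one. Already
#' relative input passes through unchanged (idempotent).
#'
#' @param x An `abundance_matrix` or plain numeric matrix.
#' @return Same shape and class as `x`, columns summing to 1.
#' @export
to_relative <- function(x) {
  totals <- colSums(x)
  zero <- totals == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(x)[zero], collapse = ", "))
  }
  out <- sweep(x, 2, totals, "/")
  if (inherits(x, "abundance_matrix")) {
    out <- structure(out, metadata = attr(x, "metadata"),
                     class = class(x))
  }
  out
}

#' Habitat specialisation index (coefficient of variation)
#'
#' For every taxon, the coefficient of variation (sample standard deviation,
#' n-1 denominator, divided by the mean) of its relative abundance across a
#' set of samples, together with its occupancy (fraction of samples where the
#' taxon is detected). Low values indicate broad, even occupancy (habitat
#' generalists); high values indicate narrow or patchy occupancy (habitat
#' specialists). A taxon detected in exactly one of n samples has
#' si = sqrt(n) regardless of its abundance.
#'
#' @param x Abundance matrix (counts or relative abundances; converted to
#'   relative abundance internally).
#' @param samples Optional character or logical vector selecting the sample
#'   subset over which to compute the index (at least 3 samples).
#' @param min_mean_rel Abundance floor: taxa whose mean relative abundance
#'   does not exceed this value are flagged absent and excluded from
#'   classification. The default 0 disables the floor; amplicon workflows
#'   conventionally use 5e-5 (0.005%).
#' @return A data.frame of class `specialisation_table` with columns
#'   `taxon`, `si`, `occupancy`, `mean_rel`, `absent` (logical: zero-mean or
#'   below-floor taxa, si = NA).
#' @export
specialisation_index <- function(x, samples = NULL, min_mean_rel = 0) {
  if (!is.null(samples)) x <- x[, samples, drop = FALSE]
  if (ncol(x) < 3) stop("specialisation index needs at least 3 samples")
  rel <- to_relative(x)
  m <- rowMeans(rel)
  s <- apply(rel, 1, stats::sd)
  occupancy <- rowMeans(rel > 0)
  absent <- m <= min_mean_rel
  si <- ifelse(absent, NA_real_, s / m)
  if (any(absent)) {
    warning(sum(absent), " taxa with zero or below-floor mean abundance ",
            "flagged absent and excluded from classification")
  }
  structure(
    data.frame(taxon = rownames(x), si = si, occupancy = occupancy,
               mean_rel = m, absent = absent, row.names = NULL,
               stringsAsFactors = FALSE),
    class = c("specialisation_table", "data.frame")
  )
}

#' Classify taxa into habitat generalists, intermediates, and specialists
#'
#' Quartile-based classification of the specialisation index: taxa strictly
#' below the first quartile of the si distribution are habitat generalists,
#' taxa strictly above the third quartile are habitat specialists, and the
#' interquartile range (including ties at either threshold) is intermediate.
#' Quartiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7) and are stored in the output for audit.
#'
#' @param table A `specialisation_table` from [specialisation_index()].
#' @return The table with added `habitat_class` column and columns/attributes
#'   `q1`, `q3`.
#' @export
classify_specialisation <- function(table) {
  si <- table$si[!is.na(table$si)]
  if (length(si) < 8) {
    stop("classification needs at least 8 taxa with a defined si ",
         "(quartiles unstable below that)")
  }
  q <- stats::quantile(si, c(0.25, 0.75), type = 7, names = FALSE)
  cls <- rep(NA_character_, nrow(table))
  ok <- !is.na(table$si)
  cls[ok] <- ifelse(table$si[ok] < q[1], "generalist",
                    ifelse(table$si[ok] > q[2], "specialist", "intermediate"))
  table$habitat_class <- cls
  table$q1 <- q[1]
  table$q3 <- q[2]
  attr(table, "q1") <- q[1]
  attr(table, "q3") <- q[2]
  table
}

#' @export
print.specialisation_table <- function(x, ...) {
  n_def <- sum(!is.na(x$si))
  cat(sprintf("specialisation_table: %d taxa (%d with defined si)\n",
              nrow(x), n_def))
  if (!is.null(x$habitat_class)) {
    tab <- table(x$habitat_class)
    cat(sprintf("  Q1 = %.4g, Q3 = %.4g\n", x$q1[1], x$q3[1]))
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  cat(sprintf("  mean si = %.4g +/- %.4g (sd)\n",
              mean(x$si, na.rm = TRUE), stats::sd(x$si, na.rm = TRUE)))
  invisible(x)
}

#' Summed relative abundance of each habitat class per sample group
#'
#' @param x Abundance matrix with metadata.
#' @param table Classified `specialisation_table`.
#' @param group_by Metadata column used to group samples (e.g. "age_class").
#' @return data.frame with one row per (group, class) plus the residual
#'   fraction carried by absent-flagged taxa.
#' @export
class_proportions <- function(x, table, group_by) {
  md <- sample_metadata(x)
  if (is.null(md) || !group_by %in% names(md)) {
    stop("unknown metadata key: ", group_by)
  }
  if (is.null(table$habitat_class)) stop("classes not assigned; run classify_specialisation()")
  rel <- to_relative(x)
  cls <- table$habitat_class[match(rownames(rel), table$taxon)]
  groups <- split(seq_len(ncol(rel)), md[[group_by]])
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (!length(idx)) {
      warning("group ", g, " empty after filtering; omitted")
      next
    }
    sample_mean <- rowMeans(rel[, idx, drop = FALSE])
    fr <- vapply(c("generalist", "intermediate", "specialist"), function(k) {
      sum(sample_mean[!is.na(cls) & cls == k])
    }, numeric(1))
    out[[g]] <- data.frame(
      group = g,
      generalist = fr[["generalist"]],
      intermediate = fr[["intermediate"]],
      specialist = fr[["specialist"]],
      residual = 1 - sum(fr),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Iterative collinearity filter for predictor tables
#'
#' While any pair of variables has absolute Pearson correlation at or above
#' the threshold, removes the lower-priority member of the worst-offending
#' pair. Constant variables (undefined correlation) are removed first with a
#' warning. Deterministic given the priority ordering.
#'
#' @param physico Numeric data.frame or matrix, samples x variables.
#' @param priority Character vector ordering all variables from most to least
#'   ecologically important.
#' @param r_threshold Absolute correlation threshold (default 0.9).
#' @return Character vector of retained variable names.
#' @export
collinearity_filter <- function(physico, priority, r_threshold = 0.9) {
  physico <- as.data.frame(physico)
  if (nrow(physico) < 3) stop("need at least 3 samples")
  vars <- colnames(physico)
  if (!setequal(vars, priority)) stop("priority must cover all variables exactly")
  rank <- match(vars, priority)
  const <- vapply(physico, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)), logical(1))
  if (any(const)) {
    warning("constant variable(s) removed: ", paste(vars[const], collapse = ", "))
    vars <- vars[!const]
  }
  repeat {
    if (length(vars) < 2) break
    cm <- abs(stats::cor(physico[, vars, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) < r_threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- vars[worst]
    drop <- pair[which.max(match(pair, priority))]
    vars <- setdiff(vars, drop)
  }
  vars
}

#' Read a taxon-by-sample abundance TSV
#'
#' Expected format: first column taxon id, remaining columns one per sample
#' with sample ids in the header.
#'
#' @param path Path to the abundance TSV.
#' @param metadata_path Optional path to a metadata TSV keyed by a `sample`
#'   column.
#' @return An `abundance_matrix`.
#' @export
read_abundance_tsv <- function(path, metadata_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  md <- if (!is.null(metadata_path)) {
    utils::read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  abundance_matrix(counts, md)
}

#' Write an abundance matrix (and optionally its metadata) as TSV
#' @param x An `abundance_matrix`.
#' @param path Output TSV path.
#' @param metadata_path Optional path for the metadata TSV.
#' @return Invisibly, `path`.
#' @export
write_abundance_tsv <- function(x, path, metadata_path = NULL) {
  df <- data.frame(taxon = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path) && !is.null(sample_metadata(x))) {
    utils::write.table(sample_metadata(x), metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a specialisation table as TSV
#' @param table A `specialisation_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_specialisation_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
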
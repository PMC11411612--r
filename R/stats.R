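#' @include classify.R
NULL

#' Summary statistics for descriptor distributions
#'
#' Mean, standard deviation (n-1 denominator) and order-statistic
#' percentiles for one or more descriptor columns, in the layout of a
#' property-distribution table (mean (SD), 50/75/90th percentile).
#'
#' @param x numeric vector, or a descriptor table (data.frame /
#'   DataFrame) whose numeric columns are each summarised
#' @param percentiles percentiles to report, default c(50, 75, 90)
#' @param quantileType quantile rule for [stats::quantile()]; the default
#'   6 is the (n+1)p empirical quantile used by common stats packages
#' @return a [S4Vectors::DataFrame] with one row per descriptor
#' @export
summariseDescriptors <- function(x, percentiles = c(50, 75, 90),
                                 quantileType = 6) {
  one <- function(v, name) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) stop("no non-missing values for ", name)
    q <- quantile(v, percentiles / 100, type = quantileType, names = FALSE)
    row <- data.frame(descriptor = name, n = length(v), mean = mean(v),
                      sd = if (length(v) > 1L) sd(v) else 0)
    for (i in seq_along(percentiles)) {
      row[[paste0("p", percentiles[i])]] <- q[i]
    }
    row
  }
  if (is.numeric(x)) {
    return(DataFrame(one(x, "value")))
  }
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  num[names(num) == "descriptor_failure"] <- FALSE
  if (!any(num)) stop("no numeric columns to summarise")
  DataFrame(do.call(rbind, lapply(names(d)[num], function(nm) one(d[[nm]], nm))))
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance
#' @return r-squared in \[0, 1\]
#' @export
pearsonR2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("r-squared undefined: zero variance in input")
  }
  cor(x, y)^2
}

#' Tukey-Kramer HSD all-pairs comparison
#'
#' Compares every pair of group means with the studentized-range
#' statistic, using the Kramer standard error for unequal group sizes:
#' q = |mi - mj| / sqrt(MSE/2 (1/ni + 1/nj)) with the pooled within-group
#' mean square. Adjusted p-values come from the studentized-range
#' distribution ([stats::ptukey()]) with k groups and N - k degrees of
#' freedom.
#'
#' @param values numeric response
#' @param groups group labels (coerced to factor), >= 2 groups with
#'   >= 2 observations each
#' @param alpha family-wise significance level, default 0.05
#' @return a [S4Vectors::DataFrame] of pairwise comparisons (`group1`,
#'   `group2`, `diff`, `se`, `q`, `p_adj`, `significant`); group means,
#'   sizes, pooled variance, df and alpha are in `metadata()`
#' @export
tukeyKramerHSD <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  ns <- tabulate(groups, k)
  if (any(ns < 2L)) {
    stop("every group needs at least 2 observations; undersized: ",
         paste(levels(groups)[ns < 2L], collapse = ", "))
  }
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  N <- length(values)
  df <- N - k
  mse <- sum((ns - 1) * vars) / df
  pairs <- utils::combn(levels(groups), 2)
  rows <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(mse / 2 * (1 / ns[match(i, levels(groups))] +
                          1 / ns[match(j, levels(groups))]))
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p_adj <- if (is.infinite(q)) 0 else
      ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = i, group2 = j, diff = diff, se = se, q = q,
               p_adj = p_adj)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  res <- DataFrame(out)
  metadata(res) <- list(means = as.list(means), n = as.list(setNames(ns,
    levels(groups))), mse = mse, df = df, alpha = alpha)
  res
}

.DEFAULT_BINS <- list(`2000-2009` = c(2000L, 2009L),
                      `2010-2019` = c(2010L, 2019L),
                      `2020-2022` = c(2020L, 2022L))

#' Temporal trend of approvals and rule-of-5 fails
#'
#' Bins approvals into periods (default 2000-2009, 2010-2019, 2020-2022)
#' and reports per bin the number of approvals, the number and percentage
#' of Lipinski fails, and the mean of each supplied descriptor.
#'
#' @param years integer approval years, one per compound
#' @param fails logical Lipinski verdicts, same length
#' @param descriptors optional descriptor table aligned with `years`;
#'   numeric columns are averaged per bin
#' @param bins named list of c(first, last) year pairs
#' @return a [S4Vectors::DataFrame] with one row per bin
#' @export
temporalTrend <- function(years, fails, descriptors = NULL,
                          bins = .DEFAULT_BINS) {
  stopifnot(length(years) == length(fails))
  years <- as.integer(years)
  lower <- vapply(bins, `[`, integer(1), 1L)
  upper <- vapply(bins, `[`, integer(1), 2L)
  binOf <- rep(NA_integer_, length(years))
  for (b in seq_along(bins)) {
    binOf[years >= lower[b] & years <= upper[b]] <- b
  }
  if (anyNA(binOf)) {
    stop("approval years outside all bins: ",
         paste(sort(unique(years[is.na(binOf)])), collapse = ", "))
  }
  rows <- lapply(seq_along(bins), function(b) {
    sel <- binOf == b
    row <- data.frame(period = names(bins)[b], n = sum(sel),
                      n_fails = sum(fails[sel]),
                      fail_pct = if (sum(sel)) 100 * mean(fails[sel]) else NA)
    if (!is.null(descriptors)) {
      d <- as.data.frame(descriptors)
      num <- vapply(d, is.numeric, logical(1))
      num[names(num) == "descriptor_failure"] <- FALSE
      for (nm in names(d)[num]) {
        row[[paste0("mean_", nm)]] <- mean(d[[nm]][sel], na.rm = TRUE)
      }
    }
    row
  })
  DataFrame(do.call(rbind, rows))
}

#' Compare descriptor distributions across a partition
#'
#' Summarises a descriptor per subset (pass/fail, macrocyclic or not,
#' ionisation class, ...) and runs a Tukey-Kramer HSD comparison across
#' the subsets. Subsets with fewer than 2 compounds are excluded with a
#' warning.
#'
#' @param descriptors descriptor table (one row per compound)
#' @param labels partition labels covering the rows
#' @param descriptor name of the descriptor column to compare
#' @param alpha significance level for the HSD test
#' @return list with elements `summary` (per-subset summary table) and
#'   `comparison` (the [tukeyKramerHSD()] result)
#' @export
subsetCompare <- function(descriptors, labels, descriptor = "mwt",
                          alpha = 0.05) {
  d <- as.data.frame(descriptors)
  stopifnot(descriptor %in% colnames(d), length(labels) == nrow(d))
  labels <- as.factor(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("subset(s) with fewer than 2 compounds excluded: ",
            paste(small, collapse = ", "))
  }
  keep <- !(labels %in% small) & !is.na(d[[descriptor]])
  v <- d[[descriptor]][keep]
  g <- droplevels(labels[keep])
  summaries <- do.call(rbind, lapply(levels(g), function(lv) {
    s <- as.data.frame(summariseDescriptors(v[g == lv]))
    s$descriptor <- descriptor
    cbind(subset = lv, s)
  }))
  list(summary = DataFrame(summaries),
       comparison = if (nlevels(g) >= 2L) {
         tukeyKramerHSD(v, g, alpha = alpha)
       })
}

#' Full property-space report
#'
#' Runs the complete 2D analysis on an [AnalysisSet] and (optionally)
#' writes the result tables as CSV files: full-set and fail-subset
#' summaries of the four rule-of-5 descriptors, flexibility/saturation
#' summaries, the macrocycle subset, descriptor correlations, the
#' percentile-derived rules, and temporal trends. If a shape table from
#' [shapeDescriptors()] is supplied, the NPR point cloud labelled by
#' Lipinski verdict is included for shape-triangle plotting.
#'
#' @param analysis an [AnalysisSet]
#' @param outDir optional directory to write the CSVs into
#' @param conventions descriptor conventions
#' @param shape optional [S4Vectors::DataFrame] of per-compound shape
#'   descriptors with an `id` column
#' @return (invisibly) a named list of all result tables
#' @export
propertyReport <- function(analysis, outDir = NULL,
                           conventions = descriptorConventions(),
                           shape = NULL) {
  stopifnot(is(analysis, "AnalysisSet"))
  rec <- drugRecords(analysis)
  desc <- computeDescriptors(analysis, conventions)
  lip <- lipinskiAssess(desc)
  macro <- isMacrocycle(rec$canonical_smiles)
  ion <- ionisationClass(rec$canonical_smiles)
  ro5 <- c("mwt", "clogp", "hbd", "hba")

  tables <- list()
  tables$table1 <- summariseDescriptors(desc[, ro5])
  failDesc <- desc[lip$fails, , drop = FALSE]
  tables$table2 <- if (sum(lip$fails) >= 1L)
    summariseDescriptors(failDesc[, ro5]) else NULL
  tables$table3 <- summariseDescriptors(
    desc[, c("rotatable_bonds", "aromatic_rings", "fsp3")])
  tables$table4 <- if (sum(macro) >= 1L)
    summariseDescriptors(desc[macro, c(ro5, "rotatable_bonds",
                                       "aromatic_rings")]) else NULL
  corm <- outer(ro5, ro5, Vectorize(function(a, b) {
    if (a == b) 1 else pearsonR2(desc[[a]], desc[[b]])
  }))
  dimnames(corm) <- list(ro5, ro5)
  tables$correlations <- corm
  tables$derived_rules <- derivePercentileRules(desc)
  tables$trends <- temporalTrend(rec$approval_year, lip$fails, desc)
  tables$lipinski <- lip
  tables$descriptors <- desc
  tables$macrocycle <- macro
  tables$ionisation <- ion
  if (!is.null(shape)) {
    sh <- as.data.frame(shape)
    sh$fails <- lip$fails[match(sh$id, desc$id)]
    tables$pmi_points <- DataFrame(sh)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(obj, name) {
      if (is.null(obj)) return()
      write.csv(as.data.frame(obj), file.path(outDir, paste0(name, ".csv")),
                row.names = is.matrix(obj))
    }
    wr(tables$table1, "table1"); wr(tables$table2, "table2")
    wr(tables$table3, "table3"); wr(tables$table4, "table4")
    wr(tables$correlations, "correlations")
    wr(tables$derived_rules, "derived_rules")
    wr(tables$trends, "trends")
    if (!is.null(shape)) wr(tables$pmi_points, "pmi_points")
  }
  invisible(tables)
}
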
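#' Pearson correlation between two measurement series
#'
#' Used to validate predicted against manually traced root distribution
#' parameters (Depth50, Width50) over a set of held-out images.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return The product-moment correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Broad-sense heritability from replicated accessions
#'
#' Estimates `H2 = V_G / V_P` by one-way random-effects variance
#' components: accessions are the random genetic factor, replicate
#' images within an accession supply the environmental (error)
#' variance. From the one-way ANOVA mean squares,
#' `V_G = (MS_accession - MS_error) / r` with `r` the harmonic mean
#' number of replicates (clipped at 0 when the estimate is negative),
#' and `V_P = V_G + MS_error`. H2 is unchanged by affine rescaling of
#' the trait, so cm and mm give the same estimate.
#'
#' @param table Data.frame with an `accession` column and the trait
#'   column.
#' @param trait Trait column name (e.g. `"depth50_cm"`).
#' @return A `heritability_result`: list with `H2`, `V_G`, `V_P`,
#'   `MS_accession`, `MS_error` and `replicates_effective`.
#' @export
broad_sense_heritability <- function(table, trait = "depth50_cm") {
  if (!all(c("accession", trait) %in% names(table)))
    stop("table must contain 'accession' and '", trait, "' columns")
  y <- table[[trait]]
  g <- factor(table$accession)
  if (nlevels(g) < 2L) stop("need at least 2 accessions")
  reps <- table(g)
  if (max(reps) < 2L) stop("need replicates within at least one accession")
  fit <- stats::aov(y ~ g)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_a <- ms[1]; ms_e <- ms[2]
  r_h <- length(reps) / sum(1 / as.numeric(reps))  # harmonic mean replicates
  v_g <- max(0, (ms_a - ms_e) / r_h)
  v_p <- v_g + ms_e
  if (v_p <= 0) stop("no phenotypic variance")
  structure(list(H2 = v_g / v_p, V_G = v_g, V_P = v_p,
                 MS_accession = ms_a, MS_error = ms_e,
                 replicates_effective = r_h),
            class = "heritability_result")
}

#' One-way fixed-effects ANOVA
#'
#' Tests for mean differences between groups (e.g. image acquisition
#' dates) with the classical F statistic on `(k - 1, N - k)` degrees of
#' freedom.
#'
#' @param groups List of numeric vectors, one per group; at least two
#'   groups of at least two values each.
#' @return List with `F`, `p_value`, `df1`, `df2`.
#' @export
oneway_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); N <- length(y)
  gm <- mean(y)
  means <- vapply(groups, mean, 1)
  ssb <- sum(vapply(groups, length, 1L) * (means - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0 && ssb == 0) return(list(F = 0, p_value = 1, df1 = df1, df2 = df2))
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' Rank-based analogue of the Tukey HSD for data without normality
#' (the use case here: comparing Depth50/Width50 between rice
#' subspecies). For each pair of groups, a Wilcoxon rank-sum statistic
#' is computed on that pair alone (midranks for ties), standardized,
#' and referred to the studentized range distribution with `k` groups
#' via the `q / sqrt(2)` convention, which controls the family-wise
#' error over all pairs.
#'
#' @param groups Named list of numeric vectors (at least 2 groups of at
#'   least 2 values).
#' @return Data.frame with `group1`, `group2`, `statistic` (standardized
#'   rank-sum) and `p_value`.
#' @export
steel_dwass <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  out <- NULL
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      xi <- groups[[i]]; xj <- groups[[j]]
      ni <- length(xi); nj <- length(xj); N <- ni + nj
      r <- rank(c(xi, xj))  # midranks
      W <- sum(r[seq_len(ni)])
      E <- ni * (N + 1) / 2
      V <- ni * nj / (N * (N - 1)) * sum((r - (N + 1) / 2)^2)
      tstat <- if (V > 0) (W - E) / sqrt(V) else 0
      p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = Inf,
                         lower.tail = FALSE)
      out <- rbind(out, data.frame(group1 = nm[i], group2 = nm[j],
                                   statistic = tstat, p_value = p,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Cluster accessions on standardized root distribution parameters
#'
#' Per-accession trait means are z-scored (mean 0, variance 1 per
#' trait) and clustered by agglomerative hierarchical clustering with
#' nearest-neighbour (single) linkage on Euclidean distances; the tree
#' is cut into `k` clusters. Complete linkage is available as an
#' alternative interpretation of the neighbour method.
#'
#' @param table Data.frame with `accession`, `depth50_cm` and
#'   `width50_cm` columns (one or more rows per accession).
#' @param k Number of clusters (default 5).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return List with `labels` (named integer vector of cluster ids),
#'   `tree` (the `hclust` object) and `scores` (the z-scored trait
#'   matrix).
#' @export
cluster_accessions <- function(table, k = 5L, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  need <- c("accession", "depth50_cm", "width50_cm")
  if (!all(need %in% names(table)))
    stop("table must contain columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(table[, c("depth50_cm", "width50_cm")],
                          by = list(accession = table$accession), FUN = mean)
  if (k > nrow(agg)) stop("k exceeds the number of accessions")
  m <- scale(as.matrix(agg[, c("depth50_cm", "width50_cm")]))
  rownames(m) <- agg$accession
  tree <- stats::hclust(stats::dist(m), method = linkage)
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree, scores = m)
}
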
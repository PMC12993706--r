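# Attribution of the calculated surface-temperature change: dynamic time
# warping ranks the decomposition components (already in degC, so no
# z-normalisation) by temporal closeness to dts_cal per season, and seasonal
# between-site differences are tested with ANOVA or Kruskal-Wallis depending
# on distributional checks.

#' Dynamic time warping distance
#'
#' Classic DTW with absolute-difference local cost, symmetric steps
#' (diagonal, horizontal, vertical), and no window constraint.
#' DTW(x, x) = 0 and the distance is symmetric.
#'
#' @param a,b numeric series (gap-free; see \code{\link{dtw_segments}} for
#'   gap handling).
#' @param min_length series shorter than this yield NA.
#' @return list with \code{distance} (summed cost along the optimal path)
#'   and \code{path_length} (number of steps on that path).
#' @export
dtw_distance <- function(a, b, min_length = 3) {
  n <- length(a); m <- length(b)
  if (n < min_length || m < min_length || anyNA(a) || anyNA(b)) {
    return(list(distance = NA_real_, path_length = NA_integer_))
  }
  cost <- abs(outer(a, b, "-"))
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- cost[i, j] +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  # backtrack for the path length; ties prefer the diagonal
  i <- n; j <- m; len <- 1L
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1 }
    else if (j == 1) { i <- i - 1 }
    else {
      choices <- c(D[i, j], D[i, j + 1], D[i + 1, j])
      pick <- which.min(choices)
      if (pick == 1) { i <- i - 1; j <- j - 1 }
      else if (pick == 2) { i <- i - 1 }
      else { j <- j - 1 }
    }
    len <- len + 1L
  }
  list(distance = D[n + 1, m + 1], path_length = len)
}

#' Gap-tolerant, path-normalised DTW distance
#'
#' Splits both series at positions where either has a gap, computes DTW on
#' each aligned gap-free segment of sufficient length, normalises each by
#' its warping-path length, and recombines the segment values weighted by
#' segment length.
#'
#' @param a,b equal-length numeric series with NA gaps.
#' @param min_length minimum segment length.
#' @return path-length-normalised distance (NA if no usable segment).
#' @export
dtw_segments <- function(a, b, min_length = 3) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  vals <- numeric(0); wts <- numeric(0)
  for (r in which(runs$values & runs$lengths >= min_length)) {
    idx <- starts[r]:ends[r]
    d <- dtw_distance(a[idx], b[idx], min_length)
    if (!is.na(d$distance)) {
      vals <- c(vals, d$distance / d$path_length)
      wts <- c(wts, length(idx))
    }
  }
  if (!length(vals)) return(NA_real_)
  sum(vals * wts) / sum(wts)
}

.dts_components <- c("d_alpha", "d_swdr", "d_lwdr", "d_eps",
                     "d_le", "d_h", "d_g", "d_i")

#' DTW similarity ranking of decomposition components
#'
#' Per (layer-implicit) group of kept decomposition days, computes the
#' gap-tolerant path-normalised DTW distance of each temperature-unit
#' component against dts_cal, then min-max scales across the eight
#' components to [0, 1]. Lower normalised distance = temporally closer.
#' Ties are broken by component name order.
#'
#' @param decomp decomposition table from \code{\link{decomposition_daily}}
#'   (kept days are used).
#' @param by grouping columns present in \code{decomp}, default
#'   \code{"season"}.
#' @param min_days minimum kept days per group.
#' @return data.frame: group columns, component, raw path-normalised
#'   distance, normalised distance in [0, 1], rank, n days.
#' @export
normalized_component_ranking <- function(decomp, by = "season",
                                         min_days = 10) {
  decomp <- decomp[decomp$kept, ]
  groups <- split(decomp, decomp[, by, drop = FALSE], drop = TRUE)
  rows <- lapply(groups, function(gd) {
    gd <- gd[order(gd$date), ]
    if (nrow(gd) < min_days) return(NULL)
    raw <- vapply(.dts_components, function(comp)
      dtw_segments(gd[[comp]], gd$dts_cal), numeric(1))
    rng <- range(raw, na.rm = TRUE)
    norm <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else raw * 0
    ord <- order(norm, .dts_components)
    rk <- integer(length(raw)); rk[ord] <- seq_along(ord)
    out <- data.frame(component = .dts_components, raw_distance = raw,
                      normalized = norm, rank = rk, n_days = nrow(gd),
                      row.names = NULL)
    for (col in rev(by)) out <- cbind(stats::setNames(
      data.frame(gd[[col]][1], stringsAsFactors = FALSE), col), out)
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# internal: compact letter display from a pairwise "significantly different"
# matrix. Letters are shared within maximal cliques of the
# not-significantly-different graph.
.compact_letters <- function(groups, diff_mat) {
  k <- length(groups)
  nsd <- !diff_mat
  diag(nsd) <- TRUE
  cliques <- list()
  for (size in k:1) {
    for (comb in utils::combn(k, size, simplify = FALSE)) {
      if (all(nsd[comb, comb])) {
        if (!any(vapply(cliques, function(cl) all(comb %in% cl), logical(1)))) {
          cliques <- c(cliques, list(comb))
        }
      }
    }
  }
  letters_out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cliques, function(cl) i %in% cl, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(letters_out, groups)
}

# internal: Dunn's rank-based post hoc test with Holm adjustment
.dunn_test <- function(values, labels) {
  ok <- !is.na(values)
  values <- values[ok]; labels <- factor(labels[ok])
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  grp <- levels(labels)
  pairs <- utils::combn(grp, 2, simplify = FALSE)
  p <- vapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    z <- (rbar[i] - rbar[j]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  data.frame(g1 = vapply(pairs, `[`, "", 1), g2 = vapply(pairs, `[`, "", 2),
             p_adj = stats::p.adjust(p, "holm"))
}

#' Seasonal between-site significance test
#'
#' Tests whether a daily variable differs among sites within one season.
#' Branch selection: Shapiro-Wilk normality per site and Levene
#' homoscedasticity at the same alpha choose one-way ANOVA with Tukey HSD;
#' any violation selects Kruskal-Wallis with Dunn's test (Holm-adjusted).
#' Sites sharing a compact-display letter are not significantly different.
#'
#' @param values daily values.
#' @param sites site labels, same length.
#' @param alpha significance level.
#' @param min_n minimum days per site.
#' @return list with \code{test} ("ANOVA" or "Kruskal-Wallis"),
#'   \code{statistic}, \code{p_value}, \code{letters} (named per site),
#'   \code{n}; or NULL with a message when n is insufficient.
#' @export
seasonal_group_test <- function(values, sites, alpha = 0.05, min_n = 8) {
  ok <- !is.na(values)
  values <- values[ok]; sites <- factor(as.character(sites[ok]))
  n <- table(sites)
  if (nlevels(sites) < 3 || any(n < min_n)) return(NULL)

  normal <- all(vapply(levels(sites), function(s) {
    v <- values[sites == s]
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v[seq_len(min(length(v), 5000))])$p.value > alpha
  }, logical(1)))
  homosced <- tryCatch(
    car::leveneTest(values ~ sites)[1, "Pr(>F)"] > alpha,
    error = function(e) FALSE)

  grp <- levels(sites)
  diff_mat <- matrix(FALSE, length(grp), length(grp),
                     dimnames = list(grp, grp))
  if (normal && homosced) {
    fit <- stats::aov(values ~ sites)
    an <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)$sites
    for (rn in rownames(tuk)) {
      pr <- strsplit(rn, "-", fixed = TRUE)[[1]]
      sig <- tuk[rn, "p adj"] < alpha
      diff_mat[pr[1], pr[2]] <- diff_mat[pr[2], pr[1]] <- sig
    }
    res <- list(test = "ANOVA", statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1])
  } else {
    kw <- stats::kruskal.test(values ~ sites)
    dn <- .dunn_test(values, sites)
    for (r in seq_len(nrow(dn))) {
      sig <- dn$p_adj[r] < alpha
      diff_mat[dn$g1[r], dn$g2[r]] <- diff_mat[dn$g2[r], dn$g1[r]] <- sig
    }
    res <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                p_value = kw$p.value)
  }
  res$letters <- .compact_letters(grp, diff_mat)
  res$n <- as.integer(n)
  res
}
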
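#' Summarize pulse fits per condition
#'
#' Per condition: number of cells, proportion classified ERK-pulse+, mean and
#' median pulse frequency (per hour), and mean basal activity — the
#' population summaries used to compare treatments.
#'
#' @param fits List of `pulse_fit` objects with condition labels.
#' @param recording_duration Recording length in minutes; defaults to each
#'   fit's own.
#' @return Data frame with one row per condition: `condition`, `n_cells`,
#'   `prop_pulse_pos`, `mean_frequency_per_h`, `median_frequency_per_h`,
#'   `mean_basal`.
#' @export
summarize_population <- function(fits, recording_duration = NULL) {
  df <- fits_to_df(fits)$cells
  if (any(is.na(df$condition))) {
    stop("all fits need a condition label", call. = FALSE)
  }
  if (!is.null(recording_duration)) {
    df$frequency_per_h <- df$n_pulses / recording_duration * 60
  }
  conds <- unique(df$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    d <- df[df$condition == cc, ]
    data.frame(condition = cc, n_cells = nrow(d),
               prop_pulse_pos = mean(d$classification == "pulse+"),
               mean_frequency_per_h = mean(d$frequency_per_h),
               median_frequency_per_h = stats::median(d$frequency_per_h),
               mean_basal = mean(d$basal))
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples: exact for small tie-free
#' samples, normal approximation with tie correction otherwise. The reported
#' statistic is `U(a, b)`, the number of pairs `(a_i, b_j)` with `a_i > b_j`
#' (counting ties as 1/2), so `U(a, b) + U(b, a) = length(a) * length(b)`.
#'
#' @param a,b Numeric samples (nonempty).
#' @return Data frame (`method`, `statistic`, `p`, `group1`, `group2`,
#'   `n1`, `n2`).
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1L) {
    # all observations tied: zero shift, no evidence either way
    u <- length(a) * length(b) / 2
    p <- 1
  } else if (!ties) {
    ht <- stats::wilcox.test(a, b, exact = TRUE, correct = TRUE)
    u <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    u <- unname(ht$statistic)
    p <- ht$p.value
  }
  data.frame(method = "Mann-Whitney U", statistic = u, p = p,
             group1 = "a", group2 = "b",
             n1 = length(a), n2 = length(b))
}

#' Steel-Dwass all-pairs comparison
#'
#' Nonparametric multiple comparison across three or more groups: every pair
#' is compared by its Wilcoxon rank statistic (computed on that pair only),
#' standardised with tie correction and referred to the Studentized-range
#' distribution over `k` groups, which controls the family-wise error rate.
#' Homoscedasticity is assessed with Bartlett's test and reported alongside
#' (not enforced).
#'
#' @param groups Named list of >= 3 nonempty numeric samples.
#' @return A list: `pairs`, a data frame with one row per pair (`group1`,
#'   `group2`, `statistic` — the standardised Studentized-range statistic —
#'   and `p`), and `bartlett_p`, the Bartlett homoscedasticity p-value.
#' @export
steel_dwass <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stop("need >= 3 groups; use mann_whitney() for two", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) == 0)) {
    stop("all groups must be nonempty", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  k <- length(groups)
  bart <- stats::bartlett.test(groups)$p.value
  combos <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(combos)), function(jj) {
    i <- combos[1, jj]; j <- combos[2, jj]
    x <- groups[[i]]; y <- groups[[j]]
    ni <- length(x); nj <- length(y)
    nn <- ni + nj
    r <- rank(c(x, y))
    ri <- sum(r[seq_len(ni)])
    e <- ni * (nn + 1) / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (nn * (nn - 1))
    v <- ni * nj / 12 * (nn + 1 - tie_term)
    stat <- if (v > 0) abs(ri - e) / sqrt(v) else 0
    p <- stats::ptukey(stat * sqrt(2), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               statistic = stat * sqrt(2), p = p)
  })
  list(pairs = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       bartlett_p = bart)
}

#' Chi-square tests with Benjamini-Hochberg adjustment
#'
#' Pearson chi-square test (no continuity correction) on each 2 x k count
#' table, with BH step-up adjustment of the p-values across tables —
#' the procedure used for families of proportion comparisons such as
#' ERK-pulse+ fractions across conditions.
#'
#' @param tables List of count matrices with nonnegative entries and positive
#'   row/column margins.
#' @return Data frame with one row per table: `table`, `statistic`, `df`,
#'   `p`, `adjusted_p` (BH; always >= `p` and <= 1).
#' @export
chi2_bh <- function(tables) {
  if (is.matrix(tables)) tables <- list(tables)
  if (length(tables) == 0) stop("need at least one table", call. = FALSE)
  res <- lapply(tables, function(tb) {
    tb <- as.matrix(tb)
    if (any(tb < 0)) stop("counts must be >= 0", call. = FALSE)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
      stop("every row and column margin must be positive", call. = FALSE)
    }
    ht <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
    c(statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  nm <- names(tables)
  out <- cbind(table = if (is.null(nm)) seq_along(tables) else nm, out)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
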
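#' Construct a differential-expression gene table
#'
#' @param gene character vector of unique gene identifiers.
#' @param log2fc numeric log2 fold changes.
#' @param significant logical significance flags.
#' @return data.frame of class `deg_table` with a derived `direction` column
#'   (`"up"`, `"down"`, or `NA` for a fold change of exactly 0).
#' @export
deg_table <- function(gene, log2fc, significant) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("gene ids must be unique")
  stopifnot(length(log2fc) == length(gene),
            length(significant) == length(gene))
  out <- data.frame(gene = gene, log2fc = as.numeric(log2fc),
                    significant = as.logical(significant))
  out$direction <- ifelse(out$log2fc > 0, "up",
                          ifelse(out$log2fc < 0, "down", NA_character_))
  class(out) <- c("deg_table", "data.frame")
  out
}

as_deg_table <- function(x) {
  if (inherits(x, "deg_table")) return(x)
  stopifnot(is.data.frame(x), all(c("gene", "log2fc", "significant") %in% names(x)))
  deg_table(x$gene, x$log2fc, x$significant)
}

#' Overlap and directional concordance of two significant gene sets
#'
#' Counts the overlap of the significant genes of two tables and, among
#' overlapping genes, how many agree in fold-change direction. Genes with a
#' log2 fold change of exactly 0 in either table carry no direction and are
#' excluded from the concordance tally (their count is reported).
#'
#' @param a,b differential-expression tables ([deg_table()] or data.frames
#'   with columns `gene`, `log2fc`, `significant`).
#' @return list: `n1`, `n2` (significant set sizes), `m` (overlap),
#'   `concordant`, `discordant`, `up_up`, `down_down`, `n_zero_direction`,
#'   `concordance_percent` (`NA` when `m = 0`).
#' @export
overlap_counts <- function(a, b) {
  a <- as_deg_table(a); b <- as_deg_table(b)
  sig_a <- a[a$significant, ]
  sig_b <- b[b$significant, ]
  shared <- intersect(sig_a$gene, sig_b$gene)
  m <- length(shared)
  da <- sig_a$direction[match(shared, sig_a$gene)]
  db <- sig_b$direction[match(shared, sig_b$gene)]
  has_dir <- !is.na(da) & !is.na(db)
  conc <- sum(da[has_dir] == db[has_dir])
  list(n1 = nrow(sig_a), n2 = nrow(sig_b), m = m,
       concordant = conc,
       discordant = sum(has_dir) - conc,
       up_up = sum(da[has_dir] == "up" & db[has_dir] == "up"),
       down_down = sum(da[has_dir] == "down" & db[has_dir] == "down"),
       n_zero_direction = m - sum(has_dir),
       concordance_percent = if (m > 0) concordance_percent(conc, m) else NA_real_)
}

#' Directional concordance percentage
#'
#' Reported as a truncated percentage (e.g. 483/510 = 94.7% prints as 94%),
#' the convention used when such overlaps are quoted as whole percents;
#' `digits` keeps more precision, still truncating.
#'
#' @param concordant number of overlapping genes with matching direction.
#' @param m overlap size (>= 1).
#' @param digits digits kept after the decimal point (default 0).
#' @return `100 * concordant / m`, truncated at `digits` decimals.
#' @export
concordance_percent <- function(concordant, m, digits = 0) {
  stopifnot(m >= 1, concordant <= m, concordant >= 0)
  floor(100 * concordant / m * 10^digits) / 10^digits
}

#' Representation factor of a gene-set overlap
#'
#' Observed overlap divided by the overlap expected for independent draws
#' from a shared universe: `RF = m / (n1 * n2 / N)`.
#'
#' @param m observed overlap.
#' @param n1,n2 significant set sizes.
#' @param N universe size (genes tested in both studies); must be supplied
#'   explicitly.
#' @return the representation factor.
#' @export
representation_factor <- function(m, n1, n2, N) {
  stopifnot(n1 <= N, n2 <= N, m <= min(n1, n2), m >= 0, N >= 1,
            n1 >= 1, n2 >= 1)
  m / (n1 * n2 / N)
}

#' Upper-tail hypergeometric p-value for a gene-set overlap
#'
#' `P(X >= m)` where `X ~ Hypergeometric(N, n1, n2)` is the overlap of two
#' random sets of sizes `n1`, `n2` drawn from a universe of `N` genes; the
#' standard companion test of the representation factor. Computed from the
#' hypergeometric distribution's log-scale tail for numerical stability.
#'
#' @inheritParams representation_factor
#' @return the upper-tail p-value.
#' @export
hypergeom_pvalue <- function(m, n1, n2, N) {
  stopifnot(n1 <= N, n2 <= N, m <= min(n1, n2), m >= 0)
  if (m == 0) return(1)
  # P(X >= m) = P(X > m - 1); log-scale evaluation, then exponentiate
  exp(stats::phyper(m - 1, n1, N - n1, n2, lower.tail = FALSE, log.p = TRUE))
}

#' Fold-change concordance regression for overlapping genes
#'
#' Ordinary least squares of one study's log2 fold changes on the other's
#' over the overlapping significant genes, with a 95% confidence band on the
#' mean response (the scatterplot-with-band comparison of two
#' differential-expression profiles).
#'
#' @param fc_a,fc_b paired numeric vectors of log2 fold changes (>= 3 pairs).
#' @param level confidence level for the band (default 0.95).
#' @return list of class `fc_regression`: `slope`, `intercept`, `r_squared`,
#'   `band` (data.frame `x`, `fit`, `lower`, `upper` at the observed x,
#'   sorted), `n`.
#' @export
fc_concordance_regression <- function(fc_a, fc_b, level = 0.95) {
  stopifnot(length(fc_a) == length(fc_b), length(fc_a) >= 3)
  d <- data.frame(x = fc_a, y = fc_b)
  fit <- stats::lm(y ~ x, data = d)
  ord <- order(d$x)
  pr <- suppressWarnings(
    stats::predict(fit, newdata = d[ord, ], interval = "confidence",
                   level = level))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 band = data.frame(x = d$x[ord], fit = pr[, "fit"],
                                   lower = pr[, "lwr"], upper = pr[, "upr"]),
                 n = length(fc_a)),
            class = "fc_regression")
}

#' @export
print.fc_regression <- function(x, ...) {
  cat(sprintf("Fold-change regression (n = %d): y = %.3f x + %.3f, R^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Full overlap analysis of two differential-expression tables
#'
#' Combines [overlap_counts()], [representation_factor()],
#' [hypergeom_pvalue()] and [fc_concordance_regression()] into one summary.
#'
#' @param a,b differential-expression tables.
#' @param universe_size number of genes tested in both studies (`N`); must
#'   be given explicitly, there is no silent default.
#' @return list of class `overlap_result`.
#' @export
analyze_overlap <- function(a, b, universe_size) {
  if (missing(universe_size))
    stop("universe_size (genes tested in both studies) must be supplied")
  a <- as_deg_table(a); b <- as_deg_table(b)
  cnt <- overlap_counts(a, b)
  rf <- representation_factor(cnt$m, cnt$n1, cnt$n2, universe_size)
  p <- hypergeom_pvalue(cnt$m, cnt$n1, cnt$n2, universe_size)
  sig_a <- a[a$significant, ]; sig_b <- b[b$significant, ]
  shared <- intersect(sig_a$gene, sig_b$gene)
  reg <- if (length(shared) >= 3)
    fc_concordance_regression(sig_a$log2fc[match(shared, sig_a$gene)],
                              sig_b$log2fc[match(shared, sig_b$gene)])
  else NULL
  structure(c(cnt, list(universe_size = universe_size,
                        representation_factor = rf,
                        p_value = p, regression = reg)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Gene-set overlap\n")
  cat(sprintf("  universe N = %d; set sizes %d and %d; overlap m = %d\n",
              x$universe_size, x$n1, x$n2, x$m))
  if (x$m > 0)
    cat(sprintf("  concordant %d/%d (%g%%); up-up %d, down-down %d\n",
                x$concordant, x$m, x$concordance_percent, x$up_up, x$down_down))
  cat(sprintf("  representation factor %.2f; upper-tail hypergeometric P = %.3g\n",
              x$representation_factor, x$p_value))
  if (!is.null(x$regression))
    print(x$regression)
  invisible(x)
}
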
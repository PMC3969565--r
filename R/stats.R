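#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional exact test: with margins fixed, the two-sided p-value is the
#' sum of hypergeometric point probabilities of all tables whose point
#' probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7, the standard convention). If any margin is
#' zero the table carries no information and p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `(a, b)` over `(c, d)`.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)   # 1
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1.0)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  min(1, p)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two samples. U is
#' computed from midranks (ties allowed). The two-sided p-value is exact --
#' by enumeration of all group labelings -- when `n1 + n2 <= 12`, and
#' otherwise uses the normal approximation with tie-corrected variance
#' (no continuity correction).
#'
#' @param xs,ys numeric vectors (both non-empty).
#' @return list with `U` (for `xs`) and `p_value` (two-sided).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$U  # 0
#' @export
mann_whitney_u <- function(xs, ys) {
  stopifnot(length(xs) >= 1, length(ys) >= 1)
  n1 <- length(xs); n2 <- length(ys)
  pooled <- c(xs, ys)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 12) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    mu <- n1 * n2 / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p_value = min(1, p))
}

#' Age-enrichment report of a gene set against a background
#'
#' Tests, per age group, whether the input set is over- or
#' under-represented relative to a background gene-age table (Fisher exact
#' on the 2x2 table input-in-group / input-not / background-in-group /
#' background-not, Bonferroni-corrected over the groups with non-empty
#' background), and globally whether the two age distributions differ
#' (Mann-Whitney U on the rank lists). Input genes present in the
#' background are removed from it before testing.
#'
#' @param input_ages data frame with columns `gene` and `rank` (e.g. from
#'   [assign_ages()]).
#' @param background data frame with columns `gene` and `rank`.
#' @param scale an [age_scale()].
#' @param mya optional named numeric mapping group name -> age in millions
#'   of years; when given, means/medians are also reported on that scale.
#' @return list of class `enrichment_report` with elements `per_group`
#'   (data frame: `rank`, `group`, `observed`, `background`, `p_fisher`,
#'   `p_adjusted`, `direction`), `u_test` (list `U`, `p_value`),
#'   `summary` (means/medians of input and background ages).
#' @export
age_enrichment_report <- function(input_ages, background,
                                  scale = default_age_scale(), mya = NULL) {
  stopifnot(all(c("gene", "rank") %in% names(input_ages)),
            all(c("gene", "rank") %in% names(background)))
  bg <- background[!background$gene %in% input_ages$gene, , drop = FALSE]
  if (!nrow(bg)) stop("background is empty after removing input genes")
  G <- nrow(scale)
  n_in <- nrow(input_ages)
  n_bg <- nrow(bg)
  obs <- tabulate(input_ages$rank, nbins = G)
  exp_ <- tabulate(bg$rank, nbins = G)
  m_tests <- sum(exp_ > 0)
  per <- lapply(seq_len(G), function(r) {
    a <- obs[r]; b <- n_in - a; c <- exp_[r]; d <- n_bg - c
    p <- fisher_exact_two_sided(a, b, c, d)
    prop_in <- if (n_in) a / n_in else 0
    prop_bg <- if (n_bg) c / n_bg else 0
    data.frame(rank = r, group = scale$name[r], observed = a, background = c,
               p_fisher = p, p_adjusted = min(1, p * m_tests),
               direction = if (prop_in > prop_bg) "over"
                           else if (prop_in < prop_bg) "under" else "equal",
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  u <- mann_whitney_u(input_ages$rank, bg$rank)
  to_units <- function(rk) {
    if (is.null(mya)) rk else unname(mya[scale$name[rk]])
  }
  ai <- to_units(input_ages$rank); ab <- to_units(bg$rank)
  summ <- list(mean_input = mean(ai), mean_background = mean(ab),
               median_input = stats::median(ai),
               median_background = stats::median(ab),
               units = if (is.null(mya)) "group rank" else "MYA",
               n_input = n_in, n_background = n_bg,
               bonferroni_m = m_tests)
  structure(list(per_group = per, u_test = u, summary = summ),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("Age enrichment:", x$summary$n_input, "input genes vs",
      x$summary$n_background, "background\n")
  sig <- x$per_group[x$per_group$p_adjusted < 0.05, , drop = FALSE]
  if (nrow(sig)) {
    cat("Significant groups (Bonferroni p < 0.05):\n")
    print.data.frame(sig, row.names = FALSE)
  } else cat("No group significant after Bonferroni correction\n")
  cat(sprintf("Mann-Whitney U = %g (p = %.3g)\n", x$u_test$U,
              x$u_test$p_value))
  invisible(x)
}
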
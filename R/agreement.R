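# Per-condition agreement analysis: chi-square tests of pooled Bouba/Kiki
# tallies against chance, cell classification, and the red/white/blue
# agreement matrix.

#' Chi-square test of a Bouba/Kiki tally against chance
#'
#' One-degree-of-freedom Pearson goodness-of-fit statistic of `kiki_count`
#' "Kiki" responses out of `n` against equal expected counts `n / 2`, without
#' continuity correction: `chi2 = (2 * kiki_count - n)^2 / n`.
#'
#' @param kiki_count number of "Kiki" responses (0..n).
#' @param n total trials (>= 1).
#' @return A list with `chi2` and `p_value` (two-sided, chi-square reference
#'   with 1 df).
#' @examples
#' chisq_against_chance(75, 100)  # chi2 = 25
#' @export
chisq_against_chance <- function(kiki_count, n) {
  .check_tally(kiki_count, n)
  chi2 <- (2 * kiki_count - n)^2 / n
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

.check_tally <- function(kiki_count, n) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(kiki_count < 0) || any(kiki_count > n))
    stop("`kiki_count` must lie in [0, n]", call. = FALSE)
  invisible(TRUE)
}

#' Classify one design cell as Bouba, Kiki or undetermined
#'
#' A cell is labelled `Kiki` when its pooled Kiki proportion exceeds one half
#' and differs significantly from chance, `Bouba` when the proportion falls
#' below one half significantly, and `undetermined` otherwise. The
#' significance band records the strongest conventional threshold the p value
#' passes (0.001, 0.01, 0.05, or `ns`).
#'
#' @inheritParams chisq_against_chance
#' @param alpha significance level separating determined from undetermined
#'   cells (default 0.05).
#' @param exact use an exact two-sided binomial test instead of the Pearson
#'   chi-square.
#' @return A one-row data frame with `n`, `kiki_count`, `proportion_kiki`,
#'   `chi2` (`NA` under `exact`), `p_value`, `label` and `significance_band`.
#' @export
classify_cell <- function(kiki_count, n, alpha = 0.05, exact = FALSE) {
  .check_tally(kiki_count, n)
  if (exact) {
    p <- binom.test(kiki_count, n, p = 0.5)$p.value
    chi2 <- NA_real_
  } else {
    ct <- chisq_against_chance(kiki_count, n)
    p <- ct$p_value
    chi2 <- ct$chi2
  }
  prop <- kiki_count / n
  label <- if (p < alpha && prop > 0.5) "Kiki"
           else if (p < alpha && prop < 0.5) "Bouba"
           else "undetermined"
  band <- if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01"
          else if (p < 0.05) "p<0.05" else "ns"
  data.frame(n = n, kiki_count = kiki_count, proportion_kiki = prop,
             chi2 = chi2, p_value = p, label = label,
             significance_band = band)
}

#' Per-condition agreement matrix
#'
#' Pools trials across participants within each design condition and
#' classifies every cell with [classify_cell()]. Cells of the design with no
#' trials are kept with a `missing` flag rather than fabricated.
#'
#' @param trials a trial data frame (see [simulate_group()] /
#'   [read_trials()]).
#' @param group optional group label to filter on (`"US"` or `"TW"`); by
#'   default all rows of `trials` are pooled.
#' @param design the [stimulus_design()] whose crossing defines the grid.
#' @param alpha,exact passed to [classify_cell()].
#' @return A data frame of class `"agreement_grid"`, one row per design
#'   condition, with the condition columns, all [classify_cell()] fields and
#'   a logical `missing` column.
#' @export
agreement_matrix <- function(trials, group = NULL,
                             design = stimulus_design(), alpha = 0.05,
                             exact = FALSE) {
  if (!is.null(group)) trials <- trials[trials$group == group, , drop = FALSE]
  grid <- design_grid(design)
  key <- function(f, a, s) paste(f, a, s, sep = "|")
  tk <- key(trials$frequency, trials$amplitude, trials$spikiness)
  gk <- key(grid$frequency, grid$amplitude, grid$spikiness)
  n <- as.vector(table(factor(tk, levels = gk)))
  kiki <- as.vector(tapply(trials$response, factor(tk, levels = gk), sum))
  kiki[is.na(kiki)] <- 0L
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (n[i] == 0) {
      rows[[i]] <- data.frame(n = 0L, kiki_count = 0L,
                              proportion_kiki = NA_real_, chi2 = NA_real_,
                              p_value = NA_real_, label = NA_character_,
                              significance_band = NA_character_)
    } else {
      rows[[i]] <- classify_cell(kiki[i], n[i], alpha = alpha, exact = exact)
    }
  }
  out <- cbind(grid, do.call(rbind, rows))
  out$missing <- out$n == 0
  class(out) <- c("agreement_grid", "data.frame")
  attr(out, "group") <- if (is.null(group)) "all" else group
  out
}

#' Compare the Kiki proportions of two tallies
#'
#' 2x2 contingency chi-square (no continuity correction) comparing the Kiki
#' proportions of two groups for one shape.
#'
#' @param count1,n1 Kiki count and total for the first group.
#' @param count2,n2 Kiki count and total for the second group.
#' @return A list with `chi2` and `p_value`.
#' @export
two_proportion_compare <- function(count1, n1, count2, n2) {
  .check_tally(count1, n1)
  .check_tally(count2, n2)
  tab <- matrix(c(count1, n1 - count1, count2, n2 - count2),
                nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Plot an agreement matrix
#'
#' Red (Bouba), blue (Kiki) and white (undetermined) tiles over the
#' frequency-by-amplitude grid, one panel per spikiness level, with colour
#' saturation graded by the significance band.
#'
#' @param cells an `"agreement_grid"` from [agreement_matrix()].
#' @return A ggplot object.
#' @export
plot_agreement <- function(cells) {
  if (!inherits(cells, "agreement_grid"))
    stop("`cells` must come from agreement_matrix()", call. = FALSE)
  d <- as.data.frame(cells)
  d <- d[!d$missing, , drop = FALSE]
  d$fill <- ifelse(d$label == "undetermined", "white",
                   ifelse(d$label == "Kiki", "blue", "red"))
  sat <- c("p<0.001" = 1, "p<0.01" = 0.65, "p<0.05" = 0.35, "ns" = 1)
  d$alpha <- sat[d$significance_band]
  d$spik_panel <- factor(paste("Spikiness", d$spikiness),
                         levels = paste("Spikiness",
                                        sort(unique(d$spikiness))))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$frequency),
                                  y = factor(.data$amplitude))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill,
                                    alpha = .data$alpha),
                       colour = "grey40") +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_alpha_identity() +
    ggplot2::facet_wrap(~spik_panel, nrow = 1) +
    ggplot2::labs(x = "Frequency", y = "Amplitude") +
    ggplot2::theme_minimal()
}
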
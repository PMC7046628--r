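# Dunn's post hoc test of pairwise mean-rank differences after a
# Kruskal-Wallis test, with tie correction; p-values Bonferroni-adjusted
# over all unordered pairs (the classical Dunn adjustment).
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(seq_along(lev), 2)
  res <- data.frame(group1 = lev[pairs[1, ]], group2 = lev[pairs[2, ]],
                    z = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i1] + 1 / n[i2]))
    res$z[j] <- (rbar[i1] - rbar[i2]) / se
  }
  p <- 2 * pnorm(-abs(res$z))
  res$p_adj <- stats::p.adjust(p, method = "bonferroni")
  res
}

#' Compare a metric across protocol groups
#'
#' Applies the study's statistical recipe: per-group normality screening by
#' the Lilliefors-corrected Kolmogorov-Smirnov test, then, by metric kind,
#' Kruskal-Wallis with Dunn's multiple-comparisons test for size metrics
#' (diameters, relative changes) or one-way ANOVA with Tukey's honest
#' significant differences for count metrics (segmentation results).
#' Adjusted p-values are reported for every unordered pair of groups.
#'
#' @param values a named list: one numeric vector of per-sample values per
#'   protocol group (at least 2 groups of at least 3 samples each).
#' @param metric_kind `"size"` or `"count"`; selects the test family.
#' @param metric_name label carried into the output.
#' @param alpha significance level (reported, not enforced).
#' @return an object of class `group_comparison` with fields `metric_name`,
#'   `metric_kind`, `groups`, `normality_p` (per group; `NA` for n < 4 or
#'   zero variance), `normality_method`, `test_used`, `omnibus_p`,
#'   `pairwise` (data frame `group1`, `group2`, `p_adj`), `alpha` and
#'   `degenerate` (`TRUE` when all values are identical).
#' @export
compare_groups <- function(values, metric_kind = c("size", "count"),
                           metric_name = "metric", alpha = 0.05) {
  metric_kind <- match.arg(metric_kind)
  if (!is.list(values) || length(values) < 2)
    stop("need at least 2 groups")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("groups must be named")
  sizes <- lengths(values)
  if (any(sizes < 3))
    stop("every group needs at least 3 samples; got: ",
         paste(sizes, collapse = ", "))
  lev <- names(values)
  v <- unlist(values, use.names = FALSE)
  g <- factor(rep(lev, sizes), levels = lev)
  normality_p <- vapply(values, function(x) {
    if (length(x) < 4 || sd(x) == 0) return(NA_real_)
    nortest::lillie.test(x)$p.value
  }, numeric(1))
  degenerate <- sd(v) == 0
  pairs <- utils::combn(seq_along(lev), 2)
  empty_pairwise <- data.frame(group1 = lev[pairs[1, ]],
                               group2 = lev[pairs[2, ]],
                               p_adj = NA_real_, stringsAsFactors = FALSE)
  if (degenerate) {
    test_used <- "none (degenerate: zero variance)"
    omnibus_p <- NA_real_
    pairwise <- empty_pairwise
  } else if (metric_kind == "size") {
    test_used <- "Kruskal-Wallis + Dunn (Bonferroni)"
    omnibus_p <- kruskal.test(v, g)$p.value
    pairwise <- dunn_test(v, g)[, c("group1", "group2", "p_adj")]
  } else {
    test_used <- "one-way ANOVA + Tukey HSD"
    fit <- aov(v ~ g)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$g
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group1 = vapply(nm, `[`, "", 2),
                           group2 = vapply(nm, `[`, "", 1),
                           p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
    rownames(pairwise) <- NULL
  }
  structure(list(metric_name = metric_name, metric_kind = metric_kind,
                 groups = lev, normality_p = normality_p,
                 normality_method = "Lilliefors (Kolmogorov-Smirnov)",
                 test_used = test_used, omnibus_p = omnibus_p,
                 pairwise = pairwise, alpha = alpha,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): %s\n", x$metric_name,
              x$metric_kind, x$test_used))
  if (!is.na(x$omnibus_p))
    cat(sprintf("  omnibus p = %.4g\n", x$omnibus_p))
  print(x$pairwise)
  invisible(x)
}

#' Aggregate results and write report artifacts
#'
#' Writes the raw result table, a per-protocol summary (mean and SD of
#' every metric per protocol and channel), and one pairwise-comparison CSV
#' per supplied [compare_groups()] object.  When depth profiles are given,
#' best-effort intensity-versus-depth and SNR-versus-depth overlay plots
#' (one curve per protocol) are rendered as PNG.
#'
#' @param results a [result_table()].
#' @param comparisons a list of `group_comparison` objects (possibly
#'   empty).
#' @param out_dir output directory, created if needed.
#' @param profiles optional named list (one element per protocol) of
#'   [z_profile()] or [snr_profile()] objects for the overlay plot.
#' @return invisibly, the paths written.
#' @export
build_report <- function(results, comparisons = list(), out_dir,
                         profiles = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(out_dir, "results.csv")
  write_results(results, p)
  paths <- c(paths, p)
  df <- as.data.frame(results)
  summ <- aggregate(value ~ protocol + channel + metric_name, df,
                    function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  summ <- cbind(summ[, c("protocol", "channel", "metric_name")],
                as.data.frame(summ$value))
  summ <- summ[order(summ$metric_name, summ$channel, summ$protocol), ]
  p <- file.path(out_dir, "summary.csv")
  write.csv(summ, p, row.names = FALSE)
  paths <- c(paths, p)
  for (cmp in comparisons) {
    p <- file.path(out_dir, paste0("pairwise_", cmp$metric_name, ".csv"))
    meta <- data.frame(group1 = "", group2 = "",
                       p_adj = NA_real_)[0, ]
    out <- cmp$pairwise
    out$metric_name <- cmp$metric_name
    out$test_used <- cmp$test_used
    out$normality_method <- cmp$normality_method
    write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(profiles) && length(profiles)) {
    try({
      p <- file.path(out_dir, "depth_profiles.png")
      grDevices::png(p, width = 900, height = 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      cols <- grDevices::hcl.colors(length(profiles), "Dark 3")
      is_snr <- inherits(profiles[[1]], "snr_profile")
      ylab <- if (is_snr) "SNR" else "mean intensity"
      yv <- function(pr) if (is_snr) pr$snr else pr$mean_intensity
      xlim <- range(unlist(lapply(profiles, `[[`, "normalized_depths_um")))
      ylim <- range(unlist(lapply(profiles, yv)), na.rm = TRUE)
      graphics::plot(NA, xlim = xlim, ylim = ylim,
                     xlab = "normalized depth (um)", ylab = ylab)
      for (i in seq_along(profiles))
        graphics::lines(profiles[[i]]$normalized_depths_um,
                        yv(profiles[[i]]), col = cols[i], lwd = 2)
      if (is_snr) graphics::abline(h = 5, lty = 2)
      graphics::legend("topright", legend = names(profiles), col = cols,
                       lwd = 2, bty = "n")
      paths <- c(paths, p)
    }, silent = TRUE)
  }
  invisible(paths)
}
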
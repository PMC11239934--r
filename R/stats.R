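#' Mean and standard error of the mean
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' sqrt(n), the summary convention used throughout the package
#' (mean +/- SEM).  With n < 2 the SEM is undefined and returned as NA
#' with a flag.
#'
#' @param values numeric vector.
#' @return list (mean, sem, n, sem_defined).
#' @export
meanSem <- function(values) {
  n <- length(values)
  if (n == 0L) stop("empty sample")
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n,
       sem_defined = n >= 2L)
}

#' Significance star code for a p-value
#'
#' Strict-inequality thresholds: p < 0.05 "*", p < 0.01 "**",
#' p < 0.001 "***", otherwise "ns" (so exactly p = 0.05 is "ns").
#'
#' @param p p-value in [0, 1].
#' @return one of "ns", "*", "**", "***".
#' @export
starCode <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Unpaired two-tailed t-test between two groups
#'
#' Pooled-variance Student's test by default (\code{variant = "welch"}
#' for the unequal-variance form), two-tailed, with per-group
#' mean +/- SEM attached.  Degenerate inputs are resolved explicitly:
#' zero variance in both groups with equal means gives t = 0, p = 1;
#' zero variance with unequal means is an infinite-t edge case reported
#' as p = 0 with a warning.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param variant "student" or "welch".
#' @param names optional group labels (length 2).
#' @return object of class \code{GroupStats}: list with \code{groups}
#'   (data.frame name, n, mean, sem), \code{t}, \code{df}, \code{p},
#'   \code{star}, \code{variant}.
#' @export
tTestUnpaired <- function(a, b, variant = c("student", "welch"),
                          names = c("a", "b")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (is.null(names)) names <- c("a", "b")
  ga <- meanSem(a); gb <- meanSem(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (ga$mean == gb$mean) {
      t <- 0; p <- 1
    } else {
      warning("zero variance with unequal means: infinite t, p reported as 0")
      t <- sign(ga$mean - gb$mean) * Inf; p <- 0
    }
    df <- if (variant == "student") length(a) + length(b) - 2L else NA_real_
  } else {
    tt <- stats::t.test(a, b, var.equal = (variant == "student"),
                        alternative = "two.sided")
    t <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(
    groups = data.frame(name = names,
                        n = c(ga$n, gb$n),
                        mean = c(ga$mean, gb$mean),
                        sem = c(ga$sem, gb$sem)),
    t = t, df = df, p = p, star = starCode(p), variant = variant
  ), class = "GroupStats")
}

#' @export
print.GroupStats <- function(x, ...) {
  cat(sprintf("Unpaired two-tailed t-test (%s)\n", x$variant))
  for (i in 1:2) {
    g <- x$groups[i, ]
    cat(sprintf("  %s: mean %.4g +/- %.4g SEM (n = %d)\n",
                g$name, g$mean, g$sem, g$n))
  }
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g  [%s]\n",
              x$t, x$df, x$p, x$star))
  invisible(x)
}

#' One summary row for a GroupStats object
#' @param gs a \code{GroupStats}.
#' @param comparison label for the comparison.
#' @return one-row data.frame.
#' @export
groupStatsRow <- function(gs, comparison = "") {
  data.frame(comparison = comparison,
             group1 = gs$groups$name[1], n1 = gs$groups$n[1],
             mean1 = gs$groups$mean[1], sem1 = gs$groups$sem[1],
             group2 = gs$groups$name[2], n2 = gs$groups$n[2],
             mean2 = gs$groups$mean[2], sem2 = gs$groups$sem[2],
             t = gs$t, df = gs$df, p = gs$p, star = gs$star,
             variant = gs$variant)
}
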
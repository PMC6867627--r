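#' Compare two motility fingerprints
#'
#' Per-cell parameters (`v_run`, `p_run`, `q`) are compared with two-sided
#' Welch two-sample t-tests on the per-cell values; the state lifetimes,
#' being population-level fit quantities, are compared by overlap of their
#' 99% confidence intervals. The summary additionally counts how many of
#' the five fingerprint parameters shifted significantly toward lower
#' motility in condition `b` (lower `v_run`, `tau_run`, `p_run`, `q`;
#' higher `tau_rest`).
#'
#' @param a,b [fingerprint()] objects for the two conditions.
#' @param alpha Significance level for the t-tests.
#' @param pooled_variance Use the pooled-variance Student t-test instead of
#'   the Welch default.
#'
#' @return Object of class `fingerprint_comparison`: list with `table`
#'   (one row per parameter: values, difference `b - a`, statistic,
#'   p-value or CI-overlap flag, significance) and `lower_motility_count`.
#' @export
compare_fingerprints <- function(a, b, alpha = 0.05, pooled_variance = FALSE) {
  stopifnot(inherits(a, "motility_fingerprint"),
            inherits(b, "motility_fingerprint"))
  cell_params <- c("v_run", "p_run", "q")
  rows <- vector("list", 5L)
  for (i in seq_along(cell_params)) {
    p <- cell_params[[i]]
    xa <- a$per_cell[[p]]
    xb <- b$per_cell[[p]]
    xa <- xa[is.finite(xa)]
    xb <- xb[is.finite(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("parameter ", p, " has fewer than 2 defined values in a condition")
    }
    if (stats::sd(c(xa, xb)) == 0) {
      stop("degenerate variance for parameter ", p,
           ": all values identical in both groups")
    }
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      stop("degenerate variance for parameter ", p)
    }
    tt <- stats::t.test(xb, xa, var.equal = pooled_variance)
    rows[[i]] <- data.frame(
      parameter = p, value_a = mean(xa), value_b = mean(xb),
      difference = mean(xb) - mean(xa),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      significant = tt$p.value < alpha,
      method = if (pooled_variance) "student_t" else "welch_t",
      stringsAsFactors = FALSE)
  }
  tau_row <- function(nm, fa, fb) {
    if (is.null(fa) || is.null(fb)) {
      return(data.frame(parameter = nm, value_a = NA_real_, value_b = NA_real_,
                        difference = NA_real_, statistic = NA_real_,
                        p_value = NA_real_, significant = NA,
                        method = "ci99_overlap", stringsAsFactors = FALSE))
    }
    overlap <- fa$ci[1L] <= fb$ci[2L] && fb$ci[1L] <= fa$ci[2L]
    data.frame(parameter = nm, value_a = fa$tau, value_b = fb$tau,
               difference = fb$tau - fa$tau, statistic = NA_real_,
               p_value = NA_real_, significant = !overlap,
               method = "ci99_overlap", stringsAsFactors = FALSE)
  }
  rows[[4L]] <- tau_row("tau_run", a$tau_run, b$tau_run)
  rows[[5L]] <- tau_row("tau_rest", a$tau_rest, b$tau_rest)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  expected_sign <- c(v_run = -1, p_run = -1, q = -1, tau_run = -1, tau_rest = 1)
  shifted <- vapply(names(expected_sign), function(p) {
    r <- tab[tab$parameter == p, ]
    isTRUE(r$significant) && sign(r$difference) == expected_sign[[p]]
  }, logical(1))
  structure(list(table = tab, lower_motility_count = sum(shifted),
                 alpha = alpha),
            class = "fingerprint_comparison")
}

#' @export
print.fingerprint_comparison <- function(x, ...) {
  cat("fingerprint comparison (difference = b - a):\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("parameters shifted toward lower motility in b: %d / 5\n",
              x$lower_motility_count))
  invisible(x)
}
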
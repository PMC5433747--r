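#' @export
print.metashift_sim <- function(x, ...) {
  cat(sprintf("metashift simulation (%s scenario, alpha = %g, seed %g)\n",
              x$config$scenario, x$config$alpha, x$seed))
  cat(sprintf("  stable phase: %d years (%s), %d native species\n",
              x$stable$years,
              if (x$stable$converged) "converged" else "cap reached",
              length(x$natives)))
  cat(sprintf("  after warming: %d natives remain (%.1f%% richness change, %.1f%% gamma-diversity change)\n",
              x$post$regional_richness, x$pct_change_richness,
              x$pct_change_gamma_div))
  invisible(x)
}

#' Summarise a single simulation run
#'
#' @param object a `metashift_sim` object.
#' @param ... unused.
#' @return data frame with one row per phase (stable, post) of the native
#'   response variables, printed together with event counts.
#' @export
summary.metashift_sim <- function(object, ...) {
  fields <- c("local_richness_mean", "regional_richness", "alpha_div",
              "beta_div", "gamma_div", "jaccard_mean", "cwm_geomean_sm",
              "lag_mean_C", "lag_sm_corr")
  row <- function(ph) {
    vals <- object[[ph]][fields]
    vals[vapply(vals, is.null, logical(1))] <- NA_real_
    as.data.frame(vals)
  }
  out <- rbind(row("stable"), row("post"))
  rownames(out) <- c("stable", "post")
  print(out, digits = 4)
  cat(sprintf(
    "\nwarming-phase events per patch: %.2f colonisations, %.2f exclusions\n",
    object$colonisations_per_patch, object$exclusions_per_patch))
  cat(sprintf("percent change: richness %+.1f%%, gamma diversity %+.1f%%\n",
              object$pct_change_richness, object$pct_change_gamma_div))
  invisible(out)
}

#' Plot a simulation run
#'
#' Two panels: regional native richness and gamma diversity through the
#' warming and settling years, and the final distribution of biomass along
#' the gradient coloured by thermal optimum rank.
#'
#' @param x a `metashift_sim` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metashift_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  yr <- x$yearly
  graphics::plot(yr$year, yr$gamma_richness, type = "l", lwd = 2,
                 xlab = "year since warming onset",
                 ylab = "regional richness", main = "richness", ...)
  graphics::abline(v = x$config$warming_years, lty = 3)
  xs <- x$landscape$patches$x
  tot <- rowSums(x$post$B_end)
  cwm_topt <- as.vector(x$post$B_end %*% x$traits$T_opt) /
    pmax(tot, .Machine$double.eps)
  graphics::plot(xs, cwm_topt, pch = 19,
                 col = grDevices::hcl.colors(10, "Zissou 1")[
                   cut(tot, 10, labels = FALSE)],
                 xlab = "gradient position (km)",
                 ylab = "CWM thermal optimum (degC)",
                 main = "final communities")
  invisible(x)
}

#' @export
print.metashift_ensemble <- function(x, ...) {
  cat(sprintf(
    "metashift ensemble: %d replicates, %s scenario, alpha = %g\n",
    nrow(x$summary), x$config$scenario, x$config$alpha))
  keys <- c("stable_regional_richness", "stable_gamma_div",
            "pct_change_richness", "pct_change_gamma_div",
            "colonisations_per_patch", "exclusions_per_patch")
  m <- x$mean[keys]
  cat(sprintf("  stable gamma richness %.1f, gamma diversity %.1f\n",
              m[1], m[2]))
  cat(sprintf("  after warming: %+.1f%% richness, %+.1f%% gamma diversity\n",
              m[3], m[4]))
  cat(sprintf("  events per patch: %.2f colonisations, %.2f exclusions\n",
              m[5], m[6]))
  invisible(x)
}

#' Summarise a replicated ensemble
#'
#' @param object a `metashift_ensemble` object.
#' @param ... unused.
#' @return data frame of replicate means and standard deviations for the
#'   main response variables.
#' @export
summary.metashift_ensemble <- function(object, ...) {
  df <- object$summary
  num <- vapply(df, is.numeric, logical(1))
  num[c("replicate", "seed")] <- FALSE
  vals <- df[, num, drop = FALSE]
  out <- data.frame(mean = colMeans(vals, na.rm = TRUE),
                    sd = apply(vals, 2, stats::sd, na.rm = TRUE))
  print(round(out, 3))
  invisible(out)
}
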
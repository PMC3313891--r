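#' @export
print.km_recon <- function(x, ...) {
  km <- x$km
  cat("Reconstructed Kaplan-Meier data -- arm '", x$arm, "'\n", sep = "")
  cat(sprintf("  %d curve coordinates, %d risk-table interval(s), information level '%s'\n",
              nrow(km), nrow(x$intervals), x$level))
  left <- km$n_hat[nrow(km)] - km$d_hat[nrow(km)] - km$cen_hat[nrow(km)]
  cat(sprintf("  patients: %d   events: %d   censored: %d (+%d at end of follow-up)\n",
              km$n_hat[1], sum(km$d_hat), sum(km$cen_hat), left))
  if (!is.na(x$tot_events))
    cat(sprintf("  reported event total: %d\n", x$tot_events))
  cat(sprintf("  survival at last coordinate (t=%g): %.4f (curve read %.4f)\n",
              km$time[nrow(km)], km$S_km[nrow(km)], x$curve$surv[nrow(km)]))
  if (length(x$diagnostics))
    cat("  diagnostics:", length(x$diagnostics), "message(s); see summary()\n")
  invisible(x)
}

#' @export
summary.km_recon <- function(object, ...) {
  structure(list(fit = object), class = "summary.km_recon")
}

#' @export
print.summary.km_recon <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPer-interval censoring fit:\n")
  print(fit$intervals, row.names = FALSE)
  if (length(fit$diagnostics)) {
    cat("\nDiagnostics:\n")
    cat(paste0("  - ", fit$diagnostics, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.km_recon <- function(x, ...) x$km

#' Plot a reconstruction against the digitized coordinates
#'
#' Draws the reconstructed product-limit step function with the digitized
#' coordinates overlaid, the basic visual check that the inversion tracked
#' the published curve.
#'
#' @param x a `km_recon` fit.
#' @param ... passed to [plot()].
#' @export
plot.km_recon <- function(x, ...) {
  km <- x$km
  plot(km$time, km$S_km, type = "s", ylim = c(0, 1),
       xlab = "time", ylab = "survival",
       main = paste0("Reconstructed KM curve -- ", x$arm), ...)
  points(x$curve$time, x$curve$surv, pch = 3, cex = 0.6, col = "grey40")
  legend("bottomleft", bty = "n", pch = c(NA, 3), lty = c(1, NA),
         col = c("black", "grey40"),
         legend = c("reconstructed", "digitized"))
  invisible(x)
}
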
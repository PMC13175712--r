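#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(ess - K - 1)`. The effective sample
#' size `ess` defaults, for fitted objects, to the number of detection
#' opportunities of the observed individuals (`M_{t+1}` times the total
#' number of secondary occasions).
#'
#' @param log_lik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param ess Effective sample size (> K + 1).
#' @return AICc (scalar).
#' @export
aicc <- function(log_lik, K, ess) {
  if (ess <= K + 1)
    stop("effective sample size must exceed K + 1 for AICc", call. = FALSE)
  -2 * log_lik + 2 * K + 2 * K * (K + 1) / (ess - K - 1)
}

#' Rank candidate model fits by AICc
#'
#' Builds the standard model-selection table: AICc, difference to the best
#' model (`delta_aicc`), Akaike weights `W = exp(-delta/2) / sum(...)`, and
#' parameter counts, sorted ascending by AICc. Ties are broken by smaller K
#' and then by model name, so the table is deterministic. All fits must be
#' to the same data and use the same likelihood mode (full-likelihood and
#' conditional-likelihood AICc values are not comparable).
#'
#' @param fits List of `"rd_fit"` objects.
#' @param ess Effective sample size; defaults to the common `ess` of the
#'   fits.
#' @return A data frame of class `"rd_model_table"` with columns `model`,
#'   `K`, `aicc`, `delta_aicc`, `weight`, `log_lik`, `converged`.
#' @export
rank_models <- function(fits, ess = NULL) {
  if (inherits(fits, "rd_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "rd_fit")))
  lik <- unique(vapply(fits, `[[`, "", "likelihood"))
  if (length(lik) != 1)
    stop("cannot rank full-likelihood and conditional fits together: ",
         "their AICc values are not comparable", call. = FALSE)
  datakey <- vapply(fits, function(f)
    paste(dim(f$data$detections), sum(f$data$detections), collapse = "-"),
    "")
  if (length(unique(datakey)) != 1)
    stop("all fits must be to the same dataset", call. = FALSE)
  if (!all(vapply(fits, `[[`, TRUE, "converged")))
    warning("ranking includes non-converged fits", call. = FALSE)
  if (is.null(ess)) ess <- fits[[1]]$ess
  tab <- data.frame(
    model = vapply(fits, function(f) format(f$model), ""),
    K = vapply(fits, `[[`, 0L, "K"),
    log_lik = vapply(fits, `[[`, 0, "log_lik"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE)
  tab$aicc <- mapply(aicc, tab$log_lik, tab$K, MoreArgs = list(ess = ess))
  ord <- order(tab$aicc, tab$K, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  tab <- tab[, c("model", "K", "aicc", "delta_aicc", "weight", "log_lik",
                 "converged")]
  class(tab) <- c("rd_model_table", "data.frame")
  attr(tab, "ess") <- ess
  tab
}

#' @export
print.rd_model_table <- function(x, digits = 3, ...) {
  cat("Model-selection table (AICc, effective sample size ",
      attr(x, "ess"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$aicc <- round(df$aicc, digits)
  df$delta_aicc <- round(df$delta_aicc, digits)
  df$weight <- round(df$weight, digits)
  df$log_lik <- round(df$log_lik, digits)
  print(df, right = FALSE)
  invisible(x)
}
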
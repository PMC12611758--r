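# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.rate_model <- function(x, ...) {
  tibble(channel = x$channel, observed = x$m, opportunity = x$n,
         rate = x$rate, flagged = x$flagged)
}

#' @export
glance.rate_model <- function(x, ...) {
  tibble(mean_rate = attr(x, "rbar"), pseudocount = attr(x, "pseudocount"),
         n_flagged_channels = sum(x$flagged),
         indel_rate = attr(x, "indel_rate"))
}

#' @export
tidy.exposure_fit <- function(x, ...) {
  tibble(signature = names(x$exposures), exposure = unname(x$exposures))
}

#' @export
glance.exposure_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_mutations = x$n_mutations,
         n_signatures = length(x$exposures))
}

#' @export
tidy.burden_regression <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         conf.low = c(x$intercept_ci[1], x$slope_ci[1]),
         conf.high = c(x$intercept_ci[2], x$slope_ci[2]))
}

#' @export
glance.burden_regression <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n, n_excluded = length(x$excluded))
}

#' @export
tidy.duplex_calls <- function(x, ...) {
  as_tibble(x$calls)
}

#' @export
glance.duplex_calls <- function(x, ...) {
  tibble(sample = x$sample_id, n_candidates = nrow(x$calls),
         n_pass = sum(x$calls$filter == "PASS"),
         mean_dx = mean(x$coverage$depth), covered_sites = nrow(x$coverage))
}
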
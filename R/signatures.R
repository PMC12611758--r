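# Fixed-signature exposure fitting.
#
# Exposures of a fixed set of reference signatures are estimated by
# multinomial maximum likelihood over the simplex, via the standard EM
# updates (equivalent to projected-gradient ascent at convergence). De novo
# signature extraction is out of scope.

#' Fit signature exposures by multinomial maximum likelihood
#'
#' Reference signatures are opportunity-adjusted to the observed sequence
#' composition before fitting (channel probability rescaled by the ratio of
#' observed to genome opportunities, then renormalised), so that exposures
#' refer to the mutational processes rather than the panel composition.
#'
#' @param catalogue a `mut_catalogue` (or tibble `channel`, `count`).
#' @param signatures reference signatures in COSMIC-style layout: a tibble
#'   with a `channel` column and one column per signature (probabilities), or
#'   a numeric matrix with channels as rows.
#' @param observed_opportunities,genome_opportunities optional opportunity
#'   tibbles (`channel`, `opportunity`) for the composition adjustment; when
#'   either is missing, signatures are used as given.
#' @param max_iter,tol EM controls.
#' @return an `exposure_fit`: list with `exposures` (named, sums to one),
#'   `loglik`, `fitted` (fitted channel probabilities), `signatures` (the
#'   adjusted matrix) and `n_mutations`.
#' @export
fit_exposures <- function(catalogue, signatures,
                          observed_opportunities = NULL,
                          genome_opportunities = NULL,
                          max_iter = 5000, tol = 1e-12) {
  cat_df <- as_tibble(catalogue)
  counts <- cat_df$count
  if (is.data.frame(signatures)) {
    sig_df <- as_tibble(signatures)
    assert_that("channel" %in% names(sig_df),
                "signature tibble needs a channel column")
    sig_df <- sig_df[match(cat_df$channel, sig_df$channel), ]
    S <- as.matrix(sig_df[, setdiff(names(sig_df), "channel")])
  } else {
    S <- as.matrix(signatures)
  }
  assert_that(ncol(S) >= 1, "need at least one reference signature")
  assert_that(nrow(S) == length(counts), "signature/catalogue channel mismatch")
  if (!is.null(observed_opportunities) && !is.null(genome_opportunities)) {
    oo <- rename(as_tibble(observed_opportunities), o = "opportunity")
    go <- rename(as_tibble(genome_opportunities), g = "opportunity")
    adj <- left_join(left_join(cat_df["channel"], oo, by = "channel"), go,
                     by = "channel")
    ratio <- ifelse(adj$g > 0, adj$o / adj$g, 0)
    S <- S * ratio
    S <- sweep(S, 2, colSums(S), "/")
  }
  K <- ncol(S)
  if (K > 1 && any(duplicated(t(round(S, 12))))) {
    warn("degenerate (identical) reference signatures; exposures not unique")
  }
  e <- rep(1 / K, K)
  n <- sum(counts)
  assert_that(n > 0, "empty catalogue")
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    p <- as.vector(S %*% e)
    p[p <= 0] <- .Machine$double.xmin
    # EM update: responsibility-weighted counts per signature
    resp <- sweep(S, 1, counts / p, "*")
    e_new <- colSums(resp) * e
    e_new <- e_new / sum(e_new)
    ll_new <- sum(counts * log(as.vector(S %*% e_new)))
    if (is.finite(ll) && abs(ll_new - ll) < tol * abs(ll_new)) {
      e <- e_new
      ll <- ll_new
      break
    }
    e <- e_new
    ll <- ll_new
  }
  names(e) <- colnames(S) %||% paste0("sig", seq_len(K))
  structure(list(exposures = e, loglik = ll,
                 fitted = as.vector(S %*% e), signatures = S,
                 n_mutations = n, channels = cat_df$channel),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("<exposure_fit> ", x$n_mutations, " mutations; exposures: ",
      paste(names(x$exposures), round(x$exposures, 3), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Signature burdens from an exposure fit
#'
#' Multiplies exposure estimates by a whole-genome mutation burden, so each
#' signature's contribution is expressed in mutations (per cell/genome, in
#' the units of `total_burden`). Signature burdens sum to the total.
#'
#' @param fit an `exposure_fit`.
#' @param total_burden total burden to apportion.
#' @return tibble `signature`, `exposure`, `burden`.
#' @export
signature_burdens <- function(fit, total_burden) {
  tibble(signature = names(fit$exposures),
         exposure = unname(fit$exposures),
         burden = unname(fit$exposures) * total_burden)
}

#' Read / write reference signatures in COSMIC-style TSV layout
#'
#' @param path TSV with a `channel` column and one column per signature.
#' @return tibble of signatures.
#' @export
read_signatures_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_signatures_tsv
#' @param signatures signature tibble to write.
#' @export
write_signatures_tsv <- function(signatures, path) {
  readr::write_tsv(signatures, path)
  invisible(path)
}
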
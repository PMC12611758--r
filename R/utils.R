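#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols n distinct rename
#'   pull across if_else count slice row_number first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom tidyr unnest pivot_longer pivot_wider replace_na
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl walk
#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats ppois qgamma pchisq qchisq uniroot rpois rbinom rexp
#'   runif rnorm quantile median ks.test lm coef confint p.adjust rmultinom
#'   setNames optimize complete.cases poisson.test
#' @importFrom utils head tail
NULL

the_bases <- c("A", "C", "G", "T")

base_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

complement <- function(x) chartr("ACGTN", "TGCAN", x)

is_pyrimidine <- function(b) b %in% c("C", "T")

#' Derive a reproducible sub-seed from a base seed
#'
#' All stochastic stages draw their seeds from one base seed through named
#' substreams, so that a whole pipeline run is reproducible from a single
#' integer.
#'
#' @param seed integer base seed.
#' @param stream character stream name.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

assert_that <- function(ok, msg, class = "duplexome_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
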
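#' Derive a reproducible sub-seed from a run seed and a stage tag
#'
#' A single run seed fans out to stage-specific sub-streams so that adding or
#' reordering a pipeline stage never perturbs the randomness consumed by
#' earlier stages. The tag is hashed with a small polynomial rolling hash and
#' folded into the seed modulo 2^31 - 1, keeping the result a valid 32-bit
#' integer seed.
#'
#' @param seed Integer run seed (non-negative).
#' @param tag Character scalar naming the consumer (e.g. `"cohort_params"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "choices_phase1")
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.character(tag), length(tag) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- seed %% m
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% m
  as.integer(h)
}

clip01 <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_domain <- function(domain) {
  if (!all(domain %in% c("monetary", "medical"))) {
    stop("unknown domain: ", paste(setdiff(domain, c("monetary", "medical")),
                                   collapse = ", "), call. = FALSE)
  }
  invisible(domain)
}
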
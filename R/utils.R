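#' Derive a reproducible child seed from a parent seed and tags
#'
#' One global seed drives the whole pipeline; each subject, fold, or null
#' ensemble gets its own substream by hashing the parent seed together with
#' small integer tags. Keeps every derived seed a valid 32-bit R integer so
#' independently re-running one subject reproduces it exactly.
#'
#' @param seed parent integer seed
#' @param ... integer tags (e.g. subject index, density index)
#' @return a single integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    # 32-bit mixing in double arithmetic (exact below 2^53)
    h <- (h * 69069 + as.numeric(t) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' AAL-116 region lookup table
#'
#' Index, label, hemisphere and a coarse resting-state-network tag for the
#' 116 regions of the Automated Anatomical Labeling atlas used as network
#' nodes. The network column is an approximate many-to-one assignment for
#' reporting (hub tables), not an analysis input.
#'
#' @return data.frame with columns `index`, `label`, `hemisphere`, `network`
#' @export
aal116 <- function() {
  path <- system.file("extdata", "aal116.csv", package = "adhdnet")
  if (path == "") path <- file.path("inst", "extdata", "aal116.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    stop(name, " must be a single positive integer", call. = FALSE)
  }
}
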
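#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n lag lead row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile sd cor rpois runif rlnorm setNames p.adjust
#'   wilcox.test complete.cases
#' @importFrom utils head tail
NULL

# Classed conditions so callers/tests can distinguish failure modes.
stop_parse <- function(msg, ...) abort(msg, class = "dinotad_parse_error", ...)
stop_coord <- function(msg, ...) abort(msg, class = "dinotad_coordinate_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "dinotad_config_error", ...)
stop_numeric <- function(msg, ...) abort(msg, class = "dinotad_numeric_error", ...)

#' Derive a stage seed from a root seed
#'
#' All randomness in the package flows from one root seed; each stage uses a
#' deterministic offset so stages are independent but jointly reproducible.
#' Result is kept within the 32-bit integer range.
#'
#' @param seed Root seed (non-negative integer).
#' @param stage Integer stage offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage = 0L) {
  s <- (as.double(seed) %% 1e6) * 2111 + as.double(stage) * 7919 + 13
  as.integer(s %% 2147483647)
}

# Random DNA of length n, chunked to keep memory flat for long chromosomes.
rand_dna <- function(n) {
  if (n <= 0) return("")
  chunk <- 1e6L
  pieces <- character(0)
  left <- as.integer(n)
  while (left > 0L) {
    k <- min(chunk, left)
    pieces <- c(pieces, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = ""))
    left <- left - k
  }
  paste(pieces, collapse = "")
}

# quantile helper returning a scalar
q_at <- function(x, p) unname(quantile(x, p, na.rm = TRUE, names = FALSE))
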
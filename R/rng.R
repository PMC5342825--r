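# Seed fan-out: one root seed, one named substream per independent source of
# randomness, so adding ROIs or trials never perturbs unrelated draws.

#' Derive a deterministic substream seed from a root seed and a stream name
#'
#' @param seed root integer seed.
#' @param stream character label of the random stream.
#' @return an integer in \code{[0, 2^31 - 59)}, suitable for \code{set.seed}.
#' @examples
#' substream_seed(1, "traces")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L, nzchar(stream))
  h <- sum(as.numeric(utf8ToInt(stream)) * seq_len(nchar(stream)))
  # modulus is prime and < 2^31 so the result is always a valid R seed
  as.integer((abs(seed) %% 2147483587 * 7919 + h * 104729) %% 2147483587)
}
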
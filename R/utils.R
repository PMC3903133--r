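#' @useDynLib smburst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# FNV-1a hash of an object's JSON rendering; used to stamp outputs with a
# configuration fingerprint without a hashing dependency.
config_hash <- function(x) {
  s <- jsonlite::toJSON(rapply(x, function(v) v, how = "list"),
                        auto_unbox = TRUE, digits = 10, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  # FNV-1a folded to 31 bits so R's integer bitwXor stays in range
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

# derive a stream-specific 32-bit seed from a base seed
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}
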
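# one-letter codes of the 20 standard amino acids, alphabetical
AA_CODES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# average amino-acid composition of well-characterised proteins (fractions);
# used as the default residue-identity distribution for synthetic bundles
AA_BACKGROUND <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0672, G = 0.0707, H = 0.0227, I = 0.0591,
  L = 0.0965, K = 0.0580, M = 0.0241, F = 0.0386, P = 0.0474,
  S = 0.0665, T = 0.0536, W = 0.0110, Y = 0.0292, V = 0.0686
)

REGIONS <- c("protein", "tunnel", "cofactor")
ORIENTATIONS <- c("pathogenic_high", "pathogenic_low")

# run code with a local, restorable RNG state so generators with explicit
# seeds never disturb the caller's random stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
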
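#' @importFrom rlang %||% abort warn
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows n count across distinct rename
#'   pull if_else row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats dnorm pnorm qnorm rnorm rpois rnbinom runif median sd
#'   ks.test fisher.test p.adjust hclust cutree dist setNames quantile
#'   complete.cases coef resid
#' @importFrom utils head tail
NULL

# Fixed per-operation offsets added to the master seed so that each generator
# stage draws from its own stream and upstream changes do not shift
# downstream draws.
.seed_offsets <- c(
  library = 101L, counts = 202L, expression = 303L, peaks = 404L,
  fit = 505L, bootstrap = 606L
)

.set_stream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.seed_offsets))
  set.seed((as.integer(seed) + .seed_offsets[[stream]]) %% .Machine$integer.max)
}

.dna_alphabet <- c("A", "C", "G", "T")

# n random DNA sequences of length len, as a character vector
.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(.dna_alphabet, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.shuffle_dna <- function(seq) {
  vapply(strsplit(seq, ""), function(ch) paste0(sample(ch), collapse = ""), "")
}

#' Reverse-complement a DNA string
#'
#' Vectorised reverse complement over the A/C/G/T/N alphabet.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x)) {
    abort(sprintf("configuration error: `%s` must be a positive integer", name))
  }
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("configuration error: `%s` must be > 0", name))
  }
}

.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("configuration error: `%s` must be in [0, 1]", name))
  }
}
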
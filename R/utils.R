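#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join desc n count rename
#' @importFrom stats lm coef pt rpois rbinom runif rnorm setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base (purine<->purine, pyrimidine<->pyrimidine)
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# fixed 12-nt J-region anchor appended 3' of the junction in synthetic reads,
# so that junction extraction has a well-defined right boundary
J_ANCHOR <- "GGTCAAGGAACC"

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "shmrep_validation_error")
}

check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x)) {
    abort(sprintf("%s contains characters outside {%s}", what,
                  paste(s2c(alphabet), collapse = ",")),
          class = "shmrep_validation_error")
  }
  invisible(x)
}

#' Translate a nucleotide string in frame 0
#'
#' Thin wrapper over the standard genetic code; used for productivity checks
#' and replacement/silent classification. `X` is returned for codons
#' containing non-ACGT characters.
#'
#' @param nt nucleotide string whose length is a multiple of 3
#' @return amino-acid string, with `*` for stop codons
#' @keywords internal
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) abort("length of `nt` must be a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# deterministic substream seed for clone k under root seed (kept < 2^31)
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) + as.double(k) * 1000003) %% 2147483629)
}
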
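#' Packaged synthetic germline V reference
#'
#' A 294-nt synthetic stand-in for a murine heavy-chain germline V segment
#' (it is *not* a natural sequence), stop-free in frame 0, with IMGT-style
#' region boundaries: FR1 1-78, CDR1 79-102, FR2 103-153, CDR2 154-177,
#' FR3 178-294 (1-based, inclusive). Used as the default reference for
#' simulations and examples so the package needs no external data.
#'
#' @return a [germline_reference()].
#' @export
#' @examples
#' ref <- synthetic_reference()
#' ref$region_bounds
synthetic_reference <- function() {
  load_reference(
    system.file("extdata", "synthetic_vh.fasta", package = "shmrep",
                mustWork = TRUE),
    system.file("extdata", "synthetic_vh_regions.tsv", package = "shmrep",
                mustWork = TRUE))
}
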
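#' Classify a substitution as transition or transversion
#'
#' Transitions are the purine-to-purine and pyrimidine-to-pyrimidine changes
#' (A<->G, C<->T); every other base change is a transversion. AID-initiated
#' somatic hypermutation is characterised by an excess of transitions.
#'
#' @param from,to character vectors of single bases in `{A,C,G,T}`; pairs must
#'   differ position-wise.
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
#' @examples
#' classify_substitution("C", "T")
#' classify_substitution(c("G", "C"), c("A", "A"))
classify_substitution <- function(from, to) {
  from <- toupper(from)
  to <- toupper(to)
  if (length(from) != length(to)) abort("`from` and `to` must have equal length")
  if (!all(from %in% DNA_BASES) || !all(to %in% DNA_BASES)) {
    abort("bases must be in {A,C,G,T}")
  }
  if (any(from == to)) abort("`from` and `to` must differ (not a substitution)")
  unname(ifelse(TRANSITION_PARTNER[from] == to, "transition", "transversion"))
}

#' Classify the 5-mer context of a mutated base
#'
#' The mutated base sits at the centre of a 5-mer read 5'-3'. Contexts are
#' scored against the canonical AID targeting motifs: WRC/GYW and WA/TW are
#' hotspots, SYC/GRS are coldspots, everything else is neutral
#' (W = A/T, R = A/G, Y = C/T, S = C/G; the underlined base of the motif is
#' the 5-mer centre).
#'
#' @param fivemer character vector of 5-mers over `{A,C,G,T}`.
#' @return character vector with values `"hotspot_WRC_GYW"`, `"hotspot_WA_TW"`,
#'   `"coldspot_SYC_GRS"` or `"neutral"`.
#' @export
#' @examples
#' classify_context("TACGT")  # WRC hotspot
#' classify_context("GTCAA")  # SYC coldspot
classify_context <- function(fivemer) {
  fivemer <- toupper(fivemer)
  if (any(nchar(fivemer) != 5L)) abort("contexts must be 5-mers")
  if (any(grepl("[^ACGT]", fivemer))) abort("contexts must be over {A,C,G,T}")
  context_class(fivemer)
}

# vectorised, no validation; NA in -> "unscored" out
context_class <- function(fivemer) {
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T"); S <- c("C", "G")
  p1 <- substr(fivemer, 1L, 1L)
  p2 <- substr(fivemer, 2L, 2L)
  ctr <- substr(fivemer, 3L, 3L)
  p4 <- substr(fivemer, 4L, 4L)
  p5 <- substr(fivemer, 5L, 5L)
  out <- rep("neutral", length(fivemer))
  out[ctr == "C" & p1 %in% W & p2 %in% R] <- "hotspot_WRC_GYW"
  out[ctr == "G" & p4 %in% Y & p5 %in% W] <- "hotspot_WRC_GYW"
  out[ctr == "A" & p2 %in% W] <- "hotspot_WA_TW"
  out[ctr == "T" & p4 %in% W] <- "hotspot_WA_TW"
  out[ctr == "C" & p1 %in% S & p2 %in% Y] <- "coldspot_SYC_GRS"
  out[ctr == "G" & p4 %in% R & p5 %in% S] <- "coldspot_SYC_GRS"
  out[is.na(fivemer)] <- "unscored"
  out
}

# collapse the detailed context class to hotspot/neutral/coldspot
context_group <- function(class) {
  dplyr::case_when(
    class %in% c("hotspot_WRC_GYW", "hotspot_WA_TW") ~ "hotspot",
    class == "coldspot_SYC_GRS" ~ "coldspot",
    class == "neutral" ~ "neutral",
    TRUE ~ "unscored"
  )
}
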
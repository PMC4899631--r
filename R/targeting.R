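#' SHM targeting model
#'
#' Relative per-site mutabilities used by the synthetic-repertoire generator.
#' Each position's rate is determined by the class of its 5-mer context on the
#' current sequence: AID hotspots (WRC/GYW and WA/TW), coldspots (SYC/GRS) or
#' neutral contexts. An optional per-5-mer override table takes precedence
#' over the class rates. Substitutions are drawn as the transition partner
#' with probability `transition_fraction`, otherwise uniformly between the two
#' transversion partners.
#'
#' @param hot_mutability relative rate for hotspot contexts (default 5).
#' @param cold_mutability relative rate for coldspot contexts (default 0.2).
#' @param neutral_mutability relative rate for neutral contexts and for the
#'   first/last two positions of a sequence, which lack a full 5-mer.
#' @param transition_fraction probability in `[0,1]` that a substitution is
#'   the transition partner of the germline base (default 0.6).
#' @param override optional named numeric vector mapping 5-mers to rates.
#' @return an object of class `targeting_model`.
#' @export
targeting_model <- function(hot_mutability = 5,
                            cold_mutability = 0.2,
                            neutral_mutability = 1,
                            transition_fraction = 0.6,
                            override = NULL) {
  for (f in c("hot_mutability", "cold_mutability", "neutral_mutability")) {
    v <- get(f)
    if (!is_scalar_number(v) || v < 0) stop_field(f, "must be a non-negative number")
  }
  if (!is_scalar_number(transition_fraction) ||
      transition_fraction < 0 || transition_fraction > 1) {
    stop_field("transition_fraction", "must be in [0,1]")
  }
  if (!is.null(override)) {
    if (is.null(names(override)) || any(names(override) == "")) {
      stop_field("override", "must be a named numeric vector keyed by 5-mer")
    }
    keys <- toupper(names(override))
    if (any(nchar(keys) != 5L) || any(grepl("[^ACGT]", keys))) {
      stop_field("override", "keys must be 5-mers over {A,C,G,T}")
    }
    if (!is.numeric(override) || any(!is.finite(override)) || any(override < 0)) {
      stop_field("override", "rates must be non-negative numbers")
    }
    names(override) <- keys
  }
  structure(
    list(hot_mutability = hot_mutability,
         cold_mutability = cold_mutability,
         neutral_mutability = neutral_mutability,
         transition_fraction = transition_fraction,
         override = override),
    class = "targeting_model"
  )
}

#' Per-position mutability of a sequence under a targeting model
#'
#' Evaluates the model on the sequence as it currently stands: each position's
#' 5-mer is looked up in the override table, else scored by its context class.
#' The first and last two positions have no complete 5-mer and receive the
#' neutral rate.
#'
#' @param sequence nucleotide string or character vector of single bases.
#' @param model a [targeting_model()].
#' @return numeric vector of relative rates, one per position.
#' @export
position_mutability <- function(sequence, model) {
  stopifnot(inherits(model, "targeting_model"))
  chars <- if (length(sequence) == 1L) s2c(sequence) else sequence
  L <- length(chars)
  rates <- rep(model$neutral_mutability, L)
  if (L >= 5L) {
    idx <- 3:(L - 2L)
    fivemers <- paste0(chars[idx - 2L], chars[idx - 1L], chars[idx],
                       chars[idx + 1L], chars[idx + 2L])
    cls <- context_class(fivemers)
    r <- rep(model$neutral_mutability, length(idx))
    r[cls %in% c("hotspot_WRC_GYW", "hotspot_WA_TW")] <- model$hot_mutability
    r[cls == "coldspot_SYC_GRS"] <- model$cold_mutability
    if (!is.null(model$override)) {
      hit <- match(fivemers, names(model$override))
      r[!is.na(hit)] <- model$override[hit[!is.na(hit)]]
    }
    rates[idx] <- r
  }
  rates
}

# draw a replacement base for `from` under the model's transition bias
draw_substitution <- function(from, transition_fraction) {
  partner <- TRANSITION_PARTNER[[from]]
  if (runif(1) < transition_fraction) {
    partner
  } else {
    others <- setdiff(DNA_BASES, c(from, partner))
    others[[sample.int(2L, 1L)]]
  }
}
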
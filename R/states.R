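#' Substrate-preference state vocabulary
#'
#' The package works with a closed three-state ecological character:
#' where a mammal nests or resides. States are always indexed in the fixed
#' order arboreal, semi-arboreal, nonarboreal; every rate matrix, probability
#' vector and count matrix in the package uses this ordering.
#'
#' @return Character vector `c("arboreal", "semi-arboreal", "nonarboreal")`.
#' @export
arb_states <- function() c("arboreal", "semi-arboreal", "nonarboreal")

# Accepted spellings, lower-cased, mapped to the canonical vocabulary.
.state_aliases <- c(
  "arboreal"       = "arboreal",
  "a"              = "arboreal",
  "arb"            = "arboreal",
  "semi-arboreal"  = "semi-arboreal",
  "semiarboreal"   = "semi-arboreal",
  "semi_arboreal"  = "semi-arboreal",
  "semi arboreal"  = "semi-arboreal",
  "s"              = "semi-arboreal",
  "semi"           = "semi-arboreal",
  "nonarboreal"    = "nonarboreal",
  "non-arboreal"   = "nonarboreal",
  "non_arboreal"   = "nonarboreal",
  "non arboreal"   = "nonarboreal",
  "n"              = "nonarboreal",
  "non"            = "nonarboreal"
)

#' Normalize state labels to the canonical vocabulary
#'
#' Case-insensitive; accepts the single-letter codes A/S/N and common
#' hyphen/underscore variants of "semi-arboreal" and "nonarboreal".
#'
#' @param x character vector of raw state labels.
#' @return character vector of canonical labels (see [arb_states()]).
#' @export
normalize_states <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.state_aliases[key])
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop("unknown character state(s) at row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(x[bad]), collapse = ", "),
         " (valid: ", paste(arb_states(), collapse = ", "), ")",
         call. = FALSE)
  }
  out
}

# Integer index (1..3) of observed states in the canonical order.
state_index <- function(x) match(normalize_states(x), arb_states())
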